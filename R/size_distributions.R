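#' Default log-spaced diameter bin grid
#'
#' 256 logarithmically spaced bin edges spanning 1.4 to 42 µm, a plausible
#' measurable range for a 70 µm electrical-sensing-zone aperture.
#'
#' @param n_edges Number of edges (bins = `n_edges - 1`).
#' @param lower,upper Range in µm.
#' @return Numeric vector of strictly increasing bin edges.
#' @export
default_bin_grid <- function(n_edges = 256, lower = 1.4, upper = 42) {
  stopifnot(n_edges >= 2, lower > 0, upper > lower)
  exp(seq(log(lower), log(upper), length.out = n_edges))
}

#' Bin per-particle diameters onto a grid
#'
#' Bins are half-open `[lower, upper)`: a diameter exactly on an edge falls
#' in the bin to its right. Diameters outside the grid are an error, so
#' that binning conserves the total particle count exactly.
#'
#' @param data A raw-dialect `particle_sizes` object.
#' @param edges Strictly increasing bin edges in µm; defaults to
#'   [default_bin_grid()].
#' @return A binned `particle_sizes` object with the same metadata.
#' @export
bin_particles <- function(data, edges = default_bin_grid()) {
  stopifnot(inherits(data, "particle_sizes"))
  if (attr(data, "dialect") != "raw") stop("bin_particles() needs raw per-particle data", call. = FALSE)
  stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  d <- data$diameter
  if (any(d < edges[1] | d >= edges[length(edges)])) {
    stop("diameters outside the bin grid; extend `edges`", call. = FALSE)
  }
  idx <- findInterval(d, edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  particle_sizes_binned(edges[-length(edges)], edges[-1], counts,
    meta = attr(data, "meta")
  )
}

as_binned <- function(data, edges = default_bin_grid()) {
  if (attr(data, "dialect") == "raw") bin_particles(data, edges) else data
}

#' Number- or volume-weighted relative size distribution
#'
#' Converts particle counts into the relative distributions the instrument
#' software plots: the share of total particle *number* per diameter bin,
#' or the share of total starch *volume*, where each bin's count is
#' weighted by the volume of a sphere at the bin's representative diameter,
#' \eqn{(\pi/6) d^3}. The representative diameter of a bin is the geometric
#' mean of its edges, consistent with the log-normal modelling downstream.
#'
#' @param data A `particle_sizes` object (raw data is binned on `edges`
#'   first).
#' @param weighting `"number"` or `"volume"`.
#' @param edges Bin grid used when `data` is raw.
#' @return A tibble of class `size_distribution` with columns `diameter`
#'   (bin midpoints, µm), `share` (percent, summing to 100), `bin_width`
#'   (µm) and attribute `weighting`.
#' @export
#' @examples
#' d <- particle_sizes_binned(c(8, 16), c(12.5, 25), c(8, 1))
#' to_distribution(d, "volume")
to_distribution <- function(data, weighting = c("number", "volume"),
                            edges = default_bin_grid()) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(data, "particle_sizes"))
  data <- as_binned(data, edges)
  if (sum(data$count) < 1) stop("empty particle data", call. = FALSE)
  mid <- sqrt(data$bin_lower * data$bin_upper)
  w <- if (weighting == "volume") data$count * (pi / 6) * mid^3 else data$count
  share <- 100 * w / sum(w)
  structure(
    tibble::tibble(
      diameter = mid,
      share = share,
      bin_width = data$bin_upper - data$bin_lower
    ),
    weighting = weighting,
    class = c("size_distribution", class(tibble::tibble()))
  )
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "<size_distribution: %s-weighted, %d bins, %.3g-%.3g um>\n",
    attr(x, "weighting"), nrow(x), min(x$diameter), max(x$diameter)
  ))
  NextMethod()
}

#' Export a size distribution as CSV
#'
#' Columns `diameter_um,share_percent`, for plotting parity with the
#' instrument's relative volume/number vs. diameter plots.
#'
#' @param dist A `size_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  readr::write_csv(
    tibble::tibble(diameter_um = dist$diameter, share_percent = dist$share),
    path,
    progress = FALSE
  )
  invisible(path)
}

#' Percentage of granules smaller than a diameter threshold
#'
#' The B-granule-sensitive summary used alongside mixture fitting: the
#' percentage (by number) of particles with diameter strictly below
#' `threshold`. On raw data this is an exact count. On binned data, bins
#' entirely below the threshold count fully; when the threshold falls
#' inside a bin, that bin's count is split pro-rata by log-width, i.e. the
#' fraction `log(threshold/lower) / log(upper/lower)` is counted as below.
#'
#' @param data A `particle_sizes` object.
#' @param threshold Diameter threshold in µm (default 10).
#' @return A single percentage in \[0, 100\].
#' @export
#' @examples
#' percent_small_granules(particle_sizes_raw(c(5, 5, 5, 20)))
percent_small_granules <- function(data, threshold = 10) {
  stopifnot(inherits(data, "particle_sizes"), threshold > 0)
  if (attr(data, "dialect") == "raw") {
    if (nrow(data) < 1) stop("empty particle data", call. = FALSE)
    return(100 * sum(data$diameter < threshold) / nrow(data))
  }
  total <- sum(data$count)
  if (total < 1) stop("empty particle data", call. = FALSE)
  below <- data$count[data$bin_upper <= threshold]
  n_below <- sum(below)
  inside <- which(data$bin_lower < threshold & data$bin_upper > threshold)
  if (length(inside)) {
    b <- data[inside, ]
    frac <- log(threshold / b$bin_lower) / log(b$bin_upper / b$bin_lower)
    n_below <- n_below + sum(b$count * frac)
  }
  100 * n_below / total
}

#' Granule number per milligram of endosperm fresh weight
#'
#' Scales an absolute particle count obtained from a volumetric run
#' (a fixed analysed volume of the granule suspension) up to the full
#' suspension, and normalises by the fresh weight of the dissected
#' endosperm the starch was purified from.
#'
#' @param count_in_analyzed_volume Particles counted in the analysed
#'   aliquot.
#' @param analyzed_volume Analysed volume in mL (e.g. 2 mL).
#' @param total_volume Total suspension volume in mL.
#' @param fresh_weight Endosperm fresh weight in mg.
#' @return Granules per mg fresh weight.
#' @export
#' @examples
#' granules_per_mg(1000, 2, 10, 50)
granules_per_mg <- function(count_in_analyzed_volume, analyzed_volume,
                            total_volume, fresh_weight) {
  stopifnot(
    count_in_analyzed_volume >= 0, analyzed_volume > 0,
    total_volume > 0, fresh_weight > 0
  )
  if (analyzed_volume > total_volume) {
    stop("analyzed_volume exceeds total suspension volume", call. = FALSE)
  }
  count_in_analyzed_volume * (total_volume / analyzed_volume) / fresh_weight
}

#' Check the minimum-particle-count quality criterion
#'
#' Well-powered size distributions need on the order of 1e5 measured
#' particles per sample; samples below the minimum are flagged with a
#' warning but not rejected. The threshold is inclusive: exactly `minimum`
#' particles passes.
#'
#' @param data A `particle_sizes` object.
#' @param minimum Minimum total particle count (default 100000).
#' @return `TRUE` (pass) or `FALSE` (warn), invisibly consistent for use in
#'   pipelines.
#' @export
qc_particle_count <- function(data, minimum = 1e5) {
  n <- total_count(data)
  if (n < minimum) {
    warning(sprintf(
      "only %s particles measured (minimum %s)",
      format(n, big.mark = ","), format(minimum, big.mark = ",")
    ), call. = FALSE)
    return(FALSE)
  }
  TRUE
}

#' Plot a size distribution
#'
#' @param object A `size_distribution`.
#' @param ... Unused.
#' @return A ggplot: relative share vs. diameter on a log axis.
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$diameter, y = .data$share)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Granule diameter (µm)",
      y = sprintf("Relative %% %s", attr(object, "weighting"))
    ) +
    ggplot2::theme_minimal()
}
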