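#' Log-normal mixture components on the volume scale
#'
#' A- and B-type starch granules show up as two log-normal modes in the
#' volume-weighted diameter distribution. A component is parameterised by
#' the mean `mu` and standard deviation `sigma` of ln(diameter/µm) of the
#' *volume-weighted* distribution, and its mixing proportion `weight`
#' (fraction of total starch volume).
#'
#' @param median_diameter Component medians in µm (volume-weighted scale).
#' @param sigma Standard deviations of ln diameter (> 0).
#' @param weight Volume mixing proportions, summing to 1.
#' @return A tibble with columns `mu`, `sigma`, `weight`, ordered by
#'   increasing median and labelled `B` (smaller median) then `A` when two
#'   components are given.
#' @export
#' @examples
#' lognormal_components(c(5, 20), c(0.25, 0.2), c(0.3, 0.7))
lognormal_components <- function(median_diameter, sigma, weight) {
  stopifnot(
    length(median_diameter) %in% 1:2,
    length(sigma) == length(median_diameter),
    length(weight) == length(median_diameter),
    all(median_diameter > 0), all(sigma > 0),
    all(weight >= 0), abs(sum(weight) - 1) < 1e-9
  )
  out <- tibble::tibble(
    mu = log(median_diameter), sigma = as.numeric(sigma),
    weight = as.numeric(weight)
  )
  label_components(out)
}

label_components <- function(comp) {
  comp <- comp[order(comp$mu), , drop = FALSE]
  comp$component <- if (nrow(comp) == 2) c("B", "A") else "A"
  comp[, c("component", "mu", "sigma", "weight")]
}

#' Exact volume-share distribution of a log-normal mixture
#'
#' Evaluates the mixture's volume-weighted probability mass on a bin grid
#' and expresses it as relative percentages — a noise-free
#' `size_distribution` useful for fit validation and as the deterministic
#' limit of the particle simulator.
#'
#' @param components A component tibble from [lognormal_components()].
#' @param edges Bin edges in µm ([default_bin_grid()] by default).
#' @return A volume-weighted `size_distribution`.
#' @export
mixture_distribution <- function(components, edges = default_bin_grid()) {
  stopifnot(all(c("mu", "sigma", "weight") %in% names(components)))
  lo <- edges[-length(edges)]
  up <- edges[-1]
  mass <- rep(0, length(lo))
  for (k in seq_len(nrow(components))) {
    mass <- mass + components$weight[k] *
      (stats::pnorm(log(up), components$mu[k], components$sigma[k]) -
        stats::pnorm(log(lo), components$mu[k], components$sigma[k]))
  }
  structure(
    tibble::tibble(
      diameter = sqrt(lo * up),
      share = 100 * mass / sum(mass),
      bin_width = up - lo
    ),
    weighting = "volume",
    class = c("size_distribution", class(tibble::tibble()))
  )
}

# log bin width of a size_distribution (edges recovered from midpoints/widths)
log_widths <- function(dist) {
  # midpoint m = sqrt(lo*up), width w = up - lo  =>  up, lo roots of
  # up*lo = m^2, up - lo = w
  lo <- (-dist$bin_width + sqrt(dist$bin_width^2 + 4 * dist$diameter^2)) / 2
  up <- lo + dist$bin_width
  log(up / lo)
}

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Fit a one- or two-component log-normal mixture to a volume distribution
#'
#' Deconvolves a volume-weighted granule size distribution into A- and
#' B-type log-normal components by bounded multi-start least squares. The
#' fit target is the volume-share density per unit ln(diameter) (shares
#' divided by each bin's log width), on which a log-normal component is a
#' Gaussian in ln d — this makes the objective independent of the bin
#' grid. Starts combine a fixed grid around 5 µm (B) and 20 µm (A) medians
#' with `sigma` in \{0.15, 0.3, 0.5\} and `weight` in \{0.1, 0.3, 0.5\},
#' topped up with seeded log-normal jitter of the medians; the best
#' sum-of-squares wins, ties going to the lower start index. Convergence
#' tolerance is 1e-10 on the SSE, at most 500 iterations per start.
#'
#' @param dist A volume-weighted `size_distribution` with at least 8
#'   nonzero bins.
#' @param n_components 1 or 2.
#' @param n_starts Number of optimisation starts (default 16).
#' @param seed Integer seed making the start jitter reproducible.
#' @return An object of class `granule_fit`: components (labelled `B` =
#'   smaller median, `A` = larger), `sse`, `converged`, `n_starts_used`,
#'   and the observed and fitted curves. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_mixture <- function(dist, n_components = 2, n_starts = 16, seed = 1) {
  stopifnot(inherits(dist, "size_distribution"))
  if (!identical(attr(dist, "weighting"), "volume")) {
    stop("fit_mixture() requires a volume-weighted distribution", call. = FALSE)
  }
  if (!n_components %in% 1:2) stop("n_components must be 1 or 2", call. = FALSE)
  if (sum(dist$share > 0) < 8) {
    stop("need at least 8 bins with nonzero share", call. = FALSE)
  }
  dlog <- log_widths(dist)
  x <- log(dist$diameter)
  y <- (dist$share / 100) / dlog

  sse_tol <- 1e-10
  ctrl <- list(maxit = 500, factr = sse_tol / .Machine$double.eps)
  mu_lo <- min(x) - 1
  mu_hi <- max(x) + 1

  if (n_components == 2) {
    obj <- function(p) {
      f <- p[5] * stats::dnorm(x, p[1], p[2]) +
        (1 - p[5]) * stats::dnorm(x, p[3], p[4])
      sum((y - f)^2)
    }
    lower <- c(mu_lo, 0.02, mu_lo, 0.02, 1e-4)
    upper <- c(mu_hi, 1.5, mu_hi, 1.5, 1 - 1e-4)
    grid <- expand.grid(sigma = c(0.15, 0.3, 0.5), w = c(0.1, 0.3, 0.5))
    starts <- run_seeded(seed, {
      lapply(seq_len(n_starts), function(i) {
        g <- grid[((i - 1) %% nrow(grid)) + 1, ]
        med <- if (i <= nrow(grid)) {
          c(5, 20)
        } else {
          c(5 * exp(stats::rnorm(1, 0, 0.3)), 20 * exp(stats::rnorm(1, 0, 0.3)))
        }
        pmin(pmax(c(log(med[1]), g$sigma, log(med[2]), g$sigma, g$w), lower), upper)
      })
    })
  } else {
    obj <- function(p) sum((y - stats::dnorm(x, p[1], p[2]))^2)
    lower <- c(mu_lo, 0.02)
    upper <- c(mu_hi, 1.5)
    mu0 <- sum(x * y * dlog) / sum(y * dlog)
    sig0 <- sqrt(max(sum((x - mu0)^2 * y * dlog) / sum(y * dlog), 1e-4))
    grid <- expand.grid(mu = c(mu0, log(5), log(10), log(20)), sigma = c(sig0, 0.15, 0.3, 0.5))
    starts <- lapply(seq_len(min(n_starts, nrow(grid))), function(i) {
      pmin(pmax(c(grid$mu[i], grid$sigma[i]), lower), upper)
    })
  }

  fits <- lapply(starts, function(p0) {
    tryCatch(
      stats::optim(p0, obj,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = ctrl
      ),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) {
    stop(
      "mixture fit failed: no start converged (", length(starts), " starts, ",
      "n_components = ", n_components, ")",
      call. = FALSE
    )
  }
  sses <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, 0)
  codes <- vapply(fits, function(f) if (is.null(f)) -1L else as.integer(f$convergence), 0L)
  # prefer a cleanly converged start unless an unconverged one is genuinely
  # better (more than a relative 1e-6 below), not just line-search jitter
  clean <- which(codes == 0L)
  pick <- if (length(clean) &&
    min(sses[clean]) <= min(sses) * (1 + 1e-6) + 1e-12) {
    clean[which.min(sses[clean])]
  } else {
    which.min(sses)
  }
  best <- fits[[pick]]
  converged <- best$convergence == 0

  comp <- if (n_components == 2) {
    label_components(tibble::tibble(
      mu = c(best$par[1], best$par[3]),
      sigma = c(best$par[2], best$par[4]),
      weight = c(best$par[5], 1 - best$par[5])
    ))
  } else {
    label_components(tibble::tibble(
      mu = best$par[1], sigma = best$par[2], weight = 1
    ))
  }

  f_hat <- rep(0, length(x))
  for (k in seq_len(nrow(comp))) {
    f_hat <- f_hat + comp$weight[k] * stats::dnorm(x, comp$mu[k], comp$sigma[k])
  }
  structure(
    list(
      components = comp,
      n_components = n_components,
      sse = best$value,
      converged = converged,
      n_starts_used = length(starts),
      seed = seed,
      curve = tibble::tibble(
        diameter = dist$diameter,
        share_observed = dist$share,
        share_fitted = 100 * f_hat * dlog
      )
    ),
    class = "granule_fit"
  )
}

#' @export
print.granule_fit <- function(x, ...) {
  cat(sprintf(
    "<granule_fit: %d component(s), sse = %.4g, %s>\n",
    x$n_components, x$sse,
    if (x$converged) "converged" else "NOT converged"
  ))
  print(x$components)
  invisible(x)
}

#' @rdname fit_mixture
#' @param x A `granule_fit`.
#' @param ... Unused.
#' @method tidy granule_fit
#' @export
tidy.granule_fit <- function(x, ...) {
  dplyr::mutate(
    x$components,
    median_diameter = exp(.data$mu),
    mean_diameter = exp(.data$mu + .data$sigma^2 / 2)
  )
}

#' @rdname fit_mixture
#' @method glance granule_fit
#' @export
glance.granule_fit <- function(x, ...) {
  m <- derive_granule_metrics(x)
  tibble::tibble(
    n_components = x$n_components,
    sse = x$sse,
    converged = x$converged,
    n_starts_used = x$n_starts_used,
    b_volume_percent = m$b_volume_percent,
    mean_diameter_A = m$mean_diameter_A,
    mean_diameter_B = m$mean_diameter_B
  )
}

#' Granule phenotype metrics from a mixture fit
#'
#' The B-type granule volume percentage is the fitted mixing weight of the
#' small-median (B) component, expressed as a percent of total starch
#' volume. The mean diameter of each component is `exp(mu + sigma^2/2)` of
#' the fitted volume-weighted component (a volume-weighted mean diameter).
#' Unimodal fits yield `b_volume_percent = 0` and an undefined (`NA`)
#' B-type mean diameter.
#'
#' @param fit A converged `granule_fit`.
#' @return A one-row tibble with `b_volume_percent`, `mean_diameter_A`,
#'   `mean_diameter_B`.
#' @export
derive_granule_metrics <- function(fit) {
  stopifnot(inherits(fit, "granule_fit"))
  if (!fit$converged) stop("mixture fit did not converge", call. = FALSE)
  comp <- fit$components
  mean_d <- exp(comp$mu + comp$sigma^2 / 2)
  if (nrow(comp) == 2) {
    tibble::tibble(
      b_volume_percent = 100 * comp$weight[comp$component == "B"],
      mean_diameter_A = mean_d[comp$component == "A"],
      mean_diameter_B = mean_d[comp$component == "B"]
    )
  } else {
    tibble::tibble(
      b_volume_percent = 0,
      mean_diameter_A = mean_d[1],
      mean_diameter_B = NA_real_
    )
  }
}

#' Select a unimodal or bimodal model for a volume distribution
#'
#' Genotypes essentially lacking B-type granules (and early-development
#' samples where B-type granules have not initiated) are fitted with a
#' single component. Model order 2 is reported only when the two-component
#' fit (a) gives the minor component at least `weight_floor` of the
#' volume, (b) separates the component medians by at least
#' `min_separation` times the wider component's sigma (two overlapping
#' components are one peak, not bimodality), and (c) improves on a
#' one-component fit that does not already explain the curve: the
#' one-component SSE must exceed `sse_floor` and the two-component fit
#' must reduce it by the relative fraction `min_sse_gain`. Conditions (b)
#' and (c) stop a noisy or exactly log-normal single peak from being
#' reported as two well-weighted overlapping components.
#'
#' @inheritParams fit_mixture
#' @param force_unimodal If `TRUE`, return 1 without fitting.
#' @param weight_floor Minimum minor-component volume fraction (default
#'   0.02).
#' @param min_separation Minimum `|mu_A - mu_B|` in units of
#'   `max(sigma_A, sigma_B)` (default 2).
#' @param min_sse_gain Minimum relative SSE reduction of the 2- over the
#'   1-component fit (default 0.3).
#' @param sse_floor One-component SSE below which the curve counts as
#'   explained and 1 is returned (default 1e-8, on the density scale).
#' @return 1 or 2.
#' @export
choose_model <- function(dist, force_unimodal = FALSE, weight_floor = 0.02,
                         min_separation = 2, min_sse_gain = 0.3,
                         sse_floor = 1e-8, n_starts = 16, seed = 1) {
  if (force_unimodal) {
    return(1L)
  }
  fit2 <- fit_mixture(dist, n_components = 2, n_starts = n_starts, seed = seed)
  fit1 <- fit_mixture(dist, n_components = 1, n_starts = n_starts, seed = seed)
  minor <- min(fit2$components$weight)
  sep <- abs(diff(fit2$components$mu)) / max(fit2$components$sigma)
  gain <- 1 - fit2$sse / fit1$sse
  bimodal <- minor >= weight_floor &&
    sep >= min_separation &&
    fit1$sse > sse_floor &&
    is.finite(gain) && gain >= min_sse_gain
  if (bimodal) 2L else 1L
}

#' Plot a mixture fit over the observed distribution
#'
#' @param object A `granule_fit`.
#' @param ... Unused.
#' @return A ggplot overlaying observed shares and the fitted mixture.
#' @method autoplot granule_fit
#' @export
autoplot.granule_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve,
    cols = c("share_observed", "share_fitted"),
    names_to = "series", names_prefix = "share_", values_to = "share"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$diameter, y = .data$share,
    colour = .data$series, linetype = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Granule diameter (µm)", y = "Relative % volume",
      colour = NULL, linetype = NULL
    ) +
    ggplot2::theme_minimal()
}
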