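#' Construct a binned particle-size dataset
#'
#' Particle-size data as exported from an electrical-sensing-zone (Coulter)
#' counter: counts of particles per diameter bin. Bins are half-open
#' `[lower, upper)`, must be contiguous, non-overlapping and strictly
#' increasing, and all diameters are in micrometres.
#'
#' @param bin_lower,bin_upper Numeric vectors of bin edges in µm.
#' @param count Non-negative integer particle counts per bin.
#' @param meta Optional named list of sample metadata. Recognised fields:
#'   `sample_id`, `analyzed_volume_ml`, `total_suspension_volume_ml`,
#'   `fresh_weight_mg`.
#' @return A tibble of class `particle_sizes` with columns `bin_lower`,
#'   `bin_upper`, `count` and attributes `dialect = "binned"` and `meta`.
#' @seealso [particle_sizes_raw()], [read_size_csv()]
#' @export
#' @examples
#' particle_sizes_binned(c(1.4, 2), c(2, 3), c(10, 20))
particle_sizes_binned <- function(bin_lower, bin_upper, count, meta = list()) {
  x <- tibble::tibble(
    bin_lower = as.numeric(bin_lower),
    bin_upper = as.numeric(bin_upper),
    count = as.numeric(count)
  )
  validate_binned(x)
  new_particle_sizes(x, dialect = "binned", meta = meta)
}

#' Construct a raw (per-particle) particle-size dataset
#'
#' @param diameter Numeric vector of per-particle diameters in µm (all > 0).
#' @inheritParams particle_sizes_binned
#' @return A tibble of class `particle_sizes` with column `diameter` and
#'   attributes `dialect = "raw"` and `meta`.
#' @export
#' @examples
#' particle_sizes_raw(c(5, 5, 5, 20))
particle_sizes_raw <- function(diameter, meta = list()) {
  x <- tibble::tibble(diameter = as.numeric(diameter))
  validate_raw(x)
  new_particle_sizes(x, dialect = "raw", meta = meta)
}

new_particle_sizes <- function(x, dialect, meta = list()) {
  structure(
    x,
    dialect = dialect,
    meta = meta,
    class = c("particle_sizes", class(tibble::tibble()))
  )
}

#' @export
print.particle_sizes <- function(x, ...) {
  dialect <- attr(x, "dialect")
  cat(sprintf(
    "<particle_sizes: %s, %s particles%s>\n", dialect,
    format(total_count(x), big.mark = ","),
    if (dialect == "binned") sprintf(", %d bins", nrow(x)) else ""
  ))
  NextMethod()
}

#' Total particle count of a dataset
#' @param data A `particle_sizes` object.
#' @return A single number.
#' @export
total_count <- function(data) {
  stopifnot(inherits(data, "particle_sizes"))
  if (attr(data, "dialect") == "binned") sum(data$count) else nrow(data)
}

validate_binned <- function(x) {
  if (nrow(x) == 0) stop("binned particle data must have at least one bin", call. = FALSE)
  if (anyNA(x)) stop("binned particle data contains missing values", call. = FALSE)
  bad <- which(x$bin_lower <= 0)
  if (length(bad)) stop("non-positive bin_lower at row ", bad[1], call. = FALSE)
  bad <- which(x$bin_upper <= x$bin_lower)
  if (length(bad)) stop("malformed bin (upper <= lower) at row ", bad[1], call. = FALSE)
  bad <- which(x$count < 0)
  if (length(bad)) stop("negative count at row ", bad[1], call. = FALSE)
  bad <- which(abs(x$count - round(x$count)) > 1e-8)
  if (length(bad)) stop("non-integer count at row ", bad[1], call. = FALSE)
  if (nrow(x) > 1) {
    lo <- x$bin_lower[-1]
    up <- x$bin_upper[-nrow(x)]
    bad <- which(lo < up - 1e-9)
    if (length(bad)) stop("overlapping bins at row ", bad[1] + 1, call. = FALSE)
    bad <- which(lo > up + 1e-9)
    if (length(bad)) stop("gap between bins at row ", bad[1] + 1, call. = FALSE)
  }
  if (sum(x$count) < 1) stop("total particle count must be >= 1", call. = FALSE)
  invisible(x)
}

validate_raw <- function(x) {
  if (nrow(x) == 0) stop("raw particle data must contain at least one diameter", call. = FALSE)
  if (anyNA(x$diameter)) stop("raw particle data contains missing diameters", call. = FALSE)
  bad <- which(x$diameter <= 0)
  if (length(bad)) stop("non-positive diameter at row ", bad[1], call. = FALSE)
  invisible(x)
}

meta_keys <- c(
  "sample_id", "analyzed_volume_ml", "total_suspension_volume_ml",
  "fresh_weight_mg"
)

parse_meta_lines <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    if (!grepl("=", kv, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num) && key != "sample_id") num else val
  }
  meta
}

read_csv_body <- function(path, col_types) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  tbl <- readr::read_csv(I(paste(body, collapse = "\n")),
    col_types = col_types, progress = FALSE
  )
  list(table = tbl, meta = parse_meta_lines(lines))
}

#' Read a particle-size CSV
#'
#' Two plain-CSV dialects are supported ('.' decimal, UTF-8). The binned
#' dialect has columns `bin_lower_um,bin_upper_um,count`; the raw dialect a
#' single `diameter_um` column. Sample metadata may precede the header as
#' `# key=value` comment lines.
#'
#' @param path Path to the CSV file.
#' @param dialect `"binned"` or `"raw"`.
#' @return A validated [particle_sizes_binned()] / [particle_sizes_raw()]
#'   object, with metadata parsed when present.
#' @export
read_size_csv <- function(path, dialect = c("binned", "raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "binned") {
    got <- read_csv_body(path, readr::cols(
      bin_lower_um = readr::col_double(),
      bin_upper_um = readr::col_double(),
      count = readr::col_double()
    ))
    need <- c("bin_lower_um", "bin_upper_um", "count")
    if (!all(need %in% names(got$table))) {
      stop("binned dialect requires columns ", paste(need, collapse = ","), call. = FALSE)
    }
    particle_sizes_binned(got$table$bin_lower_um, got$table$bin_upper_um,
      got$table$count,
      meta = got$meta
    )
  } else {
    got <- read_csv_body(path, readr::cols(diameter_um = readr::col_double()))
    if (!"diameter_um" %in% names(got$table)) {
      stop("raw dialect requires column diameter_um", call. = FALSE)
    }
    particle_sizes_raw(got$table$diameter_um, meta = got$meta)
  }
}

#' Write a particle-size CSV
#'
#' Inverse of [read_size_csv()]: metadata is emitted as `# key=value`
#' comment lines before the header, then the dialect's columns.
#'
#' @param data A `particle_sizes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_size_csv <- function(data, path) {
  stopifnot(inherits(data, "particle_sizes"))
  meta <- attr(data, "meta")
  hdr <- character(0)
  if (length(meta)) {
    hdr <- sprintf("# %s=%s", names(meta), vapply(meta, format_meta_value, ""))
  }
  if (attr(data, "dialect") == "binned") {
    body <- c(
      "bin_lower_um,bin_upper_um,count",
      sprintf(
        "%s,%s,%s", format_num(data$bin_lower), format_num(data$bin_upper),
        format_num(data$count)
      )
    )
  } else {
    body <- c("diameter_um", format_num(data$diameter))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

format_num <- function(x) formatC(x, format = "g", digits = 17)
format_meta_value <- function(v) if (is.numeric(v)) format_num(v) else as.character(v)

#' Read a replicated protein-quantification CSV
#'
#' The expected header is
#' `accession,pd_1,pd_2,pd_3,ctrl_1,ctrl_2,ctrl_3[,ratio,p_value]`, i.e.
#' per-accession replicate abundances from the affinity pulldown (`pd_*`)
#' and the no-bait control (`ctrl_*`). Tables carrying only precomputed
#' `accession,ratio,p_value` columns (e.g. transcribed from a published
#' table) are also accepted. When replicate abundances are present and the
#' `ratio` column is absent, ratios are computed with [compute_ratios()].
#'
#' @param path Path to the CSV file.
#' @param ratio_cap Passed to [compute_ratios()] when ratios are computed.
#' @return A tibble of class `protein_quant` with one row per accession.
#' @export
read_quant_csv <- function(path, ratio_cap = 100) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  got <- read_csv_body(path, readr::cols(
    accession = readr::col_character(),
    .default = readr::col_guess()
  ))
  tbl <- got$table
  if (!"accession" %in% names(tbl)) stop("quant CSV requires an accession column", call. = FALSE)
  pd_cols <- grep("^pd_[0-9]+$", names(tbl), value = TRUE)
  ctrl_cols <- grep("^ctrl_[0-9]+$", names(tbl), value = TRUE)
  has_reps <- length(pd_cols) > 0 || length(ctrl_cols) > 0
  if (has_reps) {
    if (length(pd_cols) != length(ctrl_cols)) {
      stop(sprintf(
        "unequal replicate counts: %d pulldown vs %d control columns",
        length(pd_cols), length(ctrl_cols)
      ), call. = FALSE)
    }
    ab <- as.matrix(tbl[c(pd_cols, ctrl_cols)])
    if (anyNA(ab)) stop("missing abundance values are not supported", call. = FALSE)
    if (any(ab <= 0)) stop("non-positive abundance", call. = FALSE)
  } else if (!"ratio" %in% names(tbl)) {
    stop("quant CSV needs pd_*/ctrl_* replicate columns or a ratio column", call. = FALSE)
  }
  out <- tibble::as_tibble(tbl)
  if (has_reps && !"ratio" %in% names(out)) {
    out <- compute_ratios(out, ratio_cap = ratio_cap)
  }
  if ("p_value" %in% names(out) &&
    any(out$p_value < 0 | out$p_value > 1, na.rm = TRUE)) {
    stop("p_value outside [0, 1]", call. = FALSE)
  }
  class(out) <- c("protein_quant", class(tibble::tibble()))
  out
}

#' Write a protein-quantification CSV
#'
#' @param table A `protein_quant` tibble (or any data frame with an
#'   `accession` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(table, path) {
  stopifnot("accession" %in% names(table))
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}
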