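#' Apparent amylose content from iodine colorimetry
#'
#' Empirical calibration converting the absorbance ratio of the
#' starch-iodine complex at 620 nm over 535 nm into apparent amylose
#' content (% of starch):
#' `1.4935 * exp(2.7029 * a620 / a535)`.
#' The function is strictly increasing in the ratio and depends on the two
#' absorbances only through their ratio. Values outside \[0, 100\] are
#' returned as-is with a warning rather than clamped — the calibration is
#' empirical and out-of-range values usually indicate an assay problem.
#'
#' @param a535 Absorbance at 535 nm (> 0).
#' @param a620 Absorbance at 620 nm (>= 0).
#' @return Apparent amylose content in percent (vectorised).
#' @export
#' @examples
#' apparent_amylose(a535 = 1, a620 = 0) # calibration intercept, 1.4935
apparent_amylose <- function(a535, a620) {
  if (any(a535 <= 0)) {
    stop("a535 must be positive (division by the 535 nm absorbance)", call. = FALSE)
  }
  if (any(a620 < 0)) stop("a620 must be non-negative", call. = FALSE)
  out <- 1.4935 * exp(2.7029 * (a620 / a535))
  if (any(out > 100)) {
    warning("apparent amylose above 100%; check the assay", call. = FALSE)
  }
  out
}

#' Amylose content for a table of absorbance pairs
#'
#' Tidy wrapper over [apparent_amylose()] for assay tables with one row
#' per sample.
#'
#' @param data A data frame with columns `a535` and `a620` (e.g. read from
#'   a `sample,a535,a620` CSV).
#' @return `data` with an added `amylose_percent` column, as a tibble.
#' @export
amylose_table <- function(data) {
  stopifnot(all(c("a535", "a620") %in% names(data)))
  dplyr::mutate(
    tibble::as_tibble(data),
    amylose_percent = apparent_amylose(.data$a535, .data$a620)
  )
}

#' Starch content as a percentage of sample mass
#'
#' Starch assays digest the sample to glucose and report starch in glucose
#' equivalents; the default keeps that basis. Setting
#' `anhydro_correction = TRUE` multiplies by 162/180 to convert released
#' glucose to anhydroglucose (polymer-mass) units.
#'
#' @param glucose_released Glucose released by digestion, mg.
#' @param sample_mass Sample mass (dry flour or fresh endosperm), mg.
#' @param anhydro_correction Apply the 162/180 anhydroglucose factor.
#' @return Starch content in percent of sample mass (vectorised, linear in
#'   `glucose_released`).
#' @export
#' @examples
#' starch_percent(4.7, 10) # 47%
starch_percent <- function(glucose_released, sample_mass,
                           anhydro_correction = FALSE) {
  if (any(sample_mass <= 0)) stop("sample_mass must be positive", call. = FALSE)
  if (any(glucose_released < 0)) {
    stop("glucose_released must be non-negative", call. = FALSE)
  }
  factor <- if (anhydro_correction) 162 / 180 else 1
  100 * glucose_released * factor / sample_mass
}
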