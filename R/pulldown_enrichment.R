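quant_rep_cols <- function(table) {
  pd <- grep("^pd_[0-9]+$", names(table), value = TRUE)
  ctrl <- grep("^ctrl_[0-9]+$", names(table), value = TRUE)
  if (length(pd) == 0 || length(ctrl) == 0) {
    stop("replicate abundance columns pd_*/ctrl_* are required", call. = FALSE)
  }
  if (length(pd) != length(ctrl)) {
    stop(sprintf(
      "unequal replicate counts: %d pulldown vs %d control",
      length(pd), length(ctrl)
    ), call. = FALSE)
  }
  ab <- as.matrix(table[c(pd, ctrl)])
  if (anyNA(ab)) stop("missing abundance values are not supported", call. = FALSE)
  if (any(ab <= 0)) stop("abundances must be positive", call. = FALSE)
  list(pd = pd, ctrl = ctrl)
}

#' Pulldown/control abundance ratios
#'
#' Per protein, the mean abundance over the pulldown replicates divided by
#' the mean over the no-bait control replicates. Ratios are capped at
#' `ratio_cap` (default 100), mirroring the saturated values reported by
#' proteomics quantification software for proteins essentially absent from
#' the controls.
#'
#' @param table A `protein_quant` tibble with `pd_*` and `ctrl_*` columns
#'   (equal replicate counts, all positive).
#' @param ratio_cap Cap on the reported ratio; `Inf` disables capping.
#' @return `table` with a `ratio` column added/replaced.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   accession = "P1",
#'   pd_1 = 10, pd_2 = 10, pd_3 = 10,
#'   ctrl_1 = 5, ctrl_2 = 5, ctrl_3 = 5
#' )
#' compute_ratios(tbl)$ratio # 2
compute_ratios <- function(table, ratio_cap = 100) {
  cols <- quant_rep_cols(table)
  pd_mean <- rowMeans(as.matrix(table[cols$pd]))
  ctrl_mean <- rowMeans(as.matrix(table[cols$ctrl]))
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    ratio = pmin(pd_mean / ctrl_mean, ratio_cap)
  )
  class(out) <- c("protein_quant", class(tibble::tibble()))
  out
}

#' Per-protein enrichment test
#'
#' Two-sample unequal-variance (Welch) t-test on natural-log-transformed
#' replicate abundances, pulldown vs. control, one p-value per protein.
#' This is the package's replacement for the vendor-internal
#' background-based test used by proteomics search software; equality of
#' its p-values with published tables is not claimed. P-values are floored
#' at `p_floor` (default 1e-17, matching the saturated values such
#' software prints). Degenerate input with zero variance in both groups
#' and equal means yields p = 1.
#'
#' @inheritParams compute_ratios
#' @param p_floor Lower cap applied to the p-values.
#' @return `table` with a `p_value` column added/replaced.
#' @export
test_enrichment <- function(table, p_floor = 1e-17) {
  cols <- quant_rep_cols(table)
  pd <- log(as.matrix(table[cols$pd]))
  ctrl <- log(as.matrix(table[cols$ctrl]))
  p <- vapply(seq_len(nrow(table)), function(i) {
    x <- pd[i, ]
    y <- ctrl[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, 0)
  out <- dplyr::mutate(tibble::as_tibble(table), p_value = pmax(p, p_floor))
  class(out) <- c("protein_quant", class(tibble::tibble()))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), order-preserving with the input vector.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Filter a quantification table for significant enrichment
#'
#' Applies the study-style interactor filter: retain proteins at least
#' `fold`-fold enriched in the pulldown with p below `alpha`. The raw
#' per-protein p-value is used by default (the published criterion);
#' `use_adjusted = TRUE` filters on Benjamini-Hochberg adjusted p-values
#' instead. Ratios and p-values are computed from replicate columns when
#' absent.
#'
#' @inheritParams compute_ratios
#' @param fold Minimum abundance ratio (default 2; the ratio must be
#'   `>= fold`).
#' @param alpha Significance threshold (default 0.05; strict `<`).
#' @param use_adjusted Filter on `p_adjusted` instead of raw `p_value`.
#' @return An `enrichment_result`: the full table with `ratio`, `p_value`,
#'   `p_adjusted` and logical `retained` columns; thresholds are stored as
#'   attributes. `dplyr::filter(x, retained)` gives the retained subset.
#' @export
filter_enriched <- function(table, fold = 2, alpha = 0.05,
                            use_adjusted = FALSE, ratio_cap = 100) {
  out <- tibble::as_tibble(table)
  if (!"ratio" %in% names(out)) out <- compute_ratios(out, ratio_cap = ratio_cap)
  if (!"p_value" %in% names(out)) out <- test_enrichment(out)
  if (any(out$p_value < 0 | out$p_value > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out$p_adjusted <- bh_adjust(out$p_value)
  p_used <- if (use_adjusted) out$p_adjusted else out$p_value
  out$retained <- out$ratio >= fold & p_used < alpha
  structure(out,
    fold = fold, alpha = alpha, use_adjusted = use_adjusted,
    class = c("enrichment_result", "protein_quant", class(tibble::tibble()))
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result: %d/%d retained (ratio >= %g, %s p < %g)>\n",
    sum(x$retained), nrow(x), attr(x, "fold"),
    if (attr(x, "use_adjusted")) "BH-adjusted" else "raw", attr(x, "alpha")
  ))
  NextMethod()
}

#' Volcano-style plot of an enrichment result
#'
#' @param object An `enrichment_result` from [filter_enriched()].
#' @param ... Unused.
#' @return A ggplot of log2 ratio vs. -log10 p, retained proteins
#'   highlighted.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = log2(.data$ratio), y = -log10(.data$p_value),
    colour = .data$retained
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "log2 abundance ratio (pulldown/control)",
      y = "-log10 p", colour = "retained"
    ) +
    ggplot2::theme_minimal()
}
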