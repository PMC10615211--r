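#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' The genotype-comparison machinery used for phenotype tables: a classical
#' one-way ANOVA F-test across groups followed by Tukey's honestly
#' significant difference test on all pairs (Tukey-Kramer correction for
#' unbalanced group sizes, via [stats::TukeyHSD()]).
#'
#' @param data A data frame in long format with one observation per row.
#' @param group,value Column names (strings) holding the group labels and
#'   the measured values. Defaults `"group"` and `"value"`.
#' @param alpha Significance level recorded for downstream lettering
#'   (default 0.05).
#' @return An object of class `group_comparison` with elements
#'   `f_statistic`, `df`, `p_value` (ANOVA), `pairwise` (symmetric matrix
#'   of Tukey p-values), `means` (named group means) and `alpha`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' d <- data.frame(
#'   group = rep(c("WT", "phs1"), each = 4),
#'   value = c(28, 29, 27, 28, 21, 22, 20, 21)
#' )
#' anova_tukey(d)
anova_tukey <- function(data, group = "group", value = "value", alpha = 0.05) {
  stopifnot(all(c(group, value) %in% names(data)))
  g <- factor(data[[group]])
  y <- as.numeric(data[[value]])
  if (anyNA(y)) stop("missing values in the response", call. = FALSE)
  n_per <- table(g)
  if (length(n_per) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n_per < 2)) {
    stop(
      "every group needs >= 2 replicates (offending: ",
      paste(names(n_per)[n_per < 2], collapse = ", "), ")",
      call. = FALSE
    )
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  p_anova <- an[["Pr(>F)"]][1]
  lev <- levels(g)
  pw <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  if (an[["Mean Sq"]][2] > 0) {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]
      b <- pairs[[i]][2]
      pw[a, b] <- pw[b, a] <- tk[i, "p adj"]
    }
  } else {
    # zero within-group variance: groups with equal means are indistinct,
    # any difference is exact
    mns <- tapply(y, g, mean)
    for (a in lev) {
      for (b in lev) {
        if (a != b && !isTRUE(all.equal(mns[[a]], mns[[b]]))) pw[a, b] <- 0
      }
    }
    if (is.nan(f_stat)) {
      f_stat <- 0
      p_anova <- 1
    }
  }
  structure(
    list(
      f_statistic = f_stat,
      df = c(an[["Df"]][1], an[["Df"]][2]),
      p_value = p_anova,
      pairwise = pw,
      means = tapply(y, g, mean),
      sem = tapply(y, g, function(v) stats::sd(v) / sqrt(length(v))),
      n = as.integer(n_per),
      alpha = alpha
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison: %d groups, F(%d, %d) = %.4g, p = %.3g>\n",
    length(x$means), x$df[1], x$df[2], x$f_statistic, x$p_value
  ))
  print(tidy.group_comparison(x))
  invisible(x)
}

#' @rdname anova_tukey
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  letters_ <- compact_letters(x)
  tibble::tibble(
    group = names(x$means),
    mean = as.numeric(x$means),
    sem = as.numeric(x$sem),
    n = x$n,
    letters = letters_[names(x$means)]
  )
}

#' @rdname anova_tukey
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic,
    df_between = x$df[1],
    df_within = x$df[2],
    p_value = x$p_value,
    n_groups = length(x$means),
    alpha = x$alpha
  )
}

#' Compact letter display for pairwise comparisons
#'
#' Assigns letters to groups so that two groups share a letter exactly
#' when their pairwise p-value is at or above `alpha` (not significantly
#' different). Uses the insert-and-absorb algorithm: start from one letter
#' covering all groups; for each significant pair, split every letter
#' containing both and then absorb letters whose group set is contained in
#' another's. Letters are ordered by descending group mean when means are
#' available, so the largest-mean group carries "a".
#'
#' @param x A `group_comparison` from [anova_tukey()], or a symmetric
#'   matrix of pairwise p-values with group names as dimnames.
#' @param alpha Significance threshold; defaults to the `alpha` stored in
#'   a `group_comparison`, else 0.05.
#' @param means Optional named vector of group means used only for letter
#'   ordering when `x` is a matrix.
#' @return A named character vector of letter strings, one per group.
#' @export
#' @examples
#' p <- matrix(c(1, .6, .01, .6, 1, .2, .01, .2, 1), 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
#' )
#' compact_letters(p) # chain: A "a", B "ab", C "b"
compact_letters <- function(x, alpha = NULL, means = NULL) {
  if (inherits(x, "group_comparison")) {
    if (is.null(alpha)) alpha <- x$alpha
    means <- x$means
    pw <- x$pairwise
  } else {
    pw <- as.matrix(x)
    if (is.null(alpha)) alpha <- 0.05
  }
  stopifnot(nrow(pw) == ncol(pw), !is.null(rownames(pw)))
  if (max(abs(pw - t(pw))) > 1e-12) {
    stop("pairwise p matrix must be symmetric", call. = FALSE)
  }
  groups <- rownames(pw)
  ord <- if (!is.null(means)) {
    names(sort(means[groups], decreasing = TRUE))
  } else {
    groups
  }
  # columns = letters, each a logical membership vector over ordered groups
  cols <- list(stats::setNames(rep(TRUE, length(ord)), ord))
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      a <- ord[i]
      b <- ord[j]
      if (pw[a, b] >= alpha) next
      new_cols <- list()
      for (col in cols) {
        if (col[[a]] && col[[b]]) {
          c1 <- col
          c1[[a]] <- FALSE
          c2 <- col
          c2[[b]] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop any column whose member set is a subset of another's
      keep <- rep(TRUE, length(new_cols))
      for (p in seq_along(new_cols)) {
        for (q in seq_along(new_cols)) {
          if (p != q && keep[q] &&
            all(!new_cols[[p]] | new_cols[[q]]) &&
            (any(new_cols[[p]] != new_cols[[q]]) || p > q)) {
            keep[p] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order letters by first member in the mean-descending group order
  first_member <- vapply(cols, function(col) which(col)[1], 0)
  cols <- cols[order(first_member)]
  out <- stats::setNames(rep("", length(ord)), ord)
  for (k in seq_along(cols)) {
    members <- names(cols[[k]])[cols[[k]]]
    out[members] <- paste0(out[members], letters[k])
  }
  out[groups]
}
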