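# Independent textbook-formula oracles used across tests.

# step-up BH from its definition: sort, p*(m/i), cumulative min from the top
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch two-sample t-test p-value from the formulas
welch_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vx <- var(x)
  vy <- var(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx / nx + vy / ny)
  df <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# one-way ANOVA F from sums of squares
anova_f_brute <- function(groups) {
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1
  df_w <- length(all_y) - length(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# letter-display validity: shared letter <=> p >= alpha, for every pair
letters_valid <- function(letters_, pw, alpha) {
  groups <- names(letters_)
  for (a in groups) {
    for (b in groups) {
      if (a == b) next
      shared <- length(intersect(
        strsplit(letters_[[a]], "")[[1]],
        strsplit(letters_[[b]], "")[[1]]
      )) > 0
      if (shared != (pw[a, b] >= alpha)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# fixed bimodal truth used by the recovery tests
recovery_truth <- function() {
  lognormal_components(c(5, 20), c(0.25, 0.20), c(0.30, 0.70))
}
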