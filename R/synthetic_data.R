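#' Specification for a synthetic granule population
#'
#' Seeded generator configuration for particle populations with the
#' statistical structure the deconvolution assumes: diameters drawn from a
#' one- or two-component log-normal mixture, counted on a log-spaced bin
#' grid. Components are parameterised on the volume-weighted scale (the
#' scale of the fitted plots); the generator converts volume weights to
#' number weights analytically.
#'
#' Presets reproduce the *direction* of the study system's genotype
#' differences, not any measured values:
#' \describe{
#'   \item{WT}{bimodal; B median 5 µm, sigma 0.30, volume weight 0.30;
#'     A median 21 µm, sigma 0.22.}
#'   \item{phs1_like}{fewer, larger B-type granules: B weight 0.12,
#'     B median 7.5 µm; A as WT.}
#'   \item{bgc1_like}{essentially no B component; single A component.}
#'   \item{unimodal_early}{early-development unimodal population,
#'     median 12 µm, sigma 0.35.}
#' }
#'
#' @param preset One of `"WT"`, `"phs1_like"`, `"bgc1_like"`,
#'   `"unimodal_early"`, or `NULL` when `components` is given.
#' @param components Optional [lognormal_components()] tibble overriding
#'   the preset.
#' @param n_particles Number of particles to draw (default 1e5).
#' @param noise `"multinomial"` (sampling noise on the binned counts) or
#'   `"none"` (deterministic expected counts, largest-remainder rounded).
#' @param edges Bin grid; defaults to [default_bin_grid()].
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return A `granule_spec` list.
#' @export
granule_spec <- function(preset = c("WT", "phs1_like", "bgc1_like", "unimodal_early"),
                         components = NULL, n_particles = 1e5,
                         noise = c("multinomial", "none"),
                         edges = default_bin_grid(), seed = 1) {
  noise <- match.arg(noise)
  if (is.null(components)) {
    preset <- match.arg(preset)
    components <- switch(preset,
      WT = lognormal_components(c(5, 21), c(0.30, 0.22), c(0.30, 0.70)),
      phs1_like = lognormal_components(c(7.5, 21), c(0.30, 0.22), c(0.12, 0.88)),
      bgc1_like = lognormal_components(21, 0.22, 1),
      unimodal_early = lognormal_components(12, 0.35, 1)
    )
  } else {
    preset <- "custom"
    stopifnot(all(c("mu", "sigma", "weight") %in% names(components)))
    if (abs(sum(components$weight) - 1) > 1e-9) {
      stop("component volume weights must sum to 1", call. = FALSE)
    }
    components <- label_components(tibble::as_tibble(components))
  }
  stopifnot(n_particles >= 1, length(edges) >= 2, all(diff(edges) > 0))
  structure(
    list(
      preset = preset, components = components,
      n_particles = as.integer(n_particles), noise = noise,
      edges = edges, seed = as.integer(seed)
    ),
    class = "granule_spec"
  )
}

#' Number-weighted mixture parameters implied by volume-scale components
#'
#' A log-normal volume-weighted component (mu, sigma) corresponds to a
#' number-weighted log-normal with `mu_number = mu - 3 sigma^2` and the
#' same sigma; number weights are proportional to
#' `weight / E[d^3] = weight * exp(-3 mu + 4.5 sigma^2)`.
#'
#' @param components A volume-scale component tibble.
#' @return The tibble with `mu_number` and `number_weight` columns added.
#' @export
number_scale_components <- function(components) {
  a <- components$weight * exp(-3 * components$mu + 4.5 * components$sigma^2)
  dplyr::mutate(
    tibble::as_tibble(components),
    mu_number = .data$mu - 3 * .data$sigma^2,
    number_weight = a / sum(a)
  )
}

# largest-remainder apportionment of n into integer counts with sum n
apportion <- function(n, p) {
  exact <- n * p / sum(p)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  base
}

#' Simulate a binned granule population
#'
#' Draws `n_particles` diameters from the spec's log-normal mixture
#' (volume weights converted to number weights analytically) and counts
#' them on the bin grid. With `noise = "multinomial"` the counts are one
#' multinomial draw from the exact bin probabilities; with `"none"` they
#' are the expected counts rounded by largest remainder. Probability mass
#' outside the grid (negligible for the presets) is truncated and the
#' within-grid mass renormalised. Bit-reproducible given the seed.
#'
#' @param spec A [granule_spec()].
#' @return A binned `particle_sizes` object carrying the generating truth
#'   in `attr(, "truth")`: the volume- and number-scale components, preset
#'   and seed.
#' @export
#' @examples
#' sim <- simulate_granules(granule_spec("WT", n_particles = 1e4, seed = 7))
#' total_count(sim)
simulate_granules <- function(spec) {
  stopifnot(inherits(spec, "granule_spec"))
  comp <- number_scale_components(spec$components)
  lo <- spec$edges[-length(spec$edges)]
  up <- spec$edges[-1]
  p <- rep(0, length(lo))
  for (k in seq_len(nrow(comp))) {
    p <- p + comp$number_weight[k] *
      (stats::pnorm(log(up), comp$mu_number[k], comp$sigma[k]) -
        stats::pnorm(log(lo), comp$mu_number[k], comp$sigma[k]))
  }
  if (sum(p) < 0.99) {
    warning("more than 1% of the mixture mass lies outside the bin grid",
      call. = FALSE
    )
  }
  counts <- if (spec$noise == "multinomial") {
    run_seeded(spec$seed, as.numeric(stats::rmultinom(1, spec$n_particles, p)))
  } else {
    apportion(spec$n_particles, p)
  }
  out <- particle_sizes_binned(lo, up, counts)
  attr(out, "truth") <- list(
    preset = spec$preset, components = comp,
    b_volume_percent = if (nrow(comp) == 2) {
      100 * comp$weight[comp$component == "B"]
    } else {
      0
    },
    n_particles = spec$n_particles, noise = spec$noise, seed = spec$seed
  )
  out
}

#' Simulate per-particle diameters from a spec
#'
#' Raw-dialect companion to [simulate_granules()]: individual diameters
#' sampled from the number-weighted mixture, for tests that need the
#' particle list itself (e.g. brute-force small-granule counting).
#'
#' @inheritParams simulate_granules
#' @return A raw `particle_sizes` object with the same `truth` attribute.
#' @export
simulate_particle_list <- function(spec) {
  stopifnot(inherits(spec, "granule_spec"))
  comp <- number_scale_components(spec$components)
  d <- run_seeded(spec$seed, {
    ks <- sample.int(nrow(comp), spec$n_particles,
      replace = TRUE,
      prob = comp$number_weight
    )
    stats::rlnorm(spec$n_particles, comp$mu_number[ks], comp$sigma[ks])
  })
  out <- particle_sizes_raw(d)
  attr(out, "truth") <- list(
    preset = spec$preset, components = comp,
    n_particles = spec$n_particles, seed = spec$seed
  )
  out
}

# genotype x timepoint parameter table for the developmental series
dev_series_params <- function(genotype, dpa) {
  stopifnot(genotype %in% c("WT", "phs1_like"))
  if (dpa <= 14) {
    # B-type granules have not initiated yet: unimodal, A granules growing
    med <- if (dpa <= 8) 8 else 14
    return(lognormal_components(med, 0.35, 1))
  }
  if (genotype == "WT") {
    if (dpa <= 18) {
      lognormal_components(c(4.5, 19), c(0.30, 0.24), c(0.22, 0.78))
    } else {
      lognormal_components(c(5, 21), c(0.30, 0.22), c(0.30, 0.70))
    }
  } else {
    if (dpa <= 18) {
      lognormal_components(c(6.5, 19), c(0.30, 0.24), c(0.08, 0.92))
    } else {
      lognormal_components(c(7.5, 21), c(0.30, 0.22), c(0.12, 0.88))
    }
  }
}

#' Simulate a grain-development series of granule populations
#'
#' Emulates the developmental trajectory of Triticeae endosperm starch:
#' unimodal size distributions at 8 and 14 days post anthesis (dpa),
#' turning bimodal at 18 and 22 dpa once B-type granules initiate. The
#' `phs1_like` genotype has a reduced B-component volume weight and a
#' larger B median at the late timepoints.
#'
#' @param genotype `"WT"` or `"phs1_like"`.
#' @param timepoints Sampling times in dpa (default `c(8, 14, 18, 22)`).
#' @param n_particles Particles per timepoint.
#' @param seed Base seed; timepoint t uses `seed + t`.
#' @param noise Passed to [granule_spec()].
#' @return A tibble with columns `dpa`, `genotype`, `data` (list of binned
#'   `particle_sizes`) and `truth` (list of generating component tables).
#' @export
simulate_development_series <- function(genotype = c("WT", "phs1_like"),
                                        timepoints = c(8, 14, 18, 22),
                                        n_particles = 1e5, seed = 1,
                                        noise = "multinomial") {
  genotype <- match.arg(genotype)
  rows <- purrr::map(timepoints, function(t) {
    comp <- dev_series_params(genotype, t)
    sim <- simulate_granules(granule_spec(
      components = comp, n_particles = n_particles,
      noise = noise, seed = seed + t
    ))
    tibble::tibble(
      dpa = t, genotype = genotype,
      data = list(sim), truth = list(comp)
    )
  })
  dplyr::bind_rows(rows)
}

#' Specification for a synthetic pulldown quantification table
#'
#' @param n_background Number of unenriched background proteins.
#' @param n_enriched Number of proteins spiked with the enrichment effect.
#' @param log_fold Natural-log fold enrichment of the spiked subset in the
#'   pulldown (default `log(4)`).
#' @param cv Replicate coefficient of variation of the abundances
#'   (default 0.1, a tight technical-replicate level).
#' @param n_replicates Replicates per condition (default 3).
#' @param base_abundance Geometric-mean abundance of the background
#'   (arbitrary instrument units).
#' @param seed Integer seed.
#' @return A `quant_spec` list.
#' @export
quant_spec <- function(n_background = 100, n_enriched = 10,
                       log_fold = log(4), cv = 0.1, n_replicates = 3,
                       base_abundance = 1e6, seed = 1) {
  stopifnot(
    n_background >= 0, n_enriched >= 0, n_background + n_enriched >= 1,
    cv > 0, n_replicates >= 2, base_abundance > 0
  )
  structure(
    list(
      n_background = as.integer(n_background),
      n_enriched = as.integer(n_enriched),
      log_fold = log_fold, cv = cv,
      n_replicates = as.integer(n_replicates),
      base_abundance = base_abundance, seed = as.integer(seed)
    ),
    class = "quant_spec"
  )
}

#' Simulate a replicated pulldown/control quantification table
#'
#' Background proteins have log-normal abundances with a true
#' pulldown/control ratio of 1; the enriched subset is shifted up by
#' `log_fold` in the pulldown replicates only. Replicate scatter is
#' log-normal with standard deviation `sqrt(log(1 + cv^2))` on the log
#' scale. The `true_enriched` column records the ground truth.
#'
#' @param spec A [quant_spec()].
#' @return A `protein_quant` tibble with `accession`, `pd_*`/`ctrl_*`
#'   replicate columns and a logical `true_enriched` column.
#' @export
simulate_quant_table <- function(spec) {
  stopifnot(inherits(spec, "quant_spec"))
  n <- spec$n_background + spec$n_enriched
  sd_log <- sqrt(log(1 + spec$cv^2))
  run_seeded(spec$seed, {
    enriched <- c(
      rep(FALSE, spec$n_background),
      rep(TRUE, spec$n_enriched)
    )
    base <- stats::rlnorm(n, log(spec$base_abundance), 1)
    reps <- function(mu) {
      matrix(
        stats::rlnorm(n * spec$n_replicates, rep(log(mu), spec$n_replicates), sd_log),
        nrow = n
      )
    }
    pd <- reps(base * exp(ifelse(enriched, spec$log_fold, 0)))
    ctrl <- reps(base)
    out <- tibble::tibble(
      accession = sprintf("%s%04d", ifelse(enriched, "EN", "BG"), seq_len(n))
    )
    for (r in seq_len(spec$n_replicates)) out[[paste0("pd_", r)]] <- pd[, r]
    for (r in seq_len(spec$n_replicates)) out[[paste0("ctrl_", r)]] <- ctrl[, r]
    out$true_enriched <- enriched
    class(out) <- c("protein_quant", class(tibble::tibble()))
    out
  })
}
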