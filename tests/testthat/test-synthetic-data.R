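test_that("generators are pure functions of spec and seed", {
  s <- granule_spec("WT", n_particles = 2e4, seed = 42)
  a <- simulate_granules(s)
  b <- simulate_granules(s)
  expect_identical(a$count, b$count)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_size_csv(a, p1)
  write_size_csv(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  q <- quant_spec(seed = 4)
  expect_identical(simulate_quant_table(q), simulate_quant_table(q))

  # different seeds differ
  c <- simulate_granules(granule_spec("WT", n_particles = 2e4, seed = 43))
  expect_false(identical(a$count, c$count))
})

test_that("volume-to-number weight conversion is self-consistent at n = 1e6", {
  truth <- lognormal_components(c(5, 21), c(0.30, 0.22), c(0.30, 0.70))
  raw <- simulate_particle_list(granule_spec(
    components = truth, n_particles = 1e6, seed = 3
  ))
  comp <- number_scale_components(truth)
  # assign each particle to its component by posterior odds at its diameter
  ld <- log(raw$diameter)
  dens_b <- comp$number_weight[1] * dnorm(ld, comp$mu_number[1], comp$sigma[1])
  dens_a <- comp$number_weight[2] * dnorm(ld, comp$mu_number[2], comp$sigma[2])
  vol <- raw$diameter^3
  share_b <- sum(vol * dens_b / (dens_b + dens_a)) / sum(vol)
  expect_equal(share_b, 0.30, tolerance = 0.01)
})

test_that("a zero-B preset is unimodal and chosen as such", {
  sim <- simulate_granules(granule_spec("bgc1_like", n_particles = 5e4, seed = 6))
  expect_equal(attr(sim, "truth")$b_volume_percent, 0)
  expect_identical(choose_model(to_distribution(sim, "volume"), seed = 6), 1L)
})

test_that("WT recovery: fitted B volume within 0.05 of the truth weight", {
  sim <- simulate_granules(granule_spec("WT", seed = 1)) # n = 1e5
  fit <- fit_mixture(to_distribution(sim, "volume"), 2, seed = 1)
  b <- derive_granule_metrics(fit)$b_volume_percent / 100
  expect_lt(abs(b - attr(sim, "truth")$b_volume_percent / 100), 0.05)
})

test_that("development series is unimodal early and bimodal late", {
  series <- simulate_development_series("WT", n_particles = 5e4, seed = 2)
  orders <- vapply(series$data, function(d) {
    choose_model(to_distribution(d, "volume"), seed = 2)
  }, 1L)
  expect_equal(orders, c(1L, 1L, 2L, 2L))
  expect_true(all(vapply(series$data, total_count, 0) > 0))
  expect_true(all(vapply(series$data, percent_small_granules, 0) > 0))
})

test_that("phs1-like preset has lower B volume and larger B diameter than WT late", {
  wt <- simulate_development_series("WT", n_particles = 5e4, seed = 5)
  mut <- simulate_development_series("phs1_like", n_particles = 5e4, seed = 6)
  for (tp in c(3, 4)) { # 18 and 22 dpa
    m_wt <- derive_granule_metrics(
      fit_mixture(to_distribution(wt$data[[tp]], "volume"), 2, seed = 5)
    )
    m_mut <- derive_granule_metrics(
      fit_mixture(to_distribution(mut$data[[tp]], "volume"), 2, seed = 6)
    )
    expect_lt(m_mut$b_volume_percent, m_wt$b_volume_percent)
    expect_gt(m_mut$mean_diameter_B, m_wt$mean_diameter_B)
  }
})

test_that("null quant tables stay near the nominal false-positive rate", {
  fracs <- vapply(1:100, function(s) {
    tab <- simulate_quant_table(quant_spec(
      n_background = 40, n_enriched = 0, log_fold = 0, seed = s
    ))
    res <- filter_enriched(tab, fold = 1)
    mean(res$retained)
  }, 0)
  expect_lte(mean(fracs), 0.05)
})

test_that("strong spiked effects are nearly always retained", {
  power <- vapply(1:50, function(s) {
    tab <- simulate_quant_table(quant_spec(
      n_background = 30, n_enriched = 5,
      log_fold = log(4), cv = 0.1, seed = 200 + s
    ))
    res <- filter_enriched(tab)
    sum(res$retained & res$true_enriched) / 5
  }, 0)
  expect_gte(mean(power), 0.9)
})

test_that("noise-free counts match expected masses and conserve n", {
  s <- granule_spec("WT", n_particles = 12345, noise = "none", seed = 1)
  sim <- simulate_granules(s)
  expect_equal(total_count(sim), 12345)
  # deterministic: identical regardless of RNG state
  set.seed(99)
  expect_identical(simulate_granules(s)$count, sim$count)
})
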