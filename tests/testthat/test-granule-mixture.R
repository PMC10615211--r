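test_that("noise-free bimodal density is recovered within 1% relative error", {
  truth <- recovery_truth() # B: ln 5, 0.25, w 0.30; A: ln 20, 0.20
  dist <- mixture_distribution(truth, default_bin_grid(121))
  fit <- fit_mixture(dist, n_components = 2, seed = 1)
  expect_true(fit$converged)
  got <- fit$components
  expect_equal(got$mu, truth$mu, tolerance = 0.01)
  expect_equal(got$sigma, truth$sigma, tolerance = 0.01)
  expect_equal(got$weight, truth$weight, tolerance = 0.01)
  expect_lt(fit$sse, 1e-5)
})

test_that("a single log-normal is recovered identically with n_components = 1", {
  truth <- lognormal_components(10, 0.5, 1)
  # grid wide enough that tail truncation cannot bias sigma
  dist <- mixture_distribution(truth, default_bin_grid(121, 0.8, 120))
  fit <- fit_mixture(dist, n_components = 1, seed = 1)
  expect_equal(fit$components$mu, log(10), tolerance = 1e-3)
  expect_equal(fit$components$sigma, 0.5, tolerance = 1e-3)
  expect_equal(fit$components$weight, 1)
})

test_that("component labels are stable: B is always the smaller median", {
  # relabelling invariance: construct the same mixture with swapped order
  c1 <- lognormal_components(c(5, 20), c(0.25, 0.2), c(0.3, 0.7))
  c2 <- lognormal_components(c(20, 5), c(0.2, 0.25), c(0.7, 0.3))
  expect_equal(c1, c2)
  dist <- mixture_distribution(c1, default_bin_grid(121))
  fit <- fit_mixture(dist, 2, seed = 3)
  b <- fit$components[fit$components$component == "B", ]
  a <- fit$components[fit$components$component == "A", ]
  expect_lt(b$mu, a$mu)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-9)
})

test_that("simulated 1e5-particle populations are recovered within tolerance", {
  truth <- recovery_truth()
  sim <- simulate_granules(granule_spec(
    components = truth, n_particles = 1e5, seed = 11
  ))
  fit <- fit_mixture(to_distribution(sim, "volume"), 2, seed = 11)
  got <- fit$components
  expect_equal(got$mu, truth$mu, tolerance = 0.05)
  expect_equal(got$sigma, truth$sigma, tolerance = 0.05)
  expect_lt(abs(got$weight[got$component == "B"] - 0.30), 0.05)
})

test_that("derived metrics follow the closed forms", {
  # sigma -> 0 degenerate: mean diameter equals the median
  f <- structure(
    list(
      components = lognormal_components(c(5, 20), c(1e-9, 1e-9), c(0.3, 0.7)),
      n_components = 2, sse = 0, converged = TRUE, n_starts_used = 1,
      seed = 1, curve = NULL
    ),
    class = "granule_fit"
  )
  m <- derive_granule_metrics(f)
  expect_equal(m$b_volume_percent, 30)
  expect_equal(m$mean_diameter_B, 5, tolerance = 1e-6)
  expect_equal(m$mean_diameter_A, 20, tolerance = 1e-6)

  # unimodal: exp(mu + sigma^2/2), no B component
  f1 <- structure(
    list(
      components = lognormal_components(10, 0.5, 1),
      n_components = 1, sse = 0, converged = TRUE, n_starts_used = 1,
      seed = 1, curve = NULL
    ),
    class = "granule_fit"
  )
  m1 <- derive_granule_metrics(f1)
  expect_equal(m1$b_volume_percent, 0)
  expect_equal(m1$mean_diameter_A, 10 * exp(0.125))
  expect_true(is.na(m1$mean_diameter_B))

  f1$converged <- FALSE
  expect_error(derive_granule_metrics(f1), "converge")
})

test_that("metrics from a recovery fit match the generator-implied values", {
  truth <- recovery_truth()
  dist <- mixture_distribution(truth, default_bin_grid(121))
  m <- derive_granule_metrics(fit_mixture(dist, 2, seed = 2))
  expect_equal(m$b_volume_percent, 30, tolerance = 0.01)
  expect_equal(m$mean_diameter_B, 5 * exp(0.25^2 / 2), tolerance = 0.01)
  expect_equal(m$mean_diameter_A, 20 * exp(0.20^2 / 2), tolerance = 0.01)
})

test_that("fit contract errors are raised", {
  d <- simulate_granules(granule_spec("WT", n_particles = 5000, seed = 1))
  num <- to_distribution(d, "number")
  expect_error(fit_mixture(num), "volume-weighted")
  few <- mixture_distribution(recovery_truth(), default_bin_grid(8))
  expect_error(fit_mixture(few), "at least 8 bins")
})

test_that("model choice separates unimodal from bimodal populations", {
  expect_identical(choose_model(NULL, force_unimodal = TRUE), 1L)
  wt <- simulate_granules(granule_spec("WT", n_particles = 5e4, seed = 21))
  expect_identical(choose_model(to_distribution(wt, "volume"), seed = 21), 2L)
  uni <- simulate_granules(granule_spec("bgc1_like", n_particles = 5e4, seed = 22))
  expect_identical(choose_model(to_distribution(uni, "volume"), seed = 22), 1L)
})

test_that("fitted B volume increases monotonically along a B-weight ladder", {
  weights <- seq(0.05, 0.45, by = 0.1)
  fitted_b <- vapply(seq_along(weights), function(i) {
    w <- weights[i]
    sim <- simulate_granules(granule_spec(
      components = lognormal_components(c(5, 21), c(0.3, 0.22), c(w, 1 - w)),
      n_particles = 5e4, seed = 30 + i
    ))
    fit <- fit_mixture(to_distribution(sim, "volume"), 2, seed = 30 + i)
    derive_granule_metrics(fit)$b_volume_percent
  }, 0)
  expect_true(all(diff(fitted_b) > 0))
  expect_equal(fitted_b / 100, weights, tolerance = 0.1)
})

test_that("as sigma shrinks the fitted component means approach the generating diameters", {
  truth <- lognormal_components(c(5, 20), c(0.02, 0.02), c(0.3, 0.7))
  dist <- mixture_distribution(truth, default_bin_grid(400))
  fit <- fit_mixture(dist, 2, seed = 4)
  m <- derive_granule_metrics(fit)
  expect_equal(m$mean_diameter_B, 5, tolerance = 0.01)
  expect_equal(m$mean_diameter_A, 20, tolerance = 0.01)
})

test_that("fits are deterministic given the seed", {
  sim <- simulate_granules(granule_spec("WT", n_particles = 2e4, seed = 9))
  dist <- to_distribution(sim, "volume")
  f1 <- fit_mixture(dist, 2, seed = 5)
  f2 <- fit_mixture(dist, 2, seed = 5)
  expect_identical(f1$components, f2$components)
  expect_identical(f1$sse, f2$sse)
})
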