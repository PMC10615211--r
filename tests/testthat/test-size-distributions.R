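two_bin_data <- function(counts) {
  # contiguous bins whose geometric-mean midpoints are exactly 10 and 20 um
  particle_sizes_binned(c(7.8125, 12.8), c(12.8, 31.25), counts)
}

test_that("volume weighting scales counts by d^3 at the bin midpoint", {
  d <- two_bin_data(c(8, 1)) # 8 * 10^3 == 1 * 20^3
  vol <- to_distribution(d, "volume")
  expect_equal(vol$share, c(50, 50))
  num <- to_distribution(d, "number")
  expect_equal(num$share, c(800, 100) / 9)
})

test_that("distributions are scale-invariant and sum to 100", {
  withr::local_seed(11)
  for (rep in 1:5) {
    edges <- default_bin_grid(41)
    counts <- rpois(40, 5)
    counts[sample(40, 1)] <- counts[sample(40, 1)] + 1
    d <- particle_sizes_binned(edges[-41], edges[-1], counts)
    d10 <- particle_sizes_binned(edges[-41], edges[-1], counts * 10)
    for (w in c("number", "volume")) {
      s <- to_distribution(d, w)
      expect_equal(sum(s$share), 100, tolerance = 1e-9)
      expect_true(all(s$share >= 0))
      expect_true(all(diff(s$diameter) > 0))
      expect_equal(to_distribution(d10, w)$share, s$share)
    }
  }
})

test_that("volume weighting preserves the d^3 ordering for equal counts", {
  edges <- default_bin_grid(33)
  d <- particle_sizes_binned(edges[-33], edges[-1], rep(7, 32))
  vol <- to_distribution(d, "volume")
  expect_true(all(diff(vol$share) > 0))
})

test_that("percent of small granules counts strictly below the threshold", {
  expect_equal(percent_small_granules(particle_sizes_raw(c(5, 5, 5, 20))), 75)
  expect_equal(
    percent_small_granules(particle_sizes_binned(
      c(4, 6, 18), c(6, 18, 22), c(3, 0, 1)
    ), threshold = 18), 75
  )
  # threshold on a bin edge: bin [10, 12) is not below 10
  d <- particle_sizes_binned(c(5, 10), c(10, 12), c(1, 1))
  expect_equal(percent_small_granules(d, 10), 50)
  # strictly-below on raw data: d == threshold does not count
  expect_equal(percent_small_granules(particle_sizes_raw(c(10, 5)), 10), 50)
})

test_that("threshold inside a bin is split pro-rata by log width", {
  # single bin [8, 12.5): log-midpoint 10, so half the bin's log width
  d <- particle_sizes_binned(8, 12.5, 100)
  expect_equal(percent_small_granules(d, 10), 50, tolerance = 1e-12)
})

test_that("binned small-granule percentage matches brute force on the raw list", {
  spec <- granule_spec("WT", n_particles = 20000, seed = 5)
  raw <- simulate_particle_list(spec)
  brute <- 100 * sum(raw$diameter < 10) / total_count(raw)
  fine <- bin_particles(raw, default_bin_grid(n_edges = 400, 0.5, 100))
  one_bin_share <- 100 * max(fine$count) / total_count(fine)
  expect_equal(percent_small_granules(fine, 10), brute,
    tolerance = one_bin_share / 100 + 1e-12
  )
  # convergence: finer grids get closer to the raw-list oracle
  coarse <- bin_particles(raw, default_bin_grid(n_edges = 30, 0.5, 100))
  expect_lte(
    abs(percent_small_granules(fine, 10) - brute),
    abs(percent_small_granules(coarse, 10) - brute) + 1e-9
  )
})

test_that("granules per mg applies the volumetric scale-up", {
  expect_equal(granules_per_mg(1000, 2, 10, 50), 100)
  expect_equal(granules_per_mg(0, 2, 10, 50), 0)
  expect_equal(granules_per_mg(123456, 2, 7.5, 33.2), 123456 * 3.75 / 33.2)
  expect_error(granules_per_mg(10, 5, 2, 1), "exceeds")
})

test_that("particle-count QC warns below the minimum and passes at it", {
  make <- function(n) particle_sizes_binned(1.4, 42, n)
  expect_true(qc_particle_count(make(150000)))
  expect_true(qc_particle_count(make(100000)))
  expect_warning(flag <- qc_particle_count(make(99999)), "99,999")
  expect_false(flag)
})

test_that("distribution CSV export has the plotting columns", {
  d <- two_bin_data(c(8, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_distribution_csv(to_distribution(d, "volume"), path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("diameter_um", "share_percent"))
  expect_equal(sum(back$share_percent), 100)
})
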