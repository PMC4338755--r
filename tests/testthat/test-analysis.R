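# Build a rate_timeseries directly for analysis-only tests.
fake_series <- function(rate, sample_interval = 1e-3, mask = NULL) {
  ns <- nrow(rate)
  structure(
    list(times = seq_len(ns) * sample_interval, S = NULL, rate = rate,
         applied_current = NULL, lesion_mask = mask, model = "fake",
         params = NULL,
         config = sim_config(dt = sample_interval, duration =
                               ns * sample_interval,
                             sample_interval = sample_interval)),
    class = "rate_timeseries")
}

test_that("windowed means reproduce constants and closed-form ramps", {
  const <- fake_series(matrix(40, 1000, 3))
  sm <- mean_firing(const)
  expect_equal(sm$per_node_mean, rep(40, 3))
  expect_equal(sm$total, 120)
  # full-span window of a constant series is the same constant
  expect_equal(mean_firing(const, c(0.001, 1))$per_node_mean, rep(40, 3))

  # linear ramp 0 -> 100 Hz over 10 s: last-2 s sample mean is exactly 90
  ramp <- fake_series(matrix(seq(0.01, 100, by = 0.01), ncol = 1))
  sm <- mean_firing(ramp, c(8, 10))
  expect_equal(as.numeric(sm$per_node_mean), 90)
  expect_identical(sm$n_samples, 2001L)  # both endpoints on the grid
})

test_that("windows outside the series span are errors", {
  s <- fake_series(matrix(1, 100, 2))
  expect_error(mean_firing(s, c(0.05, 0.2)), "outside")
  expect_error(mean_firing(s, c(0.09, 0.01)), "start exceeds")
})

test_that("totals respect the lesion mask and node partitions", {
  rate <- matrix(rep(c(10, 20, 30, 40), each = 50), 50, 4)
  sm_all <- mean_firing(fake_series(rate))
  expect_equal(sm_all$total, 100)
  sm_masked <- mean_firing(fake_series(rate, mask = c(FALSE, TRUE, FALSE,
                                                      TRUE)))
  expect_equal(sm_masked$total, 40)
  # additivity over a partition of the (unmasked) nodes
  expect_equal(sm_all$total, sum(sm_all$per_node_mean[1:2]) +
                 sum(sm_all$per_node_mean[3:4]))
})

test_that("delta_fr subtracts per-node means and carries masks", {
  a <- mean_firing(fake_series(matrix(50, 100, 3)))
  b <- mean_firing(fake_series(matrix(c(10, 20, 30), 100, 3, byrow = TRUE),
                               mask = c(FALSE, FALSE, TRUE)))
  d <- delta_fr(a, b)
  expect_equal(as.numeric(d), c(40, 30, 20))
  expect_identical(attr(d, "masked"), c(FALSE, FALSE, TRUE))
  # identical runs difference to zero
  expect_true(all(delta_fr(a, a) == 0))
  # totals are linear: total(a) - total(b) over commonly unmasked nodes
  expect_equal(sum(d[!attr(d, "masked")]),
               sum(a$per_node_mean[1:2]) - sum(b$per_node_mean[1:2]))
  expect_error(delta_fr(a, mean_firing(fake_series(matrix(1, 10, 2)))),
               "different node counts")
})

test_that("return_to_baseline is 0 for a series already at baseline", {
  base <- fake_series(matrix(50, 2000, 1))
  bs <- mean_firing(base)
  # a flat series compared against itself returns immediately for any band
  expect_equal(return_to_baseline(base, 1.0, bs, k_sd = 3), 0)
  expect_equal(return_to_baseline(base, 0.5, bs, k_sd = 0.5), 0)
  # with realistic noise, the matched-baseline band admits the series too
  set.seed(4)
  noisy <- fake_series(matrix(rnorm(2000, 50, 0.05), 2000, 1))
  bn <- mean_firing(noisy)
  expect_equal(return_to_baseline(noisy, 1.0, bn, k_sd = 3), 0)
})

test_that("exponential relaxation crosses the band at the analytic time", {
  # g(t) = 50 + A * exp(-(t - t0)/tau) for t > t0; baseline N(50, sd)
  sd_b <- 0.5
  A <- 20
  tau <- 0.05
  t0 <- 1
  times <- seq(1e-3, 3, by = 1e-3)
  g <- ifelse(times <= t0, 50, 50 + A * exp(-(times - t0) / tau))
  series <- fake_series(matrix(g, ncol = 1))
  baseline <- list(global_mean = 50, global_sd = sd_b)
  class(baseline) <- "firing_summary"
  k <- 2
  # crossing: A exp(-t/tau) = k * sd  =>  t = tau * log(A / (k sd))
  analytic_ms <- tau * log(A / (k * sd_b)) * 1000
  got <- return_to_baseline(series, t0, baseline, k_sd = k, hold_ms = 20)
  expect_lt(abs(got - analytic_ms), 1.5)  # within ~one sample
})

test_that("return_to_baseline is monotone in the band width", {
  set.seed(1)
  times_n <- 3000
  g <- 50 + 30 * exp(-(seq_len(times_n) * 1e-3 - 1) / 0.2)
  g[seq_len(1000)] <- 50
  series <- fake_series(matrix(g, ncol = 1))
  baseline <- structure(list(global_mean = 50, global_sd = 1),
                        class = "firing_summary")
  lat <- vapply(c(0.5, 1, 2, 4, 8),
                function(k) return_to_baseline(series, 1, baseline,
                                               k_sd = k),
                numeric(1))
  expect_false(is.unsorted(rev(lat)))
})

test_that("a series that never settles yields the not-returned sentinel", {
  g <- seq(100, 200, length.out = 500)
  series <- fake_series(matrix(g, ncol = 1))
  baseline <- structure(list(global_mean = 50, global_sd = 0.1),
                        class = "firing_summary")
  expect_identical(return_to_baseline(series, 0.1, baseline), NA_real_)
})

test_that("noise_scan tabulates reproducible totals per sigma and seed", {
  conn <- random_connectome(n = 8, seed = 3)
  p <- meanfield_params(G = 0.5)
  cfg <- sim_config(duration = 0.5, seed = 5)
  tab <- noise_scan(conn, p, sigmas = c(0, 0, 0.05), config = cfg,
                    n_seeds = 2)
  expect_identical(nrow(tab), 6L)
  expect_identical(names(tab), c("sigma", "seed", "total_rate_hz"))
  # duplicated sigma = 0 rows agree exactly
  z <- tab[tab$sigma == 0, ]
  expect_equal(z$total_rate_hz[z$seed == 5][1],
               z$total_rate_hz[z$seed == 5][2])
  # end-to-end reproducibility
  tab2 <- noise_scan(conn, p, sigmas = c(0, 0, 0.05), config = cfg,
                     n_seeds = 2)
  expect_identical(tab, tab2)
  expect_error(noise_scan(conn, p, sigmas = numeric(0), config = cfg),
               "non-empty")
})

test_that("summary CSV export carries node ids, regions and masks", {
  atl <- toy_atlas(k = 2, m = 2)
  conn <- random_connectome(n = 8, seed = 1,
                            labels = atlas_node_labels(atl))
  ts <- simulate_meanfield(conn, meanfield_params(sigma = 0),
                           sim_config(duration = 0.1))
  sm <- mean_firing(ts)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(sm, conn, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("node_id", "region", "mean_rate_hz", "masked"))
  expect_identical(back$node_id, 1:8)
  expect_identical(back$region, atlas_node_labels(atl))
})
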