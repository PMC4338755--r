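test_that("parameter and config validation reject bad values", {
  expect_error(meanfield_params(tau_S = 0), "tau_S")
  expect_error(meanfield_params(sigma = -1), "sigma")
  expect_error(sim_config(dt = 1e-4, sample_interval = 2.5e-4),
               "integer multiple")
  expect_error(sim_config(duration = 1.0005), "integer multiple")
})

test_that("default sampling grid yields exactly 10,000 samples over 10 s", {
  cfg <- sim_config()
  expect_identical(cfg$n_samples, 10000L)
  expect_identical(cfg$n_steps, 100000L)
  conn <- random_connectome(n = 3, seed = 1)
  ts <- simulate_meanfield(conn, meanfield_params(sigma = 0), cfg)
  expect_identical(dim(ts$rate), c(10000L, 3L))
  expect_identical(dim(ts$S), c(10000L, 3L))
  expect_equal(ts$times, seq(1e-3, 10, by = 1e-3))
})

test_that("synaptic input composes local, network and baseline terms", {
  p <- meanfield_params()
  conn <- empty_connectome(3)
  # zero state: baseline only
  expect_equal(synaptic_input(rep(0, 3), conn, p), rep(p$I_0, 3))
  # single uncoupled node at S = 1: w*J_N + I_0
  expect_equal(synaptic_input(1, single_node(), p),
               0.9 * 0.2609 + 0.3, tolerance = 1e-12)
  # two-node coupling at G = 2.3: x_2 = G*J_N + I_0
  two <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
  p23 <- meanfield_params(G = 2.3)
  expect_equal(synaptic_input(c(1, 0), two, p23)[2],
               2.3 * 0.2609 + 0.3, tolerance = 1e-12)
  expect_error(synaptic_input(rep(0, 2), conn, p), "n_nodes")
})

test_that("coupling sign flag flips the network term", {
  two <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
  p <- meanfield_params(G = 2)
  x_exc <- synaptic_input(c(1, 0), two, p, coupling_sign = 1)
  x_inh <- synaptic_input(c(1, 0), two, p, coupling_sign = -1)
  expect_equal(x_exc[2] - p$I_0, -(x_inh[2] - p$I_0))
})

test_that("uncoupled noise-free trajectories settle on the bisection fixed point", {
  cfg <- sim_config(duration = 6, seed = 1)
  withr::with_seed(99, {
    for (k in 1:5) {
      p <- meanfield_params(
        w = runif(1, 0.5, 1.1), gamma = runif(1, 0.4, 0.9),
        tau_S = runif(1, 0.05, 0.2), J_N = runif(1, 0.15, 0.35),
        I_0 = runif(1, 0.25, 0.4), sigma = 0)
      ts <- simulate_meanfield(single_node(), p, cfg)
      terminal <- ts$S[nrow(ts$S), 1]
      expect_equal(terminal, fixed_point_oracle(p), tolerance = 1e-6)
    }
  })
})

test_that("noise-free runs are bit-identical; seeds control stochastic runs", {
  conn <- random_connectome(n = 6, seed = 3)
  cfg <- sim_config(duration = 0.5, seed = 7)
  p0 <- meanfield_params(sigma = 0)
  expect_identical(simulate_meanfield(conn, p0, cfg)$S,
                   simulate_meanfield(conn, p0, cfg)$S)
  p <- meanfield_params(sigma = 0.05)
  a <- simulate_meanfield(conn, p, cfg)
  b <- simulate_meanfield(conn, p, cfg)
  expect_identical(a$S, b$S)
  c <- simulate_meanfield(conn, p, sim_config(duration = 0.5, seed = 8))
  expect_false(identical(a$S, c$S))
})

test_that("clamping keeps the gating variable in [0, 1] under strong noise", {
  conn <- random_connectome(n = 5, seed = 2)
  for (seed in 1:3) {
    ts <- simulate_meanfield(
      conn, meanfield_params(sigma = 0.5, G = 1),
      sim_config(duration = 0.2, seed = seed, noise_scaling = "per_step"))
    expect_true(all(ts$S >= 0 & ts$S <= 1))
    expect_true(all(is.finite(ts$rate)))
  }
})

test_that("Euler error shrinks about linearly when dt is halved", {
  p <- meanfield_params(sigma = 0)
  conn <- random_connectome(n = 4, seed = 5)
  terminal <- function(dt) {
    cfg <- sim_config(dt = dt, duration = 0.4, sample_interval = 0.1,
                      seed = 1)
    ts <- simulate_meanfield(conn, p, cfg)
    ts$S[nrow(ts$S), ]
  }
  s1 <- terminal(4e-4)
  s2 <- terminal(2e-4)
  s4 <- terminal(1e-4)
  e1 <- max(abs(s1 - s4))
  e2 <- max(abs(s2 - s4))
  # first-order scheme: halving dt about halves the error (ratio ~2,
  # between 1.5 and 3 allowing higher-order contamination)
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("relabeling nodes permutes noise-free trajectories identically", {
  conn <- random_connectome(n = 7, seed = 9)
  perm <- c(3L, 1L, 7L, 5L, 2L, 6L, 4L)
  permuted <- connectome(conn$weights[perm, perm],
                         conn$coordinates[perm, ])
  p <- meanfield_params(sigma = 0, G = 1.5)
  cfg <- sim_config(duration = 0.5, seed = 1)
  ts <- simulate_meanfield(conn, p, cfg)
  ts_perm <- simulate_meanfield(permuted, p, cfg)
  expect_equal(ts_perm$rate, ts$rate[, perm], tolerance = 1e-12)
})

test_that("calibrate_G brackets the loss of the low-firing state", {
  atl <- toy_atlas(k = 2, m = 5)  # 20 nodes
  spec <- synth_spec(n_nodes = 20, atlas = atl, target_edge_pairs = 60,
                     seed = 1)
  conn <- synthetic_connectome(spec)
  g <- calibrate_G(conn, meanfield_params(), scan_range = c(0.1, 30),
                   tol = 0.05, duration = 2,
                   config = sim_config(duration = 2, sample_interval = 1e-2))
  bracket <- attr(g, "bracket")
  expect_lt(bracket["stable"], bracket["unstable"])
  expect_lte(bracket["unstable"] - bracket["stable"], 0.05 + 1e-9)
  # certificate: re-simulate on both sides of the returned value
  probe <- function(G) {
    p <- meanfield_params(sigma = 0, G = G)
    ts <- simulate_meanfield(conn, p,
                             sim_config(duration = 2,
                                        sample_interval = 1e-2))
    mean(ts$rate[ts$times >= 1.6, ])
  }
  expect_lt(probe(bracket[["stable"]]), 20)
  expect_gt(probe(bracket[["unstable"]]), 20)
})

test_that("uncoupled networks admit no bifurcation in the scan range", {
  expect_error(
    calibrate_G(empty_connectome(4), meanfield_params(),
                scan_range = c(0.1, 10), duration = 1,
                config = sim_config(duration = 1, sample_interval = 1e-2)),
    "no bifurcation")
})

test_that("integration failure reports the offending step", {
  # unclamped state with a huge explosive gain diverges
  conn <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
  p <- meanfield_params(sigma = 0, G = 1e300)
  cfg <- sim_config(duration = 0.01, sample_interval = 1e-3, clamp_S = FALSE)
  expect_error(simulate_meanfield(conn, p, cfg), "diverged")
})
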