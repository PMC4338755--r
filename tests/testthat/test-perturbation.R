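test_that("focal lesions resolve region names to node sets", {
  atl <- load_builtin_atlas()
  les <- focal_lesion(atl, c("rCUN", "rLOCC", "rPCUN"))
  expect_identical(les$kind, "focal")
  expect_length(les$node_set, 52)
  expect_identical(focal_lesion(atl, character(0))$node_set, integer(0))
  expect_identical(focal_lesion(atl, "lPCUN")$node_set, 812:834)
  expect_error(focal_lesion(atl, "rXYZ"), "unknown region")
})

test_that("diffuse lesions sample reproducibly without replacement", {
  conn <- synthetic_connectome(synth_spec(seed = 1))
  a <- diffuse_lesion(conn, 50, seed = 7)
  b <- diffuse_lesion(conn, 50, seed = 7)
  expect_identical(a$node_set, b$node_set)
  expect_length(a$node_set, 50)
  expect_identical(anyDuplicated(a$node_set), 0L)
  c <- diffuse_lesion(conn, 50, seed = 8)
  expect_false(identical(a$node_set, c$node_set))
  expect_identical(diffuse_lesion(conn, 0)$node_set, integer(0))
  expect_error(diffuse_lesion(conn, 999), "cannot sample")
  # exclusion removes nodes from the pool
  d <- diffuse_lesion(conn, 900, seed = 1, exclude = 1:98)
  expect_false(any(d$node_set %in% 1:98))
})

test_that("apply_lesion zeroes rows and columns, keeps nodes, stays symmetric", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  conn <- connectome(w)
  les <- structure(list(node_set = 2L, kind = "focal", provenance = NULL),
                   class = "lesion")
  cut <- apply_lesion(conn, les)
  expect_identical(cut$n_nodes, 4L)
  expect_true(all(cut$weights[2, ] == 0))
  expect_true(all(cut$weights[, 2] == 0))
  expect_silent(validate_connectome(cut))
  expect_identical(cut$lesion_mask, c(FALSE, TRUE, FALSE, FALSE))
  # idempotent
  expect_identical(apply_lesion(cut, les)$weights, cut$weights)
  # empty lesion is the identity
  none <- structure(list(node_set = integer(0), kind = "focal",
                         provenance = NULL), class = "lesion")
  expect_identical(apply_lesion(conn, none)$weights, conn$weights)
})

test_that("lesion connection fractions match enumeration on a complete graph", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  conn <- connectome(w)
  les1 <- structure(list(node_set = 1L, kind = "focal", provenance = NULL),
                    class = "lesion")
  # one node of K4: 3 of 6 unordered pairs removed
  expect_equal(lesion_connection_fraction(conn, les1, "count"), 0.5)
  expect_equal(lesion_connection_fraction(conn, les1, "weight"), 0.5)
  none <- structure(list(node_set = integer(0), kind = "focal",
                         provenance = NULL), class = "lesion")
  expect_equal(lesion_connection_fraction(conn, none), 0)
  all4 <- structure(list(node_set = 1:4, kind = "focal", provenance = NULL),
                    class = "lesion")
  expect_equal(lesion_connection_fraction(conn, all4), 1)
  expect_error(lesion_connection_fraction(empty_connectome(0), les1),
               "empty connectome")
  # weight mode diverges from count mode on non-uniform weights
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[2, 1] <- 10; w2[2, 3] <- w2[3, 2] <- 1
  conn2 <- connectome(w2)
  les3 <- structure(list(node_set = 3L, kind = "focal", provenance = NULL),
                    class = "lesion")
  expect_equal(lesion_connection_fraction(conn2, les3, "count"), 0.5)
  expect_equal(lesion_connection_fraction(conn2, les3, "weight"), 1 / 11)
})

test_that("lesioned nodes follow the uncoupled single-node solution", {
  conn <- random_connectome(n = 6, seed = 4)
  les <- structure(list(node_set = c(2L, 5L), kind = "diffuse",
                        provenance = NULL), class = "lesion")
  p <- meanfield_params(sigma = 0, G = 1.5)
  cfg <- sim_config(duration = 2, seed = 1)
  ts <- simulate_meanfield(conn, p, cfg, lesion = les)
  solo <- simulate_meanfield(single_node(), p, cfg)
  expect_equal(ts$S[, 2], solo$S[, 1], tolerance = 1e-12)
  expect_equal(ts$S[, 5], solo$S[, 1], tolerance = 1e-12)
  expect_identical(ts$lesion_mask,
                   c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("stimulation windows validate and record applied current", {
  expect_error(make_stimulation(1:3, -0.1, 5, 5), "inverted")
  expect_error(make_stimulation(1:3, -0.1, -1, 5), "non-negative")
  stim <- make_stimulation(c(2, 3), -0.1, 0, 0.05)
  conn <- random_connectome(n = 4, seed = 1)
  cfg <- sim_config(duration = 0.1, seed = 1)
  ts <- simulate_meanfield(conn, meanfield_params(sigma = 0), cfg,
                           stimulation = stim)
  ap <- ts$applied_current
  expect_identical(dim(ap), c(100L, 4L))
  active <- ts$times < 0.05
  expect_true(all(ap[active, c(2, 3)] == -0.1))
  expect_true(all(ap[!active, ] == 0))
  expect_true(all(ap[, c(1, 4)] == 0))
  # window beyond the run duration is rejected
  expect_error(simulate_meanfield(conn, meanfield_params(), cfg,
                                  stimulation = make_stimulation(1, 1, 0, 1)),
               "exceeds run duration")
})

test_that("zero-amplitude stimulation leaves the dynamics unchanged", {
  conn <- random_connectome(n = 5, seed = 6)
  p <- meanfield_params(sigma = 0)
  cfg <- sim_config(duration = 0.2, seed = 1)
  plain <- simulate_meanfield(conn, p, cfg)
  null_stim <- simulate_meanfield(conn, p, cfg,
                                  stimulation = make_stimulation(1:5, 0, 0,
                                                                 0.1))
  expect_identical(plain$S, null_stim$S)
})

test_that("disjoint stimulations compose additively", {
  conn <- random_connectome(n = 4, seed = 2)
  p <- meanfield_params(sigma = 0)
  cfg <- sim_config(duration = 0.2, seed = 1)
  s1 <- make_stimulation(1, 0.05, 0, 0.1)
  s2 <- make_stimulation(2, -0.03, 0.05, 0.15)
  both <- simulate_meanfield(conn, p, cfg, stimulation = list(s1, s2))
  # the applied-current record is the sum of the two windows
  ap <- both$applied_current
  t <- both$times
  expect_true(all(ap[t < 0.1, 1] == 0.05))
  expect_true(all(ap[t >= 0.05 & t < 0.15, 2] == -0.03))
  # and the same protocol expressed as one list reproduces exactly
  again <- simulate_meanfield(conn, p, cfg, stimulation = list(s2, s1))
  expect_identical(both$S, again$S)
})
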