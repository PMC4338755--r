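# Shared fixtures, all built in code.

# A small atlas: k regions per hemisphere, each of size m (equal halves,
# so hemisphere mirroring is well-defined).
toy_atlas <- function(k = 3, m = 4) {
  n_half <- k * m
  mk <- function(hemi, offset) {
    data.frame(id = seq_len(k), hemisphere = hemi,
               abbr = paste0("REG", seq_len(k)),
               name = paste("Region", seq_len(k)),
               node_start = offset + (seq_len(k) - 1) * m + 1,
               node_end = offset + seq_len(k) * m)
  }
  brain_atlas(rbind(mk("R", 0), mk("L", n_half)))
}

# Random symmetric weighted connectome for structural tests.
random_connectome <- function(n = 20, p_edge = 0.3, seed = 1,
                              labels = NULL) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < p_edge]
  w[on] <- stats::runif(length(on), 0.05, 1)
  w <- w + t(w)
  connectome(w, matrix(stats::rnorm(3 * n, sd = 20), n, 3),
             region_label = labels)
}

# Connectome with no edges at all.
empty_connectome <- function(n = 4) {
  connectome(matrix(0, n, n))
}

# Single uncoupled node (for fixed-point checks).
single_node <- function() {
  connectome(matrix(0, 1, 1))
}

# Bisection oracle for the uncoupled sigma = 0 stationary gating value:
# solves -S/tau_S + (1 - S) * gamma * H(w*J_N*S + I_0) = 0 on [0, 1].
# Strong recurrent drive can make the balance bistable, so the bracket is
# the FIRST sign change scanning up from S = 0 -- the root a trajectory
# started near zero is attracted to. Independent of the integrator: pure
# root bracketing on the algebraic balance.
fixed_point_oracle <- function(params, iter = 80) {
  f <- function(S) {
    -S / params$tau_S +
      (1 - S) * params$gamma * transfer_rate(params$w * params$J_N * S +
                                               params$I_0, params)
  }
  grid <- seq(0, 1, length.out = 20001)
  vals <- vapply(grid, f, numeric(1))
  stopifnot(vals[1] > 0, vals[length(vals)] < 0)
  first <- which(vals <= 0)[1]
  lo <- grid[first - 1]
  hi <- grid[first]
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exhaustive shortest-path oracle: enumerates all simple paths.
brute_force_shortest <- function(conn, source, target, length_mode) {
  n <- conn$n_nodes
  w <- conn$weights
  len <- function(i, j) {
    if (length_mode == "inverse") 1 / w[i, j] else -log(w[i, j] / max(w))
  }
  best <- list(length = Inf, nodes = integer(0))
  recurse <- function(path, total) {
    cur <- path[length(path)]
    if (cur == target) {
      if (total < best$length - 1e-12 ||
          (abs(total - best$length) <= 1e-12 &&
           .lex_less(path, best$nodes))) {
        best <<- list(length = total, nodes = path)
      }
      return()
    }
    for (nb in which(w[cur, ] != 0)) {
      if (!(nb %in% path)) recurse(c(path, nb), total + len(cur, nb))
    }
  }
  recurse(source, 0)
  best
}

.lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Brute-force efferent edge oracle: double loop over all pairs.
brute_force_efferents <- function(conn, node_set) {
  out <- NULL
  n <- conn$n_nodes
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && conn$weights[i, j] != 0 &&
          (i %in% node_set || j %in% node_set)) {
        out <- rbind(out, data.frame(node_a = i, node_b = j,
                                     weight = conn$weights[i, j]))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(node_a = integer(0), node_b = integer(0),
                      weight = numeric(0))
  }
  out
}
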