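#' Population input-output transfer function
#'
#' Converts a synaptic input current `x` (nA) into a population firing rate
#' (Hz):
#' \deqn{H(x) = \frac{a x - b}{1 - \exp(-d (a x - b))}}
#' The singularity at `a*x = b` is removable; there `H = 1/d`, and a short
#' series expansion is used in a small neighbourhood so the function is
#' smooth and total. `H` is positive, increasing, and asymptotically linear
#' (`~ a*x - b`) for strong input.
#'
#' @param x input current in nA; any numeric vector.
#' @param params a [meanfield_params()] (fields `a`, `b`, `d` are used).
#' @return Firing rates in Hz, same shape as `x`.
#' @examples
#' p <- meanfield_params()
#' transfer_rate(p$b / p$a, p)  # removable singularity: 1/d = 6.4935...
#' @export
transfer_rate <- function(x, params = meanfield_params()) {
  y <- params$a * x - params$b
  u <- params$d * y
  out <- numeric(length(y))
  small <- abs(u) < 1e-8
  big <- u < -700
  mid <- !small & !big
  out[small] <- 1 / params$d + y[small] / 2 + params$d * y[small]^2 / 12
  out[mid] <- y[mid] / (-expm1(-u[mid]))
  out[big] <- 0
  dim(out) <- dim(x)
  out
}

#' Total synaptic input current
#'
#' \deqn{x_i = w J_N S_i + s\, G J_N \sum_j C_{ij} S_j + I_0 + applied_i}
#' where `s` is the coupling sign: `+1` (default, excitatory long-range
#' coupling) or `-1` for the literal inhibitory reading of the coupling
#' term.
#'
#' @param S gating vector, length `n`.
#' @param conn a `connectome` with `n` nodes.
#' @param params a [meanfield_params()].
#' @param applied per-node applied current (nA), scalar or length `n`.
#' @param coupling_sign `+1` or `-1`.
#' @return Input currents in nA, length `n`.
#' @export
synaptic_input <- function(S, conn, params = meanfield_params(), applied = 0,
                           coupling_sign = 1) {
  n <- conn$n_nodes
  if (length(S) != n) {
    stop("length(S) = ", length(S), " does not match n_nodes = ", n)
  }
  params$w * params$J_N * S +
    coupling_sign * params$G * params$J_N * drop(conn$weights %*% S) +
    params$I_0 + applied
}

.initial_state <- function(config, n) {
  s0 <- config$initial_S
  if (length(s0) == 1) s0 <- rep(s0, n)
  if (length(s0) != n) stop("initial_S must be scalar or length n_nodes")
  s0
}

.as_stim_list <- function(stimulation) {
  if (is.null(stimulation)) return(list())
  if (inherits(stimulation, "stimulation")) return(list(stimulation))
  stopifnot(all(vapply(stimulation, inherits, logical(1), "stimulation")))
  stimulation
}

.stim_arrays <- function(stims, n, duration) {
  k <- length(stims)
  amp <- matrix(0, n, max(k, 1))
  on <- numeric(max(k, 1))
  off <- numeric(max(k, 1))
  if (k == 0) return(list(amp = amp[, 0, drop = FALSE],
                          on = numeric(0), off = numeric(0)))
  for (j in seq_len(k)) {
    st <- stims[[j]]
    if (any(st$node_set < 1 | st$node_set > n)) {
      stop("stimulation node IDs must lie in 1..", n)
    }
    if (st$t_off > duration + 1e-12) {
      stop("stimulation window [", st$t_on, ", ", st$t_off,
           ") exceeds run duration ", duration, " s")
    }
    amp[st$node_set, j] <- st$amplitude
    on[j] <- st$t_on
    off[j] <- st$t_off
  }
  list(amp = amp, on = on, off = off)
}

# sample-time applied current matrix (n_samples x n), built from the same
# window convention as the integrator: active when t_on <= t < t_off
.applied_matrix <- function(stims, times, n) {
  if (length(stims) == 0) return(NULL)
  ap <- matrix(0, length(times), n)
  for (st in stims) {
    rows <- times >= st$t_on & times < st$t_off
    ap[rows, st$node_set] <- ap[rows, st$node_set] + st$amplitude
  }
  ap
}

.rate_timeseries <- function(times, S, rate, applied, lesion_mask, model,
                             params, config) {
  structure(
    list(times = times, S = S, rate = rate, applied_current = applied,
         lesion_mask = lesion_mask, model = model, params = params,
         config = config),
    class = "rate_timeseries"
  )
}

#' @export
print.rate_timeseries <- function(x, ...) {
  cat("rate_timeseries (", x$model, "): ", length(x$times), " samples x ",
      ncol(x$rate), " nodes, t in [", format(x$times[1]), ", ",
      format(x$times[length(x$times)]), "] s\n", sep = "")
  invisible(x)
}

#' Simulate the dynamical mean-field model
#'
#' Integrates the coupled stochastic gating equations
#' \deqn{dS_i/dt = -S_i/\tau_S + (1 - S_i)\,\gamma\,H(x_i) + \sigma v_i(t)}
#' with [transfer_rate()] as `H` and [synaptic_input()] as `x`, using an
#' Euler-Maruyama scheme (`S += dt * drift + sigma * sqrt(dt) * N(0,1)` by
#' default; see [sim_config()] for the per-step alternative). The state is
#' clamped into `[0, 1]` after each step when `clamp_S` is set. Identical
#' seed and inputs give bit-identical output; with `sigma = 0` the
#' integration is deterministic.
#'
#' @param conn a `connectome`.
#' @param params a [meanfield_params()].
#' @param config a [sim_config()].
#' @param lesion optional `lesion` (applied to the connectome before
#'   integrating; see [apply_lesion()]).
#' @param stimulation optional `stimulation` or list of stimulations
#'   (applied currents; see [make_stimulation()]).
#' @param coupling_sign `+1` (excitatory network coupling, default) or `-1`
#'   (the literal inhibitory reading of the coupling term).
#' @return A `rate_timeseries` with fields `times` (s), `S` (samples x
#'   nodes gating), `rate` (samples x nodes, Hz), `applied_current`
#'   (samples x nodes nA, or `NULL`), `lesion_mask`.
#' @export
simulate_meanfield <- function(conn, params = meanfield_params(),
                               config = sim_config(), lesion = NULL,
                               stimulation = NULL, coupling_sign = 1) {
  stopifnot(inherits(conn, "connectome"), inherits(params, "meanfield_params"),
            inherits(config, "sim_config"))
  if (!is.null(lesion)) conn <- apply_lesion(conn, lesion)
  n <- conn$n_nodes
  stims <- .as_stim_list(stimulation)
  sa <- .stim_arrays(stims, n, config$duration)
  Csp <- methods::as(methods::as(Matrix::Matrix(conn$weights, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  res <- .mf_integrate(
    Csp@p, Csp@i, Csp@x, n,
    params$w, params$a, params$b, params$d, params$gamma, params$tau_S,
    params$J_N, params$I_0, params$sigma, params$G, coupling_sign,
    config$dt, config$n_steps, config$steps_per_sample,
    .initial_state(config, n), config$clamp_S,
    config$noise_scaling == "sqrt_dt",
    sa$amp, sa$on, sa$off, config$seed
  )
  times <- seq_len(config$n_samples) * config$sample_interval
  .rate_timeseries(times, res$S, res$rate,
                   .applied_matrix(stims, times, n),
                   conn$lesion_mask, "meanfield", params, config)
}

# shared driver for the two discrete-time models; noise enters the summed
# input (linear-threshold) or the updated state (sigmoid)
.simulate_discrete <- function(conn, tpar, config, lesion, stimulation,
                               update, model_name,
                               noise_on = c("input", "state")) {
  noise_on <- match.arg(noise_on)
  stopifnot(inherits(conn, "connectome"), inherits(tpar, "threshold_params"),
            inherits(config, "sim_config"))
  if (!is.null(lesion)) conn <- apply_lesion(conn, lesion)
  n <- conn$n_nodes
  stims <- .as_stim_list(stimulation)
  sa <- .stim_arrays(stims, n, config$duration)
  C <- Matrix::Matrix(conn$weights, sparse = TRUE)
  set.seed(config$seed)
  r <- .initial_state(config, n)
  n_samples <- config$n_samples
  sps <- config$steps_per_sample
  out <- matrix(0, n_samples, n)
  row <- 1L
  for (step in seq_len(config$n_steps)) {
    t <- (step - 1) * config$dt
    input <- as.numeric(C %*% r)
    if (length(sa$on) > 0) {
      for (j in seq_along(sa$on)) {
        if (t >= sa$on[j] && t < sa$off[j]) input <- input + sa$amp[, j]
      }
    }
    if (tpar$noise_sd > 0 && noise_on == "input") {
      input <- input + stats::rnorm(n, sd = tpar$noise_sd)
    }
    r <- update(r, input)
    if (tpar$noise_sd > 0 && noise_on == "state") {
      r <- r + stats::rnorm(n, sd = tpar$noise_sd)
    }
    if (!all(is.finite(r))) {
      stop(model_name, " integration diverged (non-finite state) at step ",
           step)
    }
    if (step %% sps == 0) {
      out[row, ] <- r
      row <- row + 1L
    }
  }
  times <- seq_len(n_samples) * config$sample_interval
  .rate_timeseries(times, NULL, out, .applied_matrix(stims, times, n),
                   conn$lesion_mask, model_name, tpar, config)
}

#' Simulate the linear-threshold population model
#'
#' Synchronous discrete-time update
#' \deqn{a_i(t+1) = g\,[\textstyle\sum_j C_{ij} a_j(t) + applied_i +
#'   \epsilon_i - \theta]_+}
#' with rectification at the threshold `theta`, gain `g`, i.i.d. Gaussian
#' per-step noise `eps`, and an optional saturation cap `r_max`. One update
#' is performed per `dt` step of `config`.
#'
#' @inheritParams simulate_meanfield
#' @param tpar a [threshold_params()].
#' @return A `rate_timeseries` (field `S` is `NULL` for this model).
#' @export
simulate_linear_threshold <- function(conn, tpar = threshold_params(),
                                      config = sim_config(), lesion = NULL,
                                      stimulation = NULL) {
  update <- function(r, input) {
    pmin(tpar$gain * pmax(input - tpar$threshold, 0), tpar$r_max)
  }
  .simulate_discrete(conn, tpar, config, lesion, stimulation, update,
                     "linear_threshold")
}

#' Simulate the sigmoid population model
#'
#' Synchronous discrete-time update with leak:
#' \deqn{r_i(t+1) = (1 - \lambda) r_i(t) +
#'   r_{max}\,\mathrm{logistic}(g (input_i - \theta)) + \epsilon_i}
#' where `input` is the weighted network input plus applied current,
#' `lambda` the per-step decay and `r_max` the drive saturation.
#'
#' @inheritParams simulate_linear_threshold
#' @return A `rate_timeseries` (field `S` is `NULL` for this model).
#' @export
simulate_sigmoid <- function(conn, tpar = threshold_params(),
                             config = sim_config(), lesion = NULL,
                             stimulation = NULL) {
  update <- function(r, input) {
    (1 - tpar$decay) * r +
      tpar$r_max * stats::plogis(tpar$gain * (input - tpar$threshold))
  }
  .simulate_discrete(conn, tpar, config, lesion, stimulation, update,
                     "sigmoid", noise_on = "state")
}

#' Calibrate the global coupling at the edge of the bifurcation
#'
#' Finds the smallest global coupling `G` at which the network's low-firing
#' state destabilizes, by bisection on noise-free (`sigma = 0`) runs started
#' from the near-zero gating state. A run counts as destabilized when the
#' node-mean firing rate, averaged over the final fifth of the run, exceeds
#' `r_low` (20 Hz by default, between the low branch at < 10 Hz and the
#' high branch at > 150 Hz). The resting-state operating point of the
#' published 998-node model sits at this edge (G = 2.3 on the original
#' diffusion-imaging matrix).
#'
#' @param conn a `connectome`.
#' @param params a [meanfield_params()]; `sigma` is forced to 0 during
#'   calibration.
#' @param scan_range length-2 numeric bracket for `G`; the low end must be
#'   stable, the high end unstable.
#' @param tol bisection tolerance on `G`.
#' @param margin subtracted from the critical value before returning.
#' @param r_low destabilization threshold on the node-mean rate (Hz).
#' @param duration length (s) of each probe run.
#' @param config integration grid for the probe runs (duration is
#'   overridden by `duration`).
#' @return The calibrated coupling `G_crit - margin`, with attributes
#'   `bracket` (final stable/unstable bracket) and `r_low`.
#' @export
calibrate_G <- function(conn, params = meanfield_params(),
                        scan_range = c(0.1, 10), tol = 0.01, margin = 0,
                        r_low = 20, duration = 4,
                        config = sim_config(duration = duration,
                                            sample_interval = 1e-2)) {
  stopifnot(length(scan_range) == 2, scan_range[1] < scan_range[2])
  params$sigma <- 0
  probe <- function(G) {
    params$G <- G
    ts <- simulate_meanfield(conn, params, config)
    tail_rows <- ts$times >= 0.8 * config$duration
    mean(ts$rate[tail_rows, , drop = FALSE]) > r_low
  }
  lo <- scan_range[1]
  hi <- scan_range[2]
  if (probe(lo) || !probe(hi)) {
    stop("no bifurcation in range [", lo, ", ", hi,
         "]: the low-firing state must be stable at the low end and ",
         "unstable at the high end")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  structure(hi - margin, bracket = c(stable = lo, unstable = hi),
            r_low = r_low)
}
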