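#' Dynamical mean-field model parameters
#'
#' Parameter set of the reduced one-population mean-field model. Defaults
#' are the standard published values for the 998-node cortical network:
#'
#' | symbol  | meaning                        | default | unit |
#' |---------|--------------------------------|---------|------|
#' | `w`     | local recurrent excitation     | 0.9     | --   |
#' | `a`     | input-output gain              | 270     | Hz/nA |
#' | `b`     | input-output threshold         | 108     | Hz   |
#' | `d`     | input-output curvature         | 0.154   | s    |
#' | `gamma` | kinetic parameter              | 0.641   | --   |
#' | `tau_S` | synaptic gating time constant  | 0.1     | s    |
#' | `J_N`   | synaptic coupling              | 0.2609  | nA   |
#' | `I_0`   | overall external input         | 0.3     | nA   |
#' | `sigma` | noise amplitude                | 0.01    | --   |
#' | `G`     | global coupling scale          | 2.3     | --   |
#'
#' `gamma` is treated as dimensionless with `tau_S` in seconds, which makes
#' the gating equation dimensionally consistent.
#'
#' @param w,a,b,d,gamma,tau_S,J_N,I_0,sigma,G see table above.
#' @return A `meanfield_params` list.
#' @seealso [simulate_meanfield()], [transfer_rate()]
#' @export
meanfield_params <- function(w = 0.9, a = 270, b = 108, d = 0.154,
                             gamma = 0.641, tau_S = 0.1, J_N = 0.2609,
                             I_0 = 0.3, sigma = 0.01, G = 2.3) {
  p <- list(w = w, a = a, b = b, d = d, gamma = gamma, tau_S = tau_S,
            J_N = J_N, I_0 = I_0, sigma = sigma, G = G)
  if (p$tau_S <= 0) stop("tau_S must be positive")
  if (p$d <= 0) stop("d must be positive")
  if (p$a <= 0) stop("a must be positive")
  if (p$sigma < 0) stop("sigma must be non-negative")
  if (p$G < 0) stop("G must be non-negative")
  structure(p, class = "meanfield_params")
}

#' Simulation configuration
#'
#' Integration and sampling grid for all three population models. The
#' default (10 s at a 0.1 ms step, sampled every 1 ms) produces exactly
#' 10,000 samples per node.
#'
#' @param dt integration step in seconds (default `1e-4`, i.e. 0.1 ms).
#' @param duration simulated time in seconds.
#' @param sample_interval sampling period in seconds; must be an integer
#'   multiple of `dt`, and `duration` an integer multiple of it.
#' @param seed integer seed for the run's noise stream.
#' @param initial_S scalar or per-node initial gating value (mean-field
#'   model) or initial activity (discrete models).
#' @param clamp_S clamp the gating variable into `[0, 1]` after every step.
#' @param noise_scaling `"sqrt_dt"` for the Euler-Maruyama convention
#'   (increment `sigma * sqrt(dt) * N(0,1)`), `"per_step"` for plain
#'   additive per-step noise `sigma * N(0,1)`.
#' @return A `sim_config` list with derived fields `n_steps`,
#'   `steps_per_sample` and `n_samples`.
#' @export
sim_config <- function(dt = 1e-4, duration = 10, sample_interval = 1e-3,
                       seed = 1L, initial_S = 0.001, clamp_S = TRUE,
                       noise_scaling = c("sqrt_dt", "per_step")) {
  noise_scaling <- match.arg(noise_scaling)
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")
  sps <- sample_interval / dt
  if (abs(sps - round(sps)) > 1e-6) {
    stop("sample_interval must be an integer multiple of dt")
  }
  sps <- as.integer(round(sps))
  n_samples <- duration / sample_interval
  if (abs(n_samples - round(n_samples)) > 1e-6) {
    stop("duration must be an integer multiple of sample_interval")
  }
  n_samples <- as.integer(round(n_samples))
  structure(
    list(dt = dt, duration = duration, sample_interval = sample_interval,
         seed = as.integer(seed), initial_S = initial_S, clamp_S = clamp_S,
         noise_scaling = noise_scaling,
         steps_per_sample = sps, n_samples = n_samples,
         n_steps = sps * n_samples),
    class = "sim_config"
  )
}

#' Parameters of the discrete linear-threshold and sigmoid models
#'
#' Shared parameter set for the two discrete-time population models. The
#' linear-threshold model rectifies summed input above `threshold` and
#' scales it by `gain` (`decay` and `r_max` are unused there unless a
#' finite `r_max` caps the output). The sigmoid model leaks at rate
#' `decay` per step and adds a logistic drive saturating at `r_max`.
#'
#' @param threshold activation threshold on summed input.
#' @param gain input-output gain (> 0).
#' @param decay per-step leak fraction in `[0, 1]` (sigmoid model).
#' @param noise_sd per-step Gaussian noise standard deviation.
#' @param r_max saturation rate (Hz); `Inf` disables the cap for the
#'   linear-threshold model.
#' @return A `threshold_params` list.
#' @export
threshold_params <- function(threshold = 1, gain = 1, decay = 0.1,
                             noise_sd = 0, r_max = 100) {
  if (gain <= 0) stop("gain must be positive")
  if (decay < 0 || decay > 1) stop("decay must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(threshold = threshold, gain = gain, decay = decay,
                 noise_sd = noise_sd, r_max = r_max),
            class = "threshold_params")
}
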