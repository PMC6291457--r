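#' Simulate an ensemble of contracting junction traces
#'
#' Generates per-junction time series of (t, L, d_v) obeying the coupled
#' dynamics dd_v/dt = -k_c d_v and dL/dt = -k_j(s) L — integrated with the
#' same routine used for model analysis ([integrate_phase()]) — and then
#' adds independent Gaussian measurement noise to L and d_v. Initial
#' straightness is drawn uniformly from `s_init_range`; all junctions start
#' at inter-vertex distance `dv_init` (so L(0) = dv_init / s(0)).
#'
#' Noisy samples violating the geometric constraint d_v <= L are resampled;
#' the number of resampled points is recorded in the `n_resampled`
#' attribute of the result. If the model admits no interior fixed point
#' (k_j0 <= k_c), the ensemble is still generated but flagged via the
#' `no_fixed_point` attribute and a warning.
#'
#' @param model a [removal_rate_model()].
#' @param n number of junctions.
#' @param s_init_range length-2 numeric in (0, 1]: uniform range of initial
#'   straightness.
#' @param dv_init initial inter-vertex distance, um.
#' @param duration total simulated time, min.
#' @param dt sampling interval, min.
#' @param meas_noise_sd Gaussian measurement noise SD on L and d_v, um.
#' @param seed integer seed.
#' @return list of [junction_trace()] objects; attribute `noiseless` holds
#'   the noise-free traces, `n_resampled` the resample count.
#' @export
simulate_junction_ensemble <- function(model, n = 50L,
                                       s_init_range = c(0.6, 0.999),
                                       dv_init = 12.3, duration = 60,
                                       dt = 0.5, meas_noise_sd = 0,
                                       seed = 1L) {
  stopifnot(inherits(model, "removal_rate_model"), n >= 1L, dt > 0,
            duration >= dt, dv_init > 0, meas_noise_sd >= 0)
  if (length(s_init_range) != 2L || any(s_init_range <= 0) ||
      any(s_init_range > 1) || s_init_range[1L] > s_init_range[2L])
    stop("`s_init_range` must be an increasing interval within (0, 1]")
  no_fp <- !steady_state_straightness(model)$exists
  if (no_fp)
    warning("model has no interior fixed point (k_c outside (0, k_j0))")
  t_grid <- seq(0, duration, by = dt)
  n_resampled <- 0L
  res <- with_seed(seed, {
    s0s <- stats::runif(n, s_init_range[1L], s_init_range[2L])
    clean <- vector("list", n); noisy <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- integrate_phase(dv_init / s0s[i], dv_init, model, t_grid)
      clean[[i]] <- junction_trace(ph$time, ph$L, ph$d_v, junction_id = i)
      L <- ph$L; dv <- ph$d_v
      if (meas_noise_sd > 0) {
        L <- L + stats::rnorm(length(L), 0, meas_noise_sd)
        dv <- dv + stats::rnorm(length(dv), 0, meas_noise_sd)
        bad <- which(dv > L | L <= 0 | dv <= 0)
        guard <- 0L
        while (length(bad) && guard < 1000L) {
          n_resampled <- n_resampled + length(bad)
          L[bad] <- ph$L[bad] + stats::rnorm(length(bad), 0, meas_noise_sd)
          dv[bad] <- ph$d_v[bad] + stats::rnorm(length(bad), 0, meas_noise_sd)
          bad <- which(dv > L | L <= 0 | dv <= 0)
          guard <- guard + 1L
        }
      }
      noisy[[i]] <- junction_trace(ph$time, L, dv, junction_id = i)
    }
    list(clean = clean, noisy = noisy)
  })
  out <- res$noisy
  attr(out, "noiseless") <- res$clean
  attr(out, "n_resampled") <- n_resampled
  attr(out, "no_fixed_point") <- no_fp
  out
}
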