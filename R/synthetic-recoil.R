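#' Generate synthetic post-ablation recoil traces
#'
#' Tip-displacement traces after laser dissection of a junction, following
#' the saturating exponential \eqn{f(t) = A (1 - e^{-t/\tau})} with i.i.d.
#' additive Gaussian noise. Sampling starts at the cut (t = 0), where the
#' displacement is zero up to noise.
#'
#' @param A total retraction amplitude, um; > 0.
#' @param tau decay constant, s; > 0.
#' @param n number of traces.
#' @param frame_rate imaging rate in Hz (typically 1--3).
#' @param duration trace duration in s; a duration shorter than `tau`
#'   triggers a warning since the fit is then poorly constrained.
#' @param noise_sd Gaussian noise SD, um.
#' @param seed integer seed.
#' @return list of `recoil_trace` data.frames with columns `time`
#'   (s) and `displacement` (um); attribute `noiseless` holds the clean
#'   displacement vector.
#' @export
make_recoil_traces <- function(A = 2, tau = 10, n = 50L, frame_rate = 1,
                               duration = 40, noise_sd = 0.1, seed = 1L) {
  stopifnot(A > 0, tau > 0, n >= 1L, frame_rate > 0, duration > 0,
            noise_sd >= 0)
  if (duration < tau)
    warning("trace duration shorter than tau: expect a poorly constrained fit")
  t <- seq(0, duration, by = 1 / frame_rate)
  clean <- A * (1 - exp(-t / tau))
  traces <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      d <- clean + stats::rnorm(length(t), 0, noise_sd)
      structure(data.frame(time = t, displacement = d),
                trace_id = i, class = c("recoil_trace", "data.frame"))
    })
  })
  attr(traces, "noiseless") <- clean
  traces
}
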