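#' Fit a single-exponential recoil to a post-ablation trace
#'
#' Fits tip displacement after laser dissection with
#' \eqn{f(t) = A (1 - e^{-t/\tau})} (no offset: the displacement is pinned
#' at zero at the cut) by nonlinear least squares, and reports the initial
#' recoil velocity \eqn{V_0 = A/\tau}, the standard relative proxy for
#' junctional tension under the assumption of constant friction.
#'
#' Starting values are A0 = final displacement and tau0 = the first time
#' the trace reaches (1 - 1/e) A0. An `offset` term can be enabled for
#' real-data drift; it is off by default.
#'
#' @param trace data.frame with columns `time` (s, increasing from 0) and
#'   `displacement` (um), at least 5 samples.
#' @param offset logical; include an additive offset term.
#' @return list of class `recoil_fit` with `A` (um), `tau_r` (s), `V0`
#'   (= A/tau_r, um/s), `residual_sd` (um), and the `fit` object.
#' @export
fit_recoil <- function(trace, offset = FALSE) {
  stopifnot(is.data.frame(trace),
            all(c("time", "displacement") %in% names(trace)))
  t <- trace$time; d <- trace$displacement
  if (length(t) < 5L) stop("need at least 5 samples to fit a recoil trace")
  if (t[1L] != 0 || any(diff(t) <= 0))
    stop("`time` must increase from 0 (the cut)")
  A0 <- max(d[length(d)], max(d) * 0.5, 1e-6)
  i63 <- which(d >= (1 - exp(-1)) * A0)
  tau0 <- if (length(i63)) max(t[i63[1L]], t[2L]) else max(t) / 2
  dat <- data.frame(t = t, d = d)
  fit <- tryCatch({
    if (offset)
      minpack.lm::nlsLM(d ~ A * (1 - exp(-t / tau)) + b, data = dat,
                        start = list(A = A0, tau = tau0, b = 0),
                        lower = c(1e-9, 1e-9, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(d ~ A * (1 - exp(-t / tau)), data = dat,
                        start = list(A = A0, tau = tau0),
                        lower = c(1e-9, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
  }, error = function(e) stop("recoil fit did not converge: ",
                              conditionMessage(e)))
  est <- stats::coef(fit)
  if (est[["tau"]] > 10 * max(t))
    stop("unconstrained fit: tau exceeds 10x the trace duration")
  structure(list(A = est[["A"]], tau_r = est[["tau"]],
                 V0 = est[["A"]] / est[["tau"]],
                 residual_sd = stats::sd(stats::resid(fit)),
                 offset = if (offset) est[["b"]] else 0,
                 fit = fit),
            class = "recoil_fit")
}

#' @export
print.recoil_fit <- function(x, ...) {
  cat(sprintf(
    "<recoil_fit> A = %.4g um, tau = %.4g s, V0 = %.4g um/s (resid SD %.3g)\n",
    x$A, x$tau_r, x$V0, x$residual_sd))
  invisible(x)
}

#' Bin initial recoil velocities by junction straightness
#'
#' Tabulates mean initial recoil velocity V0 (+/- SE) in straightness bins,
#' the form in which recoil velocity is read as a tension-versus-
#' straightness relation. Empty bins are dropped.
#'
#' @param fits list of [fit_recoil()] results (or numeric V0 values).
#' @param s straightness of the ablated junction for each fit.
#' @param edges increasing straightness bin edges.
#' @return data.frame with columns `s_bin_center`, `mean_V0`, `se_V0`, `n`.
#' @export
velocity_vs_straightness <- function(fits, s,
                                     edges = seq(0.5, 1, by = 0.1)) {
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("`edges` must be increasing bin edges")
  V0 <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$V0, numeric(1L))
  stopifnot(length(V0) == length(s))
  bin <- cut(s, breaks = edges, include.lowest = TRUE)
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(V0, bin), function(v) {
    if (!length(v)) return(NULL)
    data.frame(mean_V0 = mean(v), se_V0 = sem(v), n = length(v))
  })
  keep <- !vapply(agg, is.null, logical(1L))
  out <- cbind(data.frame(s_bin_center = centers[keep]),
               do.call(rbind, agg[keep]))
  rownames(out) <- NULL
  out
}
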