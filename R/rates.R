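#' Construct a junction time trace
#'
#' Per-junction time series of path length L and inter-vertex distance d_v,
#' the measurement unit for rate estimation and model fitting.
#'
#' @param times time points in minutes, strictly increasing.
#' @param L junction path lengths in micrometres, > 0.
#' @param d_v inter-vertex distances in micrometres, > 0.
#' @param junction_id identifier (any scalar).
#' @param condition optional tag, `"unperturbed"` or
#'   `"after_stretch_release"`.
#' @return a data.frame of class `junction_trace` with columns `time`, `L`,
#'   `d_v`, `s`.
#' @export
junction_trace <- function(times, L, d_v, junction_id = 1L,
                           condition = c("unperturbed",
                                         "after_stretch_release")) {
  condition <- match.arg(condition)
  stopifnot(length(times) == length(L), length(times) == length(d_v))
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(L <= 0) || any(d_v <= 0)) stop("lengths must be positive")
  out <- data.frame(time = times, L = L, d_v = d_v, s = d_v / L)
  attr(out, "junction_id") <- junction_id
  attr(out, "condition") <- condition
  class(out) <- c("junction_trace", "data.frame")
  out
}

#' Estimate removal and contraction rates on fixed time intervals
#'
#' Under the exponential dynamics dL/dt = -k_j L and dd_v/dt = -k_c d_v,
#' the rates over an interval \eqn{[t, t + \Delta t]} are recovered by
#' log-ratios:
#' \deqn{k_j = \log(L(t)/L(t+\Delta t))/\Delta t, \quad
#'       k_c = \log(d_v(t)/d_v(t+\Delta t))/\Delta t.}
#' Rates are positive for shrinkage; growth yields negative rates and is
#' returned as-is. Each sample is tagged with the straightness at the
#' interval start, `s_mid = d_v(t)/L(t)`. Intervals are consecutive and
#' non-overlapping; the realised interval is the closest available sample
#' spacing at least `window` long.
#'
#' @param trace a [junction_trace()].
#' @param window interval length in minutes (default 12.5, the midpoint of
#'   the 10--15 min measurement window).
#' @return data.frame of class `rate_samples` with columns `s_mid`, `k_j`,
#'   `k_c`, `dt`, `t_start`, `junction_id`.
#' @export
estimate_rates <- function(trace, window = 12.5) {
  stopifnot(is.data.frame(trace), all(c("time", "L", "d_v") %in% names(trace)))
  if (any(trace$L <= 0) || any(trace$d_v <= 0))
    stop("non-positive lengths in trace")
  if (diff(range(trace$time)) < window)
    stop("trace shorter than the estimation window")
  tt <- trace$time
  rows <- list(); i <- 1L
  while (TRUE) {
    j <- which(tt >= tt[i] + window)
    if (!length(j)) break
    j <- j[1L]
    dt <- tt[j] - tt[i]
    rows[[length(rows) + 1L]] <- data.frame(
      s_mid = trace$d_v[i] / trace$L[i],
      k_j = log(trace$L[i] / trace$L[j]) / dt,
      k_c = log(trace$d_v[i] / trace$d_v[j]) / dt,
      dt = dt, t_start = tt[i])
    i <- j
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(s_mid = numeric(), k_j = numeric(), k_c = numeric(),
               dt = numeric(), t_start = numeric())
  out$junction_id <- rep(attr(trace, "junction_id") %||% NA, nrow(out))
  class(out) <- c("rate_samples", "data.frame")
  out
}

#' Estimate rates for an ensemble of traces
#'
#' Convenience wrapper applying [estimate_rates()] to each trace in a list
#' and row-binding the samples.
#'
#' @param traces list of [junction_trace()] objects.
#' @inheritParams estimate_rates
#' @return combined `rate_samples` data.frame.
#' @export
estimate_rates_ensemble <- function(traces, window = 12.5) {
  out <- do.call(rbind, lapply(traces, estimate_rates, window = window))
  class(out) <- c("rate_samples", "data.frame")
  out
}

#' Bin rate samples by straightness
#'
#' Groups rate samples into straightness bins and reports per-bin means and
#' standard errors of the removal and contraction rates, the form in which
#' the removal rate's straightness dependence is displayed and fitted.
#' Empty bins are dropped.
#'
#' @param samples a `rate_samples` data.frame (see [estimate_rates()]).
#' @param edges increasing straightness bin edges.
#' @return data.frame with columns `s_bin_center`, `mean_k_j`, `se_k_j`,
#'   `mean_k_c`, `se_k_c`, `n`.
#' @export
bin_rates_by_straightness <- function(samples,
                                      edges = seq(0.6, 1.05, by = 0.05)) {
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("`edges` must be increasing bin edges")
  if (!nrow(samples))
    return(data.frame(s_bin_center = numeric(), mean_k_j = numeric(),
                      se_k_j = numeric(), mean_k_c = numeric(),
                      se_k_c = numeric(), n = integer()))
  bin <- cut(samples$s_mid, breaks = edges, include.lowest = TRUE)
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(samples, bin), function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(mean_k_j = mean(d$k_j), se_k_j = sem(d$k_j),
               mean_k_c = mean(d$k_c), se_k_c = sem(d$k_c), n = nrow(d))
  })
  keep <- !vapply(agg, is.null, logical(1L))
  out <- cbind(data.frame(s_bin_center = centers[keep]),
               do.call(rbind, agg[keep]))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
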