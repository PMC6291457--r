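#' Sigmoid junction removal-rate model
#'
#' Parameter container for the straightness dynamics of a contracting
#' junction. The junction path length L shrinks as dL/dt = -k_j(s) L with a
#' removal rate that decreases sigmoidally with straightness s,
#' \deqn{k_j(s) = \frac{k_{j0}}{e^{r (s - s_0)} + 1},}
#' while the inter-vertex distance contracts at a constant tissue rate,
#' dd_v/dt = -k_c d_v. Straightness s = d_v/L then obeys
#' ds/dt = (k_j(s) - k_c) s.
#'
#' The defaults are the wild-type dorsal-closure fit: k_j0 = 0.0205 1/min,
#' s0 = 0.9202, r = 68.3, and average contraction rate k_c = 0.0091 1/min.
#'
#' @param k_j0 sigmoid plateau removal rate, 1/min; > 0.
#' @param s0 sigmoid midpoint straightness, in (0, 1).
#' @param r dimensionless sigmoid steepness; > 0.
#' @param k_c contraction rate of the inter-vertex distance, 1/min; >= 0.
#' @return an object of class `removal_rate_model`.
#' @examples
#' m <- removal_rate_model()
#' removal_rate(m$s0, m)      # half the plateau
#' steady_state_straightness(m)
#' @export
removal_rate_model <- function(k_j0 = 0.0205, s0 = 0.9202, r = 68.3,
                               k_c = 0.0091) {
  stopifnot(is.numeric(k_j0), length(k_j0) == 1L, k_j0 > 0,
            is.numeric(s0), length(s0) == 1L, s0 > 0, s0 < 1,
            is.numeric(r), length(r) == 1L, r > 0,
            is.numeric(k_c), length(k_c) == 1L, k_c >= 0)
  structure(list(k_j0 = k_j0, s0 = s0, r = r, k_c = k_c),
            class = "removal_rate_model")
}

#' @export
print.removal_rate_model <- function(x, ...) {
  cat(sprintf(
    "<removal_rate_model> k_j0 = %.4g /min, s0 = %.4g, r = %.4g, k_c = %.4g /min\n",
    x$k_j0, x$s0, x$r, x$k_c))
  fp <- steady_state_straightness(x)
  if (fp$exists)
    cat(sprintf("  fixed point s* = %.4f, relaxation tau = %.3g min\n",
                fp$s_star, fp$tau))
  else cat("  no interior fixed point (k_c outside (0, k_j0))\n")
  invisible(x)
}

#' Junction removal rate k_j(s)
#'
#' Evaluates the decreasing sigmoid k_j(s) = k_j0 / (exp(r (s - s0)) + 1).
#' Evaluation outside (0, 1] is permitted (the sigmoid is defined on the
#' whole real line; fitting routines probe it there).
#'
#' @param s straightness value(s); any finite numeric.
#' @param model a [removal_rate_model()].
#' @return removal rate(s) in 1/min.
#' @export
removal_rate <- function(s, model) {
  stopifnot(inherits(model, "removal_rate_model"), all(is.finite(s)))
  model$k_j0 / (exp(model$r * (s - model$s0)) + 1)
}

# analytic derivative dk_j/ds, used by the relaxation timescale
removal_rate_deriv <- function(s, model) {
  e <- exp(model$r * (s - model$s0))
  -model$k_j0 * model$r * e / (e + 1)^2
}

#' Steady-state straightness of the removal/contraction balance
#'
#' The fixed point s* of ds/dt = (k_j(s) - k_c) s solves k_j(s*) = k_c:
#' straightness loss through tissue contraction is exactly balanced by
#' straightness gain through junction removal. Because the sigmoid is
#' strictly decreasing, the root is unique and available in closed form,
#' \deqn{s^* = s_0 + \log(k_{j0}/k_c - 1) / r,}
#' valid whenever 0 < k_c < k_j0. Otherwise no balance is possible and the
#' result carries `exists = FALSE` (straightness then grows or decays
#' exponentially until the model's assumptions break down).
#'
#' @param model a [removal_rate_model()].
#' @return a list of class `fixed_point_result` with elements `s_star`,
#'   `tau` (the linearised relaxation timescale, min), and `exists`.
#' @export
steady_state_straightness <- function(model) {
  stopifnot(inherits(model, "removal_rate_model"))
  if (model$k_c <= 0 || model$k_c >= model$k_j0) {
    return(structure(list(s_star = NA_real_, tau = NA_real_, exists = FALSE),
                     class = "fixed_point_result"))
  }
  s_star <- model$s0 + log(model$k_j0 / model$k_c - 1) / model$r
  tau <- -1 / (removal_rate_deriv(s_star, model) * s_star)
  structure(list(s_star = s_star, tau = tau, exists = TRUE),
            class = "fixed_point_result")
}

#' @export
print.fixed_point_result <- function(x, ...) {
  if (x$exists)
    cat(sprintf("<fixed_point> s* = %.6f, tau = %.4f min\n", x$s_star, x$tau))
  else cat("<fixed_point> none (k_c outside (0, k_j0))\n")
  invisible(x)
}

#' Relaxation timescale of straightness perturbations
#'
#' Linearising ds/dt = (k_j(s) - k_c) s around the fixed point gives
#' d(s - s*)/dt = k_j'(s*) s* (s - s*), so perturbations decay with the
#' characteristic time \eqn{\tau = -1 / (k_j'(s^*)\, s^*)}, where k_j' is
#' the analytic sigmoid derivative. For the wild-type fit this is about
#' 3.1 min.
#'
#' @param model a [removal_rate_model()].
#' @return timescale in minutes.
#' @export
relaxation_timescale <- function(model) {
  fp <- steady_state_straightness(model)
  if (!fp$exists)
    stop("no interior fixed point: relaxation timescale undefined")
  fp$tau
}

#' Integrate the straightness ODE
#'
#' Integrates ds/dt = (k_j(s) - k_c) s from `s_init` over `t_grid` with an
#' adaptive integrator (relative tolerance 1e-9). The state is never
#' clamped: geometry requires s <= 1, so if the trajectory exceeds 1 the
#' constant-contraction assumptions have broken down and the result is
#' flagged via the `breakdown` attribute rather than truncated.
#'
#' @param s_init initial straightness in (0, 1].
#' @param model a [removal_rate_model()].
#' @param t_grid increasing time grid in minutes, starting at 0.
#' @param rtol,atol integrator tolerances.
#' @return numeric vector s(t) along `t_grid`, with attribute `breakdown`
#'   (TRUE if s exceeded 1 anywhere on the grid).
#' @export
integrate_straightness <- function(s_init, model, t_grid,
                                   rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(model, "removal_rate_model"),
            is.numeric(s_init), length(s_init) == 1L)
  if (!is.finite(s_init) || s_init <= 0)
    stop("`s_init` must be positive")
  check_time_grid(t_grid)
  deriv <- function(t, y, parms) list((removal_rate(y, model) - model$k_c) * y)
  out <- deSolve::ode(y = c(s = s_init), times = t_grid, func = deriv,
                      parms = NULL, rtol = rtol, atol = atol)
  s <- unname(out[, "s"])
  attr(s, "breakdown") <- any(s > 1)
  s
}

#' Integrate the (L, d_v) phase-space trajectory
#'
#' Joint integration of dL/dt = -k_j(s) L and dd_v/dt = -k_c d_v with
#' s = d_v / L. The derived straightness d_v(t)/L(t) coincides with
#' [integrate_straightness()] started from s_init = dv_init / L_init.
#'
#' @param L_init initial path length, um; > 0.
#' @param dv_init initial inter-vertex distance, um; 0 < dv_init <= L_init.
#' @param model a [removal_rate_model()].
#' @param t_grid increasing time grid in minutes, starting at 0.
#' @param rtol,atol integrator tolerances.
#' @return data.frame with columns `time`, `L`, `d_v`, `s`.
#' @export
integrate_phase <- function(L_init, dv_init, model, t_grid,
                            rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(model, "removal_rate_model"),
            is.numeric(L_init), is.numeric(dv_init))
  if (!(L_init > 0) || !(dv_init > 0) || dv_init > L_init)
    stop("need 0 < dv_init <= L_init")
  check_time_grid(t_grid)
  deriv <- function(t, y, parms) {
    s <- y[2L] / y[1L]
    list(c(-removal_rate(s, model) * y[1L], -model$k_c * y[2L]))
  }
  out <- deSolve::ode(y = c(L = L_init, d_v = dv_init), times = t_grid,
                      func = deriv, parms = NULL, rtol = rtol, atol = atol)
  data.frame(time = t_grid, L = unname(out[, "L"]),
             d_v = unname(out[, "d_v"]),
             s = unname(out[, "d_v"] / out[, "L"]))
}

check_time_grid <- function(t_grid) {
  if (length(t_grid) < 2L || t_grid[1L] != 0 || any(diff(t_grid) <= 0))
    stop("`t_grid` must be an increasing grid starting at 0")
  invisible(t_grid)
}

#' Fit the sigmoid removal-rate law to rate samples
#'
#' Nonlinear least squares for (k_j0, s0, r) on (s, k_j) pairs, typically
#' the output of [estimate_rates()] or [bin_rates_by_straightness()]. If
#' standard errors are supplied the fit is weighted by 1/SE^2 (default
#' unweighted). The contraction rate is not part of the nonlinear fit: it
#' is taken as the plain mean of the supplied contraction-rate samples,
#' reflecting its lack of clear straightness dependence.
#'
#' @param s straightness values of the samples.
#' @param k_j removal-rate values, 1/min.
#' @param k_c optional contraction-rate samples, averaged into the fitted
#'   model's `k_c` (default: 0, i.e. unknown).
#' @param se optional standard errors on `k_j` for weighting.
#' @param init a [removal_rate_model()] used as the starting point.
#' @param lower,upper parameter bounds for (k_j0, s0, r).
#' @return a list with the fitted `model` ([removal_rate_model()]),
#'   `residual_ss`, parameter covariance `vcov`, standard errors `se`, and
#'   the underlying `fit` object.
#' @export
fit_removal_rate <- function(s, k_j, k_c = NULL, se = NULL,
                             init = removal_rate_model(),
                             lower = c(k_j0 = 1e-6, s0 = 0.01, r = 0.1),
                             upper = c(k_j0 = 1, s0 = 2, r = 1e4)) {
  stopifnot(length(s) == length(k_j))
  keep <- is.finite(s) & is.finite(k_j)
  s <- s[keep]; k_j <- k_j[keep]
  if (!is.null(se)) se <- se[keep]
  if (length(s) < 4L)
    stop("under-determined: need at least 4 (s, k_j) samples for 3 parameters")
  dat <- data.frame(s = s, k_j = k_j)
  w <- if (is.null(se)) rep(1, length(s)) else 1 / se^2
  fit <- minpack.lm::nlsLM(
    k_j ~ k_j0 / (exp(r * (s - s0)) + 1),
    data = dat, weights = w,
    start = list(k_j0 = init$k_j0, s0 = init$s0, r = init$r),
    lower = unname(lower), upper = unname(upper),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- stats::coef(fit)
  at_bound <- est["r"] >= upper["r"] * (1 - 1e-8) ||
    est["r"] <= lower["r"] * (1 + 1e-8)
  if (at_bound) warning("steepness `r` hit a bound; fit poorly constrained")
  kc_hat <- if (is.null(k_c) || !length(k_c)) 0 else mean(k_c, na.rm = TRUE)
  model <- removal_rate_model(k_j0 = est[["k_j0"]],
                              s0 = min(max(est[["s0"]], 1e-8), 1 - 1e-8),
                              r = est[["r"]], k_c = max(kc_hat, 0))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  list(model = model,
       residual_ss = sum(stats::resid(fit)^2),
       vcov = vc,
       se = if (is.null(vc)) NULL else sqrt(diag(vc)),
       fit = fit)
}
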