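#' Generate a ruffled junction polyline of prescribed straightness
#'
#' Builds a junction path between two vertices a distance `d_v` apart whose
#' measured straightness matches `s_target`. Ruffles are a sum of
#' transverse sinusoidal modes vanishing at the endpoints,
#' \eqn{y(x) = a \sum_m c_m \sin(m \pi x / d_v)}, with seeded random mode
#' coefficients; the overall amplitude `a` is calibrated by bisection so
#' that the discrete arc length of the returned polyline equals
#' d_v / s_target.
#'
#' @param d_v inter-vertex distance in micrometres; > 0.
#' @param s_target straightness in (0, 1].
#' @param n_modes number of sinusoidal ruffle modes (>= 1 unless
#'   `s_target = 1`).
#' @param n_points number of polyline points (>= 2).
#' @param seed integer seed for the mode coefficients.
#' @return a [junction_polyline()] whose [straightness()] is within 1e-3 of
#'   `s_target` (bisection tolerance 1e-6).
#' @export
make_ruffled_polyline <- function(d_v, s_target, n_modes = 4L,
                                  n_points = 200L, seed = 1L) {
  stopifnot(d_v > 0, n_points >= 2L)
  if (!is.finite(s_target) || s_target <= 0 || s_target > 1)
    stop("`s_target` must lie in (0, 1]")
  x <- seq(0, d_v, length.out = max(n_points, 2L))
  if (s_target == 1)
    return(junction_polyline(cbind(x, 0)))
  if (n_modes < 1L) stop("need at least one ruffle mode when s_target < 1")
  if (n_points < 8L * n_modes)
    n_points <- 8L * n_modes  # resolve the highest mode
  x <- seq(0, d_v, length.out = n_points)
  coef <- with_seed(seed, stats::rnorm(n_modes))
  if (all(coef == 0)) coef <- rep(1, n_modes)
  basis <- vapply(seq_len(n_modes),
                  function(m) coef[m] * sin(m * pi * x / d_v), numeric(length(x)))
  shape <- rowSums(basis)
  shape <- shape / max(abs(shape))
  L_target <- d_v / s_target
  arc <- function(a) sum(sqrt(diff(x)^2 + diff(a * shape)^2))
  lo <- 0; hi <- d_v
  while (arc(hi) < L_target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (arc(mid) < L_target) lo <- mid else hi <- mid
    if (abs(arc(mid) / d_v - 1 / s_target) < 1e-9) break
  }
  junction_polyline(cbind(x, ((lo + hi) / 2) * shape))
}

# run code under a private, restorable RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
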