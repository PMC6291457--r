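#' Construct a junction polyline
#'
#' A junction is represented as an ordered 2D point path between its two
#' tricellular vertices. All coordinates are in micrometres. The polyline is
#' the carrier of the three junction geometry quantities: the path length
#' \eqn{L} (arc length of the traced path), the inter-vertex distance
#' \eqn{d_v} (straight-line distance between the endpoints), and the
#' straightness \eqn{s = d_v / L}.
#'
#' @param points numeric matrix with two columns (x, y) and at least two
#'   rows, ordered from one vertex to the other, in micrometres.
#' @return an object of class `junction_polyline`.
#' @seealso [path_length()], [straightness()], [make_ruffled_polyline()]
#' @export
junction_polyline <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be a numeric matrix with columns (x, y)")
  if (nrow(points) < 2L)
    stop("a junction polyline needs at least 2 points")
  if (anyNA(points) || any(!is.finite(points)))
    stop("polyline coordinates must be finite")
  dup <- rowSums(abs(diff(points))) == 0
  if (any(dup)) points <- points[c(TRUE, !dup), , drop = FALSE]
  if (nrow(points) < 2L)
    stop("polyline collapses to a single point")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points), class = "junction_polyline")
}

#' @export
print.junction_polyline <- function(x, ...) {
  cat(sprintf(
    "<junction_polyline> %d points; L = %.4g um, d_v = %.4g um, s = %.4g\n",
    nrow(x$points), path_length(x), intervertex_distance(x), straightness(x)))
  invisible(x)
}

as_polyline <- function(p) {
  if (inherits(p, "junction_polyline")) p else junction_polyline(p)
}

#' Junction path length L
#'
#' Arc length of the junction path: the sum of Euclidean distances between
#' consecutive polyline points.
#'
#' @param p a [junction_polyline()] or a two-column coordinate matrix.
#' @return path length in micrometres.
#' @export
path_length <- function(p) {
  p <- as_polyline(p)
  sum(sqrt(rowSums(diff(p$points)^2)))
}

#' Inter-vertex distance d_v
#'
#' Straight-line distance between the two endpoints (tricellular vertices)
#' of a junction path.
#'
#' @inheritParams path_length
#' @return inter-vertex distance in micrometres.
#' @export
intervertex_distance <- function(p) {
  p <- as_polyline(p)
  pts <- p$points
  sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
}

#' Junction straightness s
#'
#' The ratio of the inter-vertex distance to the path length,
#' \eqn{s = d_v / L \in (0, 1]}. A taut junction has \eqn{s = 1}; a ruffled
#' junction with excess material has \eqn{s < 1}.
#'
#' @inheritParams path_length
#' @return dimensionless straightness in (0, 1].
#' @export
straightness <- function(p) {
  p <- as_polyline(p)
  dv <- intervertex_distance(p)
  if (dv == 0)
    stop("coincident endpoints: straightness is undefined for closed loops")
  dv / path_length(p)
}
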