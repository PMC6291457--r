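#' Constant-area ellipse deformation of a squeezed cross-section
#'
#' Models the change in a circular cross-section squeezed laterally while
#' conserving area, as when an embryo is compressed between coverslips: the
#' lateral semi-axis grows by the imposed strain, a -> a (1 + eps), and
#' area conservation forces the height to b -> b / (1 + eps). The perimeter
#' of the resulting ellipse is evaluated with Ramanujan's second
#' approximation,
#' \deqn{P \approx \pi (a + b) \left(1 + \frac{3h}{10 + \sqrt{4 - 3h}}\right),
#'       \quad h = \left(\frac{a - b}{a + b}\right)^2.}
#'
#' @param lateral_strain signed fractional strain eps along the lateral
#'   axis; must be > -1.
#' @return a list with `height_strain` (= 1/(1+eps) - 1) and
#'   `perimeter_strain`, both signed fractions relative to the undeformed
#'   circle.
#' @examples
#' ellipse_deformation(0.30)  # ~ -23% height, ~ +5% perimeter
#' @export
ellipse_deformation <- function(lateral_strain) {
  stopifnot(is.numeric(lateral_strain), length(lateral_strain) == 1L,
            is.finite(lateral_strain))
  if (lateral_strain <= -1) stop("`lateral_strain` must be > -1")
  a <- 1 + lateral_strain
  b <- 1 / a                       # unit circle, area pi conserved
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  list(height_strain = b - 1, perimeter_strain = per / (2 * pi) - 1)
}
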