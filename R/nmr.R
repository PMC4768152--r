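# Deuterium quadrupolar splittings under motional averaging.  Each fast
# motional mode (rotation about an axis making angle beta with the C-D
# interaction tensor) scales the quadrupolar coupling by the second
# order Legendre factor (3 cos^2 beta - 1) / 2; independent fast modes
# multiply.  The powder-pattern (Pake) splitting between the two horns is
# (3/4) of the effective coupling.

#' Motional-averaging order factor
#'
#' @param beta angle in degrees between the averaging axis and the
#'   interaction tensor, in `[0, 180]`.
#' @return `(3 cos^2 beta - 1) / 2`, in `[-0.5, 1]`.
#' @examples
#' orderScaling(0)        #  1
#' orderScaling(90)       # -0.5
#' orderScaling(54.7356)  # ~0 (magic angle)
#' @export
orderScaling <- function(beta) {
  beta <- as.numeric(beta)
  if (any(is.na(beta)) || any(beta < 0) || any(beta > 180))
    stop("beta must lie in [0, 180] degrees")
  0.5 * (3 * cos(beta * pi / 180)^2 - 1)
}

#' Tetrahedral methyl-rotation angle
#'
#' The angle between a C-D bond of a methyl group and its three-fold
#' rotation axis, `acos(1/3)` = 70.5288 degrees; rapid methyl rotation
#' scales the quadrupolar coupling by exactly |1/2 (3 * (1/3) - 1)| = 1/3.
#'
#' @return Angle in degrees.
#' @export
tetrahedralAngle <- function() acos(1 / 3) * 180 / pi

#' Powder-pattern quadrupolar splitting under motional averaging
#'
#' @param chi static quadrupolar coupling constant in kHz (default 167,
#'   the static value for a C-D bond in a rigid methyl group).
#' @param modes angles (degrees) of the fast motional modes applied in
#'   sequence; each contributes a factor `|orderScaling(beta)|` and the
#'   order of modes is immaterial.  No modes gives the rigid-limit
#'   splitting `(3/4) chi`.
#' @return Splitting between the Pake horns, in kHz.
#' @examples
#' quadSplitting()                        # rigid limit: 125.25 kHz
#' quadSplitting(modes = tetrahedralAngle())  # rotating methyl: 41.75 kHz
#' @export
quadSplitting <- function(chi = 167, modes = numeric(0)) {
  chi <- as.numeric(chi)
  if (length(chi) != 1L || is.na(chi) || chi <= 0)
    stop("chi must be a single positive coupling in kHz")
  scale <- if (length(modes)) prod(abs(orderScaling(modes))) else 1
  0.75 * chi * scale
}
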