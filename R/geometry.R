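# Conversion constant hc in keV * Angstrom (CODATA-rounded).
.hc_keV_A <- 12.3984193

#' X-ray wavelength from photon energy
#'
#' @param energy photon energy in keV.
#' @return Wavelength in metres, \eqn{\lambda = hc/E} with
#'   \eqn{hc = 12.3984193} keV Angstrom.
#' @examples
#' wavelength(13.8)  # ~8.98e-11 m
#' @export
wavelength <- function(energy) {
  if (!is.numeric(energy) || any(!is.finite(energy)) || any(energy <= 0))
    stop("energy must be positive (keV)")
  .hc_keV_A / energy * 1e-10
}

#' Geometric magnification of a cone-beam setup
#'
#' @param g a [ConeBeamGeometry-class].
#' @return \eqn{M = z_{02}/z_{01} > 1}.
#' @export
magnification <- function(g) {
  stopifnot(is(g, "ConeBeamGeometry"))
  validObject(g)
  g@z02 / g@z01
}

#' Effective (demagnified) pixel size
#'
#' @param g a [ConeBeamGeometry-class].
#' @return Effective pixel size in metres, detector pixel divided by the
#'   magnification.
#' @export
effectivePixel <- function(g) {
  g@detPixel / magnification(g)
}

#' Effective propagation distance
#'
#' The Fresnel scaling theorem maps cone-beam propagation over
#' \eqn{z_{12} = z_{02} - z_{01}} at magnification M onto parallel-beam
#' propagation over \eqn{z_{eff} = z_{01} z_{12} / z_{02} = z_{12}/M}.
#'
#' @param g a [ConeBeamGeometry-class].
#' @return Effective distance in metres.
#' @export
effectiveDistance <- function(g) {
  stopifnot(is(g, "ConeBeamGeometry"))
  validObject(g)
  g@z01 * (g@z02 - g@z01) / g@z02
}

#' Fresnel number for a length scale, distance and wavelength
#'
#' The dimensionless number \eqn{F = \sigma^2/(z \lambda)} that governs the
#' imaging regime: \eqn{F \approx 1} is the direct-contrast (edge enhancement)
#' regime, \eqn{F \ll 1} the holographic regime. Here \eqn{\sigma} is the
#' (effective) pixel size, so all retrieval filters can work in pixel units.
#'
#' @param pixel length scale in metres (one pixel).
#' @param distance propagation distance in metres.
#' @param lambda wavelength in metres.
#' @return Dimensionless Fresnel number.
#' @examples
#' g <- coneBeamGeometry(13.53, 5110, 6.5, 13.8)
#' fresnelNumber(effectivePixel(g), effectiveDistance(g), wavelength(13.8))
#' @export
fresnelNumber <- function(pixel, distance, lambda) {
  if (any(!is.finite(c(pixel, distance, lambda))) ||
      any(c(pixel, distance, lambda) <= 0))
    stop("pixel, distance and lambda must all be positive")
  pixel^2 / (distance * lambda)
}

#' Fresnel numbers of a cone-beam geometry
#'
#' Convenience wrapper: Fresnel number with respect to the effective pixel
#' size in the effective parallel geometry of \code{g}.
#'
#' @param g a [ConeBeamGeometry-class].
#' @return A [FresnelPair-class] (isotropic).
#' @export
geometryFresnel <- function(g) {
  f <- fresnelNumber(effectivePixel(g), effectiveDistance(g),
                     wavelength(g@energy))
  fresnelPair(f)
}

#' Rescale Fresnel numbers to a new pixel size
#'
#' When holograms from several defocus distances are magnified onto a common
#' effective pixel grid, the Fresnel number of each rescaled hologram changes
#' by the square of the pixel ratio (\eqn{F \propto \sigma^2}).
#'
#' @param f a [FresnelPair-class].
#' @param pixelOld pixel size the pair refers to.
#' @param pixelNew pixel size after rescaling (same units as \code{pixelOld}).
#' @return A [FresnelPair-class] scaled by \code{(pixelNew/pixelOld)^2}.
#' @export
rescaleFresnel <- function(f, pixelOld, pixelNew) {
  stopifnot(is(f, "FresnelPair"))
  if (any(c(pixelOld, pixelNew) <= 0)) stop("pixel sizes must be positive")
  s <- (pixelNew / pixelOld)^2
  fresnelPair(f@fx * s, f@fy * s)
}
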