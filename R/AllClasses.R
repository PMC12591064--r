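#' @import methods
NULL

#' Cone-beam acquisition geometry
#'
#' Physical geometry of a divergent-beam (cone-beam) propagation imaging
#' setup: a quasi-point source, the sample at distance \code{z01} downstream,
#' and the detector at distance \code{z02}. All lengths are stored in metres;
#' the constructor [coneBeamGeometry()] accepts the units customary at the
#' beamline (mm for distances, micrometres for the detector pixel, keV for the
#' photon energy) and converts once.
#'
#' @slot z01 numeric, source-to-sample distance (m).
#' @slot z02 numeric, source-to-detector distance (m).
#' @slot detPixel numeric, physical detector pixel size (m).
#' @slot energy numeric, photon energy (keV).
#'
#' @seealso [magnification()], [effectivePixel()], [effectiveDistance()],
#'   [fresnelNumber()]
#' @export
setClass("ConeBeamGeometry",
  representation(z01 = "numeric", z02 = "numeric",
                 detPixel = "numeric", energy = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@z01) != 1 || !is.finite(object@z01) || object@z01 <= 0)
      msg <- c(msg, "z01 must be a single positive number")
    if (length(object@z02) != 1 || !is.finite(object@z02) || object@z02 <= 0)
      msg <- c(msg, "z02 must be a single positive number")
    if (length(object@z01) == 1 && length(object@z02) == 1 &&
        is.finite(object@z01) && is.finite(object@z02) &&
        object@z01 >= object@z02)
      msg <- c(msg, "z01 must be strictly smaller than z02")
    if (length(object@detPixel) != 1 || !is.finite(object@detPixel) ||
        object@detPixel <= 0)
      msg <- c(msg, "detPixel must be a single positive number")
    if (length(object@energy) != 1 || !is.finite(object@energy) ||
        object@energy <= 0)
      msg <- c(msg, "energy must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Per-axis (astigmatic) Fresnel numbers
#'
#' A pair of dimensionless Fresnel numbers, one per detector axis, describing
#' the effective propagation regime of a hologram. Anisotropic magnification
#' (e.g. Bragg magnifiers) makes the two differ; the isotropic case has
#' \code{fx == fy}.
#'
#' @slot fx numeric, Fresnel number along the horizontal (column) axis.
#' @slot fy numeric, Fresnel number along the vertical (row) axis.
#' @export
setClass("FresnelPair",
  representation(fx = "numeric", fy = "numeric"),
  validity = function(object) {
    if (length(object@fx) != 1 || !is.finite(object@fx) || object@fx <= 0)
      return("fx must be a single positive number")
    if (length(object@fy) != 1 || !is.finite(object@fy) || object@fy <= 0)
      return("fy must be a single positive number")
    TRUE
  })

#' Stack of normalized holograms at one or more propagation distances
#'
#' Flat-field-normalized near-field intensity images (mean level about 1) of
#' the same object recorded at D effective propagation distances, each with
#' its per-axis Fresnel numbers. Images must share a common pixel grid: for
#' cone-beam data at several defocus positions this means rescaling to the
#' common effective pixel size first (see [rescaleFresnel()]).
#'
#' @slot images list of D numeric matrices (rows = vertical axis).
#' @slot fresnel list of D [FresnelPair-class] objects.
#' @export
setClass("HologramStack",
  representation(images = "list", fresnel = "list"),
  validity = function(object) {
    if (length(object@images) < 1) return("need at least one image")
    if (length(object@images) != length(object@fresnel))
      return("images and fresnel must have equal length")
    d <- dim(object@images[[1]])
    for (im in object@images) {
      if (!is.matrix(im) || !is.numeric(im))
        return("images must be numeric matrices")
      if (!identical(dim(im), d)) return("all images must share one shape")
      if (!all(is.finite(im))) return("intensities must be finite")
      if (any(im <= 0))
        return("intensities must be > 0 (repair faulty pixels first)")
    }
    for (f in object@fresnel)
      if (!is(f, "FresnelPair")) return("fresnel must hold FresnelPair objects")
    TRUE
  })

#' Retrieved phase map
#'
#' A real-valued phase image in radians. The sign convention is that matter
#' denser than the reference medium retards the wave: phase values are
#' non-positive. Constrained retrievals enforce \code{max(values) <= 0}
#' exactly; unconstrained linear retrievals may violate it where the data do.
#'
#' @slot values numeric matrix of phase values (radians).
#' @export
setClass("PhaseMap",
  representation(values = "matrix"),
  validity = function(object) {
    if (!is.numeric(object@values)) return("values must be numeric")
    if (!all(is.finite(object@values))) return("values must be finite")
    TRUE
  })

#' Tomographic trajectory model
#'
#' Acquisition angles plus the per-projection rigid detector model used by the
#' projectors: horizontal/vertical detector shifts for each projection, a
#' global center-of-rotation offset (pixels, relative to the detector center
#' column at (N-1)/2), and a small rotation-axis tilt (radians; estimated by
#' [findCorSinogram()], stored as a diagnostic, not compensated by the
#' projectors).
#'
#' @slot angles numeric vector of projection angles (radians, increasing).
#' @slot shifts numeric matrix (n x 2): columns \code{du} (horizontal) and
#'   \code{dv} (vertical) detector offsets in pixels.
#' @slot corOffset numeric scalar, center-of-rotation offset in pixels.
#' @slot tilt numeric scalar, rotation-axis tilt in radians (|tilt| < 0.1).
#' @export
setClass("TomoGeometry",
  representation(angles = "numeric", shifts = "matrix",
                 corOffset = "numeric", tilt = "numeric"),
  validity = function(object) {
    if (length(object@angles) < 1) return("need at least one angle")
    if (is.unsorted(object@angles, strictly = FALSE))
      return("angles must be non-decreasing")
    if (!is.numeric(object@shifts) || ncol(object@shifts) != 2)
      return("shifts must be an n x 2 numeric matrix (du, dv)")
    if (nrow(object@shifts) != length(object@angles))
      return("shifts must have one row per angle")
    if (length(object@corOffset) != 1 || !is.finite(object@corOffset))
      return("corOffset must be a single finite number")
    if (length(object@tilt) != 1 || !is.finite(object@tilt) ||
        abs(object@tilt) >= 0.1)
      return("tilt must be a single number with |tilt| < 0.1 rad")
    TRUE
  })

#' Digital phantom volume
#'
#' Non-negative 3-D array of refractive-decrement (delta) proxy values, in
#' arbitrary units; projections of it are scaled to physical phase by the
#' simulator. Axis order is (z, y, x) with z the vertical (rotation) axis.
#'
#' @slot values numeric 3-D array, non-negative.
#' @slot bRatio numeric, optional beta/delta ratio used to derive absorption.
#' @export
setClass("Phantom",
  representation(values = "array", bRatio = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3) return("values must be a 3-D array")
    if (!all(is.finite(object@values))) return("values must be finite")
    if (min(object@values) < 0) return("values must be non-negative")
    if (length(object@bRatio) != 1 || object@bRatio < 0)
      return("bRatio must be a single number >= 0")
    TRUE
  })

# ---- constructors -----------------------------------------------------------

#' Construct a cone-beam geometry
#'
#' @param z01 source-to-sample distance in mm.
#' @param z02 source-to-detector distance in mm.
#' @param detPixel physical detector pixel size in micrometres.
#' @param energy photon energy in keV.
#' @return A [ConeBeamGeometry-class] object (lengths stored in metres).
#' @examples
#' g <- coneBeamGeometry(z01 = 13.53, z02 = 5110, detPixel = 6.5, energy = 13.8)
#' magnification(g)
#' @export
coneBeamGeometry <- function(z01, z02, detPixel, energy) {
  new("ConeBeamGeometry", z01 = z01 * 1e-3, z02 = z02 * 1e-3,
      detPixel = detPixel * 1e-6, energy = energy)
}

#' Construct a Fresnel-number pair
#'
#' @param fx Fresnel number along the horizontal axis.
#' @param fy Fresnel number along the vertical axis (defaults to \code{fx},
#'   the isotropic case).
#' @return A [FresnelPair-class] object.
#' @export
fresnelPair <- function(fx, fy = fx) new("FresnelPair", fx = fx, fy = fy)

#' Construct a hologram stack
#'
#' @param images a numeric matrix or a list of matrices (one per distance).
#' @param fresnel a [FresnelPair-class], a numeric scalar/pair, or a list of
#'   those, one entry per distance. A numeric pair is read as (fx, fy).
#' @return A [HologramStack-class] object.
#' @export
hologramStack <- function(images, fresnel) {
  if (is.matrix(images)) images <- list(images)
  if (!is.list(fresnel) || is(fresnel, "FresnelPair")) fresnel <- list(fresnel)
  fresnel <- lapply(fresnel, function(f) {
    if (is(f, "FresnelPair")) f
    else if (is.numeric(f) && length(f) %in% 1:2)
      fresnelPair(f[[1]], f[[length(f)]])
    else stop("fresnel entries must be FresnelPair or numeric")
  })
  if (length(fresnel) == 1 && length(images) > 1)
    fresnel <- rep(fresnel, length(images))
  new("HologramStack", images = images, fresnel = fresnel)
}

#' Construct a phase map
#' @param values numeric matrix (radians).
#' @return A [PhaseMap-class] object.
#' @export
phaseMap <- function(values) new("PhaseMap", values = as.matrix(values))

#' Construct a tomographic trajectory model
#'
#' @param angles projection angles in radians (non-decreasing).
#' @param shifts optional n x 2 matrix of per-projection (du, dv) detector
#'   shifts in pixels; defaults to zeros.
#' @param corOffset center-of-rotation offset in pixels (default 0).
#' @param tilt rotation-axis tilt in radians (default 0).
#' @return A [TomoGeometry-class] object.
#' @export
tomoGeometry <- function(angles, shifts = NULL, corOffset = 0, tilt = 0) {
  if (is.null(shifts)) shifts <- matrix(0, length(angles), 2)
  shifts <- as.matrix(shifts)
  colnames(shifts) <- c("du", "dv")
  new("TomoGeometry", angles = as.numeric(angles), shifts = shifts,
      corOffset = corOffset, tilt = tilt)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn PhaseMap-class extract the phase values matrix.
#' @param x a \code{PhaseMap}.
#' @export
phaseValues <- function(x) x@values

#' @describeIn HologramStack-class number of distances in the stack.
#' @param x a \code{HologramStack}.
#' @export
nDistances <- function(x) length(x@images)

#' @describeIn HologramStack-class list of hologram images.
#' @export
holoImages <- function(x) x@images

#' @describeIn HologramStack-class list of per-distance Fresnel pairs.
#' @export
holoFresnel <- function(x) x@fresnel

#' @describeIn TomoGeometry-class projection angles (radians).
#' @param x a \code{TomoGeometry}.
#' @export
tomoAngles <- function(x) x@angles

#' @describeIn TomoGeometry-class per-projection (du, dv) shift matrix.
#' @export
tomoShifts <- function(x) x@shifts

#' @describeIn TomoGeometry-class center-of-rotation offset (pixels).
#' @export
corOffset <- function(x) x@corOffset

#' @describeIn Phantom-class the 3-D delta-proxy array.
#' @param x a \code{Phantom}.
#' @export
phantomValues <- function(x) x@values

# ---- show methods -----------------------------------------------------------

setMethod("show", "ConeBeamGeometry", function(object) {
  cat("ConeBeamGeometry\n")
  cat(sprintf("  z01: %.4g mm   z02: %.4g mm   z12: %.4g mm\n",
              object@z01 * 1e3, object@z02 * 1e3,
              (object@z02 - object@z01) * 1e3))
  cat(sprintf("  detector pixel: %.4g um   energy: %.4g keV\n",
              object@detPixel * 1e6, object@energy))
  cat(sprintf("  M = %.4g   effective pixel: %.3f nm   effective distance: %.4g mm\n",
              magnification(object), effectivePixel(object) * 1e9,
              effectiveDistance(object) * 1e3))
})

setMethod("show", "FresnelPair", function(object) {
  cat(sprintf("FresnelPair fx = %.4g, fy = %.4g\n", object@fx, object@fy))
})

setMethod("show", "HologramStack", function(object) {
  d <- dim(object@images[[1]])
  cat(sprintf("HologramStack: %d distance(s), %d x %d pixels\n",
              length(object@images), d[1], d[2]))
  for (i in seq_along(object@fresnel))
    cat(sprintf("  [%d] fx = %.4g, fy = %.4g, mean I = %.4f\n", i,
                object@fresnel[[i]]@fx, object@fresnel[[i]]@fy,
                mean(object@images[[i]])))
})

setMethod("show", "PhaseMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("PhaseMap: %d x %d, range [%.4g, %.4g] rad\n",
              d[1], d[2], min(object@values), max(object@values)))
})

setMethod("show", "TomoGeometry", function(object) {
  cat(sprintf("TomoGeometry: %d angles in [%.4g, %.4g] rad\n",
              length(object@angles), min(object@angles), max(object@angles)))
  cat(sprintf("  corOffset = %.3f px, tilt = %.4g rad, max |shift| = %.3f px\n",
              object@corOffset, object@tilt,
              if (nrow(object@shifts)) max(abs(object@shifts)) else 0))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@values)
  cat(sprintf("Phantom: %d x %d x %d (z, y, x), values in [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(object@values), max(object@values)))
})
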