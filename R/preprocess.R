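# Raw-frame conditioning: dark subtraction and empty-beam (flat-field)
# division, PCA-synthesized flats, faulty-pixel repair, and least-curvature
# background removal around a compact object support.

#' Flat-field calibration set
#'
#' Dark frames plus empty-beam frames recorded before and after the
#' tomographic scan; the flat used at angle theta interpolates linearly
#' between the two averages over [0, thetaMax].
#'
#' @slot darks list of dark-frame matrices.
#' @slot emptiesBefore list of empty-beam matrices taken before the scan.
#' @slot emptiesAfter list of empty-beam matrices taken after the scan.
#' @slot thetaMax numeric, final acquisition angle (radians).
#' @export
setClass("FlatFieldSet",
  representation(darks = "list", emptiesBefore = "list",
                 emptiesAfter = "list", thetaMax = "numeric"),
  validity = function(object) {
    all_m <- c(object@darks, object@emptiesBefore, object@emptiesAfter)
    if (!length(object@emptiesBefore) || !length(object@emptiesAfter))
      return("need empty-beam frames before and after the scan")
    d <- dim(all_m[[1]])
    for (m in all_m) {
      if (!is.matrix(m)) return("frames must be matrices")
      if (!identical(dim(m), d)) return("all frames must share one shape")
    }
    if (length(object@thetaMax) != 1 || object@thetaMax <= 0)
      return("thetaMax must be a single positive number")
    TRUE
  })

#' Construct a flat-field calibration set
#'
#' @param darks matrix or list of matrices (may be empty list).
#' @param emptiesBefore,emptiesAfter matrix or list of matrices.
#' @param thetaMax final acquisition angle in radians.
#' @return A [FlatFieldSet-class].
#' @export
flatFieldSet <- function(darks = list(), emptiesBefore, emptiesAfter,
                         thetaMax = pi) {
  aslist <- function(x) if (is.matrix(x)) list(x) else x
  new("FlatFieldSet", darks = aslist(darks),
      emptiesBefore = aslist(emptiesBefore),
      emptiesAfter = aslist(emptiesAfter), thetaMax = thetaMax)
}

.stackMean <- function(lst) Reduce(`+`, lst) / length(lst)

#' Angle-interpolated empty-beam image
#'
#' \eqn{e_\theta = (1 - \theta/\theta_{max})\,\bar e_{before} +
#'      (\theta/\theta_{max})\,\bar e_{after}} — a convex combination of the
#' averaged empties bracketing the scan, tracking slow illumination drift.
#'
#' @param ffs a [FlatFieldSet-class].
#' @param theta acquisition angle in radians, within [0, thetaMax].
#' @return Numeric matrix, the interpolated flat.
#' @export
interpolateFlatfield <- function(ffs, theta) {
  stopifnot(is(ffs, "FlatFieldSet"))
  if (theta < 0 || theta > ffs@thetaMax)
    stop("theta must lie in [0, thetaMax]")
  w <- theta / ffs@thetaMax
  (1 - w) * .stackMean(ffs@emptiesBefore) + w * .stackMean(ffs@emptiesAfter)
}

#' Dark-subtract and flat-divide a raw frame
#'
#' \eqn{I = (raw - dark) / (flat - dark)}; the denominator is clipped at
#' 1e-6 of its median to guard against dead flat pixels.
#'
#' @param raw raw frame (matrix).
#' @param flat empty-beam frame at the same angle (matrix).
#' @param dark dark frame or NULL (matrix; averaged dark if a list).
#' @return Numeric matrix, the normalized hologram.
#' @export
flatfieldCorrect <- function(raw, flat, dark = NULL) {
  if (is.list(dark)) dark <- if (length(dark)) .stackMean(dark) else NULL
  if (!is.null(dark)) { raw <- raw - dark; flat <- flat - dark }
  flat <- pmax(flat, 1e-6 * stats::median(flat))
  raw / flat
}

#' PCA (eigen-flat) empty-beam synthesis
#'
#' Decomposes the centered empty-beam stack by SVD into eigen-flats and fits
#' the leading \code{k} coefficients to a raw frame by least squares over an
#' object-free \code{fitRegion}, synthesizing the flat that best matches the
#' illumination state of that frame. \code{k = 0} returns the mean flat
#' (classic division).
#'
#' @param empties list of empty-beam matrices (>= k + 1 frames).
#' @param raw the raw frame to be normalized.
#' @param fitRegion logical matrix, TRUE where the frame is object-free;
#'   default: all pixels.
#' @param k number of eigen-flats (default 2).
#' @return Numeric matrix, the synthesized flat (clipped positive).
#' @export
pcaFlatfield <- function(empties, raw, fitRegion = NULL, k = 2) {
  if (is.matrix(empties)) empties <- list(empties)
  n <- length(empties)
  if (k > n - 1) stop("k must be <= number of empties - 1")
  d <- dim(empties[[1]])
  if (is.null(fitRegion)) fitRegion <- matrix(TRUE, d[1], d[2])
  mu <- .stackMean(empties)
  flat <- mu
  if (k > 0) {
    E <- vapply(empties, function(e) as.vector(e - mu), numeric(prod(d)))
    sv <- svd(E, nu = k, nv = 0)
    U <- sv$u                     # eigen-flats as columns
    sel <- as.vector(fitRegion)
    cf <- stats::lsfit(U[sel, , drop = FALSE],
                       as.vector(raw - mu)[sel], intercept = FALSE)$coefficients
    flat <- mu + matrix(U %*% cf, d[1], d[2])
  }
  pmax(flat, 1e-6)
}

#' Detect and repair faulty detector pixels
#'
#' A pixel is flagged when its residual against the 3x3 median exceeds
#' \code{k} robust standard deviations (1.4826 MAD) of that residual over the
#' frame; flagged pixels are replaced by the 3x3 median. Idempotent on its
#' own output: repaired pixels equal their local median, so they are not
#' re-flagged.
#'
#' @param image numeric matrix, or a list of matrices (repaired per frame).
#' @param k threshold in MAD units (default 6).
#' @return For a matrix: \code{list(image = repaired, mask = logical flags)};
#'   for a list input, a list of such results.
#' @export
repairFaultyPixels <- function(image, k = 6) {
  if (is.list(image)) return(lapply(image, repairFaultyPixels, k = k))
  med <- median3x3(image)
  r <- image - med
  s <- stats::mad(r)             # 1.4826 * median absolute deviation
  if (s == 0) s <- .Machine$double.eps
  mask <- abs(r) > k * s
  # the clamped 3x3 window biases the median on the outermost border;
  # border pixels are never flagged
  mask[c(1, nrow(mask)), ] <- FALSE
  mask[, c(1, ncol(mask))] <- FALSE
  image[mask] <- med[mask]
  list(image = image, mask = mask)
}

# Periodic 5-point Laplacian (cheap row/col rotations).
.lap <- function(u) {
  up <- rbind(u[-1, , drop = FALSE], u[1, , drop = FALSE])
  dn <- rbind(u[nrow(u), , drop = FALSE], u[-nrow(u), , drop = FALSE])
  lf <- cbind(u[, -1, drop = FALSE], u[, 1, drop = FALSE])
  rt <- cbind(u[, ncol(u), drop = FALSE], u[, -ncol(u), drop = FALSE])
  up + dn + lf + rt - 4 * u
}

#' Least-curvature background removal
#'
#' Estimates the smooth illumination background of a hologram by biharmonic
#' (least-curvature) inpainting: outside the object support the background is
#' pinned to a Gaussian-smoothed copy of the hologram (sigma = 5 px); inside
#' the support it solves the discrete biharmonic equation (minimum total
#' squared Laplacian) by conjugate gradients. The hologram is divided by the
#' estimate, so the corrected background level is about 1.
#'
#' @param hologram numeric matrix.
#' @param objectMask logical matrix, TRUE inside the object support; must not
#'   cover the full frame. An all-FALSE mask degenerates to division by the
#'   smoothed hologram.
#' @param sigma boundary smoothing width in pixels (default 5).
#' @param tol conjugate-gradient residual tolerance (default 1e-8).
#' @param maxIter CG iteration cap (default 1000).
#' @return Numeric matrix, hologram divided by the background estimate.
#' @export
removeBackground <- function(hologram, objectMask, sigma = 5, tol = 1e-8,
                             maxIter = 1000) {
  stopifnot(is.matrix(hologram), is.logical(objectMask),
            identical(dim(hologram), dim(objectMask)))
  if (all(objectMask)) stop("objectMask must not cover the full frame")
  # symmetric-boundary smoothing: mirror-pad, blur periodically, crop
  # (a plain periodic blur would wrap non-periodic backgrounds like ramps)
  ny <- nrow(hologram); nx <- ncol(hologram)
  u0 <- gaussianBlur(mirrorPad(hologram, ny, nx),
                     sigma)[seq_len(ny), seq_len(nx)]
  if (!any(objectMask)) return(hologram / u0)
  # solve (Lap^T Lap u)|mask = 0 with u fixed to u0 outside the mask
  embed <- function(x) { u <- u0; u[objectMask] <- x; u }
  A <- function(x) { u <- u0 * 0; u[objectMask] <- x; .lap(.lap(u))[objectMask] }
  ufix <- u0; ufix[objectMask] <- 0
  b <- -.lap(.lap(ufix))[objectMask]
  x <- rep(mean(u0[!objectMask]), sum(objectMask))
  r <- b - A(x); p <- r
  rs <- sum(r^2); b2 <- max(sum(b^2), .Machine$double.eps)
  for (i in seq_len(maxIter)) {
    Ap <- A(p)
    a <- rs / sum(p * Ap)
    x <- x + a * p
    r <- r - a * Ap
    rs2 <- sum(r^2)
    if (sqrt(rs2 / b2) < tol) break
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  bg <- embed(x)
  hologram / bg
}
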