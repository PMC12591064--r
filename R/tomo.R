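# Parallel-beam tomography in the effective parallel geometry: ray-driven
# forward projection, exact-adjoint backprojection, filtered back-projection
# and SIRT. Conventions: volumes are (z, y, x) arrays with the rotation axis
# along z; projection stacks are (angle, row = v, column = u) arrays;
# sinograms (one detector row across angles) are (angle, column) matrices.
# Pixel centers sit at integer coordinates and the center of rotation is at
# detector column (N - 1)/2 + corOffset.

.checkGeom <- function(g, nProj) {
  stopifnot(is(g, "TomoGeometry"))
  validObject(g)
  if (length(g@angles) != nProj)
    stop("geometry has ", length(g@angles), " angles but data have ", nProj)
}

#' Forward projection (Radon transform)
#'
#' Line integrals by bilinear-interpolated ray sampling (step 0.5 voxel),
#' rotating about the vertical axis through the volume center offset by
#' \code{corOffset}. Per-projection detector shifts (du, dv) are applied as
#' cyclic Fourier shifts of each projection image.
#'
#' @param v a square 2-D slice (y, x) or a 3-D volume (z, y, x) with square
#'   (y, x) extent; also accepts a [Phantom-class].
#' @param g a [TomoGeometry-class].
#' @return For a slice: a sinogram matrix (angle, column). For a volume: a
#'   projection stack array (angle, row, column).
#' @export
forwardProject <- function(v, g) {
  if (is(v, "Phantom")) v <- v@values
  stopifnot(length(g@angles) >= 1)
  if (is.matrix(v)) {
    .checkGeom(g, length(g@angles))
    sino <- cpp_forward_project(v, g@angles, g@corOffset)
    if (any(g@shifts[, 1] != 0))
      for (a in seq_len(nrow(sino)))
        if (g@shifts[a, 1] != 0)
          sino[a, ] <- .shift1d(sino[a, ], g@shifts[a, 1])
    return(sino)
  }
  d <- dim(v)
  nz <- d[1]
  proj <- array(0, dim = c(length(g@angles), nz, d[3]))
  for (z in seq_len(nz))
    proj[, z, ] <- cpp_forward_project(v[z, , ], g@angles, g@corOffset)
  # per-projection rigid detector shifts
  if (any(g@shifts != 0))
    for (a in seq_along(g@angles))
      if (any(g@shifts[a, ] != 0))
        proj[a, , ] <- fourierShift(proj[a, , ],
                                    c(g@shifts[a, 2], g@shifts[a, 1]))
  proj
}

# cyclic subpixel shift of a vector via the 1-D Fourier shift theorem
.shift1d <- function(x, s) {
  n <- length(x)
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * frequencyGrid(n) * s),
                inverse = TRUE)) / n
}

#' Backprojection (adjoint of [forwardProject()])
#'
#' Scatters with the same bilinear weights the forward projector gathers
#' with; \code{<forwardProject(v), p> == <v, backproject(p)>} to floating
#' precision.
#'
#' @param p sinogram matrix (angle, column) or projection stack
#'   (angle, row, column).
#' @param g a [TomoGeometry-class].
#' @return A slice (y, x) or volume (z, y, x).
#' @export
backproject <- function(p, g) {
  if (is.matrix(p)) {
    .checkGeom(g, nrow(p))
    if (any(g@shifts[, 1] != 0))
      for (a in seq_len(nrow(p)))
        if (g@shifts[a, 1] != 0)
          p[a, ] <- .shift1d(p[a, ], -g@shifts[a, 1])
    return(cpp_backproject(p, g@angles, g@corOffset))
  }
  d <- dim(p)
  .checkGeom(g, d[1])
  if (any(g@shifts != 0))
    for (a in seq_len(d[1]))
      if (any(g@shifts[a, ] != 0))
        p[a, , ] <- fourierShift(p[a, , ], -c(g@shifts[a, 2], g@shifts[a, 1]))
  vol <- array(0, dim = c(d[2], d[3], d[3]))
  for (z in seq_len(d[2]))
    vol[z, , ] <- cpp_backproject(p[, z, ], g@angles, g@corOffset)
  vol
}

# Frequency response of the standard discrete ramp filter (Ram-Lak band
# limited kernel h(0) = 1/4, h(odd k) = -1/(pi^2 k^2)), with optional
# apodization window, on an axis of length m.
.rampFilter <- function(m, filter = c("ramlak", "shepp-logan", "hann")) {
  filter <- match.arg(filter)
  k <- c(0:(m / 2), (-m / 2 + 1):-1)
  h <- numeric(m)
  h[1] <- 0.25
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi^2 * k[odd]^2)
  H <- Re(stats::fft(h))          # real, >= 0 ramp response
  nu <- frequencyGrid(m)
  w <- switch(filter,
    "ramlak" = rep(1, m),
    "shepp-logan" = ifelse(nu == 0, 1, abs(sin(pi * nu) / (pi * nu))),
    "hann" = 0.5 * (1 + cos(2 * pi * nu)))
  H * w
}

# filter all sinogram rows (angle-major matrix) along the detector axis with
# zero padding to >= 2x length
.filterSinogram <- function(sino, filter) {
  n <- ncol(sino)
  m <- 2^ceiling(log2(2 * n))
  H <- .rampFilter(m, filter)
  pad <- matrix(0, nrow(sino), m)
  pad[, seq_len(n)] <- sino
  ft <- t(stats::mvfft(t(pad)))
  ft <- sweep(ft, 2, H, `*`)
  out <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / m
  out[, seq_len(n), drop = FALSE]
}

#' Filtered back-projection
#'
#' Ramp-filters each projection row along the detector-column axis (with the
#' chosen apodization window), undoes per-projection shifts by Fourier
#' shifting, and backprojects with weight \eqn{\pi / N_{angles}}. Uniform
#' angle coverage of \eqn{[0, \pi)} is assumed; a full-turn angle list
#' averages conjugate rays automatically through the same weighting.
#'
#' @param p sinogram (angle, column) or projection stack (angle, row, column).
#' @param g a [TomoGeometry-class] (>= 2 angles).
#' @param filter \code{"ramlak"}, \code{"shepp-logan"} or \code{"hann"}.
#' @return Reconstructed slice (y, x) or volume (z, y, x), in the units the
#'   projections are line integrals of.
#' @export
fbp <- function(p, g, filter = "ramlak") {
  if (length(g@angles) < 2) stop("fbp needs at least 2 angles")
  w <- pi / length(g@angles)
  if (is.matrix(p)) {
    .checkGeom(g, nrow(p))
    if (any(g@shifts[, 1] != 0))
      for (a in seq_len(nrow(p)))
        if (g@shifts[a, 1] != 0)
          p[a, ] <- .shift1d(p[a, ], -g@shifts[a, 1])
    q <- .filterSinogram(p, filter)
    return(w * cpp_backproject_pixel(q, g@angles, g@corOffset))
  }
  d <- dim(p)
  .checkGeom(g, d[1])
  if (any(g@shifts != 0))
    for (a in seq_len(d[1]))
      if (any(g@shifts[a, ] != 0))
        p[a, , ] <- fourierShift(p[a, , ], -c(g@shifts[a, 2], g@shifts[a, 1]))
  vol <- array(0, dim = c(d[2], d[3], d[3]))
  gz <- tomoGeometry(g@angles, corOffset = g@corOffset)
  for (z in seq_len(d[2]))
    vol[z, , ] <- fbp(p[, z, ], gz, filter)
  vol
}

#' Simultaneous iterative reconstruction technique (SIRT)
#'
#' Row/column-sum preconditioned Landweber iteration
#' \eqn{x \leftarrow x + C A^T R (p - A x)} with \eqn{R, C} the inverse
#' row/column sums of the system matrix (computed by projecting unit
#' objects), optional nonnegativity after each update. The projection
#' residual norm is nonincreasing.
#'
#' @param p sinogram (angle, column) or projection stack (angle, row, column).
#' @param g a [TomoGeometry-class].
#' @param iterations number of iterations (>= 1, default 50).
#' @param nonneg logical, clamp the volume at 0 each iteration.
#' @return Reconstruction with attribute \code{"residuals"} (per-iteration
#'   projection residual norms).
#' @export
sirt <- function(p, g, iterations = 50, nonneg = FALSE) {
  if (iterations < 1) stop("iterations must be >= 1")
  is2d <- is.matrix(p)
  n <- if (is2d) ncol(p) else dim(p)[3]
  ones <- if (is2d) matrix(1, n, n) else array(1, dim = c(dim(p)[2], n, n))
  R <- forwardProject(ones, tomoGeometry(g@angles, corOffset = g@corOffset))
  R <- 1 / pmax(R, 1e-6)
  onesP <- p * 0 + 1
  C <- backproject(onesP, tomoGeometry(g@angles, corOffset = g@corOffset))
  C <- 1 / pmax(C, 1e-6)
  x <- if (is2d) matrix(0, n, n) else array(0, dim = c(dim(p)[2], n, n))
  res <- numeric(iterations)
  for (k in seq_len(iterations)) {
    r <- p - forwardProject(x, g)
    res[k] <- sqrt(sum(r^2))
    x <- x + C * backproject(R * r, g)
    if (nonneg) x <- pmax(x, 0)
  }
  attr(x, "residuals") <- res
  x
}
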