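# Subpixel registration, center-of-rotation estimation, iterative
# reprojection alignment and sinogram ring removal.

.registrationFailure <- function(message) {
  stop(structure(class = c("registrationFailure", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' Subpixel image registration by upsampled cross-correlation
#'
#' DFT cross-correlation with integer peak search followed by local
#' refinement on an upsampled discrete transform patch (matrix-multiply DFT,
#' refinement to 1/\code{upsample} pixel). The returned shift maps \code{b}
#' onto \code{a}: \code{a(x) ~ b(x - shift)} under cyclic boundary
#' conditions.
#'
#' @param a,b numeric matrices of equal shape.
#' @param upsample integer upsampling factor (1 = integer registration).
#' @return \code{list(shift = c(dv, du), peak = normalized peak correlation)}.
#' @export
registerTranslation <- function(a, b, upsample = 1) {
  stopifnot(identical(dim(a), dim(b)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    .registrationFailure("flat (zero-variance) input")
  ny <- nrow(a); nx <- ncol(a)
  Fa <- fft2(a - mean(a)); Fb <- fft2(b - mean(b))
  X <- Fa * Conj(Fb)
  cc <- Re(ifft2(X))
  pk <- which.max(cc)
  py <- (pk - 1) %% ny
  px <- (pk - 1) %/% ny
  if (py > ny / 2) py <- py - ny
  if (px > nx / 2) px <- px - nx
  shift <- c(py, px)
  peak <- max(cc) / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  if (upsample > 1) {
    # refine on a (1.5 x 1.5) px patch around the integer peak
    u <- as.integer(upsample)
    half <- 0.75
    ys <- shift[1] + seq(-half, half, by = 1 / u)
    xs <- shift[2] + seq(-half, half, by = 1 / u)
    nuy <- frequencyGrid(ny); nux <- frequencyGrid(nx)
    Ey <- exp(2i * pi * outer(ys, nuy))        # |ys| x ny
    Ex <- exp(2i * pi * outer(nux, xs))        # nx x |xs|
    ccu <- Re(Ey %*% X %*% Ex) / length(a)
    pk <- which.max(ccu)
    iy <- (pk - 1) %% length(ys) + 1
    ix <- (pk - 1) %/% length(ys) + 1
    shift <- c(ys[iy], xs[ix])
    peak <- max(ccu) / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  list(shift = shift, peak = peak)
}

# mirror an image about the vertical pixel-center axis ((N-1)/2): exact
# column reversal
.mirrorCols <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]

#' Center of rotation from two opposing projections
#'
#' A parallel-beam projection at theta + pi is the mirror image of the one at
#' theta about the rotation axis. Mirroring the second projection about the
#' detector center column and registering it against the first yields a
#' horizontal shift of twice the center-of-rotation offset.
#'
#' @param p0 projection image at angle theta.
#' @param p180 projection image at theta + pi.
#' @param upsample registration upsampling factor (default 20).
#' @return Scalar center-of-rotation offset in pixels (subpixel).
#' @export
findCorOpposing <- function(p0, p180, upsample = 20) {
  r <- registerTranslation(p0, .mirrorCols(p180), upsample = upsample)
  r$shift[2] / 2
}

#' Center of rotation (and axis tilt) from sinogram halves
#'
#' For scans spanning more than half a turn, the rows acquired in the second
#' half rotation are mirrored and registered en bloc against their opposing
#' first-half rows, averaging the center-of-rotation estimate over all
#' angles. Given a full projection stack, the estimate is repeated for
#' several detector rows and a least-squares line over the per-row offsets
#' gives the rotation-axis tilt.
#'
#' @param sino sinogram matrix (angle, column), or a projection stack
#'   (angle, row, column) for the multi-row variant.
#' @param angles acquisition angles (radians), spanning more than pi.
#' @param nRows number of detector rows to sample in the multi-row variant
#'   (default 8).
#' @param upsample registration upsampling factor (default 20).
#' @return \code{list(cor = offset px, tilt = per-row slope in radians or NA)}.
#' @export
findCorSinogram <- function(sino, angles, nRows = 8, upsample = 20) {
  if (max(angles) - min(angles) <= pi)
    stop("angular span must exceed pi")
  if (length(dim(sino)) == 3) {
    nv <- dim(sino)[2]
    rows <- unique(round(seq(nv * 0.2, nv * 0.8, length.out = nRows)))
    cors <- vapply(rows, function(r)
      findCorSinogram(sino[, r, ], angles, upsample = upsample)$cor,
      numeric(1))
    fit <- stats::lm.fit(cbind(1, rows - (nv - 1) / 2), cors)
    return(list(cor = unname(fit$coefficients[1]),
                tilt = atan(unname(fit$coefficients[2])),
                perRow = data.frame(row = rows, cor = cors)))
  }
  # pair each first-half angle with its opposite
  first <- which(angles <= max(angles) - pi)
  if (!length(first)) stop("no opposing angle pairs found")
  opp <- vapply(first, function(i) which.min(abs(angles - (angles[i] + pi))),
                integer(1))
  A <- sino[first, , drop = FALSE]
  B <- .mirrorCols(sino[opp, , drop = FALSE])
  r <- registerTranslation(A, B, upsample = upsample)
  list(cor = r$shift[2] / 2, tilt = NA_real_)
}

#' Iterative reprojection alignment
#'
#' Alternates tomographic reconstruction under the current per-projection
#' shift model with reprojection of the reconstruction; each measured
#' projection is registered against its reprojection (after block-mean
#' binning and Gaussian band-pass filtering) and the model shift updated by
#' the damped detected shift, scaled back by the binning factor. Stops early
#' when the largest update falls below 0.1 px. The band-pass subtracts a
#' wide Gaussian blur (removing slowly varying background that biases the
#' correlation) and applies a narrow one (suppressing reconstruction streak
#' noise that otherwise dominates the high frequencies).
#'
#' @param projections projection stack (angle, row, column).
#' @param g initial [TomoGeometry-class].
#' @param iterations maximum iterations (default 50).
#' @param binning block-mean binning factor (default 4).
#' @param highpassSigma high-pass Gaussian width in binned pixels (default
#'   40/binning, the width scaling inversely with binning).
#' @param smoothSigma low-pass Gaussian width in binned pixels (default 1).
#' @param damping update damping factor in (0, 1] (default 1).
#' @param upsample registration upsampling factor (default 20).
#' @param filter FBP filter for the intermediate reconstructions.
#' @return The updated [TomoGeometry-class]; attribute \code{"history"}
#'   holds a data.frame (iteration, index, du, dv) of the applied updates.
#' @export
reprojectionAlign <- function(projections, g, iterations = 50, binning = 4,
                              highpassSigma = 40 / binning, smoothSigma = 1,
                              damping = 1, upsample = 20, filter = "ramlak") {
  stopifnot(iterations >= 1, binning >= 1)
  d <- dim(projections)
  na <- d[1]
  .checkGeom(g, na)
  hp <- function(x) gaussianBlur(x, smoothSigma) - gaussianBlur(x, highpassSigma)
  binned <- array(0, dim = c(na, d[2] %/% binning, d[3] %/% binning))
  for (a in seq_len(na)) binned[a, , ] <- blockBin(projections[a, , ], binning)
  measured <- lapply(seq_len(na), function(a) hp(binned[a, , ]))
  shifts <- g@shifts
  history <- list()
  for (it in seq_len(iterations)) {
    gb <- tomoGeometry(g@angles, shifts = shifts / binning,
                       corOffset = g@corOffset / binning, tilt = g@tilt)
    vol <- fbp(binned, gb, filter)
    reproj <- forwardProject(vol, gb)
    upd <- matrix(0, na, 2)
    for (a in seq_len(na)) {
      det <- tryCatch(
        registerTranslation(hp(reproj[a, , ]), measured[[a]],
                            upsample = upsample)$shift,
        registrationFailure = function(e) {
          warning("registration failed for projection ", a,
                  "; update skipped", call. = FALSE)
          c(0, 0)
        })
      # detected = (model - true) shift in binned pixels
      upd[a, ] <- -damping * binning * c(det[2], det[1])
    }
    shifts <- shifts + upd
    history[[it]] <- data.frame(iteration = it, index = seq_len(na),
                                du = upd[, 1], dv = upd[, 2])
    if (max(abs(upd)) < 0.1) break
  }
  out <- tomoGeometry(g@angles, shifts = shifts, corOffset = g@corOffset,
                      tilt = g@tilt)
  attr(out, "history") <- do.call(rbind, history)
  out
}

#' Additive (column-mean) ring removal
#'
#' Stripes constant in angle show up as biased sinogram column means.
#' Subtracts from every row the deviation of the column means from a robust
#' (running-median) smooth of width \code{smoothWidth}; the median removes
#' isolated stripe columns completely instead of leaking a 1/width fraction
#' of the bias back into the reference, while tracking smooth genuine
#' column-mean structure.
#'
#' @param sino sinogram matrix (angle, column).
#' @param smoothWidth odd smoothing window width >= 3 (default 31).
#' @return Filtered sinogram, same shape.
#' @export
removeRingsAdditive <- function(sino, smoothWidth = 31) {
  if (smoothWidth < 3 || smoothWidth %% 2 == 0)
    stop("smoothWidth must be odd and >= 3")
  cm <- colMeans(sino)
  sm <- stats::runmed(cm, smoothWidth, endrule = "median")
  sweep(sino, 2, cm - sm, `-`)
}

#' Wavelet-FFT ring removal
#'
#' Multilevel wavelet decomposition of the sinogram; in each level's
#' stripe-carrying band (lowpass along the angle axis, highpass along the
#' detector axis) a 1-D DFT along the angle axis is damped by
#' \eqn{g(k) = 1 - e^{-k^2/(2\sigma^2)}} (k in index units of the band's
#' angular frequency), suppressing structures constant in angle, before
#' reconstruction.
#'
#' @param sino sinogram matrix (angle, column).
#' @param levels decomposition depth (default 4).
#' @param sigma Gaussian damping width along the angle-frequency axis
#'   (default 1).
#' @param wavelet wavelet family name (default \code{"db5"}).
#' @return Filtered sinogram, same shape.
#' @export
removeRingsWavelet <- function(sino, levels = 4, sigma = 1, wavelet = "db5") {
  stopifnot(levels >= 1, sigma > 0)
  d <- dim(sino)
  m <- 2^levels
  pady <- (m - d[1] %% m) %% m
  padx <- (m - d[2] %% m) %% m
  X <- mirrorPad(sino, pady, padx)
  w <- .dwt2(X, levels, wavelet)
  for (l in seq_len(levels)) {
    band <- w$detail[[l]]$LH        # angle-low, detector-high: the stripes
    K <- nrow(band)
    k <- c(seq.int(0L, ceiling(K / 2) - 1L), seq.int(-floor(K / 2), -1L))
    damp <- 1 - exp(-k^2 / (2 * sigma^2))
    w$detail[[l]]$LH <- Re(stats::mvfft(stats::mvfft(band) * damp,
                                        inverse = TRUE)) / K
  }
  .idwt2(w)[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}
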