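# Session-local state (e.g. once-per-session warnings).
.holotomoState <- new.env(parent = emptyenv())

# Internal numerical helpers shared across modules: DFT frequency grids,
# 2-D FFT wrappers, Fourier shifting and Gaussian blurring with periodic
# boundaries, and the error function.

#' DFT frequency grid for one axis
#'
#' Frequencies in cycles/pixel in standard DFT ordering (zero first, then
#' positive, then negative), range [-1/2, 1/2).
#'
#' @param n axis length (integer >= 2).
#' @return Numeric vector of length \code{n}.
#' @examples
#' frequencyGrid(4)  # 0, 0.25, -0.5, -0.25
#' @export
frequencyGrid <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("axis length must be >= 2")
  c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L)) / n
}

# 2-D forward / inverse FFT (inverse includes 1/N normalization).
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# chi(nu) = pi * (nux^2/fx + nuy^2/fy) on the DFT grid of `shape`.
# Rows are the vertical (y) axis, columns the horizontal (x) axis.
chiGrid <- function(shape, f) {
  stopifnot(is(f, "FresnelPair"))
  ny <- shape[1]; nx <- shape[2]
  nuy <- frequencyGrid(ny); nux <- frequencyGrid(nx)
  pi * outer(nuy^2 / f@fy, rep(1, nx)) + pi * outer(rep(1, ny), nux^2 / f@fx)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Cyclic subpixel shift via the Fourier shift theorem.
# shift = c(dy, dx): output(y, x) = input(y - dy, x - dx), periodic.
fourierShift <- function(x, shift) {
  ny <- nrow(x); nx <- ncol(x)
  nuy <- frequencyGrid(ny); nux <- frequencyGrid(nx)
  ph <- exp(-2i * pi * (outer(nuy * shift[1], rep(1, nx)) +
                        outer(rep(1, ny), nux * shift[2])))
  out <- ifft2(fft2(x) * ph)
  if (is.complex(x)) out else Re(out)
}

# Periodic Gaussian blur (sigma in pixels) via Fourier multiplication.
gaussianBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  ny <- nrow(x); nx <- ncol(x)
  nuy <- frequencyGrid(ny); nux <- frequencyGrid(nx)
  g <- exp(-2 * pi^2 * sigma^2 *
             (outer(nuy^2, rep(1, nx)) + outer(rep(1, ny), nux^2)))
  Re(ifft2(fft2(x) * g))
}

# Block-mean binning by integer factor (trailing rows/cols dropped).
blockBin <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor <= 1) return(x)
  ny <- (nrow(x) %/% factor) * factor
  nx <- (ncol(x) %/% factor) * factor
  x <- x[seq_len(ny), seq_len(nx), drop = FALSE]
  xr <- rowsum(x, rep(seq_len(ny %/% factor), each = factor)) / factor
  t(rowsum(t(xr), rep(seq_len(nx %/% factor), each = factor)) / factor)
}

# Relative L2 error, guarded for a zero reference.
relErr <- function(x, ref) {
  n <- sqrt(sum((x - ref)^2)); d <- sqrt(sum(ref^2))
  if (d == 0) n else n / d
}
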