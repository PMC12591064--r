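# Discrete Fresnel free-space propagation as a unitary Fourier multiplier.
# Single source of truth for the kernel sign convention: the forward kernel is
# H(nu) = exp(-i * chi(nu)), chi(nu) = pi * (nux^2/fx + nuy^2/fy).
# Every retrieval formula elsewhere in the package is written against this
# convention and validated by simulate-then-retrieve self-consistency tests.

#' Fresnel propagation kernel
#'
#' The unimodular Fourier multiplier \eqn{H(\nu) = \exp(-i\chi(\nu))} with
#' \eqn{\chi(\nu) = \pi(\nu_x^2/f_x + \nu_y^2/f_y)}; frequencies in
#' cycles/pixel on the DFT grid of \code{shape}. \code{H(0) = 1} and
#' \eqn{|H| = 1} everywhere (unitary propagation).
#'
#' @param shape integer pair (rows, cols).
#' @param f a [FresnelPair-class].
#' @param direction \code{"forward"} (downstream) or \code{"backward"}
#'   (complex conjugate kernel).
#' @return Complex matrix of kernel values.
#' @export
propagationKernel <- function(shape, f, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  chi <- chiGrid(shape, f)
  # Warn (once per session) when the quadratic kernel phase is aliased, i.e.
  # the step between adjacent frequencies near Nyquist exceeds pi. Deep
  # holographic Fresnel numbers alias by construction; simulation and
  # retrieval share the same discrete kernel, so this is informational.
  ny <- shape[1]; nx <- shape[2]
  maxstep <- pi * max((ny - 1) / (f@fy * ny^2), (nx - 1) / (f@fx * nx^2))
  if (maxstep > pi && !isTRUE(.holotomoState$aliasWarned)) {
    .holotomoState$aliasWarned <- TRUE
    warning("propagation kernel phase is aliased at this Fresnel number and ",
            "shape (adjacent-frequency step > pi); reported once per session",
            call. = FALSE)
  }
  if (direction == "forward") exp(-1i * chi) else exp(1i * chi)
}

#' Fresnel free-space propagation
#'
#' Propagates a complex wavefront by multiplying its DFT with the Fresnel
#' kernel (periodic boundary conditions). \code{backward} propagation applies
#' the conjugate kernel and exactly inverts \code{forward}. An optional
#' symmetric (mirror) padding factor suppresses wrap-around in simulations.
#'
#' @param field complex (or real) matrix; rows = vertical axis.
#' @param f a [FresnelPair-class] (or numeric scalar/pair) of Fresnel numbers
#'   in inverse pixel^2 units.
#' @param direction \code{"forward"} or \code{"backward"}.
#' @param pad integer padding factor >= 1 (1 = none); the field is mirrored to
#'   \code{pad} times its size before the transform and cropped after.
#' @return Complex matrix of the propagated field, same shape as input.
#' @examples
#' psi <- matrix(1 + 0i, 8, 8)
#' all.equal(fresnelPropagate(psi, fresnelPair(0.1)), psi)  # H(0) = 1
#' @export
fresnelPropagate <- function(field, f, direction = c("forward", "backward"),
                             pad = 1) {
  direction <- match.arg(direction)
  if (is.numeric(f)) f <- fresnelPair(f[[1]], f[[length(f)]])
  stopifnot(is(f, "FresnelPair"))
  if (!is.matrix(field) || any(dim(field) < 2))
    stop("field must be a matrix of shape >= 2 x 2")
  pad <- as.integer(pad)
  if (pad > 1) {
    ny <- nrow(field); nx <- ncol(field)
    field <- mirrorPad(field, ny * (pad - 1L), nx * (pad - 1L))
  }
  H <- propagationKernel(dim(field), f, direction)
  out <- ifft2(fft2(field) * H)
  if (pad > 1) out <- out[seq_len(ny), seq_len(nx)]
  out
}

# Mirror (symmetric) padding: extends by my rows / mx cols using reflected
# copies, keeping the original block in the top-left corner.
mirrorPad <- function(x, my, mx) {
  ny <- nrow(x); nx <- ncol(x)
  iy <- c(seq_len(ny), rev(seq_len(ny)))[((seq_len(ny + my) - 1L) %% (2L * ny)) + 1L]
  ix <- c(seq_len(nx), rev(seq_len(nx)))[((seq_len(nx + mx) - 1L) %% (2L * nx)) + 1L]
  x[iy, ix, drop = FALSE]
}
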