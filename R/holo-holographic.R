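# Multi-distance phase retrieval in the holographic regime (Fresnel number
# << 1). The linear CTF model ties hologram contrast to the phase through
# s(nu) = sin chi + B cos chi; iterative methods refine it under the full
# nonlinear propagation model with object constraints.
#
# Convention check (anti-sign-error): with the forward propagation kernel
# exp(-i chi) used throughout, a weak homogeneous object T = exp((B + i) phi)
# satisfies DFT(I - 1) = 2 (sin chi + B cos chi) DFT(phi) exactly to first
# order in phi; this is asserted by the linearization-consistency test.

#' Object constraints for phase retrieval
#'
#' @param nonpositive logical, enforce phi <= 0 pixel-wise.
#' @param support optional logical matrix (TRUE inside the object); phase is
#'   forced to 0 outside.
#' @param lower,upper optional pixel-wise bounds (scalars).
#' @return A list of class \code{"phaseConstraints"}.
#' @export
phaseConstraints <- function(nonpositive = FALSE, support = NULL,
                             lower = -Inf, upper = Inf) {
  if (!is.null(support) && !is.logical(support))
    stop("support must be a logical matrix or NULL")
  structure(list(nonpositive = nonpositive, support = support,
                 lower = lower, upper = upper),
            class = "phaseConstraints")
}

#' @describeIn phaseConstraints TRUE when no constraint is active.
#' @param c a \code{phaseConstraints} object.
#' @export
isUnconstrained <- function(c) {
  !c$nonpositive && is.null(c$support) &&
    !is.finite(c$lower) && !is.finite(c$upper)
}

#' @describeIn phaseConstraints project a phase array onto the constraint
#'   set (idempotent).
#' @param x numeric matrix.
#' @export
projectConstraints <- function(x, c) {
  if (is.finite(c$lower)) x <- pmax(x, c$lower)
  if (is.finite(c$upper)) x <- pmin(x, c$upper)
  if (c$nonpositive) x <- pmin(x, 0)
  if (!is.null(c$support)) x[!c$support] <- 0
  x
}

#' Two-level frequency regularization profile
#'
#' Holographic-regime regularization uses a small weight for the
#' well-transferred low frequencies and a larger one beyond the first CTF
#' maximum. The crossover is a smooth erf step in \eqn{\chi} (not \eqn{|\nu|},
#' so it remains consistent under astigmatism), centred at \eqn{\chi = \pi/2}.
#'
#' @param alphaLow weight at low frequencies (default 2e-5).
#' @param alphaHigh weight at high frequencies (default 3e-5).
#' @param transitionWidth crossover width in \eqn{\chi} units (default 0.5).
#' @return A list of class \code{"regularizationProfile"}.
#' @export
regularizationProfile <- function(alphaLow = 2e-5, alphaHigh = 3e-5,
                                  transitionWidth = 0.5) {
  if (alphaLow < 0 || alphaHigh < 0) stop("weights must be >= 0")
  if (transitionWidth <= 0) stop("transitionWidth must be > 0")
  structure(list(alphaLow = alphaLow, alphaHigh = alphaHigh,
                 transitionWidth = transitionWidth),
            class = "regularizationProfile")
}

#' CTF factor s(nu) = sin(chi) + B cos(chi)
#'
#' @param shape image shape (rows, cols).
#' @param f a [FresnelPair-class].
#' @param B beta/delta ratio (>= 0).
#' @return Numeric matrix of CTF factors on the DFT grid; \code{s(0) = B}.
#' @export
ctfFactor <- function(shape, f, B) {
  if (B < 0) stop("B must be >= 0")
  chi <- chiGrid(shape, .asFresnel(f))
  sin(chi) + B * cos(chi)
}

#' Two-level regularization weights on the DFT grid
#'
#' @inheritParams ctfFactor
#' @param profile a [regularizationProfile()].
#' @return Numeric matrix \eqn{\alpha(\nu)}, \code{alphaLow} at DC rising
#'   monotonically in \eqn{\chi} to \code{alphaHigh}.
#' @export
twoLevelAlpha <- function(shape, f, profile) {
  stopifnot(inherits(profile, "regularizationProfile"))
  chi <- chiGrid(shape, .asFresnel(f))
  w <- profile$transitionWidth
  profile$alphaHigh + (profile$alphaLow - profile$alphaHigh) *
    0.5 * (1 - .erf((chi - pi / 2) / w))
}

.asHologramStack <- function(h) {
  if (is(h, "HologramStack")) h
  else stop("expected a HologramStack (see hologramStack())")
}

# Shared pieces of the CTF normal equations: per-distance factors s_d,
# Fourier data g_d = DFT(I_d - 1), the regularization alpha(nu) (from the
# first distance's Fresnel pair), and the denominator 2 sum s^2 + alpha.
.ctfParts <- function(h, B, profile) {
  h <- .asHologramStack(h)
  shape <- dim(h@images[[1]])
  s <- lapply(h@fresnel, function(f) ctfFactor(shape, f, B))
  g <- lapply(h@images, function(I) fft2(I - 1))
  alpha <- twoLevelAlpha(shape, h@fresnel[[1]], profile)
  num <- Reduce(`+`, Map(function(si, gi) si * gi, s, g))
  den <- 2 * Reduce(`+`, lapply(s, function(si) si^2)) + alpha
  list(shape = shape, s = s, g = g, alpha = alpha, num = num, den = den)
}

#' Linear CTF phase retrieval with two-level regularization
#'
#' Closed-form Fourier-domain least squares under the weak-object model
#' \eqn{\mathcal{F}(I_d - 1) = 2 s_d(\nu) \mathcal{F}(\phi)}:
#' \deqn{\hat\phi = \frac{\sum_d s_d \mathcal{F}(I_d - 1)}
#'                       {2\sum_d s_d^2 + \alpha(\nu)}.}
#' Multiple distances fill each other's CTF zeros; \eqn{\alpha(\nu)}
#' stabilizes whatever remains.
#'
#' @param h a [HologramStack-class] (pre-registered, common pixel grid).
#' @param B beta/delta ratio (>= 0).
#' @param profile a [regularizationProfile()].
#' @return A [PhaseMap-class].
#' @export
ctfRetrieve <- function(h, B, profile = regularizationProfile()) {
  parts <- .ctfParts(h, B, profile)
  phaseMap(Re(ifft2(parts$num / parts$den)))
}

#' Constrained CTF retrieval via accelerated ADMM
#'
#' Splits the CTF quadratic (Fourier-diagonal, closed-form x-update) from the
#' constraint projection (z-update) and runs accelerated ADMM with restart.
#' The returned phase is the final z iterate, so constraints hold exactly.
#'
#' @inheritParams ctfRetrieve
#' @param constraints a [phaseConstraints()]; with no active constraint the
#'   closed-form solution is returned directly.
#' @param maxIter maximum ADMM iterations (default 100).
#' @param rho augmented-Lagrangian parameter (default 1).
#' @param tol residual tolerance (default 1e-6).
#' @return A [PhaseMap-class]; attribute \code{"report"} carries the solver
#'   report.
#' @export
ctfConstrained <- function(h, B, profile = regularizationProfile(),
                           constraints = phaseConstraints(nonpositive = TRUE),
                           maxIter = 100, rho = 1, tol = 1e-6) {
  stopifnot(inherits(constraints, "phaseConstraints"))
  if (isUnconstrained(constraints)) return(ctfRetrieve(h, B, profile))
  parts <- .ctfParts(h, B, profile)
  # per-frequency quadratic a |x|^2 - 2 Re(conj(b) x):
  a <- parts$den / 2        # = sum s^2 + alpha/2
  b <- parts$num / 2
  xUpdate <- function(v, rho) Re(ifft2((2 * b + rho * fft2(v)) / (2 * a + rho)))
  zProx <- function(w, rho) projectConstraints(w, constraints)
  x0 <- projectConstraints(Re(ifft2(parts$num / parts$den)), constraints)
  res <- admmAccel(xUpdate, zProx, x0, rho = rho, maxIter = maxIter, tol = tol)
  # divergence guard: combined residual growing over 20 consecutive iterations
  tr <- res$report$objective
  tr <- tr[is.finite(tr)]
  if (length(tr) > 21 && all(diff(utils::tail(tr, 21)) > 0))
    .solverFailure("constrained CTF diverged (residual grew for 20 iterations)",
                   res$report)
  out <- phaseMap(res$z)
  attr(out, "report") <- res$report
  out
}

# Nonlinear data fidelity: amplitude residual against the propagated
# homogeneous-object transmission, plus quadratic Fourier regularization
# (and optionally smoothed TV). Returns value/gradient closures over phi.
.tikhonovObjective <- function(h, B, profile, tau = 0, epsilon = 1e-2) {
  h <- .asHologramStack(h)
  shape <- dim(h@images[[1]])
  N <- prod(shape)
  sqrtI <- lapply(h@images, sqrt)
  kernels <- lapply(h@fresnel, function(f)
    propagationKernel(shape, f, "forward"))
  alpha <- twoLevelAlpha(shape, h@fresnel[[1]], profile)
  prop <- function(x, H) ifft2(fft2(x) * H)
  value <- function(phi) {
    T <- exp((B + 1i) * phi)
    v <- 0
    for (d in seq_along(kernels)) {
      psi <- prop(T, kernels[[d]])
      v <- v + 0.5 * sum((Mod(psi) - sqrtI[[d]])^2)
    }
    ph <- fft2(phi)
    v <- v + sum(alpha * Mod(ph)^2) / (2 * N)
    if (tau > 0) {
      dy <- rbind(phi[-1, , drop = FALSE], phi[1, , drop = FALSE]) - phi
      dx <- cbind(phi[, -1, drop = FALSE], phi[, 1, drop = FALSE]) - phi
      v <- v + tau * sum(sqrt(dy^2 + dx^2 + epsilon^2))
    }
    v
  }
  grad <- function(phi) {
    T <- exp((B + 1i) * phi)
    acc <- matrix(0i, shape[1], shape[2])
    for (d in seq_along(kernels)) {
      psi <- prop(T, kernels[[d]])
      m <- Mod(psi)
      w <- (m - sqrtI[[d]]) * psi / pmax(m, 1e-12)
      acc <- acc + prop(w, Conj(kernels[[d]]))
    }
    g <- Re((B + 1i) * T * Conj(acc))
    g <- g + Re(ifft2(alpha * fft2(phi)))
    if (tau > 0) {
      dy <- rbind(phi[-1, , drop = FALSE], phi[1, , drop = FALSE]) - phi
      dx <- cbind(phi[, -1, drop = FALSE], phi[, 1, drop = FALSE]) - phi
      W <- 1 / sqrt(dy^2 + dx^2 + epsilon^2)
      Gy <- W * dy; Gx <- W * dx
      div <- (rbind(Gy[nrow(Gy), , drop = FALSE], Gy[-nrow(Gy), , drop = FALSE]) - Gy) +
             (cbind(Gx[, ncol(Gx), drop = FALSE], Gx[, -ncol(Gx), drop = FALSE]) - Gx)
      g <- g + tau * div
    }
    g
  }
  list(value = value, grad = grad)
}

#' Nonlinear Tikhonov phase retrieval
#'
#' Minimizes the amplitude residual of the full (nonlinear) propagation model
#' \deqn{J(\phi) = \sum_d \tfrac12 \| |P_{f_d}(e^{(B+i)\phi})| - \sqrt{I_d}
#'   \|^2 + \tfrac1{2N} \|\sqrt{\alpha(\nu)}\,\mathcal{F}(\phi)\|^2}
#' by the adaptive proximal gradient method with the constraint projection as
#' proximal operator, warm-started from the (projected) CTF solution. The
#' amplitude (not intensity) residual is a package convention: its gradients
#' are better conditioned at low counts.
#'
#' @inheritParams ctfConstrained
#' @param maxIter maximum PGM iterations (default 30).
#' @param tol relative iterate-change tolerance (default 1e-6).
#' @param init optional initial [PhaseMap-class] (default: projected CTF).
#' @return A [PhaseMap-class] with attribute \code{"report"}.
#' @export
tikhonovRetrieve <- function(h, B, profile = regularizationProfile(),
                             constraints = phaseConstraints(),
                             maxIter = 30, tol = 1e-6, init = NULL) {
  obj <- .tikhonovObjective(h, B, profile)
  .runTikhonov(h, B, profile, constraints, obj, maxIter, tol, init)
}

#' Tikhonov retrieval with smoothed total-variation regularization
#'
#' Adds the edge-preserving smoothed-TV penalty
#' \eqn{\tau \sum \sqrt{|\nabla\phi|^2 + \epsilon^2}} (forward differences,
#' periodic) to the nonlinear Tikhonov objective; \code{tau = 0} reduces
#' exactly to [tikhonovRetrieve()].
#'
#' @inheritParams tikhonovRetrieve
#' @param tau TV weight (>= 0).
#' @param epsilon smoothing parameter (> 0, default 1e-2).
#' @return A [PhaseMap-class] with attribute \code{"report"}.
#' @export
tikhonovTV <- function(h, B, profile = regularizationProfile(),
                       constraints = phaseConstraints(), tau = 0,
                       epsilon = 1e-2, maxIter = 30, tol = 1e-6, init = NULL) {
  if (tau < 0) stop("tau must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  obj <- .tikhonovObjective(h, B, profile, tau = tau, epsilon = epsilon)
  .runTikhonov(h, B, profile, constraints, obj, maxIter, tol, init)
}

.runTikhonov <- function(h, B, profile, constraints, obj, maxIter, tol, init) {
  stopifnot(inherits(constraints, "phaseConstraints"))
  x0 <- if (is.null(init)) {
    projectConstraints(phaseValues(ctfRetrieve(h, B, profile)), constraints)
  } else {
    projectConstraints(phaseValues(init), constraints)
  }
  p <- compositeProblem(obj$value, obj$grad,
                        prox = function(x, step)
                          projectConstraints(x, constraints),
                        x0 = x0)
  res <- pgmAdaptive(p, maxIter = maxIter, tol = tol)
  out <- phaseMap(res$x)
  attr(out, "report") <- res$report
  out
}

#' Alternating-projections phase retrieval
#'
#' Error-reduction iteration between the measurement sets (replace the
#' modulus at each distance by \eqn{\sqrt{I_d}}) and the homogeneous-object
#' set (log-space least-squares fit of \eqn{e^{(B+i)\phi}} with constraints
#' on \eqn{\phi}). Runs a fixed iteration count and reports the per-iteration
#' magnitude residual \eqn{\sum_d \||\psi_d| - \sqrt{I_d}\|}.
#'
#' @inheritParams ctfConstrained
#' @param maxIter iteration count (default 200).
#' @param init optional initial [PhaseMap-class] (default: zero phase).
#' @return A [PhaseMap-class] with attribute \code{"residuals"} (numeric
#'   vector, one entry per iteration).
#' @export
alternatingProjections <- function(h, B,
                                   constraints = phaseConstraints(),
                                   maxIter = 200, init = NULL) {
  h <- .asHologramStack(h)
  stopifnot(inherits(constraints, "phaseConstraints"))
  shape <- dim(h@images[[1]])
  sqrtI <- lapply(h@images, sqrt)
  kernels <- lapply(h@fresnel, function(f)
    propagationKernel(shape, f, "forward"))
  prop <- function(x, H) ifft2(fft2(x) * H)
  phi <- if (is.null(init)) matrix(0, shape[1], shape[2])
         else phaseValues(init)
  phi <- projectConstraints(phi, constraints)
  residuals <- numeric(maxIter)
  for (k in seq_len(maxIter)) {
    T <- exp((B + 1i) * phi)
    Tacc <- matrix(0i, shape[1], shape[2])
    res <- 0
    for (d in seq_along(kernels)) {
      psi <- prop(T, kernels[[d]])
      m <- Mod(psi)
      res <- res + sqrt(sum((m - sqrtI[[d]])^2))
      psi <- sqrtI[[d]] * psi / pmax(m, 1e-12)   # measurement projection
      Tacc <- Tacc + prop(psi, Conj(kernels[[d]]))
    }
    residuals[k] <- res
    Tbar <- Tacc / length(kernels)
    Tbar[Mod(Tbar) < 1e-12] <- 1e-12
    lt <- log(Tbar)
    # homogeneous-object projection in log space: log T = (B + i) phi
    phi <- (B * Re(lt) + Im(lt)) / (B^2 + 1)
    phi <- projectConstraints(phi, constraints)
  }
  out <- phaseMap(phi)
  attr(out, "residuals") <- residuals
  out
}
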