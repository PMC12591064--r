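# First-order solvers for composite problems min f(x) + g(x) with f smooth
# (value/gradient callables) and g handled through its proximal operator.
# These are the engines behind constrained CTF (ADMM) and the (TV-)Tikhonov
# retrievals (proximal gradient with adaptive steps).

#' Define a smooth + non-smooth composite problem
#'
#' @param smoothValue function(x) -> scalar, the smooth term f.
#' @param smoothGrad function(x) -> array like x, gradient of f.
#' @param prox function(x, step) -> array like x, proximal operator of the
#'   non-smooth term (identity for unconstrained problems). Must satisfy
#'   \code{prox(x, 0) == x}.
#' @param x0 initial iterate (numeric vector/matrix/array).
#' @return A list of class \code{"compositeProblem"}.
#' @export
compositeProblem <- function(smoothValue, smoothGrad,
                             prox = function(x, step) x, x0) {
  f0 <- smoothValue(x0)
  if (!is.finite(f0)) stop("smoothValue must be finite at x0")
  structure(list(smoothValue = smoothValue, smoothGrad = smoothGrad,
                 prox = prox, x0 = x0),
            class = "compositeProblem")
}

.solverReport <- function(objective, steps, converged, residuals = NULL) {
  list(iterations = length(objective) - 1L, objective = objective,
       steps = steps, converged = converged, residuals = residuals)
}

.solverFailure <- function(message, report) {
  stop(structure(class = c("solverFailure", "error", "condition"),
                 list(message = message, call = sys.call(-1),
                      report = report)))
}

.relChange <- function(xnew, x) {
  sqrt(sum((xnew - x)^2)) / max(sqrt(sum(x^2)), 1)
}

#' Proximal gradient method with adaptive steps and backtracking
#'
#' Spectral (Barzilai-Borwein) step-size estimation with nonmonotone
#' backtracking: a trial step is halved until the quadratic upper-bound
#' condition
#' \eqn{f(x^+) \le \max(f_{k-9},...,f_k) + \langle \nabla f(x), x^+ - x
#' \rangle + \|x^+ - x\|^2/(2\tau)}
#' holds (window of 10). Stops when the relative iterate change drops below
#' \code{tol} or after \code{maxIter} iterations.
#'
#' @param p a [compositeProblem()].
#' @param maxIter maximum iterations (default 100).
#' @param tol relative iterate-change tolerance (default 1e-6).
#' @return \code{list(x = solution, report = solver report)} where the report
#'   holds the objective trace (length iterations + 1), the step-size trace
#'   and the convergence flag.
#' @export
pgmAdaptive <- function(p, maxIter = 100, tol = 1e-6) {
  stopifnot(inherits(p, "compositeProblem"))
  x <- p$x0
  f <- p$smoothValue(x)
  g <- p$smoothGrad(x)
  gnorm <- sqrt(sum(g^2))
  if (gnorm == 0) {
    x <- p$prox(x, 0)
    return(list(x = x, report = .solverReport(c(f, p$smoothValue(x)), 0,
                                              converged = TRUE)))
  }
  # initial step from a secant probe of the local Lipschitz constant
  d <- 1e-3 * max(sqrt(sum(x^2)), 1) / gnorm
  g2 <- p$smoothGrad(x - d * g)
  L <- sqrt(sum((g - g2)^2)) / (d * gnorm)
  tau <- if (is.finite(L) && L > 0) 1 / L else 1
  fhist <- rep(f, 10)  # nonmonotone window
  objective <- f
  steps <- numeric()
  converged <- FALSE
  for (k in seq_len(maxIter)) {
    ok <- FALSE
    for (bt in 1:60) {
      xnew <- p$prox(x - tau * g, tau)
      fnew <- p$smoothValue(xnew)
      if (is.finite(fnew) &&
          fnew <= max(fhist) + sum(g * (xnew - x)) +
                  sum((xnew - x)^2) / (2 * tau)) {
        ok <- TRUE
        break
      }
      if (!is.finite(fnew) && bt >= 50)
        .solverFailure("non-finite objective during line search",
                       .solverReport(c(objective, fnew), c(steps, tau), FALSE))
      tau <- tau / 2
    }
    if (!ok)
      .solverFailure("line search failed to find an acceptable step",
                     .solverReport(objective, steps, FALSE))
    gnew <- p$smoothGrad(xnew)
    dx <- xnew - x; dg <- gnew - g
    steps <- c(steps, tau)
    objective <- c(objective, fnew)
    fhist <- c(fhist[-1], fnew)
    rc <- .relChange(xnew, x)
    # BB1 spectral step for the next iteration
    sg <- sum(dx * dg)
    if (is.finite(sg) && sg > 0) tau <- sum(dx * dx) / sg
    x <- xnew; g <- gnew; f <- fnew
    if (rc < tol) { converged <- TRUE; break }
  }
  list(x = x, report = .solverReport(objective, steps, converged))
}

#' FISTA: accelerated proximal gradient with adaptive restart
#'
#' Fixed-step proximal gradient with Nesterov momentum
#' \eqn{t_{k+1} = (1 + \sqrt{1 + 4 t_k^2})/2} and gradient-based adaptive
#' restart (momentum reset when the update direction opposes the previous
#' step). Optional backtracking halves the step on objective increase beyond
#' the quadratic model.
#'
#' @param p a [compositeProblem()].
#' @param step step size (about 1/L for gradient Lipschitz constant L).
#' @param maxIter maximum iterations (default 100).
#' @param tol relative iterate-change tolerance (default 1e-6).
#' @param backtrack logical, enable backtracking (default TRUE).
#' @return \code{list(x, report)} as in [pgmAdaptive()].
#' @export
fista <- function(p, step, maxIter = 100, tol = 1e-6, backtrack = TRUE) {
  stopifnot(inherits(p, "compositeProblem"))
  x <- p$x0
  f <- p$smoothValue(x)
  g0 <- p$smoothGrad(x)
  if (sqrt(sum(g0^2)) == 0 && identical(p$prox(x, step), x)) {
    return(list(x = x, report = .solverReport(c(f, f), step, TRUE)))
  }
  y <- x
  t <- 1
  objective <- f
  steps <- numeric()
  converged <- FALSE
  for (k in seq_len(maxIter)) {
    gy <- p$smoothGrad(y)
    fy <- p$smoothValue(y)
    repeat {
      xnew <- p$prox(y - step * gy, step)
      fnew <- p$smoothValue(xnew)
      if (!backtrack ||
          (is.finite(fnew) &&
           fnew <= fy + sum(gy * (xnew - y)) + sum((xnew - y)^2) / (2 * step)))
        break
      step <- step / 2
      if (step < .Machine$double.xmin)
        .solverFailure("FISTA backtracking underflow",
                       .solverReport(objective, steps, FALSE))
    }
    tnew <- (1 + sqrt(1 + 4 * t^2)) / 2
    # gradient-style adaptive restart: reset momentum if the momentum
    # direction opposes the last proximal step
    if (sum((y - xnew) * (xnew - x)) > 0) {
      tnew <- 1
      ynew <- xnew
    } else {
      ynew <- xnew + ((t - 1) / tnew) * (xnew - x)
    }
    steps <- c(steps, step)
    objective <- c(objective, fnew)
    rc <- .relChange(xnew, x)
    x <- xnew; y <- ynew; t <- tnew
    if (rc < tol) { converged <- TRUE; break }
  }
  list(x = x, report = .solverReport(objective, steps, converged))
}

#' Accelerated ADMM with restart for quadratic-plus-constraint problems
#'
#' Solves min f(x) + g(z) s.t. x = z where the x-update
#' argmin f(x) + (rho/2)||x - v||^2 is available in closed form (supplied as
#' \code{xUpdate}) and g is handled through its proximal operator /
#' projection \code{zProx}. Uses over-relaxation-free accelerated ADMM with
#' the restart rule: if the combined residual grows beyond \code{eta} times
#' its predecessor, momentum is reset. Optional residual balancing rescales
#' rho when primal and dual residuals diverge by more than a factor 10.
#'
#' @param xUpdate function(v, rho) -> x, closed-form proximal map of f.
#' @param zProx function(x, rho) -> z, proximal map / projection of g.
#' @param x0 initial iterate.
#' @param rho augmented-Lagrangian parameter (> 0, default 1).
#' @param maxIter maximum iterations (default 100).
#' @param tol residual tolerance (default 1e-6): converged when both primal
#'   and dual residual norms (relative to the iterate norm) fall below it.
#' @param eta restart threshold (default 0.999).
#' @param balance logical, enable residual balancing (default FALSE).
#' @return \code{list(x, z, report)}; \code{report$residuals} holds the final
#'   primal and dual residual norms.
#' @export
admmAccel <- function(xUpdate, zProx, x0, rho = 1, maxIter = 100, tol = 1e-6,
                      eta = 0.999, balance = FALSE) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0)
    stop("rho must be a single positive number")
  z <- zhat <- zprev <- x0
  u <- uhat <- uprev <- x0 * 0
  a <- 1
  cprev <- Inf
  objective <- numeric()
  converged <- FALSE
  primal <- dual <- NA_real_
  for (k in seq_len(maxIter)) {
    x <- xUpdate(zhat - uhat, rho)
    z <- zProx(x + uhat, rho)
    u <- uhat + x - z
    primal <- sqrt(sum((x - z)^2))
    dual <- rho * sqrt(sum((z - zhat)^2))
    ck <- rho * sum((u - uhat)^2) + rho * sum((z - zhat)^2)
    if (ck < eta * cprev) {
      anew <- (1 + sqrt(1 + 4 * a^2)) / 2
      zhat <- z + ((a - 1) / anew) * (z - zprev)
      uhat <- u + ((a - 1) / anew) * (u - uprev)
      a <- anew
      cprev <- ck
      zprev <- z; uprev <- u
    } else {  # restart: fall back to the last accepted iterates
      a <- 1
      zhat <- zprev
      uhat <- uprev
      cprev <- ck / eta
    }
    objective <- c(objective, primal)
    scale <- max(sqrt(sum(z^2)), 1)
    if (primal / scale < tol && dual / scale < tol) {
      converged <- TRUE
      break
    }
    if (balance && k %% 5 == 0) {
      if (primal > 10 * dual) { rho <- rho * 2; u <- u / 2; uhat <- uhat / 2 }
      else if (dual > 10 * primal) { rho <- rho / 2; u <- u * 2; uhat <- uhat * 2 }
    }
  }
  list(x = x, z = z,
       report = .solverReport(c(NA_real_, objective), rho, converged,
                              residuals = c(primal = primal, dual = dual)))
}

#' Central finite-difference gradient check
#'
#' Compares an analytic gradient callable against central differences at a
#' point; used by the test-suite to validate hand-derived gradients of the
#' retrieval objectives.
#'
#' @param value function(x) -> scalar.
#' @param grad function(x) -> array like x.
#' @param x evaluation point.
#' @param h relative step (default 1e-6, scaled by \code{max(abs(x), 1)}).
#' @return Relative maximum discrepancy between analytic and numeric gradient.
#' @export
checkGradient <- function(value, grad, x, h = 1e-6) {
  g <- grad(x)
  gn <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  step <- h * max(max(abs(x)), 1)
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + step
    xm <- x; xm[i] <- xm[i] - step
    gn[i] <- (value(xp) - value(xm)) / (2 * step)
  }
  max(abs(g - gn)) / max(max(abs(gn)), .Machine$double.eps)
}
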