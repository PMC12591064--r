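test_that("adaptive proximal gradient solves quadratics to tolerance", {
  # plain quadratic: minimizer b
  b <- c(1, -2, 3)
  p <- compositeProblem(function(x) 0.5 * sum((x - b)^2),
                        function(x) x - b, x0 = c(0, 0, 0))
  r <- pgmAdaptive(p, maxIter = 20)
  expect_true(r$report$converged)
  expect_lt(max(abs(r$x - b)), 1e-5)
  expect_lte(r$report$iterations, 20)
  # projected quadratic: argmin 1/2 (x-3)^2 s.t. x <= 0 is 0
  p2 <- compositeProblem(function(x) 0.5 * (x - 3)^2, function(x) x - 3,
                         prox = function(x, s) pmin(x, 0), x0 = -1)
  expect_equal(pgmAdaptive(p2)$x, 0, tolerance = 1e-8)
})

test_that("adaptive PGM matches a direct linear solve on a random SPD quadratic", {
  set.seed(20)
  n <- 20
  A <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
  b <- rnorm(n)
  xstar <- solve(A, b)
  p <- compositeProblem(function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x),
                        function(x) as.vector(A %*% x - b),
                        x0 = rep(0, n))
  r <- pgmAdaptive(p, maxIter = 500, tol = 1e-10)
  expect_lt(sqrt(sum((r$x - xstar)^2)) / sqrt(sum(xstar^2)), 1e-6)
  # objective trace nonincreasing up to the nonmonotone window of 10
  tr <- r$report$objective
  runmax <- vapply(seq_along(tr), function(i) max(tr[max(1, i - 9):i]),
                   numeric(1))
  expect_true(all(diff(runmax) <= 1e-12))
})

test_that("FISTA handles prox fixed points and matches PGM on a lasso", {
  # soft-threshold at 1 of the quadratic centered at 3: minimizer 2
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  p <- compositeProblem(function(x) 0.5 * (x - 3)^2, function(x) x - 3,
                        prox = function(x, s) soft(x, s * 1), x0 = 0)
  r <- fista(p, step = 1, maxIter = 200, tol = 1e-10)
  expect_equal(r$x, 2, tolerance = 1e-6)
  # zero gradient at x0 with identity prox returns x0
  p0 <- compositeProblem(function(x) 0 * sum(x), function(x) x * 0, x0 = c(1, 2))
  expect_equal(fista(p0, step = 1)$x, c(1, 2))
  # lasso instance: FISTA and pgmAdaptive agree in objective
  set.seed(8)
  n <- 10
  A <- matrix(rnorm(5 * n), 5); b <- rnorm(5); lam <- 0.1
  fval <- function(x) 0.5 * sum((A %*% x - b)^2)
  grad <- function(x) as.vector(crossprod(A, A %*% x - b))
  prox <- function(x, s) soft(x, s * lam)
  full <- function(x) fval(x) + lam * sum(abs(x))
  L <- max(eigen(crossprod(A), only.values = TRUE)$values)
  p1 <- compositeProblem(fval, grad, prox, x0 = rep(0, n))
  r1 <- fista(p1, step = 1 / L, maxIter = 3000, tol = 0)
  r2 <- pgmAdaptive(p1, maxIter = 3000, tol = 1e-14)
  expect_lt(abs(full(r1$x) - full(r2$x)), 1e-8)
})

test_that("FISTA with restart is no worse than plain gradient descent", {
  set.seed(21)
  n <- 30
  A <- crossprod(matrix(rnorm(n * n), n)) + 0.1 * diag(n)
  b <- rnorm(n)
  fval <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
  grad <- function(x) as.vector(A %*% x - b)
  L <- max(eigen(A, only.values = TRUE)$values)
  p <- compositeProblem(fval, grad, x0 = rep(0, n))
  iters <- 60
  rf <- fista(p, step = 1 / L, maxIter = iters, tol = 0)
  x <- rep(0, n)
  for (k in seq_len(iters)) x <- x - (1 / L) * grad(x)  # plain GD
  expect_lte(fval(rf$x), fval(x) + 1e-12)
})

test_that("accelerated ADMM solves constrained quadratics", {
  # 1/2 (x-b)^2 s.t. x >= 0
  xup <- function(b) function(v, rho) (b + rho * v) / (1 + rho)
  proj <- function(x, rho) pmax(x, 0)
  r1 <- admmAccel(xup(-2), proj, x0 = 0, maxIter = 200, tol = 1e-10)
  expect_equal(r1$z, 0, tolerance = 1e-6)
  r2 <- admmAccel(xup(2), proj, x0 = 0, maxIter = 200, tol = 1e-10)
  expect_equal(r2$z, 2, tolerance = 1e-6)
  expect_error(admmAccel(xup(2), proj, x0 = 0, rho = -1), "positive")
  # converged runs report both residuals below tolerance
  expect_true(r2$report$converged)
  expect_lt(max(r2$report$residuals), 1e-6 * max(1, abs(r2$z)))
})

test_that("ADMM nonnegative least squares matches active-set enumeration", {
  set.seed(33)
  n <- 5
  A <- matrix(rnorm(n * n), n)
  b <- rnorm(n)
  AtA <- crossprod(A); Atb <- crossprod(A, b)
  # brute-force oracle: enumerate all active sets (x_i = 0 vs free >= 0)
  best <- NULL; bestval <- Inf
  for (mask in 0:(2^n - 1)) {
    free <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    x <- rep(0, n)
    if (length(free)) {
      xf <- tryCatch(solve(AtA[free, free, drop = FALSE], Atb[free]),
                     error = function(e) NULL)
      if (is.null(xf) || any(xf < 0)) next
      x[free] <- xf
    }
    v <- 0.5 * sum((A %*% x - b)^2)
    if (v < bestval) { bestval <- v; best <- x }
  }
  xup <- function(v, rho) as.vector(solve(AtA + rho * diag(n),
                                          Atb + rho * v))
  r <- admmAccel(xup, function(x, rho) pmax(x, 0), x0 = rep(0, n),
                 maxIter = 2000, tol = 1e-12)
  expect_lt(max(abs(r$z - best)), 1e-6)
})

test_that("the finite-difference gradient checker flags wrong gradients", {
  f <- function(x) sum(sin(x)) + 0.5 * sum(x^2)
  g <- function(x) cos(x) + x
  x <- c(0.3, -1.2, 2)
  expect_lt(checkGradient(f, g, x), 1e-6)
  gbad <- function(x) cos(x)  # missing term
  expect_gt(checkGradient(f, gbad, x), 1e-2)
})

test_that("non-finite objectives raise a solver failure with a report", {
  # objective is finite only at the start point: every line-search trial
  # is non-finite and the solver must fail cleanly
  p <- compositeProblem(function(x) if (x == 1) 1 else NaN,
                        function(x) 1, x0 = 1)
  expect_error(pgmAdaptive(p, maxIter = 50), class = "solverFailure")
})
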