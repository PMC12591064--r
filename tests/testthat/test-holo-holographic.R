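# Study conditions throughout: two distances with Fresnel numbers 2.44e-4
# and 1.98e-4 (rescaled to the common pixel grid), beta/delta = 0.035, and
# two-level regularization weights 2e-5 / 3e-5.

test_that("CTF factor and two-level weights behave as specified", {
  f <- fresnelPair(0.05)
  s <- ctfFactor(c(16, 16), f, B = 0.1)
  expect_equal(s[1, 1], 0.1)                       # s(0) = B
  chi <- holotomo:::chiGrid(c(16, 16), f)
  expect_equal(s, sin(chi) + 0.1 * cos(chi))
  # chi = pi/2 gives 1 regardless of B; chi = pi gives -B
  expect_equal(sin(pi / 2) + 0.1 * cos(pi / 2), 1)
  prof <- regularizationProfile(2e-5, 3e-5, 0.5)
  a <- twoLevelAlpha(c(64, 64), fresnelPair(2.44e-4), prof)
  chi <- holotomo:::chiGrid(c(64, 64), fresnelPair(2.44e-4))
  expect_equal(a[1, 1], 2e-5, tolerance = 1e-3)    # alpha_low at DC
  expect_equal(max(a[chi > 10]), 3e-5, tolerance = 1e-6)
  expect_true(all(diff(a[order(chi)]) > -1e-12))   # monotone in chi
  # equal weights give a constant profile
  ac <- twoLevelAlpha(c(16, 16), fresnelPair(0.1),
                      regularizationProfile(1e-4, 1e-4))
  expect_equal(max(ac) - min(ac), 0)
})

test_that("weak-object linearization ties the CTF to the propagator convention", {
  set.seed(31)
  n <- 64
  phi <- blur2d(matrix(rnorm(n * n), n), 2)
  phi <- 1e-3 * phi / max(abs(phi))
  B <- 0.035
  f <- fresnelPair(0.05)
  I <- Mod(fresnelPropagate(exp((B + 1i) * phi), f))^2
  s <- ctfFactor(c(n, n), f, B)
  lin <- Re(stats::fft(2 * s * stats::fft(phi), inverse = TRUE)) / n^2
  expect_lt(relErr(I - 1, lin), 1e-2)
})

test_that("CTF retrieval recovers a weak object under the study conditions", {
  n <- 256
  phi <- gaussBlobPhase(n, 0.1, 30)
  h <- simulateHolograms(phi, simulationRecipe(photonCount = Inf, seed = 3))
  expect_equal(nDistances(h), 2)
  rec <- ctfRetrieve(h, 0.035)
  expect_lt(relErr(phaseValues(rec), phi), 0.02)
  # flat holograms retrieve zero phase
  flat <- hologramStack(list(matrix(1, 32, 32), matrix(1, 32, 32)),
                        list(2.44e-4, 1.98e-4))
  expect_equal(max(abs(phaseValues(ctfRetrieve(flat, 0.035)))), 0,
               tolerance = 1e-12)
})

test_that("a second distance fills CTF zeros and reduces the error", {
  n <- 256
  phi <- gaussBlobPhase(n, 0.1, 30)
  h2 <- simulateHolograms(phi, simulationRecipe(photonCount = Inf, seed = 3))
  h1 <- hologramStack(holoImages(h2)[[1]], holoFresnel(h2)[[1]])
  e1 <- relErr(phaseValues(ctfRetrieve(h1, 0.035)), phi)
  e2 <- relErr(phaseValues(ctfRetrieve(h2, 0.035)), phi)
  expect_gt(e1 / e2, 2)
})

test_that("constrained CTF enforces constraints exactly and helps where data are weak", {
  n <- 128
  phi <- gaussBlobPhase(n, 0.1, 15)
  # single-distance noisy data: the CTF zeros are unfilled, so priors carry
  # real information and the constrained solution is more accurate
  h1 <- simulateHolograms(phi, simulationRecipe(fresnel = list(2.44e-4),
                                                photonCount = 1e3, seed = 11))
  eu <- relErr(phaseValues(ctfRetrieve(h1, 0.035)), phi)
  pc <- ctfConstrained(h1, 0.035,
                       constraints = phaseConstraints(nonpositive = TRUE),
                       maxIter = 200)
  ec <- relErr(phaseValues(pc), phi)
  expect_lte(ec, eu)
  expect_lte(max(phaseValues(pc)), 0)             # exact non-positivity
  # support constraint: outside pixels are exactly zero
  g <- seq_len(n) - (n + 1) / 2
  supp <- outer(g^2, g^2, `+`) < 45^2
  ps <- ctfConstrained(h1, 0.035,
                       constraints = phaseConstraints(nonpositive = TRUE,
                                                      support = supp),
                       maxIter = 100)
  expect_identical(max(abs(phaseValues(ps)[!supp])), 0)
  # no active constraints: exactly the closed-form solution
  pu <- ctfConstrained(h1, 0.035, constraints = phaseConstraints())
  expect_lt(max(abs(phaseValues(pu) - phaseValues(ctfRetrieve(h1, 0.035)))),
            1e-8)
})

test_that("Tikhonov gradient matches central finite differences", {
  set.seed(7)
  n <- 8
  phi <- matrix(rnorm(n * n, -0.3, 0.2), n)
  h <- simulateHolograms(matrix(-0.2 * abs(rnorm(n * n)), n),
                         simulationRecipe(fresnel = list(0.1, 0.15),
                                          photonCount = Inf))
  for (tau in c(0, 0.01)) {
    obj <- holotomo:::.tikhonovObjective(h, 0.035, regularizationProfile(),
                                         tau = tau, epsilon = 0.05)
    expect_lt(checkGradient(obj$value, obj$grad, phi), 1e-5)
  }
})

test_that("Tikhonov beats CTF on strong phases and respects stationarity", {
  n <- 128
  phi <- twoBlobPhase(n, 1.5, 18)
  h <- simulateHolograms(phi, simulationRecipe(photonCount = Inf, seed = 5))
  eCTF <- relErr(phaseValues(ctfRetrieve(h, 0.035)), phi)
  pt <- tikhonovRetrieve(h, 0.035, maxIter = 40)
  eTik <- relErr(phaseValues(pt), phi)
  expect_lt(eTik, eCTF)
  rep <- attr(pt, "report")
  expect_gt(length(rep$objective), 2)
  # flat data, zero init: phi = 0 is stationary
  flat <- hologramStack(list(matrix(1, 16, 16)), list(1e-2))
  p0 <- tikhonovRetrieve(flat, 0.035, init = phaseMap(matrix(0, 16, 16)))
  expect_equal(max(abs(phaseValues(p0))), 0, tolerance = 1e-12)
})

test_that("smoothed TV regularization reduces total variation at matched residual", {
  # tau = 0 reduces exactly to the plain Tikhonov solver
  n <- 64
  phi <- gaussBlobPhase(n, 0.4, 8)
  h <- simulateHolograms(phi, simulationRecipe(photonCount = 1e3, seed = 9))
  p0 <- tikhonovRetrieve(h, 0.035, maxIter = 15)
  p00 <- tikhonovTV(h, 0.035, tau = 0, maxIter = 15)
  expect_lt(max(abs(phaseValues(p0) - phaseValues(p00))), 1e-10)
  # piecewise-constant-ish phantom with noise: TV result is less oscillatory
  d <- diskProjection(n, 14); phiP <- -0.4 * (d > 0)
  hP <- simulateHolograms(phiP, simulationRecipe(photonCount = 1e3, seed = 10))
  pTV <- tikhonovTV(hP, 0.035, tau = 1e-3, maxIter = 40)
  pNo <- tikhonovRetrieve(hP, 0.035, maxIter = 40)
  tv <- function(x) {
    dy <- rbind(x[-1, ], x[1, ]) - x; dx <- cbind(x[, -1], x[, 1]) - x
    sum(sqrt(dy^2 + dx^2))
  }
  dataRes <- function(pm) {
    T <- exp((0.035 + 1i) * phaseValues(pm))
    sum(vapply(seq_len(nDistances(hP)), function(d)
      sum((Mod(fresnelPropagate(T, holoFresnel(hP)[[d]])) -
             sqrt(holoImages(hP)[[d]]))^2), numeric(1)))
  }
  expect_lt(tv(phaseValues(pTV)), tv(phaseValues(pNo)))
  expect_lt(abs(dataRes(pTV) - dataRes(pNo)) / dataRes(pNo), 0.05)
})

test_that("alternating projections contract the magnitude residual", {
  n <- 64
  # flat data from zero phase is a fixed point
  flat <- hologramStack(list(matrix(1, n, n), matrix(1, n, n)),
                        list(2.44e-4, 1.98e-4))
  p0 <- alternatingProjections(flat, 0.035, maxIter = 5)
  expect_equal(max(abs(phaseValues(p0))), 0, tolerance = 1e-10)
  # noiseless weak simulation: residual after 200 iterations < 10% of start
  phi <- gaussBlobPhase(n, 0.1, 8)
  h <- simulateHolograms(phi, simulationRecipe(photonCount = Inf, seed = 12))
  pa <- alternatingProjections(h, 0.035, maxIter = 200)
  r <- attr(pa, "residuals")
  expect_lt(r[200] / r[1], 0.1)
  # after a measurement projection the modulus equals sqrt(I) exactly
  T <- exp((0.035 + 1i) * phaseValues(pa))
  psi <- fresnelPropagate(T, holoFresnel(h)[[1]])
  psi <- sqrt(holoImages(h)[[1]]) * psi / Mod(psi)
  expect_equal(Mod(psi), sqrt(holoImages(h)[[1]]), tolerance = 1e-12)
})

test_that("holographic retrievals are translation equivariant", {
  n <- 64
  phi <- gaussBlobPhase(n, 0.1, 8)
  h <- simulateHolograms(phi, simulationRecipe(photonCount = Inf, seed = 2))
  sh <- function(x) x[c(9:n, 1:8), c(14:n, 1:13)]
  hs <- hologramStack(lapply(holoImages(h), sh), holoFresnel(h))
  expect_equal(sh(phaseValues(ctfRetrieve(h, 0.035))),
               phaseValues(ctfRetrieve(hs, 0.035)), tolerance = 1e-10)
  expect_equal(sh(phaseValues(alternatingProjections(h, 0.035, maxIter = 10))),
               phaseValues(alternatingProjections(hs, 0.035, maxIter = 10)),
               tolerance = 1e-8)
})

test_that("constraint projections are idempotent and validated", {
  set.seed(13)
  x <- matrix(rnorm(64), 8)
  supp <- matrix(rep(c(TRUE, FALSE), 32), 8)
  c1 <- phaseConstraints(nonpositive = TRUE, support = supp, lower = -2)
  p1 <- projectConstraints(x, c1)
  expect_identical(projectConstraints(p1, c1), p1)
  expect_true(all(p1 <= 0) && all(p1 >= -2) && all(p1[!supp] == 0))
  expect_true(isUnconstrained(phaseConstraints()))
  expect_false(isUnconstrained(c1))
  expect_error(hologramStack(list(matrix(1, 4, 4), matrix(1, 5, 5)),
                             list(0.1, 0.1)))
  expect_error(hologramStack(matrix(-1, 4, 4), 0.1))
})
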