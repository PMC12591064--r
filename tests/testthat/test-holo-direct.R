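test_that("Paganin retrieval handles flat fields and recovers a disk", {
  f <- fresnelPair(0.1); B <- 0.05
  ones <- matrix(1, 32, 32)
  expect_equal(phaseValues(paganin(ones, f, B)), ones * 0, tolerance = 1e-12)
  expect_equal(phaseValues(paganin(ones * 0.8, f, B)),
               ones * log(0.8) / (2 * B), tolerance = 1e-10)
  # simulate a single-material disk and retrieve
  n <- 128
  d <- diskProjection(n, 30)
  phi <- blur2d(-0.5 * d / max(d), 1.5)
  h <- simulateHolograms(phi, simulationRecipe(fresnel = list(0.1),
                                               bRatio = B, photonCount = Inf))
  rec <- paganin(holoImages(h)[[1]], f, B)
  expect_lt(relErr(phaseValues(rec), phi), 0.05)
  expect_error(paganin(ones - 2, f, B), "> 0")
  expect_error(paganin(ones, f, 0), "> 0")
})

test_that("generalized Paganin matches classic at low frequency, damps less at Nyquist", {
  f <- fresnelPair(0.1); B <- 0.05
  ones <- matrix(1, 32, 32)
  expect_equal(phaseValues(generalizedPaganin(ones, f, B)), ones * 0,
               tolerance = 1e-12)
  # strictly band-limited input (|nu| <= 0.02): both filters agree
  set.seed(14)
  n <- 256
  x <- matrix(rnorm(n * n), n)
  nu <- frequencyGrid(n)
  r2 <- sqrt(outer(nu^2, rep(1, n)) + outer(rep(1, n), nu^2))
  X <- stats::fft(x); X[r2 > 0.02] <- 0
  low <- Re(stats::fft(X, inverse = TRUE)) / n^2
  I <- 1 + 0.01 * low / max(abs(low))
  pg <- phaseValues(paganin(I, f, B))
  gp <- phaseValues(generalizedPaganin(I, f, B))
  expect_lt(relErr(gp, pg), 1e-4)
  # at Nyquist the discrete chi is smaller, so the filter damps less
  chiN <- holotomo:::chiGrid(c(2, 2), f)[1, 2]          # nu = 0.5
  chidN <- holotomo:::discreteChiGrid(c(2, 2), f)[1, 2]
  expect_lt(chidN, chiN)
  expect_gt(1 / (1 + chidN / B), 1 / (1 + chiN / B))    # filter values
  # small-nu Taylor limit: discrete form matches chi to O(nu^4)
  nu <- 1e-3
  chi <- pi * nu^2 / 0.1
  chid <- (1 - cos(2 * pi * nu)) / (2 * pi * 0.1)
  expect_lt(abs(chid - chi) / chi, 1e-4)
})

test_that("modified Bronnikov recovers weak pure-phase objects", {
  ones <- matrix(1, 16, 16)
  expect_equal(phaseValues(modifiedBronnikov(ones, fresnelPair(0.2))),
               ones * 0, tolerance = 1e-12)
  # pure phase objects carry no DC information (mean(I) = 1 exactly), so
  # the retrieved map is compared up to its unobservable mean offset
  n <- 64
  phi <- gaussBlobPhase(n, 0.05, 3)
  h <- simulateHolograms(phi, simulationRecipe(fresnel = list(0.2),
                                               bRatio = 0, photonCount = Inf))
  rec <- phaseValues(modifiedBronnikov(holoImages(h)[[1]],
                                       fresnelPair(0.2), 1e-3))
  rec <- rec - mean(rec) + mean(phi)
  expect_lt(relErr(rec, phi), 0.05)
  # agreement with B = 0 CTF retrieval on the band 0.05 < chi < 0.3, where
  # neither filter is dominated by its (different) low-frequency regularizer
  n <- 128
  d <- diskProjection(n, n / 4)
  phi <- blur2d(-0.05 * d / max(d), 4)
  h <- simulateHolograms(phi, simulationRecipe(fresnel = list(0.2),
                                               bRatio = 0, photonCount = Inf))
  I <- holoImages(h)[[1]]
  rec <- modifiedBronnikov(I, fresnelPair(0.2), 1e-3)
  ctf <- phaseValues(ctfRetrieve(h, B = 0,
                                 regularizationProfile(1e-6, 1e-6)))
  chi <- holotomo:::chiGrid(c(n, n), fresnelPair(0.2))
  keep <- chi > 0.05 & chi < 0.3
  bp <- function(x) { X <- stats::fft(x); X[!keep] <- 0
                      Re(stats::fft(X, inverse = TRUE)) / length(x) }
  expect_lt(relErr(bp(phaseValues(rec)), bp(ctf)), 0.02)
  expect_error(modifiedBronnikov(I, fresnelPair(0.2), 0), "> 0")
})

test_that("Bronnikov-aided correction suppresses propagation fringes", {
  n <- 128
  ones <- matrix(1, n, n)
  expect_equal(bronnikovAidedCorrection(ones, fresnelPair(0.3)), ones,
               tolerance = 1e-10)
  # gamma = 0 returns the input untouched
  set.seed(2)
  I <- 1 + 0.1 * blur2d(matrix(rnorm(n * n), n), 3)
  expect_identical(bronnikovAidedCorrection(I, fresnelPair(0.3), gamma = 0), I)
  # absorbing + phase disk: edge fringes reduced at least 5x
  d <- diskProjection(n, 25)
  phi <- blur2d(-0.8 * d / max(d), 1)
  B <- 0.1
  h <- simulateHolograms(phi, simulationRecipe(fresnel = list(0.4),
                                               bRatio = B, photonCount = Inf))
  I <- holoImages(h)[[1]]
  # alpha = 2B makes the Bronnikov filter consistent with the homogeneous
  # object at low frequency (numerator 2 chi + 2B matches the denominator)
  A <- bronnikovAidedCorrection(I, fresnelPair(0.4), alpha = 2 * B, gamma = 1)
  ideal <- exp(2 * B * phi)          # attenuation-only image
  overshoot <- function(x) max(abs(x - ideal))
  expect_gt(overshoot(I) / overshoot(A), 5)
})

test_that("direct-contrast filters are translation equivariant", {
  set.seed(6)
  n <- 64
  I <- 1 + 0.05 * blur2d(matrix(rnorm(n * n), n), 2)
  f <- fresnelPair(0.15)
  sh <- function(x) x[c(11:n, 1:10), c(5:n, 1:4)]
  expect_equal(sh(phaseValues(paganin(I, f, 0.05))),
               phaseValues(paganin(sh(I), f, 0.05)), tolerance = 1e-10)
  expect_equal(sh(phaseValues(generalizedPaganin(I, f, 0.05))),
               phaseValues(generalizedPaganin(sh(I), f, 0.05)),
               tolerance = 1e-10)
  expect_equal(sh(phaseValues(modifiedBronnikov(I, f))),
               phaseValues(modifiedBronnikov(sh(I), f)), tolerance = 1e-10)
  expect_equal(sh(bronnikovAidedCorrection(I, f)),
               bronnikovAidedCorrection(sh(I), f), tolerance = 1e-10)
})

test_that("Paganin output is non-positive for smooth sub-unity holograms", {
  set.seed(7)
  n <- 64
  I <- 1 - 0.2 * abs(blur2d(matrix(rnorm(n * n), n), 5))
  I <- I / max(I)                      # I <= 1, low-pass content
  rec <- phaseValues(paganin(I, fresnelPair(0.1), 0.05))
  expect_lte(max(rec), 1e-6)
})

test_that("generalized Paganin converges to classic under grid refinement", {
  # halving the pixel size twice: the discrepancy drops ~4x per step
  B <- 0.05
  disc <- function(n, Fpix) {
    d <- diskProjection(n, n / 4)
    phi <- blur2d(-0.3 * d / max(d), n / 32)
    h <- simulateHolograms(phi, simulationRecipe(fresnel = list(Fpix),
                                                 bRatio = B, photonCount = Inf))
    I <- holoImages(h)[[1]]
    relErr(phaseValues(generalizedPaganin(I, fresnelPair(Fpix), B)),
           phaseValues(paganin(I, fresnelPair(Fpix), B)))
  }
  # same physical setup: pixel halves => F quadruples with n doubling
  d1 <- disc(32, 0.05)
  d2 <- disc(64, 0.2)
  d3 <- disc(128, 0.8)
  expect_gt(d1 / d2, 3)
  expect_gt(d2 / d3, 3)
})
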