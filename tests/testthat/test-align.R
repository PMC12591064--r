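test_that("registration recovers integer and subpixel shifts", {
  set.seed(61)
  n <- 64
  a <- blur2d(matrix(rnorm(n * n), n), 2)
  # identical images
  expect_equal(registerTranslation(a, a)$shift, c(0, 0))
  # known subpixel shift: b(x) = a(x - s) means registration returns -s
  b <- cyclicShift(a, 2.25, -0.75)
  r <- registerTranslation(a, b, upsample = 100)
  expect_lt(max(abs(r$shift - c(-2.25, 0.75))), 0.01)
  # integer cyclic shift, exact at upsample 1
  b2 <- a[c(4:n, 1:3), c(60:n, 1:59)]
  expect_equal(registerTranslation(a, b2)$shift, c(3, -5))
  # antisymmetry
  r2 <- registerTranslation(b, a, upsample = 100)
  expect_lt(max(abs(r$shift + r2$shift)), 0.01)
  expect_error(registerTranslation(matrix(1, 8, 8), matrix(1, 8, 8)),
               class = "registrationFailure")
})

test_that("center of rotation is recovered from opposing projections", {
  ph <- sheppLogan3d(64, scale = 0.75)
  sl <- phantomValues(ph)
  # symmetric setup: offset 0
  g0 <- tomoGeometry(c(0, pi))
  p0 <- forwardProject(sl, g0)
  expect_lt(abs(findCorOpposing(p0[1, , ], p0[2, , ])), 0.05)
  # offset 7.3 px
  g7 <- tomoGeometry(c(0, pi), corOffset = 7.3)
  p7 <- forwardProject(sl, g7)
  cor1 <- findCorOpposing(p7[1, , ], p7[2, , ])
  expect_lt(abs(cor1 - 7.3), 0.1)
  # fixed point: compensating the estimated offset leaves < 0.05 px
  gc <- tomoGeometry(c(0, pi), corOffset = 7.3 - cor1)
  pc <- forwardProject(sl, gc)
  expect_lt(abs(findCorOpposing(pc[1, , ], pc[2, , ])), 0.05)
})

test_that("sinogram-based CoR averages over angles and sees axis tilt", {
  ph <- sheppLogan3d(64, scale = 0.75)
  vol <- phantomValues(ph)
  ang <- seq(0, 2 * pi, length.out = 181)[1:180]
  g <- tomoGeometry(ang, corOffset = 4)
  sino <- forwardProject(vol[32, , ], g)
  fc <- findCorSinogram(sino, ang)
  expect_lt(abs(fc$cor - 4), 0.1)
  expect_error(findCorSinogram(sino[1:60, ], ang[1:60]), "span")
  # per-projection jitter: the all-angle average beats a single pair
  set.seed(62)
  jit <- runif(180, -2, 2)
  sj <- sino
  for (a in 1:180) sj[a, ] <- holotomo:::.shift1d(sino[a, ], jit[a])
  fj <- findCorSinogram(sj, ang)
  # single-pair estimate from 1-D profiles of the same jittered data
  i0 <- 1; i180 <- which.min(abs(ang - pi))
  corPair <- findCorOpposing(rbind(sj[i0, ], sj[i0, ]),
                             rbind(sj[i180, ], sj[i180, ]))
  expect_lt(abs(fj$cor - 4), abs(corPair - 4))
  # two detector rows with a tilted axis: slope recovered within 20%
  tilt <- 0.01
  rows <- round(seq(16, 48, length.out = 6))
  stack <- array(0, dim = c(180, 64, 64))
  for (r in seq_along(rows)) {
    gr <- tomoGeometry(ang, corOffset = 4 + tan(tilt) * (rows[r] - 31.5))
    stack[, rows[r], ] <- forwardProject(vol[rows[r], , ], gr)
  }
  # non-sampled rows are empty; restrict the multi-row estimate to sampled
  cors <- vapply(rows, function(r)
    findCorSinogram(stack[, r, ], ang)$cor, numeric(1))
  fit <- stats::lm.fit(cbind(1, rows - 31.5), cors)
  expect_lt(abs(atan(fit$coefficients[2]) - tilt) / tilt, 0.2)
})

test_that("reprojection alignment recovers injected jitter", {
  set.seed(21)
  n <- 64; nAng <- 90
  ph <- sheppLogan3d(n, scale = 0.75)
  ang <- seq(0, pi, length.out = nAng + 1)[1:nAng]
  g0 <- tomoGeometry(ang)
  proj <- forwardProject(phantomValues(ph), g0)
  jit <- matrix(runif(2 * nAng, -10, 10), nAng, 2)
  pj <- proj
  for (a in 1:nAng)
    pj[a, , ] <- cyclicShift(proj[a, , ], jit[a, 2], jit[a, 1])
  # already-aligned data: converged at the first iteration
  gAligned <- reprojectionAlign(pj, tomoGeometry(ang, shifts = jit),
                                iterations = 5, binning = 4,
                                highpassSigma = 5)
  h0 <- attr(gAligned, "history")
  expect_equal(max(h0$iteration), 1)
  expect_lt(max(abs(h0[, c("du", "dv")])), 0.1 + 1e-9)
  # from scratch: residual well below a pixel, decreasing over iterations
  gA <- reprojectionAlign(pj, g0, iterations = 40, binning = 4,
                          highpassSigma = 5)
  expect_lt(gaugeFixedShiftRMS(tomoShifts(gA), jit, ang), 0.5)
  # error decreases (allowing plateaus) over the first iterations
  errs <- numeric(6)
  g <- g0
  for (it in 1:6) {
    g <- reprojectionAlign(pj, g, iterations = 1, binning = 4,
                           highpassSigma = 5)
    errs[it] <- gaugeFixedShiftRMS(tomoShifts(g), jit, ang)
  }
  expect_true(all(diff(errs) <= 0.05))
})

test_that("additive ring removal deletes isolated stripes, spares smooth data", {
  # isolated column offset on a flat sinogram: removed exactly
  S <- matrix(1, 90, 128)
  Ss <- S; Ss[, 40] <- Ss[, 40] + 0.7
  expect_lt(max(abs(removeRingsAdditive(Ss, 31) - S)), 1e-6)
  # zero sinogram stays zero
  expect_equal(removeRingsAdditive(matrix(0, 45, 64)), matrix(0, 45, 64))
  expect_error(removeRingsAdditive(S, 4), "odd")
  # stripe-free smooth sinogram barely changes
  n <- 128; g <- seq_len(n) - (n + 1) / 2
  blob <- exp(-(outer((g - 15)^2, rep(1, n)) +
                  outer(rep(1, n), (g + 20)^2)) / (2 * 16^2))
  ang <- seq(0, pi, length.out = 91)[1:90]
  sino <- forwardProject(blob, tomoGeometry(ang))
  out <- removeRingsAdditive(sino, 31)
  expect_lt(sqrt(mean((out - sino)^2)) / diff(range(sino)), 0.02)
})

test_that("wavelet-FFT ring removal suppresses stripes with low distortion", {
  n <- 128; g <- seq_len(n) - (n + 1) / 2
  blob <- exp(-(outer((g - 15)^2, rep(1, n)) +
                  outer(rep(1, n), (g + 20)^2)) / (2 * 12^2))
  ang <- seq(0, pi, length.out = 181)[1:180]
  sino <- forwardProject(blob, tomoGeometry(ang))
  amp <- 0.1 * diff(range(sino))
  st <- sino; st[, 40] <- st[, 40] + amp
  f <- removeRingsWavelet(st, levels = 4, sigma = 1)
  clean <- removeRingsWavelet(sino, levels = 4, sigma = 1)
  resid <- abs(mean(f[, 40] - clean[, 40]))
  expect_gt(amp / resid, 5)
  # stripe-free distortion < 2% of dynamic range
  expect_lt(sqrt(mean((clean - sino)^2)) / diff(range(sino)), 0.02)
  # sigma -> 0 limit: the damping factor is the identity on every detail
  # coefficient except exact zero angular frequency, so applying the filter
  # twice changes nothing more than applying it once
  tiny1 <- removeRingsWavelet(st, levels = 2, sigma = 1e-9)
  tiny2 <- removeRingsWavelet(tiny1, levels = 2, sigma = 1e-9)
  expect_lt(max(abs(tiny2 - tiny1)) / diff(range(st)), 1e-10)
})

test_that("the wavelet transform reconstructs perfectly", {
  set.seed(63)
  for (wav in c("haar", "db2", "db5")) {
    X <- matrix(rnorm(64 * 96), 64)
    w <- holotomo:::.dwt2(X, 3, wav)
    expect_lt(max(abs(holotomo:::.idwt2(w) - X)), 1e-10)
  }
  expect_error(holotomo:::.getFilters("sym4"), "unknown wavelet")
})
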