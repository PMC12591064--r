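# Fixture builders shared across the suite. All fixtures are generated in
# code; seeds are fixed by the calling tests.

# holographic kernels at deep Fresnel numbers are aliased by construction;
# the package warns once per session, which is noise in a test run
suppressWarnings(
  fresnelPropagate(matrix(1 + 0i, 4, 4), fresnelPair(2.44e-4))
)

relErr <- function(x, ref) {
  sqrt(sum((x - ref)^2)) / sqrt(sum(ref^2))
}

# centered Gaussian blob phase map, phi <= 0, peak -amp
gaussBlobPhase <- function(n, amp, sigma) {
  g <- seq_len(n) - (n + 1) / 2
  -amp * exp(-outer(g^2, g^2, `+`) / (2 * sigma^2))
}

# two-blob asymmetric phase map (less symmetric than a single blob)
twoBlobPhase <- function(n, amp, sigma) {
  g <- seq_len(n) - (n + 1) / 2
  b1 <- exp(-outer(g^2, g^2, `+`) / (2 * sigma^2))
  b2 <- 0.5 * exp(-(outer((g - n / 6)^2, (g + n / 5)^2, `+`)) / (2 * (sigma / 2)^2))
  -amp * (b1 + b2) / max(b1 + b2)
}

# 2-D Gaussian blur along the first (row) axis only, periodic
blurRows <- function(x, sigma) {
  nu <- frequencyGrid(nrow(x))
  k <- exp(-2 * pi^2 * sigma^2 * nu^2)
  Re(stats::mvfft(stats::mvfft(x) * k, inverse = TRUE)) / nrow(x)
}

# isotropic periodic Gaussian blur of a matrix
blur2d <- function(x, sigma) t(blurRows(t(blurRows(x, sigma)), sigma))

# band-limited phantom: Gaussian sigma (separable, all three axes)
blurPhantom <- function(ph, sigma = 1) {
  v <- phantomValues(ph)
  n <- dim(v)[1]
  for (z in seq_len(n)) v[z, , ] <- blur2d(v[z, , ], sigma)
  for (y in seq_len(n)) v[, y, ] <- blurRows(v[, y, ], sigma)
  v[v < 0] <- 0
  new("Phantom", values = v, bRatio = 0)
}

# cyclic shift of a matrix by (dy, dx) via the Fourier shift theorem
cyclicShift <- function(x, dy, dx) {
  ny <- nrow(x); nx <- ncol(x)
  ph <- exp(-2i * pi * (outer(frequencyGrid(ny) * dy, rep(1, nx)) +
                        outer(rep(1, ny), frequencyGrid(nx) * dx)))
  Re(stats::fft(stats::fft(x) * ph, inverse = TRUE)) / length(x)
}

# horizontal-shift gauge of tomographic alignment: component expressible as
# a + b cos(theta) + c sin(theta) (du) and a constant (dv) is unobservable
gaugeFixedShiftRMS <- function(estimated, truth, angles) {
  r <- estimated - truth
  X <- cbind(1, cos(angles), sin(angles))
  ru <- r[, 1] - X %*% qr.solve(X, r[, 1])
  rv <- r[, 2] - mean(r[, 2])
  sqrt(mean(c(ru^2, rv^2)))
}

# antialiased disk slice (partial-volume edge), for projector oracles
aaDisk <- function(n, R) {
  g <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(g^2, g^2, `+`))
  pmin(pmax(R - r + 0.5, 0), 1)
}
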