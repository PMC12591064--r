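# Minimal orthonormal discrete wavelet transform (periodic boundaries) used
# by the wavelet-FFT ring filter. Only what the filter needs: multilevel 2-D
# analysis/synthesis with Daubechies filters. The periodized orthonormal
# filter bank is orthogonal for any even length, so synthesis is the exact
# transpose of analysis (perfect reconstruction, asserted in the tests).

# Daubechies scaling (lowpass) filters; standard published coefficients.
.waveletFilters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db5 = c(3.3357252854737712e-03, -1.2580751999081999e-02,
          -6.2414902127982744e-03, 7.7571493840045719e-02,
          -3.2244869584638375e-02, -2.4229488706638203e-01,
          1.3842814590132074e-01, 7.2430852843777294e-01,
          6.0382926979718965e-01, 1.6010239797419293e-01))

.qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

.getFilters <- function(wavelet) {
  h <- .waveletFilters[[wavelet]]
  if (is.null(h)) stop("unknown wavelet: ", wavelet,
                       " (available: ", paste(names(.waveletFilters),
                                              collapse = ", "), ")")
  list(lo = h, hi = .qmf(h))
}

# One analysis level along the rows of X (length must be even):
# a[k, ] = sum_n lo[n] X[(2k + n - 1) mod N + 1, ], similarly d with hi.
.dwtRows <- function(X, f) {
  N <- nrow(X)
  K <- N / 2
  a <- matrix(0, K, ncol(X))
  d <- matrix(0, K, ncol(X))
  base <- 2 * (seq_len(K) - 1)
  for (n in seq_along(f$lo)) {
    idx <- (base + n - 1) %% N + 1
    a <- a + f$lo[n] * X[idx, , drop = FALSE]
    d <- d + f$hi[n] * X[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

# transpose of .dwtRows (synthesis; exact inverse for orthonormal filters)
.idwtRows <- function(a, d, f) {
  K <- nrow(a)
  N <- 2 * K
  X <- matrix(0, N, ncol(a))
  base <- 2 * (seq_len(K) - 1)
  for (n in seq_along(f$lo)) {
    idx <- (base + n - 1) %% N + 1
    acc <- f$lo[n] * a + f$hi[n] * d
    X[idx, ] <- X[idx, ] + acc
  }
  X
}

# Multilevel 2-D analysis. Returns list(LL = coarse, detail = list per level
# of list(LH, HL, HH)); band names give (row filter, column filter), rows
# being the first image axis. Axis lengths must be divisible by 2^levels.
.dwt2 <- function(X, levels, wavelet = "db5") {
  f <- .getFilters(wavelet)
  detail <- vector("list", levels)
  for (l in seq_len(levels)) {
    if (nrow(X) %% 2 || ncol(X) %% 2)
      stop("image axes must be divisible by 2^levels")
    r <- .dwtRows(X, f)
    aa <- .dwtRows(t(r$a), f)   # columns of the row-lowpass part
    dd <- .dwtRows(t(r$d), f)
    detail[[l]] <- list(LH = t(aa$d),  # row-low, col-high
                        HL = t(dd$a),  # row-high, col-low
                        HH = t(dd$d))
    X <- t(aa$a)
  }
  list(LL = X, detail = detail, wavelet = wavelet)
}

.idwt2 <- function(w) {
  f <- .getFilters(w$wavelet)
  X <- w$LL
  for (l in rev(seq_along(w$detail))) {
    b <- w$detail[[l]]
    ra <- t(.idwtRows(t(X), t(b$LH), f))
    rd <- t(.idwtRows(t(b$HL), t(b$HH), f))
    X <- .idwtRows(ra, rd, f)
  }
  X
}
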