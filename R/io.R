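# Stack I/O and the pipeline driver. Stacks travel as uncompressed
# little-endian 32-bit float multi-page TIFF (SampleFormat = IEEE float), a
# format every imaging toolchain reads; the reader/writer below covers
# exactly that profile.

.tiffTag <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  writeBin(as.integer(value), con, size = 4, endian = "little")
}

#' Write an image stack as 32-bit float TIFF
#'
#' Multi-page, uncompressed, little-endian, IEEE-float TIFF. Values round
#' trip bit-exactly at float32 precision through [readStack()].
#'
#' @param stack a matrix, a list of equal-shape matrices, or a 3-D array
#'   (page, row, column).
#' @param path output file path (parent directory must exist).
#' @return Invisibly, the path.
#' @export
writeStack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[1]), function(i) stack[i, , ])
  if (!length(stack)) stop("empty stack")
  d <- dim(stack[[1]])
  for (im in stack)
    if (!identical(dim(im), d)) stop("all pages must share one shape")
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  nbytes <- 4 * prod(d)
  npages <- length(stack)
  # layout per page: pixel data then IFD (12 entries); header points at the
  # first IFD, each IFD chains to the next
  dataOff <- function(p) 8 + (p - 1) * (nbytes + 2 + 12 * 12 + 4)
  ifdOff <- function(p) dataOff(p) + nbytes
  writeBin(as.integer(ifdOff(1)), con, size = 4, endian = "little")
  for (p in seq_len(npages)) {
    # TIFF stores rows sequentially (row-major)
    writeBin(as.numeric(t(stack[[p]])), con, size = 4, endian = "little")
    writeBin(12L, con, size = 2, endian = "little")
    .tiffTag(con, 256, 4, 1, d[2])            # ImageWidth
    .tiffTag(con, 257, 4, 1, d[1])            # ImageLength
    .tiffTag(con, 258, 3, 1, 32)              # BitsPerSample
    .tiffTag(con, 259, 3, 1, 1)               # Compression: none
    .tiffTag(con, 262, 3, 1, 1)               # Photometric: black is zero
    .tiffTag(con, 273, 4, 1, dataOff(p))      # StripOffsets
    .tiffTag(con, 277, 3, 1, 1)               # SamplesPerPixel
    .tiffTag(con, 278, 4, 1, d[1])            # RowsPerStrip
    .tiffTag(con, 279, 4, 1, nbytes)          # StripByteCounts
    .tiffTag(con, 282, 3, 1, 1)               # XResolution (dummy, SHORT)
    .tiffTag(con, 283, 3, 1, 1)               # YResolution (dummy, SHORT)
    .tiffTag(con, 339, 3, 1, 3)               # SampleFormat: IEEE float
    nxt <- if (p < npages) ifdOff(p + 1) else 0
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a 32-bit float TIFF stack
#'
#' Reads the profile [writeStack()] writes (uncompressed little-endian
#' float32, one sample per pixel); strip layout is honoured, so float TIFFs
#' from other tools in that profile load too.
#'
#' @param path file path.
#' @return A 3-D array (page, row, column); single-page files give a
#'   1 x rows x columns array.
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II")
    stop("not a little-endian TIFF: ", path)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (u16(2) != 42) stop("not a TIFF: ", path)
  off <- u32(4)
  pages <- list()
  while (off != 0) {
    nent <- u16(off)
    tags <- list()
    for (i in seq_len(nent)) {
      base <- off + 2 + (i - 1) * 12
      tags[[as.character(u16(base))]] <-
        list(type = u16(base + 2), count = u32(base + 4),
             value = u32(base + 8),
             value16 = u16(base + 8), valOff = base + 8)
    }
    tv <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(NULL)
      if (t$type == 3) t$value16 else t$value
    }
    w <- tv(256); h <- tv(257)
    if (is.null(w) || is.null(h)) stop("malformed TIFF page")
    if (!identical(tv(259), 1)) stop("compressed TIFF not supported")
    if (!identical(tv(258), 32) || !identical(tv(339), 3))
      stop("only 32-bit float TIFF supported")
    # strip offsets/counts may be inline (count 1) or in an offset array
    readArr <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (t$count == 1) return(if (t$type == 3) t$value16 else t$value)
      sz <- if (t$type == 3) 2 else 4
      vapply(seq_len(t$count), function(k)
        if (sz == 2) u16(t$value + (k - 1) * 2) else u32(t$value + (k - 1) * 4),
        numeric(1))
    }
    offs <- readArr(273)
    cnts <- readArr(279)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seg <- raw[offs[s] + seq_len(cnts[s])]
      vals <- c(vals, readBin(seg, "numeric", cnts[s] / 4, size = 4,
                              endian = "little"))
    }
    if (length(vals) != w * h) stop("pixel count mismatch in TIFF page")
    pages[[length(pages) + 1]] <- matrix(vals, h, w, byrow = TRUE)
    off <- u32(off + 2 + nent * 12)
  }
  out <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (p in seq_along(pages)) out[p, , ] <- pages[[p]]
  out
}

# ---- run configuration ------------------------------------------------------

.configKeys <- list(
  top = c("seed", "simulate", "retrieve", "align", "rings", "reconstruct",
          "io", "geometry"),
  geometry = c("z01_mm", "z02_mm", "det_pixel_um", "energy_keV",
               "fresnel_x", "fresnel_y"),
  simulate = c("phantom", "n", "angles", "scale", "fresnel", "betadelta",
               "photons", "jitter", "phi_max"),
  retrieve = c("method", "fresnel", "betadelta", "alpha", "alpha_low",
               "alpha_high", "nonpositive", "support_radius", "iters",
               "tau", "epsilon", "gamma"),
  align = c("cor", "reproject", "iters", "binning", "highpass", "damping"),
  rings = c("method", "levels", "sigma", "smooth_width", "wavelet"),
  reconstruct = c("algorithm", "filter", "iterations"),
  io = c("out_dir", "volume", "report"))

.configError <- function(message) {
  stop(structure(class = c("configError", "error", "condition"),
                 list(message = message, call = NULL)))
}

.checkKeys <- function(block, name) {
  allowed <- .configKeys[[name]]
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    .configError(paste0("unknown key(s) in ", name, ": ",
                        paste(bad, collapse = ", ")))
  block
}

#' Read and validate a pipeline configuration
#'
#' YAML with blocks \code{simulate}, \code{retrieve}, \code{align},
#' \code{rings}, \code{reconstruct}, \code{io}, optional \code{geometry}
#' (either physical \code{z01_mm}/\code{z02_mm}/\code{det_pixel_um}/
#' \code{energy_keV} or direct \code{fresnel_x}/\code{fresnel_y}), plus a
#' top-level \code{seed}. Unknown keys are rejected.
#'
#' @param path YAML file path, or a list already parsed.
#' @return Validated config list (class \code{"runConfig"}).
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  .checkKeys(cfg, "top")
  for (b in intersect(names(cfg), names(.configKeys)))
    if (b != "top" && is.list(cfg[[b]])) .checkKeys(cfg[[b]], b)
  if (!is.null(cfg$retrieve$method) &&
      !cfg$retrieve$method %in% c("ctf", "ctf-constrained", "tikhonov",
                                  "tikhonov-tv", "ap", "paganin", "gpaganin",
                                  "mbronnikov", "bac"))
    .configError(paste("unknown retrieval method:", cfg$retrieve$method))
  structure(cfg, class = "runConfig")
}

# dispatch a single-projection retrieval by method name
.retrieveByMethod <- function(method, h, cfg) {
  B <- cfg$betadelta %||% 0.035
  profile <- regularizationProfile(cfg$alpha_low %||% 2e-5,
                                   cfg$alpha_high %||% 3e-5)
  cons <- phaseConstraints(nonpositive = isTRUE(cfg$nonpositive))
  iters <- cfg$iters %||% 30
  switch(method,
    "ctf" = ctfRetrieve(h, B, profile),
    "ctf-constrained" = ctfConstrained(h, B, profile, cons, maxIter = iters),
    "tikhonov" = tikhonovRetrieve(h, B, profile, cons, maxIter = iters),
    "tikhonov-tv" = tikhonovTV(h, B, profile, cons, tau = cfg$tau %||% 1e-3,
                               epsilon = cfg$epsilon %||% 1e-2,
                               maxIter = iters),
    "ap" = alternatingProjections(h, B, cons, maxIter = iters),
    "paganin" = paganin(holoImages(h)[[1]], holoFresnel(h)[[1]], B),
    "gpaganin" = generalizedPaganin(holoImages(h)[[1]], holoFresnel(h)[[1]], B),
    "mbronnikov" = modifiedBronnikov(holoImages(h)[[1]], holoFresnel(h)[[1]],
                                     cfg$alpha %||% 1e-3),
    "bac" = bronnikovAidedCorrection(holoImages(h)[[1]], holoFresnel(h)[[1]],
                                     cfg$alpha %||% 1e-3,
                                     cfg$gamma %||% 1),
    stop("unknown method: ", method))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate -> retrieve -> align -> rings -> reconstruct pipeline
#'
#' Executes the configured stages and writes the reconstructed volume
#' (float TIFF) plus a machine-readable JSON report (config digest, seed,
#' per-stage timings, and quality metrics including the phantom correlation
#' when ground truth is available).
#'
#' @param config a \code{runConfig} (see [readRunConfig()]) or a path to one.
#' @param outDir output directory (created if missing); overrides
#'   \code{io$out_dir}.
#' @return The report, invisibly (list).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) || (is.list(config) && !inherits(config, "runConfig")))
    config <- readRunConfig(config)
  outDir <- outDir %||% config$io$out_dir %||% tempfile("holotomo-run-")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  report <- list(config_digest = .digest(unclass(config)), seed = seed,
                 timings = list(), metrics = list())
  tic <- function() proc.time()[["elapsed"]]
  # --- simulate ---
  t0 <- tic()
  sc <- config$simulate
  if (is.null(sc)) .configError("pipeline currently requires a simulate block")
  n <- sc$n %||% 64
  nAng <- sc$angles %||% ceiling(pi / 2 * n / 2) * 2
  phantom <- switch(sc$phantom %||% "shepp-logan",
    "shepp-logan" = sheppLogan3d(n, scale = sc$scale %||% 0.8),
    "ball" = ballPhantom(n, radius = n * 0.3),
    .configError(paste("unknown phantom:", sc$phantom)))
  fres <- sc$fresnel %||% list(2.44e-4, 1.98e-4)
  if (!is.list(fres)) fres <- as.list(fres)
  recipe <- simulationRecipe(fresnel = fres,
                             bRatio = sc$betadelta %||% 0.035,
                             photonCount = sc$photons %||% 1e4,
                             jitterAmplitude = sc$jitter %||% 0,
                             phiMax = sc$phi_max %||% 0.3, seed = seed)
  g0 <- tomoGeometry(seq(0, pi, length.out = nAng + 1)[seq_len(nAng)])
  sim <- simulateHolograms(phantom, recipe, g0)
  report$timings$simulate <- tic() - t0
  # --- retrieve ---
  t0 <- tic()
  method <- config$retrieve$method %||% "ctf"
  na <- length(tomoAngles(g0))
  phase <- array(0, dim = dim(sim$holograms[[1]]))
  for (a in seq_len(na)) {
    h <- hologramStack(lapply(sim$holograms, function(s) s[a, , ]),
                       recipe$fresnel)
    pm <- .retrieveByMethod(method, h, config$retrieve %||% list())
    phase[a, , ] <- phaseValues(pm)
  }
  report$timings$retrieve <- tic() - t0
  # --- align ---
  t0 <- tic()
  geom <- g0
  ac <- config$align
  if (!is.null(ac)) {
    if (identical(ac$cor, "opposing") && max(tomoAngles(g0)) < pi) {
      # opposing pair unavailable in [0, pi) scans: skip with zero offset
    }
    if (isTRUE(ac$reproject)) {
      geom <- reprojectionAlign(phase, geom,
                                iterations = ac$iters %||% 30,
                                binning = ac$binning %||% 4,
                                highpassSigma = ac$highpass %||%
                                  (40 / (ac$binning %||% 4)),
                                damping = ac$damping %||% 1)
      resid <- geom@shifts - sim$shifts
      resid <- sweep(resid, 2, colMeans(resid))  # global offset is gauge
      report$metrics$shift_rms_residual_px <- sqrt(mean(resid^2))
    }
  }
  report$timings$align <- tic() - t0
  # --- rings ---
  t0 <- tic()
  rc <- config$rings
  if (!is.null(rc)) {
    for (v in seq_len(dim(phase)[2])) {
      phase[, v, ] <- switch(rc$method %||% "wavelet",
        "wavelet" = removeRingsWavelet(phase[, v, ],
                                       levels = rc$levels %||% 4,
                                       sigma = rc$sigma %||% 1,
                                       wavelet = rc$wavelet %||% "db5"),
        "additive" = removeRingsAdditive(phase[, v, ],
                                         smoothWidth = rc$smooth_width %||% 31),
        .configError(paste("unknown ring method:", rc$method)))
    }
  }
  report$timings$rings <- tic() - t0
  # --- reconstruct ---
  t0 <- tic()
  alg <- config$reconstruct$algorithm %||% "fbp"
  vol <- switch(alg,
    "fbp" = fbp(phase, geom, filter = config$reconstruct$filter %||% "ramlak"),
    "sirt" = sirt(phase, geom,
                  iterations = config$reconstruct$iterations %||% 50),
    .configError(paste("unknown reconstruction algorithm:", alg)))
  report$timings$reconstruct <- tic() - t0
  # phase projections are negative line integrals of delta: flip sign
  truth <- phantomValues(phantom)
  sl <- dim(vol)[1] %/% 2
  report$metrics$phantom_correlation <-
    stats::cor(as.vector(-vol[sl, , ]), as.vector(truth[sl, , ]))
  volPath <- file.path(outDir, config$io$volume %||% "volume.tif")
  writeStack(vol, volPath)
  repPath <- file.path(outDir, config$io$report %||% "report.json")
  jsonlite::write_json(report, repPath, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

# tiny stable digest (polynomial rolling hash over the serialized object)
# for run provenance
.digest <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
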