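# Synthetic-data generation: digital phantoms, hologram simulation through
# the package's own Fresnel propagator, photon noise and trajectory jitter.
# The simulator is the fixture generator for the whole test-suite: its
# defaults mirror a deeply holographic two-distance acquisition (Fresnel
# numbers 2.44e-4 / 1.98e-4, beta/delta 0.035).

# Modified Shepp-Logan ellipsoid table: value, semi-axes (a, b, c) along
# (x, y, z), center (x0, y0, z0), rotation phi about z (degrees).
.sheppLoganTable <- matrix(c(
   1.0, 0.6900, 0.9200, 0.810,  0.00,  0.000,  0.00,   0,
  -0.8, 0.6624, 0.8740, 0.780,  0.00, -0.0184, 0.00,   0,
  -0.2, 0.1100, 0.3100, 0.220,  0.22,  0.000,  0.00, -18,
  -0.2, 0.1600, 0.4100, 0.280, -0.22,  0.000,  0.00,  18,
   0.1, 0.2100, 0.2500, 0.410,  0.00,  0.350, -0.15,   0,
   0.1, 0.0460, 0.0460, 0.050,  0.00,  0.100,  0.25,   0,
   0.1, 0.0460, 0.0460, 0.050,  0.00, -0.100,  0.25,   0,
   0.1, 0.0460, 0.0230, 0.050, -0.08, -0.605,  0.00,   0,
   0.1, 0.0230, 0.0230, 0.020,  0.00, -0.606,  0.00,   0,
   0.1, 0.0230, 0.0460, 0.020,  0.06, -0.605,  0.00,   0),
  ncol = 8, byrow = TRUE)

#' 3-D Shepp-Logan phantom
#'
#' The standard ten-ellipsoid head phantom (modified contrast variant,
#' values in [0, 1]) evaluated on an n^3 grid. The model is resolution
#' independent: a voxel's value depends only on its normalized coordinate.
#'
#' @param n grid size per axis (>= 16).
#' @param scale coordinate scale factor <= 1; values < 1 shrink the phantom
#'   inside the grid, leaving a margin (useful when projections will be
#'   shifted).
#' @return A [Phantom-class] with values array (z, y, x).
#' @export
sheppLogan3d <- function(n, scale = 1) {
  if (n < 16) stop("n must be >= 16")
  g <- (seq_len(n) - (n + 1) / 2) / (n / 2) / scale
  vol <- array(0, dim = c(n, n, n))
  x <- rep(g, each = n)            # within-slice (y, x) grid, y fastest
  y <- rep(g, times = n)
  for (e in seq_len(nrow(.sheppLoganTable))) {
    p <- .sheppLoganTable[e, ]
    phi <- p[8] * pi / 180
    xr <- (x - p[5]) * cos(phi) + (y - p[6]) * sin(phi)
    yr <- -(x - p[5]) * sin(phi) + (y - p[6]) * cos(phi)
    inplane <- (xr / p[2])^2 + (yr / p[3])^2   # length n^2 (y, x)
    for (iz in seq_len(n)) {
      zr <- (g[iz] - p[7]) / p[4]
      if (abs(zr) <= 1) {
        inside <- inplane <= 1 - zr^2
        if (any(inside))
          vol[iz, , ][inside] <- vol[iz, , ][inside] + p[1]
      }
    }
  }
  vol[vol < 0] <- 0
  new("Phantom", values = vol, bRatio = 0)
}

#' Uniform ball phantom
#'
#' @param n grid size per axis.
#' @param radius ball radius in voxels.
#' @param value voxel value inside the ball (default 1).
#' @return A [Phantom-class]; its parallel projection has the closed form
#'   \eqn{2 v \sqrt{R^2 - r^2}}, handy as an analytic oracle.
#' @export
ballPhantom <- function(n, radius, value = 1) {
  c0 <- (n + 1) / 2
  g <- seq_len(n) - c0
  vol <- array(0, dim = c(n, n, n))
  r2p <- outer(g^2, g^2, `+`)      # (y, x) plane distances
  for (iz in seq_len(n)) {
    d2 <- radius^2 - g[iz]^2
    if (d2 > 0) vol[iz, , ][r2p <= d2] <- value
  }
  new("Phantom", values = vol, bRatio = 0)
}

#' Analytic disk (projected ball) phase map
#'
#' The parallel projection of a uniform ball: \eqn{2 v \sqrt{R^2 - r^2}}
#' inside radius R, 0 outside, on an n x n pixel grid.
#'
#' @param n image size.
#' @param radius disk radius in pixels.
#' @param value volume density (projection max is \code{2 * radius * value}).
#' @return Numeric matrix.
#' @export
diskProjection <- function(n, radius, value = 1) {
  c0 <- (n + 1) / 2
  g <- seq_len(n) - c0
  r2 <- outer(g^2, g^2, `+`)
  m <- matrix(0, n, n)
  inside <- r2 <= radius^2
  m[inside] <- 2 * value * sqrt(radius^2 - r2[inside])
  m
}

#' Simulation recipe
#'
#' Bundles the acquisition conditions of a simulated experiment. Defaults
#' follow a deeply holographic two-distance scan: Fresnel numbers 2.44e-4 and
#' 1.98e-4 (already rescaled to the common pixel grid), beta/delta 0.035, a
#' photon budget of 1e4 counts per pixel, no jitter, and a peak phase shift
#' of 0.3 rad (within the weak-object validity domain of linear CTF
#' retrieval).
#'
#' @param fresnel list of [FresnelPair-class] (or numerics), one per distance.
#' @param bRatio beta/delta ratio (>= 0).
#' @param photonCount Poisson scale in counts/pixel; \code{Inf} = noiseless.
#' @param jitterAmplitude per-projection rigid shift amplitude in pixels
#'   (uniform in +/- amplitude, both axes).
#' @param phiMax peak |phase| in radians the projections are scaled to.
#' @param seed RNG seed; a fixed seed makes outputs bit-reproducible.
#' @return A list of class \code{"simulationRecipe"}.
#' @export
simulationRecipe <- function(fresnel = list(2.44e-4, 1.98e-4),
                             bRatio = 0.035, photonCount = 1e4,
                             jitterAmplitude = 0, phiMax = 0.3, seed = 1) {
  if (!is.list(fresnel)) fresnel <- list(fresnel)
  fresnel <- lapply(fresnel, .asFresnel)
  if (!(photonCount > 0)) stop("photonCount must be > 0 (Inf = noiseless)")
  structure(list(fresnel = fresnel, bRatio = bRatio,
                 photonCount = photonCount,
                 jitterAmplitude = jitterAmplitude,
                 phiMax = phiMax, seed = seed),
            class = "simulationRecipe")
}

.poissonize <- function(I, photons) {
  if (!is.finite(photons)) return(I)
  n <- length(I)
  matrix(stats::rpois(n, as.vector(I) * photons) / photons,
         nrow(I), ncol(I))
}

#' Simulate holograms from a phase map or a phantom
#'
#' Forward chain: (project the phantom to line integrals and scale them to
#' peak phase \code{-phiMax}) -> transmission \eqn{e^{(B+i)\phi}} -> Fresnel
#' propagation to each distance -> intensity -> Poisson noise -> optional
#' per-projection rigid jitter (applied to the phase before propagation, as
#' sample movement).
#'
#' For a single phase map (matrix or [PhaseMap-class], used verbatim, no
#' rescaling) the result is a [HologramStack-class]. For a
#' [Phantom-class] plus [TomoGeometry-class] the result is a list with the
#' per-distance hologram stacks (arrays (angle, row, column)), the
#' jitter-free ground-truth phase maps, and the per-projection ground-truth
#' shifts.
#'
#' @param object a phase map (matrix/[PhaseMap-class]) or [Phantom-class].
#' @param recipe a [simulationRecipe()].
#' @param g a [TomoGeometry-class]; required for phantom input.
#' @return See details.
#' @export
simulateHolograms <- function(object, recipe = simulationRecipe(), g = NULL) {
  stopifnot(inherits(recipe, "simulationRecipe"))
  set.seed(recipe$seed)
  B <- recipe$bRatio
  if (is(object, "PhaseMap") || is.matrix(object)) {
    phi <- if (is(object, "PhaseMap")) phaseValues(object) else object
    imgs <- lapply(recipe$fresnel, function(f) {
      psi <- fresnelPropagate(exp((B + 1i) * phi), f, "forward")
      .poissonize(Mod(psi)^2, recipe$photonCount)
    })
    return(hologramStack(imgs, recipe$fresnel))
  }
  if (!is(object, "Phantom")) stop("object must be a phase map or Phantom")
  if (is.null(g)) stop("phantom simulation needs a TomoGeometry")
  proj <- forwardProject(object@values,
                         tomoGeometry(g@angles, corOffset = g@corOffset))
  mx <- max(proj)
  if (mx <= 0) stop("phantom projects to zero")
  phiStack <- -recipe$phiMax * proj / mx     # (angle, row, column), phi <= 0
  na <- dim(proj)[1]
  shifts <- if (recipe$jitterAmplitude > 0) {
    matrix(stats::runif(2 * na, -recipe$jitterAmplitude,
                        recipe$jitterAmplitude), na, 2)
  } else matrix(0, na, 2)
  colnames(shifts) <- c("du", "dv")
  holos <- lapply(recipe$fresnel, function(f)
    array(0, dim = dim(proj)))
  for (a in seq_len(na)) {
    phi <- phiStack[a, , ]
    if (any(shifts[a, ] != 0))
      phi <- fourierShift(phi, c(shifts[a, 2], shifts[a, 1]))
    T <- exp((B + 1i) * phi)
    for (d in seq_along(recipe$fresnel)) {
      psi <- fresnelPropagate(T, recipe$fresnel[[d]], "forward")
      holos[[d]][a, , ] <- .poissonize(Mod(psi)^2, recipe$photonCount)
    }
  }
  list(holograms = holos, phase = phiStack, shifts = shifts,
       geometry = g, recipe = recipe)
}
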