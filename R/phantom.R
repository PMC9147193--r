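# Synthetic multi-coil acquisition generator: piecewise-smooth ellipse
# phantoms (magnitude-image anatomy), smooth complex coil sensitivity
# profiles, additive complex Gaussian k-space noise, regular undersampling.
# Every derived test in the package consumes scenes from this module, so its
# defaults define the study conditions of the test suite.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so seeded
#' generators do not disturb the surrounding stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random ellipse phantom
#'
#' Superposition of `num_ellipses` randomly placed, sized, rotated and
#' weighted ellipses inside a fixed elliptical "skull" outline, clipped to
#' `[0, 1]`. Emulates a piecewise-smooth real-valued magnitude image (the
#' ground truth `x` of the acquisition model). Deterministic per seed.
#'
#' @param rows,cols Grid size (>= 16).
#' @param num_ellipses Number of random interior ellipses; 0 gives a zero image.
#' @param seed Integer seed.
#' @return Real matrix with values in `[0, 1]`.
#' @export
make_phantom <- function(rows, cols, num_ellipses = 8L, seed = 1L) {
  if (rows < 16L || cols < 16L) stop("phantom dims must be >= 16")
  if (num_ellipses == 0L) return(matrix(0, rows, cols))
  u <- matrix(rep(seq(-1, 1, length.out = cols), each = rows), rows, cols)
  v <- matrix(rep(seq(-1, 1, length.out = rows), times = cols), rows, cols)
  with_seed(seed, {
    img <- matrix(0, rows, cols)
    # enclosing outline, then random interior structure
    img <- img + 0.45 * ((u / 0.85)^2 + (v / 0.9)^2 <= 1)
    for (i in seq_len(num_ellipses)) {
      cx <- stats::runif(1, -0.45, 0.45)
      cy <- stats::runif(1, -0.45, 0.45)
      a <- stats::runif(1, 0.08, 0.4)
      b <- stats::runif(1, 0.08, 0.4)
      th <- stats::runif(1, 0, pi)
      w <- stats::runif(1, -0.4, 0.6)
      ur <- (u - cx) * cos(th) + (v - cy) * sin(th)
      vr <- -(u - cx) * sin(th) + (v - cy) * cos(th)
      img <- img + w * ((ur / a)^2 + (vr / b)^2 <= 1)
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Smooth synthetic coil sensitivity maps
#'
#' Complex Gaussian-bump magnitude profiles centered at equally spaced points
#' on a circle around the field of view, each with a smooth linear phase
#' ramp, normalized pixelwise so the root sum of squares is exactly 1
#' everywhere. With a single coil the magnitude is 1 everywhere.
#'
#' @param rows,cols Grid size.
#' @param num_coils Number of receiver coils (>= 1).
#' @param seed Integer seed (small jitter of centers/phases).
#' @return Complex `(rows, cols, num_coils)` array with pixelwise RSS 1.
#' @export
make_coil_maps <- function(rows, cols, num_coils, seed = 1L) {
  if (num_coils < 1L) stop("num_coils must be >= 1")
  u <- matrix(rep(seq(-1, 1, length.out = cols), each = rows), rows, cols)
  v <- matrix(rep(seq(-1, 1, length.out = rows), times = cols), rows, cols)
  with_seed(seed, {
    S <- array(0i, c(rows, cols, num_coils))
    for (cc in seq_len(num_coils)) {
      ang <- 2 * pi * (cc - 1) / num_coils + stats::runif(1, -0.1, 0.1)
      cx <- 1.3 * cos(ang)
      cy <- 1.3 * sin(ang)
      width <- stats::runif(1, 0.9, 1.1)
      mag <- exp(-((u - cx)^2 + (v - cy)^2) / (2 * width^2))
      ph <- stats::runif(1, -0.5, 0.5) * u + stats::runif(1, -0.5, 0.5) * v +
        stats::runif(1, -pi, pi)
      S[, , cc] <- mag * exp(1i * ph)
    }
    r <- rss_combine(S)
    S / as.vector(r)   # recycles over coils; bumps are positive so r > 0
  })
}

#' Synthetic acquisition scene
#'
#' Bundles the ground-truth image, true coil maps, noise level and mask
#' parameters that define one simulated acquisition; the record against which
#' parameter-recovery tests compare.
#'
#' @param rows,cols Grid size.
#' @param num_coils Number of coils.
#' @param acceleration,acs_fraction,offset Mask parameters
#'   (see [make_equispaced_mask()]).
#' @param noise_sigma Standard deviation of the complex Gaussian k-space
#'   noise per entry (variance `noise_sigma^2` split evenly between real and
#'   imaginary parts).
#' @param num_ellipses Phantom complexity.
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(rows = 64L, cols = 64L, num_coils = 4L,
                          acceleration = 4L, acs_fraction = 0.125,
                          offset = 0L, noise_sigma = 0, num_ellipses = 8L,
                          seed = 1L) {
  x <- make_phantom(rows, cols, num_ellipses, seed = seed)
  S <- make_coil_maps(rows, cols, num_coils, seed = seed + 1L)
  mask <- make_equispaced_mask(cols, acceleration, acs_fraction, offset)
  structure(
    list(x = x, maps = S, mask = mask, noise_sigma = noise_sigma, seed = seed,
         rows = as.integer(rows), cols = as.integer(cols),
         num_coils = as.integer(num_coils)),
    class = "phantom_scene")
}

#' Simulate a multi-coil acquisition
#'
#' Applies the acquisition model `y = M F S x + noise`: the ground-truth
#' image is weighted by the coil maps, Fourier transformed per coil,
#' corrupted by i.i.d. complex Gaussian noise of per-entry variance
#' `noise_sigma^2`, and undersampled with the scene's mask. The noise draw is
#' seeded by the scene, so simulation is reproducible.
#'
#' @param scene A [phantom_scene()].
#' @return List with `y` (undersampled k-space), `y_full` (fully sampled,
#'   noisy), `mask`, `x` (ground truth), and `maps` (true coil maps).
#' @export
simulate_acquisition <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  y_full <- fft2c(apply_maps(scene$maps, scene$x))
  if (scene$noise_sigma > 0) {
    n <- length(y_full)
    eps <- with_seed(scene$seed + 2L,
      complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2))
    y_full <- y_full + scene$noise_sigma * array(eps, dim(y_full))
  }
  list(y = apply_mask(y_full, scene$mask), y_full = y_full,
       mask = scene$mask, x = scene$x, maps = scene$maps)
}

#' Batch of simulated scenes
#'
#' Convenience generator for train/validation sets: `n` scenes with distinct
#' sub-seeds derived from `seed`, shared mask parameters.
#'
#' @inheritParams phantom_scene
#' @param n Number of scenes.
#' @return List of simulated samples, each a list with `y`, `mask`, `target`
#'   (the ground-truth image) and the generating `scene`.
#' @export
simulate_dataset <- function(n, rows = 64L, cols = 64L, num_coils = 4L,
                             acceleration = 4L, acs_fraction = 0.125,
                             noise_sigma = 0.005, seed = 1L) {
  lapply(seq_len(n), function(i) {
    sc <- phantom_scene(rows, cols, num_coils, acceleration, acs_fraction,
                        noise_sigma = noise_sigma, seed = seed + 101L * i)
    acq <- simulate_acquisition(sc)
    list(y = acq$y, mask = acq$mask, target = acq$x, scene = sc)
  })
}
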