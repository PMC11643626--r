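#' Parametric model of intracellular flow
#'
#' Describes the advection imposed on mobile puncta in a synthetic movie or
#' evaluated analytically on a grid. The supported regimes mirror the
#' qualitative behaviours seen in live hemocytes: centripetal (inward) flow,
#' circular flow in either sense, stalled (jitter-only) motion, uniform
#' translation and the exactly-zero field.
#'
#' The default centripetal speed profile is a linear ramp from 0 at the
#' cell center to `speed` at `cell_radius`, so the fastest radial motion
#' occurs near the cell margin. Pass a function `speed_profile(r)` for any
#' other radial dependence (e.g. a constant).
#'
#' @param kind one of `"centripetal"`, `"circular_cw"`, `"circular_ccw"`,
#'   `"stalled"`, `"uniform_translation"`, `"zero"`.
#' @param center cell center `(x, y)` in pixels.
#' @param speed characteristic speed in px/frame (`>= 0`). For the ramp
#'   profile this is the speed reached at `cell_radius`; for
#'   `uniform_translation` the magnitude of `direction` after scaling.
#' @param cell_radius cell radius in px used by the ramp profile and by
#'   movie generation to place particles.
#' @param speed_profile optional function of radius (px) returning speed in
#'   px/frame; overrides the default ramp.
#' @param jitter_sd isotropic Gaussian positional jitter, px/frame sd,
#'   added to every mobile particle on top of the deterministic update.
#' @param direction unit direction for `uniform_translation`.
#'
#' @return An object of class `flow_model`.
#' @export
flow_model <- function(kind = c("centripetal", "circular_cw", "circular_ccw",
                                "stalled", "uniform_translation", "zero"),
                       center = c(0, 0), speed = 0.5, cell_radius = 100,
                       speed_profile = NULL, jitter_sd = 0,
                       direction = c(1, 0)) {
  kind <- match.arg(kind)
  if (speed < 0) stop("`speed` must be >= 0")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  if (cell_radius <= 0) stop("`cell_radius` must be > 0")
  if (is.null(speed_profile))
    speed_profile <- function(r) speed * pmin(r / cell_radius, 1)
  structure(list(kind = kind, center = center, speed = speed,
                 cell_radius = cell_radius, speed_profile = speed_profile,
                 jitter_sd = jitter_sd,
                 direction = direction / sqrt(sum(direction^2))),
            class = "flow_model")
}

# Deterministic per-frame displacement (px/frame) of the model at (x, y).
# Returns a list(vx, vy); vectorized over positions.
model_velocity <- function(model, x, y) {
  dx <- x - model$center[1]
  dy <- y - model$center[2]
  r <- sqrt(dx^2 + dy^2)
  ux <- ifelse(r > 0, dx / r, 0)
  uy <- ifelse(r > 0, dy / r, 0)
  s <- model$speed_profile(r)
  switch(model$kind,
    centripetal = list(vx = -s * ux, vy = -s * uy),
    # ccw is counter-clockwise in (x, y) coordinates: at angle theta the
    # tangent is (-sin, +cos)
    circular_ccw = list(vx = -s * uy, vy = s * ux),
    circular_cw = list(vx = s * uy, vy = -s * ux),
    stalled = list(vx = 0 * x, vy = 0 * y),
    uniform_translation = list(vx = rep(model$speed * model$direction[1], length(x)),
                               vy = rep(model$speed * model$direction[2], length(x))),
    zero = list(vx = 0 * x, vy = 0 * y),
    stop("unknown flow model kind: ", model$kind)
  )
}

#' Evaluate a flow model as a noiseless vector field on a grid
#'
#' Serves as the analytic oracle for the flow-quantification stage: a pure
#' inward field must give a radial component of `-speed` and a direction
#' offset of 180 degrees everywhere, a circular field a direction offset of
#' +/-90 degrees.
#'
#' @param model a [flow_model()].
#' @param grid `(nx, ny)` number of grid points along x and y.
#' @param extent `(width, height)` in px covered by the grid; grid points
#'   are placed at equal spacing strictly inside the extent.
#' @param center optional evaluation center override, `(x, y)` px.
#' @param pixel_size,frame_interval calibration attached to the field.
#'
#' @return A [flow_field()] with every vector valid.
#' @export
generate_analytic_flow <- function(model, grid = c(16, 16),
                                   extent = NULL, center = NULL,
                                   pixel_size = 0.1, frame_interval = 5) {
  if (length(grid) != 2L || any(grid < 2))
    stop("`grid` must be (nx, ny) with both >= 2")
  if (!is.null(center)) model$center <- center
  if (is.null(extent)) extent <- c(2, 2) * model$cell_radius + 1
  x <- seq(1, extent[1], length.out = grid[1])
  y <- seq(1, extent[2], length.out = grid[2])
  gx <- matrix(rep(x, each = grid[2]), nrow = grid[2])
  gy <- matrix(rep(y, times = grid[1]), nrow = grid[2])
  v <- model_velocity(model, as.vector(gx), as.vector(gy))
  flow_field(x = x, y = y,
             vx = matrix(v$vx, nrow = grid[2]),
             vy = matrix(v$vy, nrow = grid[2]),
             valid = matrix(TRUE, grid[2], grid[1]),
             pixel_size = pixel_size, frame_interval = frame_interval)
}

# Render isotropic 2D Gaussian puncta into an H x W image. Each punctum is
# drawn on a +/- 4 sigma patch only.
render_puncta <- function(h, w, xs, ys, amp, sigma) {
  img <- matrix(0, h, w)
  half <- ceiling(4 * sigma)
  for (p in seq_along(xs)) {
    cx <- xs[p]; cy <- ys[p]
    j0 <- max(1L, floor(cx) - half); j1 <- min(w, ceiling(cx) + half)
    i0 <- max(1L, floor(cy) - half); i1 <- min(h, ceiling(cy) + half)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    gx <- exp(-((jj - cx)^2) / (2 * sigma^2))
    gy <- exp(-((ii - cy)^2) / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + amp[p] * outer(gy, gx)
  }
  img
}

#' Generate a synthetic punctate movie with known ground truth
#'
#' Simulates a field of diffraction-limited fluorescent puncta inside a
#' circular cell: a mobile subset advected by a [flow_model()] (plus
#' optional positional jitter) and a static subset standing in for the
#' immobile background pool. Frames are rendered as sums of isotropic 2D
#' Gaussians on a constant baseline, with optional Poisson shot noise or
#' additive Gaussian read noise and optional whole-field photobleaching.
#' The exact pre-noise particle tracks are returned as ground truth, so
#' downstream velocity estimates can be scored against the imposed flow.
#'
#' Particle starting positions are drawn uniformly in the disk of radius
#' `model$cell_radius` about `model$center`; draws falling outside the
#' image are rejected and resampled. The same `seed` always reproduces the
#' identical movie and ground truth.
#'
#' @param model a [flow_model()]; its `center` and `cell_radius` place the
#'   particles.
#' @param n_particles total number of puncta (`> 0`).
#' @param static_fraction fraction in `[0, 1]` of puncta that never move.
#' @param psf_sigma Gaussian width of a punctum, px.
#' @param noise `"none"`, `"poisson"` (intensities are photon counts) or
#'   `"gaussian"` (additive, sd `noise_sd`, clipped at 0).
#' @param noise_sd sd of Gaussian read noise, intensity units.
#' @param n_frames number of frames (`>= 2`).
#' @param shape image size `(H, W)` px.
#' @param pixel_size,frame_interval calibration (um/px, s).
#' @param amplitude peak intensity of one punctum (photons for Poisson).
#' @param baseline constant background offset added to every pixel.
#' @param bleach_rate optional per-frame exponential photobleaching rate
#'   applied to the whole field (0 = off).
#' @param seed integer RNG seed; recorded in the ground truth.
#'
#' @return A list with elements `movie` (a [ccs_movie()], mask set to the
#'   cell disk) and `truth`: a list with `tracks` (data.frame `particle`,
#'   `frame`, `x_px`, `y_px`, `is_static`), the model, and the seed.
#' @export
generate_ccs_movie <- function(model, n_particles = 100, static_fraction = 0.3,
                               psf_sigma = 1.5,
                               noise = c("poisson", "none", "gaussian"),
                               noise_sd = 2,
                               n_frames = 60, shape = c(256, 256),
                               pixel_size = 0.1, frame_interval = 5,
                               amplitude = 100, baseline = 10,
                               bleach_rate = 0, seed = 1) {
  noise <- match.arg(noise)
  if (n_particles < 1) stop("need at least one particle")
  if (n_frames < 2) stop("`n_frames` must be >= 2")
  if (psf_sigma <= 0) stop("`psf_sigma` must be > 0")
  if (static_fraction < 0 || static_fraction > 1)
    stop("`static_fraction` must be in [0, 1]")
  h <- shape[1]; w <- shape[2]
  if (model$center[1] < 1 || model$center[1] > w ||
      model$center[2] < 1 || model$center[2] > h)
    stop("model center must lie inside the image")

  withr::with_seed(seed, {
    # rejection-sample uniform positions in the cell disk, inside the image
    sample_disk <- function(n) {
      xs <- numeric(0); ys <- numeric(0)
      while (length(xs) < n) {
        m <- 2 * (n - length(xs)) + 8
        r <- model$cell_radius * sqrt(stats::runif(m))
        th <- stats::runif(m, 0, 2 * pi)
        px <- model$center[1] + r * cos(th)
        py <- model$center[2] + r * sin(th)
        ok <- px >= 1 & px <= w & py >= 1 & py <= h
        xs <- c(xs, px[ok]); ys <- c(ys, py[ok])
      }
      list(x = xs[seq_len(n)], y = ys[seq_len(n)])
    }
    pos <- sample_disk(n_particles)
    n_static <- round(static_fraction * n_particles)
    is_static <- rep(FALSE, n_particles)
    if (n_static > 0) is_static[seq_len(n_static)] <- TRUE

    xs <- pos$x; ys <- pos$y
    tracks <- vector("list", n_frames)
    static_img <- if (any(is_static))
      render_puncta(h, w, xs[is_static], ys[is_static],
                    rep(amplitude, sum(is_static)), psf_sigma)
    else matrix(0, h, w)

    frames <- array(0, dim = c(h, w, n_frames))
    for (k in seq_len(n_frames)) {
      tracks[[k]] <- data.frame(particle = seq_len(n_particles), frame = k,
                                x_px = xs, y_px = ys, is_static = is_static)
      mob <- !is_static
      clean <- static_img +
        if (any(mob))
          render_puncta(h, w, xs[mob], ys[mob],
                        rep(amplitude, sum(mob)), psf_sigma)
        else 0
      clean <- clean + baseline
      if (bleach_rate > 0) clean <- clean * exp(-bleach_rate * (k - 1))
      frames[, , k] <- clean
      if (k < n_frames && any(mob)) {
        v <- model_velocity(model, xs[mob], ys[mob])
        xs[mob] <- xs[mob] + v$vx
        ys[mob] <- ys[mob] + v$vy
        if (model$jitter_sd > 0) {
          nm <- sum(mob)
          xs[mob] <- xs[mob] + stats::rnorm(nm, 0, model$jitter_sd)
          ys[mob] <- ys[mob] + stats::rnorm(nm, 0, model$jitter_sd)
        }
      }
    }
    if (noise == "poisson") {
      frames[] <- stats::rpois(length(frames), lambda = frames)
    } else if (noise == "gaussian") {
      frames[] <- pmax(0, frames + stats::rnorm(length(frames), 0, noise_sd))
    }

    ii <- matrix(rep(seq_len(h), w), h, w)
    jj <- matrix(rep(seq_len(w), each = h), h, w)
    mask <- (jj - model$center[1])^2 + (ii - model$center[2])^2 <=
      (model$cell_radius * 1.05)^2

    movie <- ccs_movie(frames, pixel_size = pixel_size,
                       frame_interval = frame_interval, mask = mask)
    truth <- list(tracks = do.call(rbind, tracks), model = model, seed = seed,
                  amplitude = amplitude, baseline = baseline,
                  psf_sigma = psf_sigma)
    list(movie = movie, truth = truth)
  })
}
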