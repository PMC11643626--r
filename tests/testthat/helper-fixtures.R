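# Shared fixtures built in code at test time.

# Smooth random texture: white noise blurred with a small box kernel, so
# cross-correlation peaks are well localized but not single-pixel.
smooth_texture <- function(n, seed = 1, kernel = 5) {
  withr::with_seed(seed, {
    z <- matrix(stats::runif(n * n), n, n)
  })
  EBImage::filter2(z, matrix(1 / kernel^2, kernel, kernel))
}

# Circular (wrap-around) integer shift of a matrix: content moves by
# (+dx, +dy) in (col, row).
circ_shift <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1 - dy) %% h) + 1
  ci <- ((seq_len(w) - 1 - dx) %% w) + 1
  m[ri, ci]
}

# Movie from a list of frames with default calibration.
frames_movie <- function(frames, pixel_size = 0.1, frame_interval = 5,
                         mask = NULL) {
  ccs_movie(simplify2array(frames), pixel_size = pixel_size,
            frame_interval = frame_interval, mask = mask)
}

# A flow_field built directly from vector matrices on an integer grid.
make_field <- function(vx, vy, valid = NULL, x = NULL, y = NULL,
                       pixel_size = 0.1, frame_interval = 5) {
  ny <- nrow(vx); nx <- ncol(vx)
  if (is.null(valid)) valid <- matrix(TRUE, ny, nx)
  if (is.null(x)) x <- seq_len(nx) * 10
  if (is.null(y)) y <- seq_len(ny) * 10
  flow_field(x = x, y = y, vx = vx, vy = vy, valid = valid,
             pixel_size = pixel_size, frame_interval = frame_interval)
}

# Independent bisection oracle for the spherical-indenter pair: solves
# delta(a) = depth by plain interval bisection, then evaluates the force
# expression directly. Used to cross-check the package's root-finder.
sneddon_bisect_oracle <- function(depth, E, nu, R, iters = 200) {
  dfun <- function(a) if (a <= 0) 0 else a / 2 * log((R + a) / (R - a))
  lo <- 0; hi <- R * (1 - 1e-12)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (dfun(mid) < depth) lo <- mid else hi <- mid
  }
  a <- (lo + hi) / 2
  E / (1 - nu^2) * ((a^2 + R^2) / 2 * log((R + a) / (R - a)) - a * R)
}
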