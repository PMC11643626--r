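# Cross-correlate two equally-sized matrices via FFT and return the
# displacement (dx, dy) of `b` relative to `a` with 3-point subpixel peak
# refinement. Means are removed first so flat offsets do not bias the peak.
# With `phase = TRUE` the cross-power spectrum is whitened (true phase
# correlation), which turns a pure translation into a delta peak — used for
# whole-frame drift registration; windowed PIV keeps the plain correlation.
# The fitted log-Gaussian falls back to a parabola when a neighbour of the
# peak is nonpositive.
cross_correlate_shift <- function(a, b, phase = FALSE, max_shift = Inf) {
  a <- a - mean(a); b <- b - mean(b)
  h <- nrow(a); w <- ncol(a)
  spec <- Conj(stats::fft(a)) * stats::fft(b)
  if (phase) {
    mag <- Mod(spec)
    spec <- spec / (mag + 1e-12 * max(mag))
  }
  cc <- Re(stats::fft(spec, inverse = TRUE)) / length(a)
  if (is.finite(max_shift)) {
    # restrict the peak search to displacements within max_shift
    dys <- c(0:(h - 1)); dys[dys > h / 2] <- dys[dys > h / 2] - h
    dxs <- c(0:(w - 1)); dxs[dxs > w / 2] <- dxs[dxs > w / 2] - w
    cc[abs(dys) > max_shift, ] <- -Inf
    cc[, abs(dxs) > max_shift] <- -Inf
  }
  idx <- which.max(cc)
  pi_ <- ((idx - 1L) %% h) + 1L
  pj_ <- ((idx - 1L) %/% h) + 1L
  wrap <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  dy <- wrap(pi_, h); dx <- wrap(pj_, w)
  # circular neighbours of the peak for subpixel interpolation
  at <- function(i, j) cc[((i - 1L) %% h) + 1L, ((j - 1L) %% w) + 1L]
  c0 <- cc[pi_, pj_]
  cym <- at(pi_ - 1L, pj_); cyp <- at(pi_ + 1L, pj_)
  cxm <- at(pi_, pj_ - 1L); cxp <- at(pi_, pj_ + 1L)
  sub <- function(cm, c0, cp) {
    if (!is.finite(cm) || !is.finite(cp)) return(0)
    if (cm > 0 && c0 > 0 && cp > 0) {
      den <- log(cm) - 2 * log(c0) + log(cp)
      if (den < 0) return((log(cm) - log(cp)) / (2 * den))
    }
    den <- cm - 2 * c0 + cp
    if (den < 0) (cm - cp) / (2 * den) else 0
  }
  ddy <- sub(cym, c0, cyp); ddx <- sub(cxm, c0, cxp)
  if (!is.finite(ddy) || abs(ddy) > 1) ddy <- 0
  if (!is.finite(ddx) || abs(ddx) > 1) ddx <- 0
  list(dx = dx + ddx, dy = dy + ddy, peak = c0)
}

# Shift an image by (dx, dy): output(x) = input(x + (dx, dy)) sampled with
# bilinear interpolation; pixels falling outside the input are set to 0.
shift_image <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  xq <- matrix(rep(seq_len(w), each = h), h, w) + dx
  yq <- matrix(rep(seq_len(h), w), h, w) + dy
  bilinear_sample(img, xq, yq)
}

# Bilinear sampling of img at fractional (x, y) = (col, row); 0 outside.
bilinear_sample <- function(img, xq, yq) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xq); y0 <- floor(yq)
  fx <- xq - x0; fy <- yq - y0
  get <- function(i, j) {
    v <- matrix(0, nrow(xq), ncol(xq))
    ok <- i >= 1 & i <= h & j >= 1 & j <= w
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  v00 <- get(y0, x0);     v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  dim(out) <- dim(xq)
  out
}

#' Estimate and remove translational drift from a movie
#'
#' Mechanical drift moves the whole cell with respect to the camera frame
#' and, left uncorrected, contaminates every downstream flow vector with
#' the global offset of the cell's center of mass. Consecutive frames are
#' registered by phase-correlation translation estimation with 3-point
#' subpixel peak refinement (consecutive frames overlap strongly, so the
#' peak stays locked even when little static structure is present); the
#' interframe shifts are accumulated into each frame's translation
#' relative to the reference frame and removed by bilinear interpolation
#' with zero fill at the edges. The peak search is limited to `max_shift`
#' px per frame step.
#'
#' @param movie a [ccs_movie()].
#' @param reference index of the reference frame (default first frame).
#' @param max_shift largest admissible interframe translation, px.
#'
#' @return A list with `movie` (the registered [ccs_movie()]) and `drift`:
#'   a data.frame `(frame, dx_px, dy_px)` of the estimated translation of
#'   each frame relative to the reference (the reference row is `(0, 0)`).
#' @export
estimate_and_apply_drift <- function(movie, reference = 1L,
                                     max_shift = NULL) {
  nt <- dim(movie)[3]
  if (reference < 1L || reference > nt) stop("invalid reference frame")
  if (is.null(max_shift)) max_shift <- min(dim(movie)[1:2]) / 4
  out <- unclass(movie)
  # interframe shifts, then cumulative drift relative to the reference
  step_dx <- numeric(nt); step_dy <- numeric(nt)
  for (k in 2:nt) {
    fa <- movie_frame(movie, k - 1L)
    fb <- movie_frame(movie, k)
    if (all(fb == 0) || all(fa == 0)) {
      if (all(fb == 0))
        warning("frame ", k, " is all zero; registration skipped")
      next
    }
    s <- cross_correlate_shift(fa, fb, phase = TRUE, max_shift = max_shift)
    step_dx[k] <- s$dx
    step_dy[k] <- s$dy
  }
  cum_dx <- cumsum(step_dx); cum_dy <- cumsum(step_dy)
  drift <- data.frame(frame = seq_len(nt),
                      dx_px = cum_dx - cum_dx[reference],
                      dy_px = cum_dy - cum_dy[reference])
  for (k in seq_len(nt)) {
    if (drift$dx_px[k] == 0 && drift$dy_px[k] == 0) next
    fr <- movie_frame(movie, k)
    if (all(fr == 0)) next
    out[, , k] <- pmax(0, shift_image(fr, drift$dx_px[k], drift$dy_px[k]))
  }
  list(movie = ccs_movie(out, pixel_size = attr(movie, "pixel_size"),
                         frame_interval = attr(movie, "frame_interval"),
                         mask = attr(movie, "mask")),
       drift = drift)
}

#' Static-background intensity correction
#'
#' Punctate movies of structures such as clathrin-coated pits often sit on
#' a bright pool of immobile fluorescence. Writing the recorded intensity
#' as `I0(i,j,k) = S(i,j) + M(i,j,k)` (static plus moving), the temporal
#' mean frame `Imean(i,j) = mean_k I0(i,j,k)` contains all of `S` plus a
#' small time-averaged trace of `M`. Subtracting it with clipping,
#'
#'   `Ic(i,j,k) = max(0, I0(i,j,k) - Imean(i,j))`,
#'
#' removes every temporally constant structure exactly, while a pixel lit
#' transiently in a single frame out of `N` retains `(N-1)/N` of its moving
#' intensity. The spatial pattern of the moving component is preserved up
#' to this uniform attenuation, which is what windowed cross-correlation
#' needs. Apply after drift correction, since drift turns static structures
#' into apparent motion.
#'
#' @param movie a drift-corrected [ccs_movie()] with `N >= 2` frames.
#'
#' @return A list with `movie` (the corrected [ccs_movie()], nonnegative)
#'   and `mean_frame` (the `H x W` temporal mean image).
#' @export
intensity_correct <- function(movie) {
  nt <- dim(movie)[3]
  if (nt < 2L) stop("intensity correction needs at least 2 frames")
  mean_frame <- apply(unclass(movie), c(1, 2), mean)
  out <- unclass(movie)
  for (k in seq_len(nt)) out[, , k] <- pmax(0, out[, , k] - mean_frame)
  list(movie = ccs_movie(out, pixel_size = attr(movie, "pixel_size"),
                         frame_interval = attr(movie, "frame_interval"),
                         mask = attr(movie, "mask")),
       mean_frame = mean_frame)
}

#' Write a drift table as CSV
#'
#' @param drift the `drift` data.frame from [estimate_and_apply_drift()].
#' @param path output CSV path.
#' @export
write_drift_table <- function(drift, path) {
  utils::write.csv(drift, path, row.names = FALSE)
  invisible(path)
}
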