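#' Estimate the cell center
#'
#' The center `(xc, yc)` about which radial and angular flow statistics are
#' computed. For a movie the time-maximum projection is used (puncta sweep
#' out the cell area over the movie), restricted to the mask when present,
#' and the intensity-weighted centroid is returned. For a logical mask the
#' centroid of the `TRUE` pixels is returned.
#'
#' @param x a [ccs_movie()] or an `H x W` logical mask.
#' @return Numeric `(xc, yc)` in px (x = column, y = row).
#' @export
estimate_cell_center <- function(x) {
  if (is.logical(x) && is.matrix(x)) {
    if (!any(x)) stop("empty mask")
    wts <- x * 1
  } else if (inherits(x, "ccs_movie")) {
    proj <- apply(unclass(x), c(1, 2), max)
    mask <- attr(x, "mask")
    if (!is.null(mask)) proj[!mask] <- 0
    if (all(proj == 0)) stop("movie projection is empty")
    wts <- proj
  } else stop("`x` must be a ccs_movie or a logical mask")
  h <- nrow(wts); w <- ncol(wts)
  tot <- sum(wts)
  xc <- sum(wts * matrix(rep(seq_len(w), each = h), h, w)) / tot
  yc <- sum(wts * matrix(rep(seq_len(h), w), h, w)) / tot
  c(xc = xc, yc = yc)
}

# Polar decomposition of a flow field about a center: for each valid grid
# point returns r (px), theta (rad), v_r and v_t (px/frame) and theta_v.
polar_components <- function(field, center) {
  ny <- length(field$y); nx <- length(field$x)
  gx <- rep(field$x, each = ny) - center[1]
  gy <- rep(field$y, times = nx) - center[2]
  r <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx)
  vx <- as.vector(field$vx); vy <- as.vector(field$vy)
  # a vector exactly at the center has no defined radial direction
  ok <- as.vector(field$valid) & is.finite(vx) & is.finite(vy) & r > 0
  vr <- vx * cos(theta) + vy * sin(theta)
  vt <- -vx * sin(theta) + vy * cos(theta)
  data.frame(r = r, theta = theta, vx = vx, vy = vy,
             vr = vr, vt = vt, valid = ok)
}

#' Radial flow-speed profile
#'
#' Projects a (typically time-averaged) flow field onto polar coordinates
#' about the cell center and averages the radial component over annuli:
#' each valid vector at distance `r` from the center contributes its
#' `Vr = Vx cos(theta) + Vy sin(theta)` to the annulus `[r, r + dr)`. The
#' signed convention uses the outward unit radial vector, so inward
#' (centripetal) flow gives `Vr < 0`. The tangential component `Vt` is
#' reported alongside. Velocities are converted to um/s with the field's
#' calibration.
#'
#' @param field a [flow_field()].
#' @param center `(xc, yc)` in px; see [estimate_cell_center()].
#' @param dr_px annulus width in px (default 60).
#' @return A data.frame of class `radial_profile` with columns `r_in_um`,
#'   `r_mid_um`, `vr_um_s`, `vt_um_s`, `n`; annuli with no vectors carry
#'   `NA`, not zero. Attributes: `dr_px`, `dr_um`, `center`.
#' @export
radial_profile <- function(field, center, dr_px = 60) {
  pc <- polar_components(field, center)
  pc <- pc[pc$valid, ]
  if (nrow(pc) == 0) stop("no valid vectors")
  scale <- field$pixel_size / field$frame_interval  # px/frame -> um/s
  n_ann <- ceiling(max(pc$r) / dr_px)
  bin <- pmin(floor(pc$r / dr_px), n_ann - 1L) + 1L
  vr <- tapply(pc$vr, factor(bin, levels = seq_len(n_ann)), mean)
  vt <- tapply(pc$vt, factor(bin, levels = seq_len(n_ann)), mean)
  n <- tapply(rep(1, nrow(pc)), factor(bin, levels = seq_len(n_ann)), sum)
  n[is.na(n)] <- 0
  out <- data.frame(
    r_in_um = (seq_len(n_ann) - 1L) * dr_px * field$pixel_size,
    r_mid_um = ((seq_len(n_ann) - 0.5) * dr_px) * field$pixel_size,
    vr_um_s = as.numeric(vr) * scale,
    vt_um_s = as.numeric(vt) * scale,
    n = as.numeric(n))
  structure(out, dr_px = dr_px, dr_um = dr_px * field$pixel_size,
            center = center, class = c("radial_profile", "data.frame"))
}

#' Flow-direction histogram
#'
#' For each valid, nonzero vector computes the direction offset
#' `theta_dir = theta_v - theta` between the velocity direction
#' `theta_v = atan2(Vy, Vx)` and the outward polar direction `theta` of its
#' grid point, wrapped to `[0, 360)` degrees, and bins the offsets into a
#' normalized histogram. Pure inward radial flow concentrates at 180
#' degrees, outward flow at 0, circular flow at 90 or 270 depending on
#' sense; stalled movies give a broad, near-uniform distribution.
#'
#' Bins are centered on the canonical signature angles: with the default
#' 24 bins the bin centers are 0, 15, ..., 180, ... degrees, so a pure
#' radial or circular flow concentrates in the interior of one bin rather
#' than on a bin edge (the first bin wraps across 0/360).
#'
#' @param field a [flow_field()].
#' @param center `(xc, yc)` px.
#' @param n_bins number of equal bins covering the circle (default 24).
#' @param weight if `"none"` (default) each vector counts once; if
#'   `"magnitude"` vectors are weighted by speed.
#' @return A data.frame of class `direction_histogram` with columns
#'   `bin_left_deg`, `bin_center_deg`, `density` (per degree, integrates to
#'   1) and `count`; attribute `n_total`.
#' @export
direction_histogram <- function(field, center, n_bins = 24,
                                weight = c("none", "magnitude")) {
  weight <- match.arg(weight)
  pc <- polar_components(field, center)
  speed <- sqrt(pc$vx^2 + pc$vy^2)
  pc <- pc[pc$valid & speed > 0, ]
  if (nrow(pc) == 0) stop("no valid nonzero vectors")
  theta_v <- atan2(pc$vy, pc$vx)
  tdir <- (theta_v - pc$theta) * 180 / pi
  tdir <- tdir %% 360
  width <- 360 / n_bins
  # bin k has center (k-1)*width; the first bin wraps across 0/360
  bin <- (floor((tdir + width / 2) / width) %% n_bins) + 1L
  wts <- if (weight == "magnitude") sqrt(pc$vx^2 + pc$vy^2) else rep(1, nrow(pc))
  cnt <- tapply(wts, factor(bin, levels = seq_len(n_bins)), sum)
  cnt[is.na(cnt)] <- 0
  cnt <- as.numeric(cnt)
  centers <- (seq_len(n_bins) - 1L) * width
  out <- data.frame(
    bin_left_deg = (centers - width / 2) %% 360,
    bin_center_deg = centers,
    density = cnt / sum(cnt) / width,
    count = cnt)
  structure(out, n_total = nrow(pc), n_bins = n_bins,
            class = c("direction_histogram", "data.frame"))
}

#' Center of the modal bin of a direction histogram
#'
#' @param hist a [direction_histogram()].
#' @return Bin-center angle in degrees of the most occupied bin.
#' @export
modal_direction <- function(hist) {
  hist$bin_center_deg[which.max(hist$density)]
}

#' Plot a radial speed profile
#'
#' Plots the magnitude of the annulus-averaged radial velocity against
#' radial distance (radial speed, um/s).
#'
#' @param x a [radial_profile()].
#' @param signed plot the signed `Vr` instead of `|Vr|`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.radial_profile <- function(x, signed = FALSE, ...) {
  v <- if (signed) x$vr_um_s else abs(x$vr_um_s)
  graphics::plot(x$r_mid_um, v, type = "b", pch = 16,
                 xlab = expression("r (" * mu * "m)"),
                 ylab = if (signed) expression(V[r] ~ "(" * mu * "m/s)")
                 else expression("Radial speed (" * mu * "m/s)"), ...)
  if (signed) graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Plot a flow-direction histogram on polar axes
#'
#' @param x a [direction_histogram()].
#' @param polar draw as a polar rose (default) or as a bar plot.
#' @param ... ignored.
#' @export
plot.direction_histogram <- function(x, polar = TRUE, ...) {
  if (!polar) {
    graphics::barplot(x$density, names.arg = round(x$bin_center_deg),
                      xlab = expression(theta[dir] ~ "(degrees)"),
                      ylab = "density (1/deg)")
    return(invisible(x))
  }
  rmax <- max(x$density)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(rmax * cos(th), rmax * sin(th), col = "grey70")
  for (i in seq_len(nrow(x))) {
    a0 <- x$bin_left_deg[i] * pi / 180
    a1 <- a0 + (360 / nrow(x)) * pi / 180
    aa <- seq(a0, a1, length.out = 8)
    graphics::polygon(c(0, x$density[i] * cos(aa)),
                      c(0, x$density[i] * sin(aa)),
                      col = "steelblue", border = "white")
  }
  graphics::text(rmax * 1.08 * cos(c(0, pi / 2, pi, 3 * pi / 2)),
                 rmax * 1.08 * sin(c(0, pi / 2, pi, 3 * pi / 2)),
                 c("0", "90", "180", "270"))
  invisible(x)
}

#' Quiver plot of a flow field
#'
#' @param x a [flow_field()].
#' @param scale arrow length multiplier (px of plot per px/frame).
#' @param ... passed to [graphics::plot()].
#' @export
plot.flow_field <- function(x, scale = NULL, ...) {
  ny <- length(x$y); nx <- length(x$x)
  gx <- rep(x$x, each = ny); gy <- rep(x$y, times = nx)
  u <- as.vector(x$vx); v <- as.vector(x$vy)
  ok <- as.vector(x$valid) & is.finite(u) & is.finite(v)
  if (is.null(scale)) {
    sp <- sqrt(u[ok]^2 + v[ok]^2)
    scale <- if (any(sp > 0)) 0.4 * mean(diff(x$x)) / max(sp) else 1
  }
  graphics::plot(NA, xlim = range(x$x), ylim = rev(range(x$y)), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", ...)
  graphics::arrows(gx[ok], gy[ok], gx[ok] + scale * u[ok],
                   gy[ok] + scale * v[ok], length = 0.04, col = "steelblue")
  invisible(x)
}
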