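#' Gridded 2D flow field
#'
#' Container for one PIV vector field (or a time average of them): a
#' regular grid of window centers with per-point velocity components in
#' px/frame and a validity mask. Invalid vectors are flagged, never
#' silently zeroed. The attached calibration converts px/frame to um/s.
#'
#' @param x,y grid coordinates (px) of window centers along columns (`x`,
#'   length `nx`) and rows (`y`, length `ny`).
#' @param vx,vy `ny x nx` matrices of velocity components, px/frame.
#' @param valid `ny x nx` logical matrix.
#' @param pixel_size,frame_interval calibration (um/px, s).
#' @param extra optional named list of provenance fields.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(x, y, vx, vy, valid, pixel_size, frame_interval,
                       extra = list()) {
  stopifnot(is.matrix(vx), all(dim(vx) == c(length(y), length(x))),
            all(dim(vy) == dim(vx)), all(dim(valid) == dim(vx)))
  if (any(is.finite(vx[valid]) == FALSE) || any(is.finite(vy[valid]) == FALSE))
    stop("valid vectors must be finite")
  structure(c(list(x = x, y = y, vx = vx, vy = vy, valid = valid,
                   pixel_size = pixel_size, frame_interval = frame_interval),
              extra),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d x %d grid, %d/%d valid vectors\n",
              length(x$x), length(x$y), sum(x$valid), length(x$valid)))
  sp <- sqrt(x$vx[x$valid]^2 + x$vy[x$valid]^2)
  if (length(sp))
    cat(sprintf("  speed (px/frame): median %.3g, max %.3g\n",
                stats::median(sp), max(sp)))
  invisible(x)
}

# Bilinear interpolation of values Z defined on a regular grid (xg, yg)
# at query points (xq, yq); queries outside the grid are clamped to the
# border (nearest-value extrapolation).
interp_grid <- function(xg, yg, Z, xq, yq) {
  nx <- length(xg); ny <- length(yg)
  # degenerate single-row/column grids: constant along that axis
  if (nx == 1L) { xg <- c(xg, xg + 1); Z <- cbind(Z, Z); nx <- 2L }
  if (ny == 1L) { yg <- c(yg, yg + 1); Z <- rbind(Z, Z); ny <- 2L }
  ix <- findInterval(xq, xg, all.inside = TRUE)
  iy <- findInterval(yq, yg, all.inside = TRUE)
  x0 <- xg[ix]; x1 <- xg[ix + 1]
  y0 <- yg[iy]; y1 <- yg[iy + 1]
  tx <- pmin(1, pmax(0, (xq - x0) / (x1 - x0)))
  ty <- pmin(1, pmax(0, (yq - y0) / (y1 - y0)))
  z00 <- Z[cbind(iy, ix)];     z01 <- Z[cbind(iy, ix + 1)]
  z10 <- Z[cbind(iy + 1, ix)]; z11 <- Z[cbind(iy + 1, ix + 1)]
  (1 - ty) * ((1 - tx) * z00 + tx * z01) + ty * ((1 - tx) * z10 + tx * z11)
}

# Replace NAs in a matrix by Laplace (spring) interpolation from the
# non-NA entries: iterative relaxation of the discrete Laplace equation
# with the known entries as boundary conditions.
laplace_fill <- function(Z) {
  known <- !is.na(Z)
  if (all(known)) return(Z)
  fill <- mean(Z[known])
  Z[!known] <- fill
  ny <- nrow(Z); nx <- ncol(Z)
  for (iter in seq_len(2000L)) {
    up    <- Z[c(1, seq_len(ny - 1)), , drop = FALSE]
    down  <- Z[c(seq_len(ny - 1) + 1, ny), , drop = FALSE]
    left  <- Z[, c(1, seq_len(nx - 1)), drop = FALSE]
    right <- Z[, c(seq_len(nx - 1) + 1, nx), drop = FALSE]
    new <- (up + down + left + right) / 4
    delta <- max(abs(new[!known] - Z[!known]))
    Z[!known] <- new[!known]
    if (delta < 1e-9) break
  }
  Z
}

# 3x3 mean filter with border handling by averaging available neighbours.
mean3 <- function(Z) {
  ny <- nrow(Z); nx <- ncol(Z)
  acc <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  for (di in -1:1) for (dj in -1:1) {
    si <- pmin(pmax(seq_len(ny) + di, 1), ny)
    sj <- pmin(pmax(seq_len(nx) + dj, 1), nx)
    inside_i <- seq_len(ny) + di >= 1 & seq_len(ny) + di <= ny
    inside_j <- seq_len(nx) + dj >= 1 & seq_len(nx) + dj <= nx
    w <- outer(as.numeric(inside_i), as.numeric(inside_j))
    acc <- acc + w * Z[si, sj, drop = FALSE]
    cnt <- cnt + w
  }
  acc / cnt
}

# 3x3 neighbourhood median excluding the center; NAs ignored.
neighbour_median <- function(Z) {
  ny <- nrow(Z); nx <- ncol(Z)
  out <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ii <- max(1, i - 1):min(ny, i + 1)
    jj <- max(1, j - 1):min(nx, j + 1)
    vals <- Z[ii, jj]
    center <- which(ii == i) + (which(jj == j) - 1L) * length(ii)
    vals <- vals[-center]
    vals <- vals[!is.na(vals)]
    if (length(vals) >= 3) out[i, j] <- stats::median(vals)
  }
  out
}

#' Multipass FFT cross-correlation PIV on one frame pair
#'
#' Estimates the displacement field from `frame_a` to `frame_b` by windowed
#' FFT cross-correlation with coarse-to-fine refinement: each pass divides
#' the image into interrogation windows (default schedule 512 -> 128 -> 64
#' px at 50% overlap), seeds the interrogation window in `frame_b` with the
#' displacement interpolated from the previous pass (window offsetting),
#' and localizes the correlation peak with 3-point Gaussian subpixel
#' refinement. Optionally the second frame is bilinearly deformed by the
#' intermediate displacement field between passes.
#'
#' A window larger than the frame is shrunk (with a warning) to the largest
#' power of two that fits. Windows whose center falls outside the mask, or
#' that contain no intensity variation, yield invalid vectors.
#'
#' @param frame_a,frame_b equally-sized numeric matrices.
#' @param passes decreasing interrogation window sizes in px; the final
#'   window must be >= 16 px.
#' @param overlap window overlap fraction in `[0, 0.75]`.
#' @param mask optional `H x W` logical matrix; pixels outside are zeroed
#'   and vectors centered outside are invalid.
#' @param deform if `TRUE`, apply full bilinear image deformation to
#'   `frame_b` between passes instead of integer window offsetting only.
#' @param pixel_size,frame_interval calibration attached to the result.
#'
#' @return A [flow_field()] in px/frame on the final-pass grid.
#' @export
compute_flow_pair <- function(frame_a, frame_b,
                              passes = c(512, 128, 64), overlap = 0.5,
                              mask = NULL, deform = FALSE,
                              pixel_size = 0.1, frame_interval = 5) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must have the same shape")
  if (is.unsorted(rev(passes))) stop("`passes` must be decreasing")
  if (passes[length(passes)] < 16) stop("final window must be >= 16 px")
  if (overlap < 0 || overlap > 0.75) stop("`overlap` must be in [0, 0.75]")
  h <- nrow(frame_a); w <- ncol(frame_a)
  maxfit <- 2^floor(log2(min(h, w)))
  if (passes[1] > maxfit) {
    warning("first window (", passes[1], " px) larger than frame; shrunk to ",
            maxfit, " px")
    passes <- unique(pmin(passes, maxfit))
  }
  if (!is.null(mask)) {
    frame_a <- frame_a * mask
    frame_b <- frame_b * mask
  }
  b_work <- frame_b
  prev <- NULL  # list(x, y, vx, vy) from previous pass
  for (p in seq_along(passes)) {
    win <- passes[p]
    step <- max(4L, round(win * (1 - overlap)))
    x0 <- unique(c(seq(1L, w - win + 1L, by = step), w - win + 1L))
    y0 <- unique(c(seq(1L, h - win + 1L, by = step), h - win + 1L))
    xc <- x0 + (win - 1) / 2
    yc <- y0 + (win - 1) / 2
    nx <- length(x0); ny <- length(y0)
    vx <- matrix(NA_real_, ny, nx); vy <- matrix(NA_real_, ny, nx)
    valid <- matrix(TRUE, ny, nx)
    # seed displacements from previous pass
    if (!is.null(prev)) {
      gx <- rep(xc, each = ny); gy <- rep(yc, times = nx)
      sx <- matrix(interp_grid(prev$x, prev$y, prev$vx, gx, gy), ny, nx)
      sy <- matrix(interp_grid(prev$x, prev$y, prev$vy, gx, gy), ny, nx)
      if (deform) {
        # resample frame_b backwards along the seed field; the residual
        # correlation then measures the remaining displacement
        fullx <- interp_grid(prev$x, prev$y, prev$vx,
                             rep(seq_len(w), each = h), rep(seq_len(h), w))
        fully <- interp_grid(prev$x, prev$y, prev$vy,
                             rep(seq_len(w), each = h), rep(seq_len(h), w))
        b_work <- bilinear_sample(frame_b,
                                  matrix(rep(seq_len(w), each = h), h, w) +
                                    matrix(fullx, h, w),
                                  matrix(rep(seq_len(h), w), h, w) +
                                    matrix(fully, h, w))
      }
    } else {
      sx <- matrix(0, ny, nx); sy <- matrix(0, ny, nx)
    }
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      if (!is.null(mask) &&
          !mask[round(yc[i]), round(xc[j])]) {
        valid[i, j] <- FALSE
        next
      }
      # integer window offset from the seed (zero if deforming: the seed is
      # already taken out of b_work)
      ox <- if (deform) 0L else as.integer(round(sx[i, j]))
      oy <- if (deform) 0L else as.integer(round(sy[i, j]))
      bx0 <- min(max(x0[j] + ox, 1L), w - win + 1L)
      by0 <- min(max(y0[i] + oy, 1L), h - win + 1L)
      ox <- bx0 - x0[j]; oy <- by0 - y0[i]
      wa <- frame_a[y0[i]:(y0[i] + win - 1L), x0[j]:(x0[j] + win - 1L)]
      wb <- b_work[by0:(by0 + win - 1L), bx0:(bx0 + win - 1L)]
      if (stats::sd(wa) == 0 || stats::sd(wb) == 0) {
        valid[i, j] <- FALSE
        next
      }
      s <- cross_correlate_shift(wa, wb)
      base_x <- if (deform) sx[i, j] else 0
      base_y <- if (deform) sy[i, j] else 0
      vx[i, j] <- base_x + ox + s$dx
      vy[i, j] <- base_y + oy + s$dy
    }
    # carry a fully-populated field into the next pass
    vx_fill <- vx; vy_fill <- vy
    vx_fill[!valid] <- NA; vy_fill[!valid] <- NA
    if (any(valid)) {
      vx_fill <- laplace_fill(vx_fill)
      vy_fill <- laplace_fill(vy_fill)
    } else {
      vx_fill[] <- 0; vy_fill[] <- 0
    }
    prev <- list(x = xc, y = yc, vx = vx_fill, vy = vy_fill)
  }
  vx[!valid] <- NA; vy[!valid] <- NA
  flow_field(x = prev$x, y = prev$y, vx = vx, vy = vy, valid = valid,
             pixel_size = pixel_size, frame_interval = frame_interval,
             extra = list(passes = passes, overlap = overlap))
}

#' Outlier filtering, gap interpolation and smoothing of a flow field
#'
#' The standard post-processing chain applied to every raw per-pair field,
#' in order: (1) a global standard-deviation filter invalidating vectors
#' whose x or y component deviates from the field mean by more than
#' `sd_threshold` standard deviations; (2) a local median filter
#' invalidating vectors whose component residual to the 3x3 neighbourhood
#' median (center excluded) exceeds `median_threshold` px/frame (plus a
#' small epsilon floor); (3) Laplace interpolation filling the invalidated
#' and missing vectors from their valid neighbours; (4) one pass of 3x3
#' mean spatial smoothing. With fewer than 4 valid vectors interpolation is
#' refused and the field is returned with invalids flagged.
#'
#' @param field a [flow_field()] from [compute_flow_pair()].
#' @param sd_threshold global filter threshold in standard deviations.
#' @param median_threshold local filter threshold in px/frame.
#' @param eps epsilon floor added to the median threshold.
#' @param smooth logical; apply the final 3x3 mean smoothing pass.
#' @return A [flow_field()]; interpolated vectors are marked valid and
#'   recorded in the `interpolated` element.
#' @export
postprocess_flow <- function(field, sd_threshold = 4, median_threshold = 4,
                             eps = 0.1, smooth = TRUE) {
  vx <- field$vx; vy <- field$vy
  valid <- field$valid & is.finite(vx) & is.finite(vy)
  outside <- !field$valid  # masked-out points stay invalid throughout
  # (1) global SD filter, per component
  if (sum(valid) >= 2) {
    mu_x <- mean(vx[valid]); sd_x <- stats::sd(vx[valid])
    mu_y <- mean(vy[valid]); sd_y <- stats::sd(vy[valid])
    bad <- valid & ((abs(vx - mu_x) > sd_threshold * sd_x & sd_x > 0) |
                      (abs(vy - mu_y) > sd_threshold * sd_y & sd_y > 0))
    valid[bad] <- FALSE
  }
  # (2) local median filter, per component
  vxm <- vx; vxm[!valid] <- NA
  vym <- vy; vym[!valid] <- NA
  medx <- neighbour_median(vxm); medy <- neighbour_median(vym)
  bad <- valid & !is.na(medx) & !is.na(medy) &
    (abs(vx - medx) > median_threshold + eps |
       abs(vy - medy) > median_threshold + eps)
  valid[bad] <- FALSE
  interpolated <- !valid & !outside
  if (sum(valid) < 4) {
    warning("fewer than 4 valid vectors; interpolation refused")
    vx[!valid] <- NA; vy[!valid] <- NA
    return(flow_field(field$x, field$y, vx, vy, valid,
                      field$pixel_size, field$frame_interval,
                      extra = list(interpolated = interpolated & FALSE)))
  }
  # (3) fill invalid vectors by Laplace interpolation
  vx[!valid] <- NA; vy[!valid] <- NA
  vx <- laplace_fill(vx); vy <- laplace_fill(vy)
  # (4) one-step 3x3 mean smoothing
  if (smooth) {
    vx <- mean3(vx); vy <- mean3(vy)
  }
  new_valid <- !outside
  vx[outside] <- NA; vy[outside] <- NA
  flow_field(field$x, field$y, vx, vy, new_valid,
             field$pixel_size, field$frame_interval,
             extra = list(interpolated = interpolated))
}

#' Time-averaged steady-state flow field
#'
#' Averages a sequence of per-frame-pair flow fields into the steady-state
#' field `V(i,j) = <v(i,j,k)>`: at each grid point the arithmetic mean over
#' the frame pairs where that point carried a valid vector. A grid point of
#' the average is valid only if it was valid in at least `min_valid_frac`
#' of the fields.
#'
#' @param fields list of [flow_field()]s sharing grid and calibration.
#' @param min_valid_frac minimum fraction of frames a point must be valid
#'   in (default 0.5).
#' @return A [flow_field()] with an `n_valid` count matrix.
#' @export
time_average <- function(fields, min_valid_frac = 0.5) {
  if (length(fields) == 0) stop("empty field sequence")
  f1 <- fields[[1]]
  for (f in fields)
    if (!identical(f$x, f1$x) || !identical(f$y, f1$y))
      stop("all fields must share the same grid")
  acc_x <- matrix(0, length(f1$y), length(f1$x))
  acc_y <- acc_x; cnt <- acc_x
  for (f in fields) {
    ok <- f$valid & is.finite(f$vx) & is.finite(f$vy)
    acc_x[ok] <- acc_x[ok] + f$vx[ok]
    acc_y[ok] <- acc_y[ok] + f$vy[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  valid <- cnt >= max(1, min_valid_frac * length(fields))
  vx <- ifelse(cnt > 0, acc_x / cnt, NA_real_)
  vy <- ifelse(cnt > 0, acc_y / cnt, NA_real_)
  vx[!valid] <- NA; vy[!valid] <- NA
  flow_field(f1$x, f1$y, vx, vy, valid, f1$pixel_size, f1$frame_interval,
             extra = list(n_valid = cnt, n_fields = length(fields)))
}

#' PIV over all consecutive frame pairs of a movie
#'
#' Convenience wrapper running [compute_flow_pair()] and
#' [postprocess_flow()] on every consecutive pair of frames.
#'
#' @param movie a [ccs_movie()] (drift- and intensity-corrected).
#' @param passes,overlap,deform see [compute_flow_pair()].
#' @param sd_threshold,median_threshold see [postprocess_flow()].
#' @param postprocess logical; run the post-processing chain per pair.
#' @return List of [flow_field()]s, one per frame pair.
#' @export
compute_movie_flow <- function(movie, passes = c(512, 128, 64), overlap = 0.5,
                               deform = FALSE, sd_threshold = 4,
                               median_threshold = 4, postprocess = TRUE) {
  nt <- dim(movie)[3]
  mask <- attr(movie, "mask")
  fields <- vector("list", nt - 1L)
  for (k in seq_len(nt - 1L)) {
    f <- suppressWarnings(
      compute_flow_pair(movie_frame(movie, k), movie_frame(movie, k + 1L),
                        passes = passes, overlap = overlap, mask = mask,
                        deform = deform,
                        pixel_size = attr(movie, "pixel_size"),
                        frame_interval = attr(movie, "frame_interval")))
    if (postprocess)
      f <- postprocess_flow(f, sd_threshold = sd_threshold,
                            median_threshold = median_threshold)
    fields[[k]] <- f
  }
  fields
}

#' Actin-flow PIV preset
#'
#' Maps the physical correlation sizes conventionally used for cortical
#' actin flow (source window 0.5 um, search window 1.0 um) onto pixel
#' interrogation windows at a movie's calibration, rounding up to the next
#' even size and enforcing the 16 px minimum.
#'
#' @param pixel_size um/px of the movie.
#' @param source_um,search_um physical window sizes in um.
#' @return A decreasing vector of pass sizes usable as `passes`.
#' @export
actin_piv_passes <- function(pixel_size, source_um = 0.5, search_um = 1.0) {
  px <- function(um) max(16L, 2L * ceiling(um / pixel_size / 2))
  search <- px(search_um); source <- px(source_um)
  if (search <= source) search <- 2L * source
  c(search, source)
}

#' Serialize a flow field to CSV
#'
#' One row per grid point: `x_px, y_px, vx_px_frame, vy_px_frame, valid`.
#'
#' @param field a [flow_field()].
#' @param path output CSV path.
#' @export
write_flow_field <- function(field, path) {
  ny <- length(field$y); nx <- length(field$x)
  df <- data.frame(
    x_px = rep(field$x, each = ny),
    y_px = rep(field$y, times = nx),
    vx_px_frame = as.vector(field$vx),
    vy_px_frame = as.vector(field$vy),
    valid = as.vector(field$valid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a flow field written by [write_flow_field()]
#'
#' @param path CSV path.
#' @param pixel_size,frame_interval calibration to attach.
#' @return A [flow_field()].
#' @export
read_flow_field <- function(path, pixel_size = 0.1, frame_interval = 5) {
  df <- utils::read.csv(path)
  x <- sort(unique(df$x_px)); y <- sort(unique(df$y_px))
  ny <- length(y); nx <- length(x)
  o <- order(match(df$x_px, x), match(df$y_px, y))
  df <- df[o, ]
  flow_field(x, y,
             vx = matrix(df$vx_px_frame, ny, nx),
             vy = matrix(df$vy_px_frame, ny, nx),
             valid = matrix(df$valid, ny, nx),
             pixel_size = pixel_size, frame_interval = frame_interval)
}
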