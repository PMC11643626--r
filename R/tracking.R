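#' Detect diffraction-limited spots in one frame
#'
#' Laplacian-of-Gaussian blob detection at a single scale: the frame is
#' convolved with a scale-normalized LoG kernel of width `sigma`, local
#' maxima of the response above `threshold * max(response)` are kept, and
#' each detection is refined to subpixel precision by an
#' intensity-weighted centroid on a 5x5 patch of the response.
#'
#' @param frame `H x W` numeric matrix.
#' @param sigma expected spot width, px.
#' @param threshold relative detection threshold in `(0, 1)`.
#' @return data.frame `(x_px, y_px, response)`; zero rows if nothing
#'   detected.
#' @export
detect_spots <- function(frame, sigma = 1.5, threshold = 0.2) {
  half <- ceiling(4 * sigma)
  ax <- seq(-half, half)
  g <- exp(-ax^2 / (2 * sigma^2))
  g <- g / sum(g)
  # separable scale-normalized LoG: sigma^2 * (d2/dx2 + d2/dy2) G
  d2 <- ((ax^2 - sigma^2) / sigma^4) * exp(-ax^2 / (2 * sigma^2))
  d2 <- d2 / sum(exp(-ax^2 / (2 * sigma^2)))
  log_kernel <- sigma^2 * (outer(d2, g) + outer(g, d2))
  resp <- -EBImage::filter2(frame, log_kernel, boundary = "replicate")
  h <- nrow(resp); w <- ncol(resp)
  rmax <- max(resp)
  if (rmax <= 0) return(data.frame(x_px = numeric(0), y_px = numeric(0),
                                   response = numeric(0)))
  # 8-neighbour local maxima above the relative threshold
  is_max <- resp >= threshold * rmax
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    si <- pmin(pmax(seq_len(h) + di, 1), h)
    sj <- pmin(pmax(seq_len(w) + dj, 1), w)
    is_max <- is_max & resp >= resp[si, sj]
  }
  # exclude the border where the centroid patch would clip
  is_max[c(1:2, (h - 1):h), ] <- FALSE
  is_max[, c(1:2, (w - 1):w)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(x_px = numeric(0), y_px = numeric(0),
                                        response = numeric(0)))
  out <- data.frame(x_px = numeric(nrow(idx)), y_px = numeric(nrow(idx)),
                    response = numeric(nrow(idx)))
  for (s in seq_len(nrow(idx))) {
    i <- idx[s, 1]; j <- idx[s, 2]
    patch <- resp[(i - 2):(i + 2), (j - 2):(j + 2)]
    patch <- pmax(patch - min(patch), 0)
    tot <- sum(patch)
    out$y_px[s] <- i + sum(patch * ((-2):2)) / tot
    out$x_px[s] <- j + sum(t(patch) * ((-2):2)) / tot
    out$response[s] <- resp[i, j]
  }
  out
}

#' Detect and link puncta into trajectories
#'
#' Per-frame LoG spot detection followed by greedy mutual-nearest-neighbour
#' linking: a detection in frame `k+1` is linked to an active track if each
#' is the other's nearest candidate within `max_disp` px; ties are broken
#' by smallest displacement, then lowest particle id. With `memory > 0` a
#' track missing from up to `memory` consecutive frames may be resumed
#' within a proportionally enlarged search radius (gap closing).
#'
#' @param movie a [ccs_movie()] with at least 2 frames.
#' @param spot_sigma expected spot width, px.
#' @param detect_threshold relative detection threshold.
#' @param max_disp maximum frame-to-frame displacement, px.
#' @param memory frames a track may vanish and still be resumed.
#' @return List of `trajectory` objects: data.frames `(frame, x_px, y_px)`
#'   with attributes `particle`, `pixel_size`, `frame_interval`.
#' @export
detect_and_link <- function(movie, spot_sigma = 1.5, detect_threshold = 0.2,
                            max_disp = 5, memory = 0L) {
  nt <- dim(movie)[3]
  if (nt < 2L) stop("movie must have at least 2 frames")
  dets <- lapply(seq_len(nt), function(k)
    detect_spots(movie_frame(movie, k), sigma = spot_sigma,
                 threshold = detect_threshold))
  if (all(vapply(dets, nrow, 1L) == 0L))
    stop("no detections in any frame")
  # active track state: id, last frame, last position
  tracks <- list()
  active <- data.frame(id = integer(0), last_frame = integer(0),
                       x = numeric(0), y = numeric(0))
  next_id <- 1L
  for (k in seq_len(nt)) {
    d <- dets[[k]]
    nd <- nrow(d)
    assigned_det <- rep(FALSE, nd)
    if (nrow(active) > 0 && nd > 0) {
      gap <- k - active$last_frame
      usable <- gap <= memory + 1L
      # candidate pairs within the (gap-scaled) search radius
      cand <- NULL
      for (a in which(usable)) {
        dist <- sqrt((d$x_px - active$x[a])^2 + (d$y_px - active$y[a])^2)
        lim <- max_disp * gap[a]
        ok <- which(dist <= lim)
        if (length(ok))
          cand <- rbind(cand, data.frame(a = a, det = ok, dist = dist[ok]))
      }
      if (!is.null(cand)) {
        cand <- cand[order(cand$dist, active$id[cand$a]), ]
        used_a <- rep(FALSE, nrow(active))
        for (r in seq_len(nrow(cand))) {
          a <- cand$a[r]; dd <- cand$det[r]
          if (used_a[a] || assigned_det[dd]) next
          # mutual nearest: this is the globally shortest remaining link
          # involving either endpoint, so greedy order enforces mutuality
          used_a[a] <- TRUE; assigned_det[dd] <- TRUE
          id <- active$id[a]
          tracks[[id]] <- rbind(tracks[[id]],
                                data.frame(frame = k, x_px = d$x_px[dd],
                                           y_px = d$y_px[dd]))
          active$last_frame[a] <- k
          active$x[a] <- d$x_px[dd]; active$y[a] <- d$y_px[dd]
        }
      }
    }
    # start new tracks from unassigned detections
    if (nd > 0) for (dd in which(!assigned_det)) {
      tracks[[next_id]] <- data.frame(frame = k, x_px = d$x_px[dd],
                                      y_px = d$y_px[dd])
      active <- rbind(active, data.frame(id = next_id, last_frame = k,
                                         x = d$x_px[dd], y = d$y_px[dd]))
      next_id <- next_id + 1L
    }
    # retire tracks whose gap exceeded memory
    active <- active[k - active$last_frame <= memory, , drop = FALSE]
  }
  lapply(seq_along(tracks), function(id)
    structure(tracks[[id]], particle = id,
              pixel_size = attr(movie, "pixel_size"),
              frame_interval = attr(movie, "frame_interval"),
              class = c("trajectory", "data.frame")))
}

#' Construct a trajectory from positions
#'
#' @param frame integer frame indices, strictly increasing.
#' @param x_px,y_px positions in px.
#' @param pixel_size,frame_interval calibration (um/px, s).
#' @param particle id label.
#' @return A `trajectory` data.frame.
#' @export
trajectory <- function(frame, x_px, y_px, pixel_size = 0.1,
                       frame_interval = 5, particle = 1L) {
  if (is.unsorted(frame, strictly = TRUE))
    stop("frames must be strictly increasing")
  structure(data.frame(frame = frame, x_px = x_px, y_px = y_px),
            particle = particle, pixel_size = pixel_size,
            frame_interval = frame_interval,
            class = c("trajectory", "data.frame"))
}

#' Mean instantaneous velocity of one trajectory
#'
#' The average, over consecutive observations, of the Euclidean distance
#' moved per frame interval: for each step, `(step length in um) / (step
#' duration in s)`, then the mean of these instantaneous velocities. Steps
#' spanning closed gaps use the true elapsed time.
#'
#' @param traj a `trajectory` (length >= 2).
#' @return Mean instantaneous velocity in um/s.
#' @export
mean_instantaneous_velocity <- function(traj) {
  if (nrow(traj) < 2) stop("trajectory must have at least 2 points")
  px <- attr(traj, "pixel_size"); dt <- attr(traj, "frame_interval")
  steps <- sqrt(diff(traj$x_px)^2 + diff(traj$y_px)^2) * px
  durations <- diff(traj$frame) * dt
  mean(steps / durations)
}

#' Radial displacement of a trajectory relative to the cell center
#'
#' The series `r(t) - r(0)` of distances to the cell center, in um:
#' negative values indicate net movement towards the center (centripetal),
#' positive values movement away from it.
#'
#' @param traj a `trajectory`.
#' @param center `(xc, yc)` px.
#' @return data.frame `(frame, t_s, dr_um)` with `dr_um[1] == 0`.
#' @export
radial_displacement_series <- function(traj, center) {
  px <- attr(traj, "pixel_size"); dt <- attr(traj, "frame_interval")
  r <- sqrt((traj$x_px - center[1])^2 + (traj$y_px - center[2])^2) * px
  data.frame(frame = traj$frame,
             t_s = (traj$frame - traj$frame[1]) * dt,
             dr_um = r - r[1])
}

#' Space-time kymograph along a line
#'
#' Samples the movie's intensity along a fixed line in every frame,
#' averaging over `width` parallel pixel rows perpendicular to the line.
#' The result has one row per frame (time increases downwards) and one
#' column per unit distance along the line, so a punctum moving at
#' constant speed appears as a straight oblique streak while a stalled
#' punctum draws a vertical line.
#'
#' @param movie a [ccs_movie()].
#' @param line `list(c(x0, y0), c(x1, y1))` or a 2x2 matrix (rows =
#'   endpoints) in px.
#' @param width perpendicular averaging width in px (odd, default 3).
#' @return A `T x D` matrix of class `kymograph` with attributes
#'   `pixel_size` and `frame_interval`.
#' @export
kymograph <- function(movie, line, width = 3L) {
  if (is.list(line)) line <- rbind(line[[1]], line[[2]])
  p0 <- line[1, ]; p1 <- line[2, ]
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length line")
  h <- dim(movie)[1]; w <- dim(movie)[2]
  if (any(c(p0, p1) < 1) || p0[1] > w || p1[1] > w || p0[2] > h || p1[2] > h)
    stop("line endpoints must lie inside the image")
  nsamp <- ceiling(len) + 1L
  tpar <- seq(0, 1, length.out = nsamp)
  u <- (p1 - p0) / len                # along-line unit vector (x, y)
  perp <- c(-u[2], u[1])
  offs <- seq_len(width) - (width + 1) / 2
  nt <- dim(movie)[3]
  out <- matrix(0, nt, nsamp)
  base_x <- p0[1] + tpar * len * u[1]
  base_y <- p0[2] + tpar * len * u[2]
  for (k in seq_len(nt)) {
    fr <- movie_frame(movie, k)
    acc <- numeric(nsamp)
    for (o in offs) {
      acc <- acc + bilinear_sample(fr,
                                   matrix(base_x + o * perp[1], 1),
                                   matrix(base_y + o * perp[2], 1))[1, ]
    }
    out[k, ] <- acc / length(offs)
  }
  structure(out, pixel_size = attr(movie, "pixel_size"),
            frame_interval = attr(movie, "frame_interval"),
            class = "kymograph")
}

#' @export
plot.kymograph <- function(x, ...) {
  z <- t(unclass(x))                  # columns = time for image()
  graphics::image(x = seq_len(nrow(z)) * attr(x, "pixel_size"),
                  y = seq_len(ncol(z)) * attr(x, "frame_interval"),
                  z = z, ylim = rev(range(seq_len(ncol(z)) *
                                            attr(x, "frame_interval"))),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = expression("distance (" * mu * "m)"),
                  ylab = "time (s)", useRaster = TRUE, ...)
  invisible(x)
}

#' Write trajectories to CSV
#'
#' @param trajs list of trajectories from [detect_and_link()].
#' @param path output CSV path.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- lapply(trajs, function(tr)
    data.frame(particle = attr(tr, "particle"), frame = tr$frame,
               x_px = tr$x_px, y_px = tr$y_px))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
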