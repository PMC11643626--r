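#' Time-lapse movie container
#'
#' A `ccs_movie` wraps a `H x W x T` array of nonnegative intensities with
#' the spatial and temporal calibration needed to convert pixel/frame
#' quantities to micrometres and seconds. Frames are indexed `[row, col,
#' frame]` with `row` increasing downwards (image convention); a position
#' `(x, y)` in pixels means `(col, row)`.
#'
#' Conceptually the recorded intensity at pixel `(i, j)` in frame `k`
#' decomposes as `I0(i,j,k) = S(i,j) + M(i,j,k)`: a static component `S`
#' (immobile structures, background pool) plus a moving, time-dependent
#' component `M`. The static part carries no motion information but biases
#' windowed cross-correlation towards zero displacement; see
#' [intensity_correct()] for the correction built on this decomposition.
#'
#' @param frames numeric `H x W x T` array, intensities `>= 0`.
#' @param pixel_size pixel size in micrometres per pixel (`> 0`).
#' @param frame_interval time between frames in seconds (`> 0`).
#' @param mask optional `H x W` logical matrix marking the cell interior.
#'
#' @return An object of class `ccs_movie`: the frame array with attributes
#'   `pixel_size`, `frame_interval` and (optionally) `mask`.
#' @seealso [read_movie()], [write_movie()], [intensity_correct()]
#' @export
ccs_movie <- function(frames, pixel_size, frame_interval, mask = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a H x W x T array")
  if (dim(frames)[3] < 2L)
    stop("a movie needs at least 2 frames")
  if (any(frames < 0))
    stop("intensities must be nonnegative")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0 (um/px)")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be > 0 (s)")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == dim(frames)[1:2]))
      stop("`mask` must be a logical H x W matrix matching the frames")
  }
  structure(frames,
            pixel_size = pixel_size,
            frame_interval = frame_interval,
            mask = mask,
            class = "ccs_movie")
}

#' @export
print.ccs_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("ccs_movie: %d x %d px, %d frames\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel size     %.4g um/px\n", attr(x, "pixel_size")))
  cat(sprintf("  frame interval %.4g s\n", attr(x, "frame_interval")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  if (!is.null(attr(x, "mask")))
    cat(sprintf("  mask: %d px inside\n", sum(attr(x, "mask"))))
  invisible(x)
}

n_frames <- function(movie) dim(movie)[3]

#' Extract one frame as a plain matrix
#'
#' @param movie a [ccs_movie()].
#' @param k frame index.
#' @return `H x W` numeric matrix.
#' @export
movie_frame <- function(movie, k) {
  stopifnot(k >= 1L, k <= dim(movie)[3])
  f <- movie[, , k]
  dim(f) <- dim(movie)[1:2]
  f
}

#' Write a movie as a multi-frame TIFF with a calibration sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled to `[0, 1]`; the
#' scale factor together with the pixel size and frame interval is written
#' to a JSON sidecar (`<path>.json`) so that [read_movie()] restores the
#' original intensities and calibration exactly.
#'
#' @param movie a [ccs_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  scale <- max(movie, 1e-12)
  pages <- lapply(seq_len(dim(movie)[3]), function(k) movie_frame(movie, k) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = attr(movie, "pixel_size"),
               frame_interval_s = attr(movie, "frame_interval"),
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path. Calibration is taken from the JSON sidecar if
#'   present, otherwise `pixel_size` and `frame_interval` must be given.
#' @param pixel_size,frame_interval calibration overrides (um/px, s).
#' @return A [ccs_movie()].
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("no calibration sidecar found; supply `pixel_size` and `frame_interval`")
  frames <- simplify2array(pages) * scale
  ccs_movie(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}
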