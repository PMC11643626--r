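#' FRAP trace container
#'
#' A bleach-recovery experiment on one region of interest: the ROI
#' intensity, a whole-cell (reference) intensity tracking acquisition
#' photobleaching, and a background intensity, sampled at common times.
#'
#' @param t_s acquisition times, s.
#' @param roi ROI mean intensity.
#' @param reference whole-cell/reference mean intensity.
#' @param background background intensity (default 0).
#' @param bleach_index index of the first post-bleach frame (`> 1`).
#' @param n_pre number of pre-bleach frames (default `bleach_index - 1`).
#' @return An object of class `frap_trace` (a data.frame with attributes).
#' @export
frap_trace <- function(t_s, roi, reference, background = 0,
                       bleach_index, n_pre = bleach_index - 1L) {
  n <- length(t_s)
  if (length(roi) != n || length(reference) != n)
    stop("all series must have the same length")
  if (length(background) == 1L) background <- rep(background, n)
  if (bleach_index <= 1L || bleach_index > n)
    stop("`bleach_index` must point past at least one pre-bleach frame")
  structure(data.frame(t_s = t_s, roi = roi, reference = reference,
                       background = background),
            bleach_index = as.integer(bleach_index),
            n_pre = as.integer(n_pre),
            class = c("frap_trace", "data.frame"))
}

#' Generate a synthetic FRAP trace with known ground truth
#'
#' Pre-bleach plateau at unit normalized intensity, a single-frame bleach
#' dropping the ROI to `1 - bleach_depth`, then single-exponential
#' recovery towards `floor + mobile_fraction * (1 - floor)` where
#' `floor = 1 - bleach_depth`: with full mobility the trace returns to the
#' pre-bleach plateau, with no mobility it stays at the bleached floor.
#' Optional acquisition photobleaching decays the reference channel (and
#' the ROI with it), which the double normalization must undo.
#'
#' @param mobile_fraction fraction of fluorophores free to exchange, `[0, 1]`.
#' @param tau recovery time constant, s (`> 0`).
#' @param bleach_depth fraction of ROI intensity removed by the bleach.
#' @param pre_frames pre-bleach frames (default 15).
#' @param post_frames post-bleach frames (default 50).
#' @param frame_interval s between frames (default 5.66).
#' @param noise_sd Gaussian noise sd on each channel, normalized units.
#' @param acq_bleach_rate per-frame exponential acquisition-bleaching rate
#'   applied to all channels (0 = off).
#' @param intensity_scale raw-intensity scale factor.
#' @param background constant background level (raw units).
#' @param seed RNG seed.
#' @return A [frap_trace()] with attribute `truth`.
#' @export
generate_frap_trace <- function(mobile_fraction = 0.6, tau = 10,
                                bleach_depth = 0.8, pre_frames = 15L,
                                post_frames = 50L, frame_interval = 5.66,
                                noise_sd = 0, acq_bleach_rate = 0,
                                intensity_scale = 1000, background = 50,
                                seed = 1) {
  if (tau <= 0) stop("`tau` must be > 0")
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("`mobile_fraction` must be in [0, 1]")
  n <- pre_frames + post_frames
  t_s <- (seq_len(n) - 1) * frame_interval
  floor_ <- 1 - bleach_depth
  asym <- floor_ + mobile_fraction * (1 - floor_)
  roi_norm <- c(rep(1, pre_frames),
                floor_ + (asym - floor_) *
                  (1 - exp(-(t_s[(pre_frames + 1):n] -
                               t_s[pre_frames + 1]) / tau)))
  ref_norm <- rep(1, n)
  decay <- exp(-acq_bleach_rate * (seq_len(n) - 1))
  roi <- background + intensity_scale * roi_norm * decay
  ref <- background + intensity_scale * ref_norm * decay
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      roi <- roi + stats::rnorm(n, 0, noise_sd * intensity_scale)
      ref <- ref + stats::rnorm(n, 0, noise_sd * intensity_scale)
    })
  }
  tr <- frap_trace(t_s, roi, ref, background = background,
                   bleach_index = pre_frames + 1L, n_pre = pre_frames)
  attr(tr, "truth") <- list(mobile_fraction = mobile_fraction, tau = tau,
                            bleach_depth = bleach_depth, seed = seed,
                            acq_bleach_rate = acq_bleach_rate)
  tr
}

#' Double (full-scale) normalization of a FRAP trace
#'
#' Background-subtracted ROI intensity divided by the
#' background-subtracted reference intensity — cancelling acquisition
#' photobleaching and gain fluctuations — then scaled so the pre-bleach
#' mean equals 1. The single-normalization variant (no reference division)
#' is selectable.
#'
#' @param trace a [frap_trace()].
#' @param variant `"double"` (default) or `"single"`.
#' @return data.frame `(t_s, norm)` with attribute `bleach_index`.
#' @export
double_normalize <- function(trace, variant = c("double", "single")) {
  variant <- match.arg(variant)
  n_pre <- attr(trace, "n_pre")
  if (n_pre < 2) stop("need at least 2 pre-bleach frames")
  roi <- trace$roi - trace$background
  ref <- trace$reference - trace$background
  if (variant == "double") {
    if (any(ref == 0)) stop("zero reference intensity")
    norm <- roi / ref
  } else {
    norm <- roi
  }
  pre <- mean(norm[seq_len(n_pre)])
  if (pre == 0) stop("zero pre-bleach intensity")
  structure(data.frame(t_s = trace$t_s, norm = norm / pre),
            bleach_index = attr(trace, "bleach_index"),
            class = c("frap_curve", "data.frame"))
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Fits `I(t) = I0 + A * (1 - exp(-(t - t_bleach)/tau))` to the
#' post-bleach portion (nonlinear least squares, Levenberg-Marquardt).
#' The mobile fraction is `(plateau - floor) / (1 - floor)` with
#' `floor = I0` (the fitted post-bleach intensity) and plateau `I0 + A`,
#' taking the pre-bleach level as 1 by construction of the normalization;
#' the half-time of recovery is `tau * log(2)`. Raw mobile-fraction
#' estimates outside `[0, 1]` are clamped and flagged.
#'
#' @param curve result of [double_normalize()] (or any data.frame with
#'   `t_s` and `norm`).
#' @param bleach_index first post-bleach frame (taken from the curve's
#'   attribute when missing).
#' @return list: `mobile_fraction`, `t_half_s`, `tau_s`, `I0`, `plateau`,
#'   `converged`, `clamped`.
#' @export
fit_recovery <- function(curve, bleach_index = attr(curve, "bleach_index")) {
  if (is.null(bleach_index)) stop("`bleach_index` required")
  post <- curve[seq.int(bleach_index, nrow(curve)), ]
  if (nrow(post) < 10) stop("need at least 10 post-bleach frames")
  t0 <- post$t_s[1]
  df <- data.frame(t = post$t_s - t0, y = post$norm)
  i0_start <- df$y[1]
  a_start <- max(stats::median(utils::tail(df$y, 5)) - i0_start, 1e-3)
  tau_start <- max(diff(range(df$t)) / 4, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 + A * (1 - exp(-t / tau)), data = df,
                      start = list(I0 = i0_start, A = a_start,
                                   tau = tau_start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mobile_fraction = NA_real_, t_half_s = NA_real_,
                tau_s = NA_real_, I0 = NA_real_, plateau = NA_real_,
                converged = FALSE, clamped = FALSE))
  cf <- stats::coef(fit)
  i0 <- unname(cf["I0"]); a <- unname(cf["A"]); tau <- unname(cf["tau"])
  plateau <- i0 + a
  mf_raw <- if (abs(1 - i0) < 1e-12) NA_real_ else (plateau - i0) / (1 - i0)
  clamped <- is.finite(mf_raw) && (mf_raw < 0 || mf_raw > 1)
  mf <- min(max(mf_raw, 0), 1)
  list(mobile_fraction = mf, t_half_s = tau * log(2), tau_s = tau,
       I0 = i0, plateau = plateau, converged = TRUE, clamped = clamped)
}

#' Read a FRAP trace from CSV
#'
#' Expects columns `t_s`, `roi`, `reference` and optionally `background`.
#'
#' @param path CSV path.
#' @param bleach_index first post-bleach frame.
#' @return A [frap_trace()].
#' @export
read_frap_trace <- function(path, bleach_index) {
  df <- utils::read.csv(path)
  bg <- if ("background" %in% names(df)) df$background else 0
  frap_trace(df$t_s, df$roi, df$reference, background = bg,
             bleach_index = bleach_index)
}

#' Write a FRAP trace as CSV
#'
#' @param trace a [frap_trace()].
#' @param path output path.
#' @export
write_frap_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
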