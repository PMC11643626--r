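#' Flow-pipeline configuration
#'
#' Bundles every tunable of the end-to-end flow analysis. Defaults follow
#' the package's standard processing chain: three PIV passes 512 -> 128 ->
#' 64 px at 50% overlap, outlier thresholds of 4, an annulus width of 60
#' px and a 24-bin direction histogram.
#'
#' @param passes PIV interrogation window schedule, px (decreasing).
#' @param overlap window overlap fraction.
#' @param deform use full image deformation between passes.
#' @param sd_threshold,median_threshold post-processing thresholds.
#' @param dr_px radial annulus width, px.
#' @param n_bins direction-histogram bins.
#' @param min_valid_frac minimum valid-frame fraction for the time average.
#' @param reference_frame drift-correction reference frame.
#' @param center optional fixed cell center `(x, y)` px; estimated from the
#'   movie when `NULL`.
#' @param seed seed recorded in the run manifest.
#' @param out_dir optional output directory; when set, all stage outputs
#'   and a JSON run manifest are written there.
#' @param write_intermediates also write the corrected movie and per-pair
#'   fields (large) to `out_dir`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(passes = c(512, 128, 64), overlap = 0.5,
                            deform = FALSE, sd_threshold = 4,
                            median_threshold = 4, dr_px = 60, n_bins = 24,
                            min_valid_frac = 0.5, reference_frame = 1L,
                            center = NULL, seed = 1L, out_dir = NULL,
                            write_intermediates = FALSE) {
  cfg <- list(passes = passes, overlap = overlap, deform = deform,
              sd_threshold = sd_threshold, median_threshold = median_threshold,
              dr_px = dr_px, n_bins = n_bins,
              min_valid_frac = min_valid_frac,
              reference_frame = reference_frame, center = center,
              seed = seed, out_dir = out_dir,
              write_intermediates = write_intermediates)
  stopifnot(overlap >= 0, overlap <= 0.75, dr_px > 0, n_bins >= 4,
            sd_threshold > 0, median_threshold > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields not present in the file keep their [pipeline_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  vals <- vals[intersect(names(vals), known)]
  do.call(pipeline_config, vals)
}

#' Run the full flow-analysis pipeline on a movie
#'
#' Executes the complete chain used to quantify punctate flow in a
#' time-lapse movie: translational drift correction, static-background
#' intensity correction, multipass FFT PIV on every consecutive frame
#' pair, per-pair outlier filtering / interpolation / smoothing, time
#' averaging to the steady-state field, cell-center estimation, and
#' finally the radial speed profile `Vr(r)` and the flow-direction
#' histogram `P(theta_dir)`. When `config$out_dir` is set, every stage's
#' tabular output plus a JSON manifest (configuration, seed, package
#' version) is written to disk so a run can be audited or resumed.
#'
#' @param movie a [ccs_movie()] (or path to a TIFF readable by
#'   [read_movie()]).
#' @param config a [pipeline_config()].
#' @return list of class `flow_pipeline_result`: `profile`
#'   ([radial_profile()]), `histogram` ([direction_histogram()]),
#'   `mean_field` (time-averaged [flow_field()]), `fields` (per-pair
#'   fields), `center`, `drift`, `mean_frame`, `config`.
#' @export
run_flow_pipeline <- function(movie, config = pipeline_config()) {
  if (is.character(movie)) movie <- read_movie(movie)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dc <- stage("drift_correction", estimate_and_apply_drift(
    movie, reference = config$reference_frame))
  ic <- stage("intensity_correction", intensity_correct(dc$movie))
  fields <- stage("piv", compute_movie_flow(
    ic$movie, passes = config$passes, overlap = config$overlap,
    deform = config$deform, sd_threshold = config$sd_threshold,
    median_threshold = config$median_threshold))
  mean_field <- stage("time_average",
                      time_average(fields, config$min_valid_frac))
  center <- if (!is.null(config$center)) config$center
  else stage("center", estimate_cell_center(dc$movie))
  profile <- stage("radial_profile",
                   radial_profile(mean_field, center, dr_px = config$dr_px))
  histogram <- stage("direction_histogram",
                     direction_histogram(mean_field, center,
                                         n_bins = config$n_bins))
  res <- structure(list(profile = profile, histogram = histogram,
                        mean_field = mean_field, fields = fields,
                        center = center, drift = dc$drift,
                        mean_frame = ic$mean_frame, config = config),
                   class = "flow_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, movie, ic)
  res
}

# Persist the stage outputs and a run manifest under config$out_dir.
write_pipeline_outputs <- function(res, movie, ic) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(res$config$out_dir, f)
  write_drift_table(res$drift, p("drift.csv"))
  tiff::writeTIFF(res$mean_frame / max(res$mean_frame, 1e-12),
                  p("mean_frame.tif"), bits.per.sample = 32L)
  write_flow_field(res$mean_field, p("mean_field.csv"))
  utils::write.csv(as.data.frame(res$profile), p("radial_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$histogram),
                   p("direction_histogram.csv"), row.names = FALSE)
  if (isTRUE(res$config$write_intermediates)) {
    write_movie(ic$movie, p("corrected.tif"))
    for (k in seq_along(res$fields))
      write_flow_field(res$fields[[k]], p(sprintf("field_%04d.csv", k)))
  }
  manifest <- list(
    package = "ccsflow",
    version = as.character(utils::packageVersion("ccsflow")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(res$config)[!vapply(unclass(res$config), is.null,
                                         TRUE)],
    center = as.numeric(res$center),
    n_frames = dim(movie)[3])
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}

#' @export
print.flow_pipeline_result <- function(x, ...) {
  cat("flow_pipeline_result\n")
  cat(sprintf("  center: (%.1f, %.1f) px\n", x$center[1], x$center[2]))
  cat(sprintf("  modal direction: %.1f deg\n", modal_direction(x$histogram)))
  ok <- !is.na(x$profile$vr_um_s)
  if (any(ok))
    cat(sprintf("  Vr range: [%.4g, %.4g] um/s over %d annuli\n",
                min(x$profile$vr_um_s[ok]), max(x$profile$vr_um_s[ok]),
                sum(ok)))
  invisible(x)
}
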