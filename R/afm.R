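#' AFM force curve container
#'
#' Holds one approach (or approach/retract) curve: base-piezo displacement
#' and cantilever deflection in metres, the cantilever spring constant and
#' the indenter (bead) radius. Channels recorded in volts are converted by
#' the photodetector sensitivity before construction.
#'
#' @param piezo_m base-piezo displacement, m, ordered by increasing
#'   displacement on the approach.
#' @param deflection_m cantilever deflection, m (same length).
#' @param k cantilever spring constant, N/m (`> 0`).
#' @param R indenter (bead) radius, m (`> 0`); default 2.5 um, a 5 um
#'   diameter glass bead.
#' @param segment character vector of `"approach"`/`"retract"` labels, or a
#'   single value recycled.
#' @param sensitivity_nm_V optional detector sensitivity used for the
#'   volt-to-metre conversion, recorded for provenance.
#' @return An object of class `force_curve` (a data.frame with attributes).
#' @export
force_curve <- function(piezo_m, deflection_m, k, R = 2.5e-6,
                        segment = "approach", sensitivity_nm_V = NULL) {
  if (length(piezo_m) != length(deflection_m))
    stop("piezo and deflection channels must have equal length")
  if (k <= 0) stop("spring constant must be > 0")
  if (R <= 0) stop("indenter radius must be > 0")
  structure(data.frame(piezo_m = piezo_m, deflection_m = deflection_m,
                       segment = rep(segment, length.out = length(piezo_m))),
            k = k, R = R, sensitivity_nm_V = sensitivity_nm_V,
            class = c("force_curve", "data.frame"))
}

#' Sneddon spherical-indenter model
#'
#' Force and indentation depth of a rigid sphere of radius `R` pressed into
#' an elastic half-space, parameterized by the contact-circle radius `a`:
#'
#'   `F(a) = E / (1 - nu^2) * ((a^2 + R^2)/2 * log((R + a)/(R - a)) - a R)`
#'   `delta(a) = a/2 * log((R + a)/(R - a))`
#'
#' Both are strictly increasing in `a` on `[0, R)` and diverge as
#' `a -> R`. In the shallow limit `delta << R` they reduce to the Hertz
#' sphere contact `F = (4/3) E/(1 - nu^2) sqrt(R) delta^(3/2)`.
#'
#' @param a contact radius, m, in `[0, R)`; vectorized.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio.
#' @param R indenter radius, m.
#' @return list with `F` (N) and `delta` (m).
#' @export
sneddon_model <- function(a, E, nu = 0.5, R = 2.5e-6) {
  if (any(a < 0) || any(a >= R)) stop("contact radius must satisfy 0 <= a < R")
  lg <- ifelse(a > 0, log((R + a) / (R - a)), 0)
  list(F = E / (1 - nu^2) * ((a^2 + R^2) / 2 * lg - a * R),
       delta = a / 2 * lg)
}

# delta(a) for the spherical indenter; vectorized, delta(0) = 0.
sneddon_depth <- function(a, R) {
  ifelse(a > 0, a / 2 * log((R + a) / (R - a)), 0)
}

#' Invert the Sneddon depth relation
#'
#' Solves `delta(a) = delta` for the contact radius by bracketed
#' root-finding on `[0, R)` to relative tolerance `1e-10`. Vectorized over
#' `delta`.
#'
#' @param delta indentation depth(s), m, `>= 0`.
#' @param R indenter radius, m.
#' @return Contact radius / radii, m.
#' @export
sneddon_contact_radius <- function(delta, R) {
  vapply(delta, function(d) {
    if (d <= 0) return(0)
    upper <- R * (1 - 1e-12)
    if (sneddon_depth(upper, R) < d)
      stop("depth too large for indenter radius (delta(a) diverges at a = R)")
    stats::uniroot(function(a) sneddon_depth(a, R) - d,
                   lower = 0, upper = upper, tol = R * 1e-10)$root
  }, numeric(1))
}

# Sneddon force at given depths for E = 1 Pa (the fit design vector).
sneddon_force_unit <- function(delta, nu, R) {
  a <- sneddon_contact_radius(delta, R)
  sneddon_model(a, E = 1, nu = nu, R = R)$F
}

# Fast spline approximation of the unit-modulus Sneddon force over
# [0, dmax], used inside the contact-point search where the exact inverse
# would be called thousands of times. The final modulus fit always uses
# the exact root-finding inverse.
sneddon_force_unit_spline <- function(nu, R, dmax) {
  dgrid <- seq(0, dmax, length.out = 200)
  fgrid <- sneddon_force_unit(dgrid, nu, R)
  stats::splinefun(dgrid, fgrid, method = "hyman")
}

#' Sneddon force at given indentation depths
#'
#' Convenience wrapper solving `delta -> a` and evaluating `F(a)`.
#'
#' @param delta depths, m.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio.
#' @param R indenter radius, m.
#' @return Forces, N.
#' @export
sneddon_force <- function(delta, E, nu = 0.5, R = 2.5e-6) {
  E * sneddon_force_unit(delta, nu, R)
}

#' Generate a synthetic AFM approach curve
#'
#' Forward-simulates a nanoindentation approach on an elastic cell: a flat
#' pre-contact baseline of piezo travel `contact_offset`, then
#' self-consistent Sneddon contact in which for each piezo position `z`
#' past contact the depth solves `delta + F(delta)/k = z - contact_offset`
#' (the piezo travel is shared between cell deformation and cantilever
#' bending). Gaussian force noise is added to the deflection channel, so
#' `F = k * d_cant` and `delta = d_pz - d_cant` hold exactly for the
#' noise-free part.
#'
#' @param E Young's modulus, Pa (`> 0`).
#' @param R indenter radius, m (`> 0`).
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @param k spring constant, N/m (`> 0`).
#' @param max_depth maximum cell deformation, m (`0 < max_depth < R`).
#' @param n_points samples along the approach.
#' @param noise_sd Gaussian force noise sd, N.
#' @param contact_offset pre-contact piezo travel, m.
#' @param seed RNG seed.
#' @return A [force_curve()] with attribute `truth` recording all inputs.
#' @export
generate_force_curve <- function(E = 1000, R = 2.5e-6, nu = 0.5, k = 0.2,
                                 max_depth = 500e-9, n_points = 400,
                                 noise_sd = 0, contact_offset = 200e-9,
                                 seed = 1) {
  if (E <= 0 || R <= 0 || k <= 0) stop("E, R and k must be > 0")
  if (nu < 0 || nu > 0.5 + 1e-9) stop("nu must be in [0, 0.5]")
  if (max_depth <= 0 || max_depth >= R)
    stop("max_depth must satisfy 0 < max_depth < R")
  f_max <- sneddon_force(max_depth, E, nu, R)
  z_end <- contact_offset + max_depth + f_max / k
  z <- seq(0, z_end, length.out = n_points)
  past <- pmax(0, z - contact_offset)
  delta <- vapply(past, function(zc) {
    if (zc == 0) return(0)
    stats::uniroot(function(d) d + sneddon_force(d, E, nu, R) / k - zc,
                   lower = 0, upper = zc, tol = R * 1e-12)$root
  }, numeric(1))
  f <- sneddon_force(delta, E, nu, R)
  d_cant <- f / k
  if (noise_sd > 0)
    d_cant <- withr::with_seed(seed,
      d_cant + stats::rnorm(n_points, 0, noise_sd) / k)
  fc <- force_curve(piezo_m = z, deflection_m = d_cant, k = k, R = R)
  attr(fc, "truth") <- list(E = E, R = R, nu = nu, k = k,
                            max_depth = max_depth,
                            contact_offset = contact_offset,
                            noise_sd = noise_sd, seed = seed)
  fc
}

#' Convert a force curve to force and deformation
#'
#' `F = k * d_cant`; the cell deformation is the piezo displacement minus
#' the cantilever deflection, `delta = d_pz - d_cant`. If a contact point
#' is given both are referenced to it (force relative to the baseline
#' value, deformation relative to the contact deformation).
#'
#' @param curve a [force_curve()].
#' @param contact optional result of [detect_contact_point()]; if supplied
#'   the output is contact-aligned and baseline-detrended.
#' @return data.frame `(force_N, delta_m)`.
#' @export
force_deformation <- function(curve, contact = NULL) {
  k <- attr(curve, "k")
  f <- k * curve$deflection_m
  delta <- curve$piezo_m - curve$deflection_m
  if (!is.null(contact)) {
    f <- f - (contact$baseline_intercept + contact$baseline_slope *
                curve$piezo_m) * k
    delta <- delta - contact$delta_at_contact
  }
  data.frame(force_N = f, delta_m = delta)
}

#' Detect the contact point of an approach curve
#'
#' The pre-contact region is first linearly detrended (baseline tilt
#' correction). Each candidate contact index then splits the curve into a
#' flat baseline before and a Sneddon-contact region after; the index
#' minimizing the combined residual sum of squares — flat-baseline RSS
#' before plus best-fit Sneddon RSS after — is the contact point. The
#' search is coarse-to-fine: every `stride`-th index first, then
#' exhaustively in the winning neighbourhood.
#'
#' @param curve a [force_curve()] (approach, increasing piezo).
#' @param nu,R model parameters for the trial Sneddon fits.
#' @param max_depth fit depth range used in the trial fits, m.
#' @param snr_min minimum ratio of peak force to baseline noise below
#'   which the curve is declared to never contact.
#' @return list: `index`, `offset_m` (piezo position of contact),
#'   `delta_at_contact`, `baseline_intercept`, `baseline_slope` (both in
#'   deflection metres vs piezo metres).
#' @export
detect_contact_point <- function(curve, nu = 0.5, R = attr(curve, "R"),
                                 max_depth = 500e-9, snr_min = 5) {
  n <- nrow(curve)
  if (n < 20) stop("curve too short for contact detection")
  z <- curve$piezo_m; dc <- curve$deflection_m
  # provisional baseline: first 20% of the approach
  i0 <- max(5L, floor(0.2 * n))
  bl <- stats::lm.fit(cbind(1, z[seq_len(i0)]), dc[seq_len(i0)])
  noise <- stats::sd(bl$residuals)
  dc_detr <- dc - (bl$coefficients[1] + bl$coefficients[2] * z)
  if (max(dc_detr) < snr_min * max(noise, 1e-15))
    stop("no contact detected: curve never rises above the baseline")
  k <- attr(curve, "k")
  funit <- sneddon_force_unit_spline(nu, R, max_depth * 1.2)
  z0 <- NA_real_
  # residual of a trial contact at piezo position z0 (continuous): flat
  # zero baseline before, best-fit Sneddon after, both in deflection units.
  # Force is referenced to the detrended baseline level, not to the noisy
  # sample at z0: the model itself pins F(contact) = 0.
  rss_z <- function(z0) {
    dd <- (z - z0) - dc_detr
    ff <- dc_detr                  # force / k relative to the baseline
    sel <- which(z >= z0 & dd >= 0 & dd <= max_depth)
    if (length(sel) < 5) return(Inf)
    f1 <- funit(dd[sel]) / k
    e_hat <- sum(f1 * ff[sel]) / sum(f1^2)
    if (!is.finite(e_hat) || e_hat <= 0) return(Inf)
    rss_b <- sum(dc_detr[z < z0]^2)
    rss_b + sum((ff[sel] - e_hat * f1)^2)
  }
  # two rounds: the first locates the contact with the provisional
  # baseline, the second re-detrends on the accepted pre-contact region
  # only (at high stiffness the fixed 20% window can overlap the contact)
  for (round in 1:2) {
    cand <- seq(5L, n - 10L)
    stride <- max(1L, floor(length(cand) / 40))
    coarse <- cand[seq(1, length(cand), by = stride)]
    r_coarse <- vapply(z[coarse], rss_z, numeric(1))
    best <- coarse[which.min(r_coarse)]
    fine <- seq(max(5L, best - stride), min(n - 10L, best + stride))
    r_fine <- vapply(z[fine], rss_z, numeric(1))
    ic <- fine[which.min(r_fine)]
    # continuous sub-sample refinement of the contact position
    lo <- z[max(5L, ic - 2L)]; hi <- z[min(n - 10L, ic + 2L)]
    z0 <- if (hi > lo)
      stats::optimize(rss_z, c(lo, hi), tol = (hi - lo) * 1e-6)$minimum
    else z[ic]
    if (!is.finite(rss_z(z0)) || rss_z(z0) > min(r_fine)) z0 <- z[ic]
    ic <- which.min(abs(z - z0))
    if (sum(z < z0) >= 8) {
      pre <- z < z0
      bl <- stats::lm.fit(cbind(1, z[pre]), dc[pre])
      dc_detr <- dc - (bl$coefficients[1] + bl$coefficients[2] * z)
    } else break
  }
  # at contact the deflection equals the baseline line, so the reference
  # deformation is z0 minus the baseline deflection there
  list(index = ic, offset_m = z0,
       delta_at_contact = z0 - (bl$coefficients[1] +
                                  bl$coefficients[2] * z0),
       baseline_intercept = unname(bl$coefficients[1]),
       baseline_slope = unname(bl$coefficients[2]))
}

#' Fit the Young's modulus to contact-aligned force-deformation data
#'
#' Least-squares estimate of `E` in the Sneddon spherical-indenter model
#' with `R` and `nu` held fixed. Because the model force is linear in `E`,
#' the estimate is the exact linear-least-squares projection
#' `E = sum(F_1 * F) / sum(F_1^2)` where `F_1` is the model force at
#' `E = 1` for each measured depth. The fit uses only depths in
#' `[0, max_depth]`.
#'
#' @param force_N measured forces, N, contact-aligned (0 at contact).
#' @param delta_m measured deformations, m, contact-aligned.
#' @param R indenter radius, m.
#' @param nu Poisson ratio (default 0.5, incompressible).
#' @param max_depth maximum deformation included in the fit, m (default
#'   500 nm).
#' @return An object of class `indentation_fit`: list with `E_Pa`, `nu`,
#'   `R`, `n`, `max_depth`, `rms_N` (residual RMS), `contact_radius_m`
#'   (per-sample `a`), `delta_m`, `force_N`, `fitted_N`.
#' @export
fit_youngs_modulus <- function(force_N, delta_m, R = 2.5e-6, nu = 0.5,
                               max_depth = 500e-9) {
  if (length(force_N) != length(delta_m)) stop("mismatched lengths")
  if (max_depth >= R) stop("max_depth must be < R")
  sel <- which(delta_m >= 0 & delta_m <= max_depth)
  if (length(sel) < 10) stop("fewer than 10 samples in the fit range")
  dd <- delta_m[sel]; ff <- force_N[sel]
  f1 <- sneddon_force_unit(dd, nu, R)
  e_hat <- sum(f1 * ff) / sum(f1^2)
  fitted <- e_hat * f1
  structure(list(E_Pa = e_hat, nu = nu, R = R, n = length(sel),
                 max_depth = max_depth,
                 rms_N = sqrt(mean((ff - fitted)^2)),
                 contact_radius_m = sneddon_contact_radius(dd, R),
                 delta_m = dd, force_N = ff, fitted_N = fitted),
            class = "indentation_fit")
}

#' @export
print.indentation_fit <- function(x, ...) {
  cat(sprintf("indentation_fit: E = %.4g Pa (nu = %.2f, R = %.3g um)\n",
              x$E_Pa, x$nu, x$R * 1e6))
  cat(sprintf("  %d samples, depth <= %.0f nm, residual RMS %.3g nN\n",
              x$n, x$max_depth * 1e9, x$rms_N * 1e9))
  invisible(x)
}

#' Analyze one raw force curve end to end
#'
#' Contact-point detection, baseline detrending, conversion to force and
#' deformation, and Sneddon fit of the Young's modulus.
#'
#' @param curve a [force_curve()] (approach segment).
#' @param nu Poisson ratio.
#' @param max_depth fit range, m.
#' @return An `indentation_fit` with the contact-detection result attached
#'   as element `contact`.
#' @export
analyze_force_curve <- function(curve, nu = 0.5, max_depth = 500e-9) {
  keep <- curve$segment == "approach"
  if (!all(keep))
    curve <- force_curve(curve$piezo_m[keep], curve$deflection_m[keep],
                         k = attr(curve, "k"), R = attr(curve, "R"),
                         sensitivity_nm_V = attr(curve, "sensitivity_nm_V"))
  contact <- detect_contact_point(curve, nu = nu, R = attr(curve, "R"),
                                  max_depth = max_depth)
  fd <- force_deformation(curve, contact)
  fit <- fit_youngs_modulus(fd$force_N, fd$delta_m, R = attr(curve, "R"),
                            nu = nu, max_depth = max_depth)
  fit$contact <- contact
  fit
}

#' Per-cell stiffness summary
#'
#' One modulus per cell from a grid of force curves (e.g. a 6x6 map):
#' the median of the per-curve estimates.
#'
#' @param fits list of `indentation_fit`s for one cell.
#' @return list with `E_Pa` (median), `E_mad_Pa`, `n_curves`.
#' @export
summarize_cell_stiffness <- function(fits) {
  e <- vapply(fits, function(f) f$E_Pa, numeric(1))
  list(E_Pa = stats::median(e), E_mad_Pa = stats::mad(e), n_curves = length(e))
}

#' Read a force curve from TSV/CSV
#'
#' Expects columns `piezo_m` and `deflection_m` (metres), or `piezo_V` and
#' `deflection_V` (volts) together with `sensitivity_nm_V` arguments for
#' conversion; an optional `segment` column labels approach/retract.
#'
#' @param path file path (tab- or comma-separated, header required).
#' @param k spring constant, N/m.
#' @param R indenter radius, m.
#' @param sensitivity_nm_V detector sensitivity for volt channels.
#' @param piezo_sensitivity_nm_V base-piezo sensitivity for volt channels.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, k, R = 2.5e-6, sensitivity_nm_V = NULL,
                             piezo_sensitivity_nm_V = sensitivity_nm_V) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (all(c("piezo_m", "deflection_m") %in% names(df))) {
    pz <- df$piezo_m; dc <- df$deflection_m
  } else if (all(c("piezo_V", "deflection_V") %in% names(df))) {
    if (is.null(sensitivity_nm_V))
      stop("volt channels need `sensitivity_nm_V`")
    pz <- df$piezo_V * piezo_sensitivity_nm_V * 1e-9
    dc <- df$deflection_V * sensitivity_nm_V * 1e-9
  } else stop("no recognizable piezo/deflection columns")
  seg <- if ("segment" %in% names(df)) df$segment else "approach"
  force_curve(pz, dc, k = k, R = R, segment = seg,
              sensitivity_nm_V = sensitivity_nm_V)
}

#' Write a force curve as TSV with unit-bearing headers
#'
#' @param curve a [force_curve()].
#' @param path output path.
#' @export
write_force_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Batch-fit a directory of force curves
#'
#' @param dir directory containing TSV/CSV curves.
#' @param k,R,nu,max_depth see [read_force_curve()] and
#'   [analyze_force_curve()].
#' @param pattern filename regexp.
#' @return data.frame `(curve_id, E_Pa, contact_offset_m, rms_N)`.
#' @export
fit_force_curve_dir <- function(dir, k, R = 2.5e-6, nu = 0.5,
                                max_depth = 500e-9, pattern = "\\.(tsv|csv)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  rows <- lapply(files, function(f) {
    fit <- analyze_force_curve(read_force_curve(f, k = k, R = R),
                               nu = nu, max_depth = max_depth)
    data.frame(curve_id = basename(f), E_Pa = fit$E_Pa,
               contact_offset_m = fit$contact$offset_m, rms_N = fit$rms_N)
  })
  do.call(rbind, rows)
}
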