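test_that("force and deformation follow from the raw channels", {
  # d_cant = 0 everywhere: F = 0, delta = d_pz
  pz <- seq(0, 1e-6, length.out = 50)
  fc <- force_curve(pz, rep(0, 50), k = 0.2)
  fd <- force_deformation(fc)
  expect_true(all(fd$force_N == 0))
  expect_equal(fd$delta_m, pz)

  # k = 0.2 N/m, d_cant = 100 nm -> F = 20 nN; d_pz 600 nm -> delta 500 nm
  fc2 <- force_curve(600e-9, 100e-9, k = 0.2)
  fd2 <- force_deformation(fc2)
  expect_equal(fd2$force_N, 20e-9)
  expect_equal(fd2$delta_m, 500e-9)

  expect_error(force_curve(1:3 * 1e-9, 1:2 * 1e-9, k = 0.2), "equal length")
})

test_that("the indenter model obeys its limits and monotonicity", {
  R <- 2.5e-6
  z <- sneddon_model(0, E = 1000, nu = 0.5, R = R)
  expect_equal(z$F, 0); expect_equal(z$delta, 0)

  a <- seq(0, R * 0.98, length.out = 60)
  m <- sneddon_model(a, E = 1000, nu = 0.5, R = R)
  expect_true(all(diff(m$F) > 0))
  expect_true(all(diff(m$delta) > 0))
  expect_error(sneddon_model(R, E = 1000, nu = 0.5, R = R), "a < R")

  # F is linear in E
  m2 <- sneddon_model(a, E = 2000, nu = 0.5, R = R)
  expect_equal(m2$F, 2 * m$F, tolerance = 1e-12)
})

test_that("depth inversion agrees with an independent bisection oracle", {
  R <- 2.5e-6; E <- 1000; nu <- 0.5
  f_pkg <- sneddon_force(100e-9, E, nu, R)
  f_oracle <- sneddon_bisect_oracle(100e-9, E, nu, R)
  expect_equal(f_pkg, f_oracle, tolerance = 1e-8)
  # round trip delta -> a -> delta
  d <- c(1e-9, 50e-9, 300e-9, 500e-9)
  a <- sneddon_contact_radius(d, R)
  expect_equal(ccsflow:::sneddon_depth(a, R), d, tolerance = 1e-9)
})

test_that("shallow indentation matches the Hertz closed form within 1%", {
  R <- 2.5e-6; E <- 1000; nu <- 0.5
  d <- seq(1e-10, 0.01 * R, length.out = 40)
  fs <- sneddon_force(d, E, nu, R)
  fh <- 4 / 3 * E / (1 - nu^2) * sqrt(R) * d^1.5
  expect_true(all(abs(fs - fh) / fh < 0.01))
})

test_that("contact detection recovers known offsets", {
  fc <- generate_force_curve(E = 1000, contact_offset = 200e-9,
                             noise_sd = 0, n_points = 400)
  cp <- detect_contact_point(fc)
  dz <- diff(fc$piezo_m[1:2])
  expect_lt(abs(cp$offset_m - 200e-9), dz)  # within one sample

  # pure flat baseline never contacts
  flat <- force_curve(seq(0, 1e-6, length.out = 100), rep(0, 100), k = 0.2)
  expect_error(detect_contact_point(flat), "no contact")

  # noisy curves at force SNR 20: offset precision is limited by the joint
  # (E, contact) estimation problem; the median error stays within a few
  # sample spacings (~20 nm here), far inside the fitted depth range
  fmax <- sneddon_force(500e-9, 1000, 0.5, 2.5e-6)
  offs <- vapply(1:5, function(s) {
    fcn <- generate_force_curve(E = 1000, contact_offset = 200e-9,
                                noise_sd = fmax / 20, seed = s)
    detect_contact_point(fcn)$offset_m
  }, numeric(1))
  expect_lt(stats::median(abs(offs - 200e-9)), 20e-9)
})

test_that("noiseless round trips recover E to 0.1%", {
  fc <- generate_force_curve(E = 1000, noise_sd = 0)
  fit <- analyze_force_curve(fc)
  expect_equal(fit$E_Pa, 1000, tolerance = 1e-3)
  expect_lt(fit$rms_N, 1e-11)
})

test_that("round trips are near-identity across the physiological range", {
  for (E in c(100, 1000, 10000, 100000)) for (nu in c(0.3, 0.5)) {
    fit <- analyze_force_curve(
      generate_force_curve(E = E, nu = nu, noise_sd = 0), nu = nu)
    expect_equal(fit$E_Pa, E, tolerance = 0.01)
  }
})

test_that("the modulus estimate scales exactly with force", {
  fc <- generate_force_curve(E = 1500, noise_sd = 0)
  cp <- detect_contact_point(fc)
  fd <- force_deformation(fc, cp)
  f1 <- fit_youngs_modulus(fd$force_N, fd$delta_m)
  f3 <- fit_youngs_modulus(3 * fd$force_N, fd$delta_m)
  expect_equal(f3$E_Pa, 3 * f1$E_Pa, tolerance = 1e-12)
})

test_that("E is invariant to a constant pre-alignment channel offset", {
  fc <- generate_force_curve(E = 1200, noise_sd = 0)
  shifted <- force_curve(fc$piezo_m + 3e-8, fc$deflection_m + 3e-8,
                         k = attr(fc, "k"), R = attr(fc, "R"))
  e1 <- analyze_force_curve(fc)$E_Pa
  e2 <- analyze_force_curve(shifted)$E_Pa
  expect_equal(e2, e1, tolerance = 1e-4)
})

test_that("fit range and sample-count guards hold", {
  expect_error(fit_youngs_modulus(1:5 * 1e-9, 1:5 * 1e-9), "10 samples")
  expect_error(fit_youngs_modulus(rep(1e-9, 20), seq(0, 3e-6, length.out = 20),
                                  R = 2.5e-6, max_depth = 3e-6), "max_depth")
})

test_that("per-cell summary takes the median over grid curves", {
  fits <- lapply(c(900, 1000, 1100, 5000), function(e) list(E_Pa = e))
  s <- summarize_cell_stiffness(fits)
  expect_equal(s$E_Pa, 1050)
  expect_equal(s$n_curves, 4)
})

test_that("force curves survive TSV round trips including volt channels", {
  fc <- generate_force_curve(E = 800, noise_sd = 0, n_points = 60)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_curve(fc, path)
  back <- read_force_curve(path, k = 0.2)
  expect_equal(back$piezo_m, fc$piezo_m, tolerance = 1e-12)
  expect_equal(back$deflection_m, fc$deflection_m, tolerance = 1e-12)

  # volt channels with a 50 nm/V sensitivity
  vpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(piezo_V = fc$piezo_m / 50e-9,
                   deflection_V = fc$deflection_m / 50e-9)
  utils::write.table(df, vpath, sep = "\t", row.names = FALSE, quote = FALSE)
  vback <- read_force_curve(vpath, k = 0.2, sensitivity_nm_V = 50)
  expect_equal(vback$piezo_m, fc$piezo_m, tolerance = 1e-12)
})
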