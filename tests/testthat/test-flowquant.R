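unit_model <- function(kind, center = c(101, 101))
  flow_model(kind, center = center, cell_radius = 100,
             speed_profile = function(r) rep(1, length(r)))

test_that("cell center estimation finds disks, pairs and blobs", {
  mask <- matrix(FALSE, 160, 200)
  ii <- matrix(rep(1:160, 200), 160, 200)
  jj <- matrix(rep(1:200, each = 160), 160, 200)
  mask[(jj - 100)^2 + (ii - 80)^2 <= 30^2] <- TRUE
  expect_equal(unname(estimate_cell_center(mask)), c(100, 80),
               tolerance = 1e-6)

  two <- ((jj - 60)^2 + (ii - 40)^2 <= 15^2) |
    ((jj - 140)^2 + (ii - 120)^2 <= 15^2)
  expect_equal(unname(estimate_cell_center(two)), c(100, 80),
               tolerance = 1e-6)
  expect_error(estimate_cell_center(matrix(FALSE, 5, 5)), "empty")

  # off-center bright blob in a movie
  blob <- ccsflow:::render_puncta(120, 120, 83, 41, 100, 3)
  mv <- frames_movie(list(blob, blob))
  cc <- estimate_cell_center(mv)
  expect_lt(abs(cc[1] - 83), 1)
  expect_lt(abs(cc[2] - 41), 1)
})

test_that("pure inward flow gives Vr = -s and all mass at 180 degrees", {
  f <- generate_analytic_flow(unit_model("centripetal"), grid = c(21, 21))
  center <- c(101, 101)
  prof <- radial_profile(f, center, dr_px = 30)
  scale <- f$pixel_size / f$frame_interval
  pop <- prof$n > 0
  expect_true(any(pop))
  expect_equal(prof$vr_um_s[pop], rep(-1 * scale, sum(pop)),
               tolerance = 1e-10)
  expect_equal(prof$vt_um_s[pop], rep(0, sum(pop)), tolerance = 1e-10)

  h <- direction_histogram(f, center)
  expect_equal(modal_direction(h), 180)
  expect_equal(sum(h$count > 0), 1)  # every vector in the 180-degree bin
  expect_equal(sum(h$density) * 15, 1, tolerance = 1e-12)
})

test_that("circular flow gives Vr = 0 and mass at +/-90 degrees", {
  center <- c(101, 101)
  f <- generate_analytic_flow(unit_model("circular_ccw"), grid = c(21, 21))
  prof <- radial_profile(f, center, dr_px = 30)
  pop <- prof$n > 0
  expect_equal(prof$vr_um_s[pop], rep(0, sum(pop)), tolerance = 1e-10)
  expect_equal(abs(prof$vt_um_s[pop]),
               rep(f$pixel_size / f$frame_interval, sum(pop)),
               tolerance = 1e-10)
  expect_equal(modal_direction(direction_histogram(f, center)), 90)

  fcw <- generate_analytic_flow(unit_model("circular_cw"), grid = c(21, 21))
  expect_equal(modal_direction(direction_histogram(fcw, center)), 270)
})

test_that("a linear inward ramp's slope is recovered within 2%", {
  m <- flow_model("centripetal", center = c(101, 101), cell_radius = 100,
                  speed_profile = function(r) 0.01 * r)
  f <- generate_analytic_flow(m, grid = c(41, 41))
  prof <- radial_profile(f, c(101, 101), dr_px = 10)
  pop <- prof$n >= 10
  fit <- stats::lm(vr_um_s ~ r_mid_um, data = prof[pop, ])
  # Vr(r) = -0.01 r px/frame -> slope -0.01 / frame_interval in (um/s)/um
  expect_equal(unname(coef(fit)["r_mid_um"]), -0.01 / f$frame_interval,
               tolerance = 0.02)
})

test_that("isotropic directions give a uniform histogram within the
           multinomial band", {
  n <- 60
  withr::with_seed(71, {
    th <- stats::runif(n * n, 0, 2 * pi)
  })
  f <- make_field(matrix(cos(th), n, n), matrix(sin(th), n, n),
                  x = seq_len(n) * 5 + 1000, y = seq_len(n) * 5 + 1000)
  # center far away so grid angles vary; directions are iid uniform, hence
  # theta_dir is uniform too
  h <- direction_histogram(f, c(0, 0), n_bins = 24)
  band <- stats::qbinom(c(0.005, 0.995), n * n, 1 / 24)
  expect_true(all(h$count >= band[1] & h$count <= band[2]))
})

test_that("quarter-turn rotation leaves Vr(r) and P(theta_dir) unchanged", {
  withr::with_seed(72, {
    vx <- matrix(rnorm(15^2), 15, 15)
    vy <- matrix(rnorm(15^2), 15, 15)
  })
  g <- seq_len(15) * 8
  center <- c(mean(g), mean(g))
  f <- make_field(vx, vy, x = g, y = g)
  # rotate grid and vectors by a quarter turn about the center:
  # position (x,y) -> (y, -x), vector (vx,vy) -> (vy, -vx); on the matrix
  # this is a transpose/reverse remap
  rot_pos <- function(M) t(M[, rev(seq_len(15))])
  f_rot <- make_field(rot_pos(vy), rot_pos(-vx), x = g, y = g)
  p1 <- radial_profile(f, center, dr_px = 16)
  p2 <- radial_profile(f_rot, center, dr_px = 16)
  expect_equal(p2$vr_um_s, p1$vr_um_s, tolerance = 1e-10)
  h1 <- direction_histogram(f, center)
  h2 <- direction_histogram(f_rot, center)
  expect_equal(h2$density, h1$density, tolerance = 1e-12)
})

test_that("scaling vectors scales Vr and leaves the histogram fixed", {
  f <- generate_analytic_flow(unit_model("centripetal"), grid = c(15, 15))
  f3 <- f; f3$vx <- 3 * f3$vx; f3$vy <- 3 * f3$vy
  center <- c(101, 101)
  p1 <- radial_profile(f, center); p3 <- radial_profile(f3, center)
  pop <- p1$n > 0
  expect_equal(p3$vr_um_s[pop], 3 * p1$vr_um_s[pop], tolerance = 1e-12)
  expect_equal(direction_histogram(f3, center)$density,
               direction_histogram(f, center)$density)
})

test_that("empty annuli carry NA and zero-vector fields are rejected", {
  f <- generate_analytic_flow(unit_model("centripetal"), grid = c(5, 5))
  prof <- radial_profile(f, c(101, 101), dr_px = 10)
  expect_true(any(prof$n == 0))
  expect_true(all(is.na(prof$vr_um_s[prof$n == 0])))

  z <- generate_analytic_flow(unit_model("zero"), grid = c(5, 5))
  expect_error(direction_histogram(z, c(101, 101)), "nonzero")
})
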