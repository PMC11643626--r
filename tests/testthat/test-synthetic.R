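test_that("flow model update rules give the documented analytic vectors", {
  unit <- function(kind)
    flow_model(kind, center = c(50, 50), speed = 1,
               speed_profile = function(r) rep(1, length(r)))
  v <- ccsflow:::model_velocity(unit("centripetal"), 60, 50)
  expect_equal(c(v$vx, v$vy), c(-1, 0))
  v <- ccsflow:::model_velocity(unit("circular_ccw"), 60, 50)
  expect_equal(c(v$vx, v$vy), c(0, 1))
  v <- ccsflow:::model_velocity(unit("circular_cw"), 60, 50)
  expect_equal(c(v$vx, v$vy), c(0, -1))
  z <- flow_model("zero", center = c(50, 50))
  v <- ccsflow:::model_velocity(z, c(10, 60, 90), c(20, 50, 80))
  expect_true(all(v$vx == 0) && all(v$vy == 0))
})

test_that("analytic flow fields are valid everywhere and reject bad grids", {
  m <- flow_model("centripetal", center = c(33, 33), cell_radius = 32)
  f <- generate_analytic_flow(m, grid = c(9, 7))
  expect_s3_class(f, "flow_field")
  expect_true(all(f$valid))
  expect_true(all(is.finite(f$vx)))
  expect_error(generate_analytic_flow(m, grid = c(1, 5)), "grid")
})

test_that("stalled jitter-free tracks are constant and static movies freeze", {
  m <- flow_model("stalled", center = c(40, 40), cell_radius = 30,
                  jitter_sd = 0)
  sim <- generate_ccs_movie(m, n_particles = 20, static_fraction = 0,
                            n_frames = 8, shape = c(80, 80), noise = "none",
                            seed = 5)
  spreads <- tapply(sim$truth$tracks$x_px, sim$truth$tracks$particle,
                    function(x) diff(range(x)))
  expect_true(all(spreads == 0))

  sim2 <- generate_ccs_movie(m, n_particles = 20, static_fraction = 1,
                             n_frames = 5, shape = c(80, 80), noise = "none",
                             seed = 5)
  for (k in 2:5)
    expect_equal(movie_frame(sim2$movie, k), movie_frame(sim2$movie, 1))
})

test_that("constant inward speed moves a particle in by speed per frame", {
  # a particle starting at radius 50 px under 0.3 px/frame inward motion
  # must sit at radius 47 px after 10 frames
  m <- flow_model("centripetal", center = c(100, 100), cell_radius = 60,
                  speed_profile = function(r) rep(0.3, length(r)))
  x <- 150; y <- 100
  for (i in 1:10) {
    v <- ccsflow:::model_velocity(m, x, y)
    x <- x + v$vx; y <- y + v$vy
  }
  expect_equal(sqrt((x - 100)^2 + (y - 100)^2), 47, tolerance = 1e-12)
})

test_that("ground-truth mean speed matches the imposed speed", {
  sp <- 0.4
  m <- flow_model("centripetal", center = c(64, 64), cell_radius = 50,
                  speed_profile = function(r) rep(sp, length(r)),
                  jitter_sd = 0.05)
  sim <- generate_ccs_movie(m, n_particles = 60, static_fraction = 0,
                            n_frames = 30, shape = c(128, 128), seed = 2)
  tr <- sim$truth$tracks
  steps <- unlist(lapply(split(tr, tr$particle), function(d)
    sqrt(diff(d$x_px)^2 + diff(d$y_px)^2)))
  # jitter-driven tolerance: sd/sqrt(n * T)
  tol <- 3 * 0.05 / sqrt(length(steps)) + 0.01
  expect_equal(mean(steps), sp, tolerance = (tol + 0.02) / sp)
})

test_that("movie generation is bit-identical under the same seed", {
  m <- flow_model("centripetal", center = c(40, 40), cell_radius = 30,
                  jitter_sd = 0.1)
  a <- generate_ccs_movie(m, n_particles = 15, n_frames = 4,
                          shape = c(80, 80), seed = 99)
  b <- generate_ccs_movie(m, n_particles = 15, n_frames = 4,
                          shape = c(80, 80), seed = 99)
  expect_identical(unclass(a$movie), unclass(b$movie))
  expect_identical(a$truth$tracks, b$truth$tracks)
  c_ <- generate_ccs_movie(m, n_particles = 15, n_frames = 4,
                           shape = c(80, 80), seed = 100)
  expect_false(identical(unclass(a$movie), unclass(c_$movie)))
})

test_that("synthetic force curves obey the indenter pair at every sample", {
  fc <- generate_force_curve(E = 2000, R = 2.5e-6, nu = 0.4, k = 0.2,
                             contact_offset = 150e-9, noise_sd = 0)
  truth <- attr(fc, "truth")
  fd <- data.frame(force_N = attr(fc, "k") * fc$deflection_m,
                   delta_m = fc$piezo_m - fc$deflection_m - 150e-9)
  past <- fd$delta_m > 1e-12
  expect_equal(fd$force_N[past],
               sneddon_force(fd$delta_m[past], 2000, 0.4, 2.5e-6),
               tolerance = 1e-9)
  # pre-contact baseline is flat zero force
  expect_true(all(abs(fd$force_N[fc$piezo_m < 150e-9]) < 1e-18))
})

test_that("force generation scales linearly in E and rejects deep contact", {
  f1 <- generate_force_curve(E = 1000, noise_sd = 0)
  f2 <- generate_force_curve(E = 2000, noise_sd = 0)
  # compare forces at matched depth, not matched piezo position
  d1 <- f1$piezo_m - f1$deflection_m
  fd1 <- approx(d1, f1$deflection_m * 0.2, xout = 400e-9)$y
  expect_equal(sneddon_force(400e-9, 2000, 0.5, 2.5e-6),
               2 * sneddon_force(400e-9, 1000, 0.5, 2.5e-6))
  expect_gt(max(f2$deflection_m), max(f1$deflection_m))
  expect_error(generate_force_curve(max_depth = 3e-6, R = 2.5e-6),
               "max_depth")
})

test_that("synthetic FRAP traces hit their closed-form values", {
  # full mobility: asymptote returns to the pre-bleach plateau
  tr <- generate_frap_trace(mobile_fraction = 1, tau = 5, noise_sd = 0)
  nc <- double_normalize(tr)
  expect_equal(utils::tail(nc$norm, 1), 1, tolerance = 1e-3)
  # no mobility: flat at the post-bleach floor
  tr0 <- generate_frap_trace(mobile_fraction = 0, bleach_depth = 0.8,
                             noise_sd = 0)
  nc0 <- double_normalize(tr0)
  post <- nc0$norm[attr(tr0, "bleach_index"):nrow(nc0)]
  expect_true(all(abs(post - 0.2) < 1e-9))
  # closed form at t = tau after the bleach
  tr6 <- generate_frap_trace(mobile_fraction = 0.6, tau = 10,
                             bleach_depth = 0.8, frame_interval = 5,
                             noise_sd = 0)
  nc6 <- double_normalize(tr6)
  bi <- attr(tr6, "bleach_index")
  t_rel <- nc6$t_s - nc6$t_s[bi]
  at10 <- approx(t_rel[bi:nrow(nc6)], nc6$norm[bi:nrow(nc6)], xout = 10)$y
  floor_ <- 0.2
  expected <- floor_ + 0.6 * (1 - floor_) * (1 - exp(-10 / 10))
  expect_equal(at10, expected, tolerance = 1e-9)
})
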