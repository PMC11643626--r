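make_pair <- function(dx = 8, dy = 0, n = 256, seed = 21) {
  big <- smooth_texture(n + 40, seed = seed)
  a <- big[21:(n + 20), 21:(n + 20)]
  b <- big[(21 - dy):(n + 20 - dy), (21 - dx):(n + 20 - dx)]
  list(a = a, b = b)
}

test_that("identical frames give an identically zero field", {
  p <- make_pair(0, 0)
  f <- compute_flow_pair(p$a, p$a, passes = c(256, 128, 64))
  expect_true(all(f$valid))
  expect_lt(max(abs(c(f$vx, f$vy))), 1e-10)
})

test_that("a known integer translation is recovered within 0.1 px", {
  p <- make_pair(8, 0)
  f <- compute_flow_pair(p$a, p$b, passes = c(256, 128, 64))
  expect_true(all(abs(f$vx[f$valid] - 8) < 0.1))
  expect_true(all(abs(f$vy[f$valid]) < 0.1))
})

test_that("oversized first windows shrink with a warning", {
  p <- make_pair(2, 1, n = 128)
  expect_warning(f <- compute_flow_pair(p$a, p$b, passes = c(512, 64)),
                 "shrunk")
  expect_true(all(abs(f$vx[f$valid] - 2) < 0.15))
  expect_true(all(abs(f$vy[f$valid] - 1) < 0.15))
})

test_that("a fully masked image yields no valid vectors", {
  p <- make_pair(0, 0, n = 128)
  mask <- matrix(FALSE, 128, 128)
  f <- compute_flow_pair(p$a, p$a, passes = c(128, 64), mask = mask)
  expect_equal(sum(f$valid), 0)
})

test_that("swapping frame order negates the field", {
  p <- make_pair(5, -3)
  f1 <- compute_flow_pair(p$a, p$b, passes = c(256, 128, 64))
  f2 <- compute_flow_pair(p$b, p$a, passes = c(256, 128, 64))
  ok <- f1$valid & f2$valid
  expect_true(all(abs(f1$vx[ok] + f2$vx[ok]) < 0.2))
  expect_true(all(abs(f1$vy[ok] + f2$vy[ok]) < 0.2))
})

test_that("window deformation refines the offset-seeded estimate", {
  p <- make_pair(6, 2)
  f <- compute_flow_pair(p$a, p$b, passes = c(256, 128, 64), deform = TRUE)
  expect_true(all(abs(f$vx[f$valid] - 6) < 0.15))
  expect_true(all(abs(f$vy[f$valid] - 2) < 0.15))
})

test_that("uniform fields are fixed points of post-processing", {
  vx <- matrix(2, 8, 8); vy <- matrix(-1, 8, 8)
  f <- make_field(vx, vy)
  g <- postprocess_flow(f)
  expect_equal(g$vx, vx, tolerance = 1e-12)
  expect_equal(g$vy, vy, tolerance = 1e-12)
  expect_true(all(g$valid))
  expect_equal(sum(g$interpolated), 0)
})

test_that("a lone outlier is replaced by a neighbourhood-consistent value", {
  withr::with_seed(31, {
    vx <- matrix(rnorm(100, 2, 0.05), 10, 10)
    vy <- matrix(rnorm(100, 0, 0.05), 10, 10)
  })
  vx_out <- vx; vx_out[5, 5] <- 2 + 10 * stats::sd(vx) * 10
  f <- postprocess_flow(make_field(vx_out, vy), smooth = FALSE)
  expect_true(f$interpolated[5, 5])
  expect_gt(f$vx[5, 5], min(vx[4:6, 4:6]) - 0.1)
  expect_lt(f$vx[5, 5], max(vx[4:6, 4:6]) + 0.1)
  # far-away vectors untouched when smoothing is off
  expect_equal(f$vx[1, 1], vx[1, 1], tolerance = 1e-12)
  expect_equal(f$vx[10, 10], vx[10, 10], tolerance = 1e-12)
})

test_that("clean fields pass filters untouched before smoothing", {
  withr::with_seed(32, {
    vx <- matrix(rnorm(64, 1, 0.02), 8, 8)
    vy <- matrix(rnorm(64, -1, 0.02), 8, 8)
  })
  f <- postprocess_flow(make_field(vx, vy), smooth = FALSE)
  expect_equal(f$vx, vx, tolerance = 1e-12)
  expect_equal(sum(f$interpolated), 0)
})

test_that("post-processing refuses interpolation with < 4 valid vectors", {
  vx <- matrix(NA_real_, 5, 5); vy <- vx
  valid <- matrix(FALSE, 5, 5)
  vx[1, 1] <- 1; vy[1, 1] <- 0; valid[1, 1] <- TRUE
  f <- make_field(vx, vy, valid = valid)
  expect_warning(g <- postprocess_flow(f), "refused")
  expect_equal(sum(g$valid), 1)
})

test_that("time averaging matches the per-point mean and validity rule", {
  withr::with_seed(41, {
    fs <- lapply(1:6, function(i)
      make_field(matrix(rnorm(36), 6, 6), matrix(rnorm(36), 6, 6)))
  })
  avg <- time_average(fs)
  manual <- Reduce(`+`, lapply(fs, `[[`, "vx")) / 6
  expect_equal(avg$vx, manual, tolerance = 1e-12)

  # N copies of a field average to that field
  same <- time_average(rep(list(fs[[1]]), 4))
  expect_equal(same$vx, fs[[1]]$vx)

  # a field and its negation average to zero
  neg <- fs[[1]]; neg$vx <- -neg$vx; neg$vy <- -neg$vy
  zero <- time_average(list(fs[[1]], neg))
  expect_lt(max(abs(c(zero$vx, zero$vy))), 1e-12)

  # points valid in under half the fields are invalid in the average
  part <- fs
  for (i in 1:4) part[[i]]$valid[2, 2] <- FALSE
  avg2 <- time_average(part)
  expect_false(avg2$valid[2, 2])
  expect_error(time_average(list()), "empty")
})

test_that("PIV speed does not exceed the imposed particle speed", {
  sp <- 0.8
  m <- flow_model("uniform_translation", center = c(64, 64), speed = sp,
                  cell_radius = 60, direction = c(1, 0))
  sim <- generate_ccs_movie(m, n_particles = 60, static_fraction = 0,
                            n_frames = 10, shape = c(128, 128), seed = 17)
  fields <- compute_movie_flow(sim$movie, passes = c(128, 64))
  avg <- time_average(fields)
  speeds <- sqrt(avg$vx[avg$valid]^2 + avg$vy[avg$valid]^2)
  expect_true(all(speeds <= sp * 1.15))
  expect_gt(stats::median(speeds), 0.5 * sp)
})

test_that("flow fields survive a CSV round trip", {
  withr::with_seed(51, f <- make_field(matrix(rnorm(20), 4, 5),
                                       matrix(rnorm(20), 4, 5)))
  f$valid[2, 3] <- FALSE; f$vx[2, 3] <- NA; f$vy[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_field(f, path)
  g <- read_flow_field(path, pixel_size = 0.1, frame_interval = 5)
  expect_equal(g$vx, f$vx, tolerance = 1e-6)
  expect_equal(g$valid, f$valid)
})

test_that("the actin preset maps physical window sizes to passes", {
  p <- actin_piv_passes(pixel_size = 0.05)
  expect_true(all(diff(p) < 0))
  expect_gte(p[length(p)], 10)
  expect_equal(p[1], 20)  # 1.0 um at 0.05 um/px
})
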