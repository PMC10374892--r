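blank_norm <- function(n = 60, h = 1) {
  structure(list(values = matrix(0, n, n), reference_max = 1,
                 grid_spacing = h, origin = c(0, 0), mode = "plan_view_2d"),
            class = "norm_polymer")
}

# radially advancing cure front: plateau inside r0, linear ramp over w
radial_cure <- function(n, h, center, r0, w = 12) {
  xs <- igisml:::grid_x(n, h, c(0, 0))
  ys <- igisml:::grid_y(n, h, c(0, 0))
  r <- sqrt(outer(ys - center[2], xs - center[1],
                  function(a, b) a^2 + b^2))
  v <- (r0 + w - r) / w
  v[v < 0] <- 0; v[v > 1] <- 1
  structure(list(values = v, reference_max = 1, grid_spacing = h,
                 origin = c(0, 0), mode = "plan_view_2d"),
            class = "norm_polymer")
}

test_that("a blank field renders as uniform background", {
  cam <- camera_model(noise_sigma = 0)
  fr <- render_frame(blank_norm(), cam, 0)
  expect_true(all(fr$image == cam$background_level))
  expect_equal(fr$timestamp, 0)
})

test_that("rendering is deterministic without noise and seeded with it", {
  norm <- radial_cure(80, 1, c(40, 40), 20)
  cam0 <- camera_model(noise_sigma = 0)
  expect_identical(render_frame(norm, cam0, 1), render_frame(norm, cam0, 1))
  camn <- camera_model(noise_sigma = 3)
  set.seed(7); a <- render_frame(norm, camn, 1)
  set.seed(7); b <- render_frame(norm, camn, 1)
  expect_identical(a, b)
})

test_that("an advancing front shows a bright band leading a dark band", {
  cam <- camera_model(noise_sigma = 0)
  norm <- radial_cure(120, 1, c(60, 60), 30, w = 16)
  img <- render_frame(norm, cam, 0)$image
  rr <- seq(1, 55, by = 0.5)
  v <- igisml:::sample_bilinear(img, 1, c(0, 0), cbind(60 + rr, rep(60, length(rr))))
  r_dark <- rr[which.min(v)]
  beyond <- rr > r_dark
  expect_lt(min(v), cam$background_level - 10)        # dark edge present
  expect_gt(max(v[beyond]), cam$background_level + 10) # bright halo outside it
  expect_gt(rr[beyond][which.max(v[beyond])], r_dark)  # bright band leads
})

test_that("tracking masks have the analytic annulus area", {
  grid <- list(nrow = 160, ncol = 160, spacing = 1, origin = c(0, 0))
  tm <- build_tracking_mask(circle_shape(c(80, 80), 50), grid, thickness = 10)
  expect_lt(abs(sum(tm$mask) - 2 * pi * 50 * 10) / (2 * pi * 50 * 10), 0.05)
  # minimal thickness on a tiny outline still yields a closed band
  tm2 <- build_tracking_mask(circle_shape(c(80, 80), 3), grid, thickness = 2)
  expect_gt(sum(tm2$mask), 0)
  expect_error(build_tracking_mask(circle_shape(c(80, 80), 200), grid),
               "exceeds the frame")
  expect_error(build_tracking_mask(circle_shape(c(80, 80), 50), grid,
                                   thickness = 1))
})

test_that("tracker values are the exact masked mean and geometry is checked", {
  grid <- list(nrow = 60, ncol = 60, spacing = 1, origin = c(0, 0))
  tm <- build_tracking_mask(circle_shape(c(30, 30), 15), grid, thickness = 6)
  img <- matrix(runif(3600, 0, 255), 60, 60)
  fr <- structure(list(image = img, timestamp = 0.1), class = "frame")
  st <- update_tracker(new_tracker(), fr, tm)
  expect_equal(st$series, sum(img * tm$mask) / sum(tm$mask))
  bad <- structure(list(image = matrix(0, 10, 10), timestamp = 0), class = "frame")
  expect_error(update_tracker(st, bad, tm), "geometries differ")
})

test_that("constant-background frames never trigger", {
  grid <- list(nrow = 40, ncol = 40, spacing = 1, origin = c(0, 0))
  tm <- build_tracking_mask(circle_shape(c(20, 20), 10), grid, thickness = 4)
  st <- new_tracker(rule = "cutoff")
  for (k in 1:30) {
    fr <- structure(list(image = matrix(40, 40, 40), timestamp = k / 100),
                    class = "frame")
    st <- update_tracker(st, fr, tm)
  }
  expect_false(st$triggered)
})

test_that("a synthetic ring crossing the annulus triggers within a frame", {
  grid <- list(nrow = 80, ncol = 80, spacing = 1, origin = c(0, 0))
  tm <- build_tracking_mask(circle_shape(c(40, 40), 20), grid, thickness = 6)
  xs <- igisml:::grid_x(80, 1, c(0, 0))
  ys <- igisml:::grid_y(80, 1, c(0, 0))
  rmat <- sqrt(outer(ys - 40, xs - 40, function(a, b) a^2 + b^2))
  k_cross <- 12L  # ring programmed to reach radius 20 at frame 12
  st <- new_tracker(cutoff = 100, rule = "cutoff", n_baseline = 2)
  trigger_frame <- NA
  for (k in 1:25) {
    ring_r <- 20 * k / k_cross
    img <- matrix(40, 80, 80)
    img[abs(rmat - ring_r) <= 3] <- 255
    fr <- structure(list(image = img, timestamp = k / 100), class = "frame")
    st <- update_tracker(st, fr, tm)
    if (st$triggered && is.na(trigger_frame)) trigger_frame <- k
  }
  expect_false(is.na(trigger_frame))
  expect_lte(abs(trigger_frame - k_cross), 2)
})

test_that("peak rules fire on confirmed maxima of double-bump series", {
  w <- 5L
  for (sep in c(3 * w, 4 * w, 6 * w, 10 * w)) {
    t <- 1:120
    v <- 40 + 80 * exp(-(t - 30)^2 / 18) + 70 * exp(-(t - 30 - sep)^2 / 18)
    expect_identical(length(find_peaks(v, w, prominence = 5)), 2L)
  }
  # monotone rising series below cutoff: no trigger under any rule
  st <- new_tracker(cutoff = 1000, rule = "cutoff")
  grid <- list(nrow = 20, ncol = 20, spacing = 1, origin = c(0, 0))
  tm <- build_tracking_mask(circle_shape(c(10, 10), 5), grid, thickness = 4)
  for (k in 1:40) {
    fr <- structure(list(image = matrix(40 + k, 20, 20), timestamp = k / 100),
                    class = "frame")
    st <- update_tracker(st, fr, tm)
  }
  expect_false(st$triggered)
  expect_false(check_trigger(st, "first_peak"))
  # second-peak rule fires only after the second maximum is confirmed
  t <- 1:100
  v <- 40 + 80 * exp(-(t - 25)^2 / 18) + 70 * exp(-(t - 60)^2 / 18)
  st2 <- new_tracker(rule = "second_peak", peak_window = w)
  fired_at <- NA
  for (k in t) {
    fr <- structure(list(image = matrix(v[k], 20, 20), timestamp = k / 100),
                    class = "frame")
    st2 <- update_tracker(st2, fr, tm)
    if (st2$triggered && is.na(fired_at)) fired_at <- k
  }
  expect_gte(fired_at, 60)
  expect_lte(fired_at, 60 + 2 * w)
})

test_that("multi-pattern tracking reduces to the scalar tracker and rejects overlap", {
  grid <- list(nrow = 60, ncol = 60, spacing = 1, origin = c(0, 0))
  tm1 <- build_tracking_mask(circle_shape(c(20, 30), 8), grid, thickness = 4)
  tm2 <- build_tracking_mask(circle_shape(c(45, 30), 8), grid, thickness = 4)
  frames <- lapply(1:20, function(k)
    structure(list(image = matrix(40 + 5 * k, 60, 60), timestamp = k / 100),
              class = "frame"))
  multi <- multi_pattern_tracking(frames, list(tm1), cutoff = 90, rule = "cutoff")
  solo <- new_tracker(cutoff = 90, rule = "cutoff")
  for (f in frames) solo <- update_tracker(solo, f, tm1)
  expect_equal(multi[[1]]$series, solo$series)
  expect_equal(multi[[1]]$trigger_time, solo$trigger_time)
  tm_overlap <- build_tracking_mask(circle_shape(c(25, 30), 8), grid, thickness = 4)
  expect_error(multi_pattern_tracking(frames, list(tm1, tm_overlap)),
               "overlap")
})

test_that("tracker series round-trip through CSV", {
  st <- new_tracker(cutoff = 50, rule = "cutoff")
  grid <- list(nrow = 20, ncol = 20, spacing = 1, origin = c(0, 0))
  tm <- build_tracking_mask(circle_shape(c(10, 10), 5), grid, thickness = 4)
  for (k in 1:10) {
    fr <- structure(list(image = matrix(10 * k, 20, 20), timestamp = k / 100),
                    class = "frame")
    st <- update_tracker(st, fr, tm)
  }
  f <- tempfile(fileext = ".csv")
  write_tracker_csv(st, f)
  df <- read.csv(f)
  expect_equal(df$value, st$series)
  expect_equal(sum(df$triggered), sum(st$times >= st$trigger_time))
  unlink(f)
})
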