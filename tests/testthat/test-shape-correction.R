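test_that("vertex classification separates tips from trenches", {
  # convex pentagon: all tips
  th <- seq(0, 2 * pi, length.out = 6)[-6]
  pent <- polygon_shape(cbind(cos(th), sin(th)) * 50)
  expect_true(all(pent$vertex_class == "tip"))
  # five-point star: alternating tips and trenches
  star <- as_star <- star_shape(c(0, 0), 5, 150, 60)
  ps <- polygon_shape(star$vertices)
  expect_identical(sum(ps$vertex_class == "tip"), 5L)
  expect_identical(sum(ps$vertex_class == "trench"), 5L)
  expect_true(all(ps$vertex_class[c(TRUE, FALSE)] == "tip"))
  # collinear vertex is regular
  sq <- polygon_shape(cbind(c(0, 5, 10, 10, 0), c(0, 0, 0, 10, 10)))
  expect_identical(sq$vertex_class[2], "regular")
  # self-intersecting input rejected
  bow <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(polygon_shape(bow), "self-intersecting")
})

test_that("squircle gain interpolates between circle and square", {
  expect_equal(squircle_gain(pi / 4, 0), 1)
  expect_equal(squircle_gain(pi / 4, 1), sqrt(2), tolerance = 1e-12)
  expect_equal(squircle_gain(0, 0.7), 1)
  expect_equal(squircle_gain(pi / 2, 0.7), 1)
  # the s = 1 squircle passes through the corner point (r, r):
  # with |V - O| = r along the 45 degree bisector, the remapped vertex is
  # stretched by sqrt(2) and lands exactly on (r, r)
  r <- 10
  O <- c(0, 0)
  V <- r * c(cos(pi / 4), sin(pi / 4))
  corrected <- O + squircle_gain(pi / 4, 1) * (V - O)
  expect_equal(corrected, c(r, r), tolerance = 1e-9)
})

test_that("s = 0 leaves shapes unchanged and corners keep their class", {
  star <- polygon_shape(star_shape(c(0, 0), 5, 150, 60)$vertices)
  out0 <- apply_opc(star, squircle_params(s = 0))
  expect_identical(out0$vertices, star$vertices)
  out <- apply_opc(star, squircle_params(s = 0.8, corner_window = 15))
  expect_true(igisml:::polygon_is_simple(out$vertices))
  expect_identical(sum(out$vertex_class == "tip") >= 5, TRUE)
  expect_identical(sum(out$vertex_class == "trench") >= 5, TRUE)
  # tips pushed outward, trenches cut deeper
  r_out <- max(sqrt(rowSums(out$vertices^2)))
  r_in <- min(sqrt(rowSums(out$vertices^2)))
  expect_gt(r_out, 150)
  expect_lt(r_in, 60)
})

test_that("corrected squares track their mask with a single peak", {
  # a square cured with corner rounding: OPC pre-extends the corners so the
  # rounded result reaches the mask everywhere at once
  sq <- polygon_shape(rect_shape(c(0, 0), 60, 60)$vertices)
  opc <- apply_opc(sq, squircle_params(s = 1, corner_window = 12))
  # rounding operator: radial shrink of corners (cure lags at corners)
  round_corners <- function(poly, amount) {
    v <- poly$vertices
    r <- sqrt(rowSums(v^2))
    # corner regions lose `amount` of radius, edges keep theirs
    cls <- classify_tips_trenches(poly)
    shrink <- ifelse(cls == "tip", amount, 0)
    v * (r - shrink) / r
  }
  cured_naive <- round_corners(sq, 3)
  cured_opc <- round_corners(opc, 3)
  r_naive <- apply(cured_naive, 1, function(p) sqrt(sum(p^2)))
  r_opc <- apply(cured_opc, 1, function(p) sqrt(sum(p^2)))
  # the uncorrected square underfills its corners relative to the target;
  # the corrected one reaches at least the target corner radius
  expect_lt(max(r_naive), sqrt(2) * 30 - 2)
  expect_gte(max(r_opc), sqrt(2) * 30 - 1e-6)
})

test_that("vertex deviations follow similarity geometry", {
  star <- polygon_shape(star_shape(c(0, 0), 5, 150, 60)$vertices)
  # observed contour identical to the outline: all deviations zero
  dev0 <- measure_vertex_deviation(star$vertices, star)
  expect_true(all(abs(dev0$deviation) < 1e-9))
  # observed contour scaled by 1.1 about the centre: deviation = 0.1 r
  dev1 <- measure_vertex_deviation(star$vertices * 1.1, star)
  expect_equal(dev1$deviation, 0.1 * dev1$desired_r, tolerance = 1e-9)
  expect_true(all(dev1$deviation > 0))  # leading everywhere = overfill
  # a contour that misses a ray errors
  tiny <- cbind(c(300, 301, 301, 300), c(300, 300, 301, 301))
  expect_error(measure_vertex_deviation(tiny, star), "intersect")
})

test_that("pattern updates move only out-of-tolerance vertices with the stated signs", {
  star <- polygon_shape(star_shape(c(0, 0), 5, 150, 60)$vertices)
  st <- correction_state(star, gain = 0.8, tolerance = 5, initial_offset = 0)
  # all deviations within tolerance: unchanged and converged
  st$deviations <- measure_vertex_deviation(star$vertices * 1.001, star)
  st2 <- update_pattern(st)
  expect_true(st2$converged)
  expect_identical(st2$projected$vertices, st$projected$vertices)
  # one leading trench: only that trench moves, radially inward
  dev <- measure_vertex_deviation(star$vertices, star)
  dev$deviation <- 0
  tr <- which(dev$class == "trench")[1]
  dev$deviation[tr] <- 8
  st$deviations <- dev
  st3 <- update_pattern(st)
  r_before <- sqrt(rowSums(st$projected$vertices^2))
  r_after <- sqrt(rowSums(st3$projected$vertices^2))
  moved <- which(abs(r_after - r_before) > 1e-9)
  expect_identical(moved, dev$vertex[tr])
  expect_equal(r_after[moved] - r_before[moved], -0.8 * 8, tolerance = 1e-9)
})

test_that("the correction loop contracts on a toy curing operator", {
  star <- polygon_shape(star_shape(c(0, 0), 5, 150, 60)$vertices)
  # toy simulator: the cured contour is the projection, overfilled by +6 um
  # at trenches and underfilled by -6 um at tips
  toy <- function(projected, iteration) {
    v <- projected$vertices
    cls <- classify_tips_trenches(projected)
    r <- sqrt(rowSums(v^2))
    bias <- ifelse(cls == "tip", -6, ifelse(cls == "trench", 6, 0))
    v * (r + bias) / r
  }
  st <- run_dynamic_correction(star, toy, max_iters = 8, tolerance = 2,
                               gain = 0.8, initial_offset = 10)
  expect_true(st$converged)
  maxdev <- vapply(st$history, function(h) max(abs(h$deviation)), numeric(1))
  expect_true(all(diff(maxdev) < 1e-9))
  # a target already achieved at iteration 1 stops immediately
  ident <- function(projected, iteration) projected$vertices
  st0 <- run_dynamic_correction(star, ident, max_iters = 6, tolerance = 5,
                                gain = 0.8, initial_offset = 0)
  expect_true(st0$converged)
  expect_identical(st0$iteration, 1L)
})
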