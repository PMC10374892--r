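test_that("a dark radical-free state is a fixed point", {
  params <- kinetic_params()
  light <- structure(list(values = matrix(0, 8, 8), grid_spacing = 1,
                          origin = c(0, 0)), class = "light_field")
  f0 <- igisml:::new_species_fields(light, params)
  f1 <- step_kinetics(f0, light, params, 0.005)
  expect_equal(f1$S, f0$S)
  expect_equal(f1$R, f0$R)
  expect_equal(f1$M, f0$M)
  expect_equal(f1$P, f0$P)
})

test_that("zero-diffusion kinetics match an independent ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (draw in 1:20) {
    params <- kinetic_params(
      k_i = runif(1, 0.02, 0.3), k_p = runif(1, 0.5, 20),
      k_t = runif(1, 0, 50), gamma_t = runif(1, 0, 10),
      D_R = 0, D_M = 0)
    I <- runif(1, 1, 22)
    want <- ode_oracle(params, I, t_end = 0.2)
    got <- single_cell_run(params, I, t_end = 0.2, dt = 2e-5)
    rel <- abs(got - want) / pmax(abs(want), 1e-8)
    expect_lt(max(rel[c("S", "M", "P")]), 1e-4)
  }
})

test_that("time steps violating the diffusion stability bound are refused", {
  params <- kinetic_params(D_R = 100)
  light <- structure(list(values = matrix(1, 4, 4), grid_spacing = 1,
                          origin = c(0, 0)), class = "light_field")
  f <- igisml:::new_species_fields(light, params)
  expect_error(step_kinetics(f, light, params, dt = 0.01),
               "admissible dt")
  b <- stability_bounds(params, 1, 22)
  expect_equal(b$diffusion, 1 / 400)
  expect_lte(b$dt, 0.9 * b$diffusion + 1e-12)
})

test_that("zero exposure time produces no polymer", {
  res <- quick_exposure(t_end = 0, half = 40)
  expect_true(all(res$fields$P == 0))
  expect_equal(res$time_on, 0)
  expect_true(all(res$norm$values == 0))
})

test_that("monomer plus polymer is conserved under no-flux boundaries", {
  # pure reaction and with monomer diffusion switched on
  for (DM in c(0, 10)) {
    params <- kinetic_params(D_M = DM)
    res <- quick_exposure(params = params, t_end = 0.5, half = 40)
    tot0 <- params$M0 * length(res$fields$M)
    tot1 <- sum(res$fields$M) + sum(res$fields$P)
    expect_lt(abs(tot1 - tot0) / tot0, 1e-6)
  }
})

test_that("species evolve monotonically", {
  params <- kinetic_params()
  res1 <- quick_exposure(params = params, t_end = 0.3, half = 40)
  res2 <- quick_exposure(params = params, t_end = 0.6, half = 40)
  expect_true(all(res2$fields$S <= res1$fields$S + 1e-12))
  expect_true(all(res2$fields$M <= res1$fields$M + 1e-12))
  expect_true(all(res2$fields$P >= res1$fields$P - 1e-12))
})

test_that("normalization is guarded, scale invariant and reaches 1", {
  expect_true(all(normalize_polymer(matrix(0, 3, 3))$values == 0))
  expect_equal(normalize_polymer(matrix(0, 3, 3))$reference_max, 0)
  P <- matrix(runif(25), 5, 5)
  n1 <- normalize_polymer(P)
  n2 <- normalize_polymer(3.7 * P)
  expect_equal(n1$values, n2$values, tolerance = 1e-12)
  expect_equal(max(n1$values), 1)
  expect_error(normalize_polymer(matrix(-1, 2, 2)), "non-negative")
})

test_that("partial-zone extent matches the analytic threshold crossing", {
  # synthetic axisymmetric profile exp(-(r - R)^2 / (2 sigma^2)) outside R
  R <- 17.5; sigma <- 20; h <- 0.5
  r <- (seq_len(400) - 0.5) * h
  prof <- ifelse(r <= R, 1, exp(-(r - R)^2 / (2 * sigma^2)))
  norm <- structure(list(values = matrix(prof, 2, 400, byrow = TRUE),
                         reference_max = 1, grid_spacing = h,
                         origin = c(0, 0), mode = "axisymmetric_rz"),
                    class = "norm_polymer")
  theta <- 0.05
  want <- sigma * sqrt(-2 * log(theta))
  got <- measure_partial_zone_extent(norm, R, theta)
  expect_equal(got, want, tolerance = h)
  expect_error(measure_partial_zone_extent(norm, R, 1.5), "theta")
  # nothing above theta outside the pattern -> extent 0
  norm$values[] <- rep(ifelse(r <= R, 1, 0), each = 2)
  expect_equal(measure_partial_zone_extent(norm, R, theta), 0)
})

test_that("flushing resets liquid, freezes gel, and leaves no memory", {
  params <- kinetic_params()
  res <- quick_exposure(params = params, t_end = 1, half = 60)
  # nothing gelled: flush resets the whole domain
  low <- normalize_polymer(res$fields$P * 0 + 1e-9, reference_max = 1)
  low$values <- res$norm$values * 0.01
  f_reset <- apply_flush(res$fields, low, params)
  expect_true(all(f_reset$S == params$S0))
  expect_true(all(f_reset$M == params$M0))
  expect_true(all(f_reset$P == 0))
  expect_true(all(f_reset$R == 0))
  # everything gelled: fields unchanged except radicals
  high <- res$norm; high$values <- high$values * 0 + 1
  f_keep <- apply_flush(res$fields, high, params)
  expect_equal(f_keep$P, res$fields$P)
  expect_equal(f_keep$M, res$fields$M)
  expect_true(all(f_keep$R == 0))
  expect_true(all(f_keep$solid))
  # statelessness: after a flush, an exposure far from the solid region
  # reproduces the polymer field of an exposure into fresh pre-polymer
  pr <- illumination_profile(22 * 0.24, "graded")
  m <- rasterize_pattern(circle_shape(c(60, 0), 12.5), 2,
                         xlim = c(-120, 120), ylim = c(-120, 120), pad = 0)
  lf <- build_light_field(m, pr)
  dom <- sim_domain("plan_view_2d", extent = c(240, 240), grid_spacing = 2,
                    exposure_time = 1)
  fresh <- run_exposure(dom, lf, params)
  flushed <- igisml:::new_species_fields(lf, params)
  flushed$solid[110:120, 1:10] <- TRUE  # solid block far from the pattern
  flushed$R[] <- 0
  after <- run_exposure(dom, lf, params, fields = flushed)
  live <- !after$fields$solid
  expect_lt(max(abs(after$fields$P[live] - fresh$fields$P[live])) /
              max(fresh$fields$P), 1e-6)
})

test_that("high intensity and short exposure place the polymer maximum on a ring at the pattern edge", {
  params <- kinetic_params(k_i = 2, k_p = 100, k_t = 200, gamma_t = 0,
                           D_R = 10, D_M = 50)
  res <- quick_exposure(params = params, peak = 150, radius = 17.5,
                        t_end = 0.3, h = 1, half = 60, kind = "top_hat")
  rr <- seq(0, 50, by = 0.5)
  v <- igisml:::sample_bilinear(res$fields$P, 1, c(-60, -60), cbind(rr, 0))
  r_at_max <- rr[which.max(v)]
  expect_gt(r_at_max, 12)
  expect_lt(r_at_max, 20)
  expect_gt(max(v) / v[1], 1.05)
})

test_that("bridging between two exposures grows monotonically as the gap shrinks", {
  params <- kinetic_params()
  pr <- illumination_profile(22 * 0.24, "graded")
  mid_levels <- vapply(c(150, 100, 50, 25), function(gap) {
    pitch <- 35 + gap
    half_x <- ceiling((pitch / 2 + 120) / 2) * 2
    m <- rasterize_pattern(list(circle_shape(c(-pitch / 2, 0), 17.5),
                                circle_shape(c(pitch / 2, 0), 17.5)), 2,
                           xlim = c(-half_x, half_x), ylim = c(-120, 120),
                           pad = 0)
    lf <- build_light_field(m, pr)
    dom <- sim_domain("plan_view_2d",
                      extent = c(2 * half_x, 240), grid_spacing = 2,
                      exposure_time = 1)
    res <- run_exposure(dom, lf, params)
    igisml:::sample_bilinear(res$norm$values, 2, c(-half_x, -120),
                             matrix(c(0, 0), 1))
  }, numeric(1))
  expect_true(all(diff(mid_levels) > 0))
})
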