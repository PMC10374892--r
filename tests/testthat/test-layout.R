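test_that("designs round-trip through DXF", {
  des <- device_design(
    cured = list(circle_shape(c(100.123456, 50.654321), 17.5),
                 polygon_shape_simple(cbind(c(0, 40, 40, 0), c(0, 0, 20, 20)))),
    channels = list(rect_shape(c(20, 60), 80, 10)))
  f <- tempfile(fileext = ".dxf")
  write_design_dxf(des, f)
  back <- read_design(f)
  expect_identical(length(back$cured), 2L)
  expect_identical(length(back$channels), 1L)
  expect_equal(back$cured[[1]]$center, des$cured[[1]]$center, tolerance = 1e-6)
  expect_equal(back$cured[[1]]$radius, des$cured[[1]]$radius, tolerance = 1e-6)
  expect_equal(back$cured[[2]]$vertices, des$cured[[2]]$vertices,
               tolerance = 1e-6)
  unlink(f)
})

test_that("open polylines and unsupported entities are rejected loudly", {
  f <- tempfile(fileext = ".dxf")
  writeLines(c("0", "SECTION", "2", "ENTITIES",
               "0", "LWPOLYLINE", "8", "CURE", "90", "3", "70", "0",
               "10", "0", "20", "0", "10", "10", "20", "0", "10", "10", "20", "10",
               "0", "ENDSEC", "0", "EOF"), f)
  expect_error(read_design(f), "open LWPOLYLINE")
  writeLines(c("0", "SECTION", "2", "ENTITIES",
               "0", "SPLINE", "8", "CURE", "5", "AB12",
               "0", "ENDSEC", "0", "EOF"), f)
  expect_error(read_design(f), "SPLINE.*AB12")
  # wrong layer is reported too
  writeLines(c("0", "SECTION", "2", "ENTITIES",
               "0", "CIRCLE", "8", "SCRIBBLE", "10", "0", "20", "0", "40", "5",
               "0", "ENDSEC", "0", "EOF"), f)
  expect_error(read_design(f), "SCRIBBLE")
  unlink(f)
})

test_that("tiling partitions the cured area exactly", {
  # design fitting one tile: single unit, geometry unchanged
  d1 <- device_design(cured = list(circle_shape(c(100, 100), 30)))
  u1 <- tile_design(d1, dmd_field = c(1920, 1080), margin = 100)
  expect_identical(length(u1), 1L)
  a_circle <- polygon_area(shape_vertices(circle_shape(c(100, 100), 30), 180))
  expect_equal(polygon_area(u1[[1]]$shape$vertices), a_circle, tolerance = 1e-9)
  # a wide design split over tiles: clipped pieces sum to the original area
  wide <- device_design(cured = list(
    polygon_shape_simple(cbind(c(0, 3000, 3000, 1500, 0),
                               c(0, 0, 800, 1200, 800)))))
  units <- tile_design(wide, dmd_field = c(1920, 1080), margin = 100)
  expect_gt(length(units), 1L)
  a_sum <- sum(vapply(units, function(u) polygon_area(u$shape$vertices),
                      numeric(1)))
  a_orig <- polygon_area(wide$cured[[1]]$vertices)
  expect_lt(abs(a_sum - a_orig) / a_orig, 1e-6)
  # empty design warns and yields no units
  expect_warning(u0 <- tile_design(device_design()), "empty")
  expect_identical(length(u0), 0L)
})

test_that("stitch expansion dilates masks and protects channels", {
  des <- device_design(
    cured = list(rect_shape(c(50, 50), 40, 40)),
    channels = list(rect_shape(c(50, 90), 200, 20)))
  units <- tile_design(des)
  # expansion 0, no channels: mask equals the plain rasterization
  no_chan <- device_design(cured = des$cured)
  u0 <- stitch_expand(tile_design(no_chan), no_chan, expansion = 0)
  plain <- rasterize_pattern(u0[[1]]$shape, 1,
                             xlim = u0[[1]]$mask$origin[1] +
                               c(0, ncol(u0[[1]]$mask$grid)),
                             ylim = u0[[1]]$mask$origin[2] +
                               c(0, nrow(u0[[1]]$mask$grid)), pad = 0)
  expect_identical(u0[[1]]$mask$grid, plain$grid)
  # expanded mask strictly contains the original and avoids the channel
  ux <- stitch_expand(units, des, expansion = 50)
  m <- ux[[1]]$mask
  expect_gt(sum(m$grid), sum(plain$grid))
  xs <- igisml:::grid_x(ncol(m$grid), m$pixel_pitch, m$origin)
  ys <- igisml:::grid_y(nrow(m$grid), m$pixel_pitch, m$origin)
  on <- which(m$grid > 0, arr.ind = TRUE)
  pts <- cbind(xs[on[, 2]], ys[on[, 1]])
  in_channel <- igisml:::points_in_polygon(pts, des$channels[[1]]$vertices)
  expect_false(any(in_channel))
})

test_that("the 3x3 fixture slices into 7 groups, matching the exhaustive optimum", {
  des <- fixture_design("grid3x3", diameter = 25, gap = 30)  # 55 um pitch
  units <- tile_design(des)
  sched <- slice_schedule(units, d_critical = 150, metric = "center")
  expect_identical(length(sched$slices), 7L)
  adj <- units_conflict_adj(sched$units, 150)
  expect_identical(chromatic_number(adj), 7L)
  expect_true(verify_schedule(sched))
  # every unit scheduled exactly once
  expect_setequal(unlist(sched$slices),
                  vapply(units, function(u) u$unit_id, integer(1)))
  # flush events between consecutive slices only
  expect_identical(sched$flush_after, c(rep(TRUE, 6), FALSE))
})

test_that("greedy slicing is feasible and optimal on random small instances", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(4:9, 1)
    centers <- cbind(runif(n, 0, 400), runif(n, 0, 400))
    cured <- lapply(seq_len(n), function(i) circle_shape(centers[i, ], 10))
    units <- tile_design(device_design(cured = cured))
    d_crit <- runif(1, 60, 250)
    sched <- slice_schedule(units, d_crit, metric = "center")
    expect_true(verify_schedule(sched))
    adj <- units_conflict_adj(sched$units, d_crit)
    n_greedy <- length(sched$slices)
    expect_lte(n_greedy, max(rowSums(adj)) + 1)      # Brooks-style bound
    expect_gte(n_greedy, as.integer(chromatic_number(adj)))
  }
  # single unit: one slice, no flush
  s1 <- slice_schedule(tile_design(device_design(
    cured = list(circle_shape(c(0, 0), 10)))), 150)
  expect_identical(length(s1$slices), 1L)
  expect_identical(s1$flush_after, FALSE)
})

test_that("boundary metric schedules by gap rather than centre distance", {
  cured <- list(circle_shape(c(0, 0), 40), circle_shape(c(150, 0), 40))
  units <- tile_design(device_design(cured = cured))
  # centres 150 apart: no conflict under the centre metric at d_crit 150
  expect_identical(length(slice_schedule(units, 150, "center")$slices), 1L)
  # boundary gap is 70: conflict under the boundary metric
  expect_identical(length(slice_schedule(units, 150, "boundary")$slices), 2L)
})

test_that("DLD lattices follow the row-shift arithmetic", {
  # zero shift: rectangular lattice, columns aligned
  d0 <- generate_dld(dld_spec(pillar_diameter = 30, gap = 26, row_shift = 0,
                              extent = c(300, 300)))
  cx <- vapply(d0$cured, function(s) s$center[1], numeric(1))
  cy <- vapply(d0$cured, function(s) s$center[2], numeric(1))
  expect_identical(length(unique(round(cx[cy == cy[1]], 9))),
                   length(unique(round(cx, 9))))
  # pitch 56, shift 2: displacement pattern repeats every 28 rows
  spec <- dld_spec(pillar_diameter = 30, gap = 26, row_shift = 2,
                   extent = c(120, 56 * 30))
  d <- generate_dld(spec)
  cy <- vapply(d$cured, function(s) s$center[2], numeric(1))
  cx <- vapply(d$cured, function(s) s$center[1], numeric(1))
  rows <- sort(unique(round(cy, 9)))
  shift_of_row <- vapply(rows, function(y) min(cx[round(cy, 9) == y]), numeric(1))
  expect_equal(shift_of_row[29], shift_of_row[1], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(shift_of_row[2], shift_of_row[1])))
  # printed variants are constructible
  expect_s3_class(generate_dld(dld_spec(35, 30, 1.3, extent = c(400, 400))),
                  "device_design")
  expect_s3_class(generate_dld(dld_spec(35, 30, 2.6, extent = c(400, 400))),
                  "device_design")
  expect_error(dld_spec(35, 30, row_shift = 70), "row_shift")
  expect_error(dld_spec(-1, 30, 1))
})

test_that("mask export writes a slice-major index that round-trips", {
  des <- fixture_design("grid3x3")
  units <- stitch_expand(tile_design(des), des, expansion = 0)
  sched <- slice_schedule(units, d_critical = 150)
  outdir <- tempfile("masks")
  idx <- export_masks(sched, outdir)
  expect_identical(nrow(idx), 9L)
  expect_true(all(diff(idx$slice_id) >= 0))  # slice-major ordering
  expect_true(all(file.exists(file.path(outdir, idx$file))))
  # re-importing a mask and its centre reproduces the unit geometry
  row1 <- idx[1, ]
  m <- read_mask_png(file.path(outdir, row1$file),
                     pixel_pitch = row1$pixel_pitch,
                     origin = c(row1$origin_x, row1$origin_y))
  u <- Filter(function(u) u$unit_id == row1$unit_id, sched$units)[[1]]
  expect_lt(max(abs(m$center - u$center)), row1$pixel_pitch)
  expect_identical(sum(m$grid), sum(u$mask$grid))
  # empty schedule: warning plus empty index
  expect_warning(
    idx0 <- export_masks(slice_schedule(list(), 150), tempfile("m0")),
    "empty")
  expect_identical(nrow(idx0), 0L)
  unlink(outdir, recursive = TRUE)
})

test_that("the block-letter text fixture compiles from a drawing without manual steps", {
  des <- fixture_design("lehigh")
  f <- tempfile(fileext = ".dxf")
  write_design_dxf(des, f)
  back <- read_design(f)
  expect_identical(length(back$cured), length(des$cured))
  units <- stitch_expand(tile_design(back), back, expansion = 10)
  sched <- slice_schedule(units, 150)
  expect_gt(length(units), 0)
  expect_true(verify_schedule(sched))
  # no expanded mask pixel intrudes into the channel void
  ch <- back$channels[[1]]$vertices
  for (u in units[1:3]) {
    m <- u$mask
    on <- which(m$grid > 0, arr.ind = TRUE)
    xs <- igisml:::grid_x(ncol(m$grid), m$pixel_pitch, m$origin)
    ys <- igisml:::grid_y(nrow(m$grid), m$pixel_pitch, m$origin)
    pts <- cbind(xs[on[, 2]], ys[on[, 1]])
    expect_false(any(igisml:::points_in_polygon(pts, ch)))
  }
  unlink(f)
})
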