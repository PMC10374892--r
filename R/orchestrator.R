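# End-to-end closed-loop fabrication runs, the in-silico d_critical
# calibration, the reference axisymmetric simulation, the four exposure-mode
# comparison, and the dynamic star-correction driver.
#
# Multi-exposure runs keep one global species state; each exposure is
# integrated on a cropped window that covers the illumination tail plus a
# radical-diffusion pad, so long rows of patterns stay affordable. Cure
# levels across exposures are expressed relative to the polymer maximum of
# an isolated reference exposure of the first unit (P_ref), which plays the
# role of the "fully cured" level when gelling and flushing.

# cure level in [0, 1] relative to the reference polymer maximum, with
# solidified voxels pinned at 1
cure_level <- function(fields, P_ref) {
  lvl <- fields$P / P_ref
  lvl[lvl > 1] <- 1
  lvl[fields$solid] <- 1
  lvl
}

# run a function with a deterministic RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# window reach of one exposure: clamped illumination tail + diffusion pad
exposure_reach <- function(profile, params, t_exp) {
  tail <- if (profile$kind == "graded" && profile$tail_floor > 0)
    profile$tail_scale * log(1 / profile$tail_floor) else 0
  tail + 4 * sqrt(max(params$D_R, params$D_M) * max(t_exp, 0.1)) + 10
}

# zero light field covering a um extent
zero_light <- function(xlim, ylim, h) {
  nx <- as.integer(round((xlim[2] - xlim[1]) / h))
  ny <- as.integer(round((ylim[2] - ylim[1]) / h))
  structure(list(values = matrix(0, ny, nx), grid_spacing = h,
                 origin = c(xlim[1], ylim[1])),
            class = "light_field")
}

# light field for shapes on an exact um window (edges snapped to the grid)
light_for_shapes <- function(shapes, profile, h, xlim, ylim) {
  m <- rasterize_pattern(shapes, pixel_pitch = h, xlim = xlim, ylim = ylim, pad = 0)
  build_light_field(m, profile, grid_spacing = h)
}

crop_fields <- function(fields, rows, cols) {
  out <- fields
  for (nm in c("S", "R", "M", "P")) out[[nm]] <- fields[[nm]][rows, cols, drop = FALSE]
  out$solid <- fields$solid[rows, cols, drop = FALSE]
  out$origin <- c(fields$origin[1] + (cols[1] - 1) * fields$grid_spacing,
                  fields$origin[2] + (nrow(fields$S) - rows[length(rows)]) * fields$grid_spacing)
  out
}

paste_fields <- function(fields, sub, rows, cols) {
  for (nm in c("S", "R", "M", "P")) fields[[nm]][rows, cols] <- sub[[nm]]
  fields$solid[rows, cols] <- sub$solid
  fields$n_clipped <- fields$n_clipped + sub$n_clipped
  fields
}

# index window (rows, cols) covering a um bbox clipped to the grid
window_indices <- function(fields, xlim, ylim) {
  h <- fields$grid_spacing
  nr <- nrow(fields$S); nc <- ncol(fields$S)
  c0 <- max(1L, floor((xlim[1] - fields$origin[1]) / h) + 1L)
  c1 <- min(nc, ceiling((xlim[2] - fields$origin[1]) / h))
  r1 <- max(1L, nr - ceiling((ylim[2] - fields$origin[2]) / h) + 1L)
  r0 <- min(nr, nr - floor((ylim[1] - fields$origin[2]) / h))
  list(rows = r1:r0, cols = c0:c1)
}

window_extent <- function(fields, rows, cols) {
  h <- fields$grid_spacing
  nr <- nrow(fields$S)
  list(xlim = fields$origin[1] + c(cols[1] - 1, cols[length(cols)]) * h,
       ylim = fields$origin[2] + c(nr - rows[length(rows)], nr - rows[1] + 1) * h)
}

# maximum polymer of an isolated exposure of `shapes` (the reference cure)
reference_polymer_max <- function(shapes, profile, params, h, t_exp) {
  bb <- lapply(shapes, shape_bbox)
  xr <- range(vapply(bb, function(b) b$xlim, numeric(2)))
  yr <- range(vapply(bb, function(b) b$ylim, numeric(2)))
  pad <- 4 * sqrt(max(params$D_R, 1) * t_exp) + 20
  xlim <- c(xr[1] - pad, xr[2] + pad)
  ylim <- c(yr[1] - pad, yr[2] + pad)
  xlim <- xlim[1] + c(0, ceiling(diff(xlim) / h) * h)
  ylim <- ylim[1] + c(0, ceiling(diff(ylim) / h) * h)
  light <- light_for_shapes(shapes, profile, h, xlim, ylim)
  dom <- sim_domain("plan_view_2d", extent = c(diff(xlim), diff(ylim)),
                    grid_spacing = h, exposure_time = t_exp)
  res <- run_exposure(dom, light, params)
  max(res$fields$P)
}

#' Fabricate a device design in the closed-loop simulator
#'
#' Compiles the design into projection units, orders them deterministically,
#' and executes one of the four exposure modes against the reaction-diffusion
#' simulator: "single_exposure" projects every unit at once for the fixed
#' dose; "sequential" exposes units one at a time with no flushing;
#' "flush_only" flushes partially cured material after every slice without
#' edge tracking; "tracked_flush" additionally tracks each unit's annular
#' mask and switches its light off at trigger. Tracked units that never
#' trigger are stopped at the hard dose cap and flagged.
#'
#' @param design A [device_design()].
#' @param fc A [fabrication_config()].
#' @return A `fabrication_report`: per-unit table (`units`: order, trigger
#'   time, delivered dose, and the equivalent diameter measured in situ at
#'   the end of that unit's own exposure, the way the live image shows it),
#'   `cure` (final cure-level matrix in
#'   `[0, 1]` with grid metadata), `schedule`, `spread` (max pairwise
#'   equivalent-diameter difference, um), `fidelity` (mean absolute
#'   deviation of measured from designed equivalent diameters, um; the
#'   mode-comparison figure of merit), `P_ref`, `seed` and the config
#'   snapshot.
#' @export
fabricate <- function(design, fc) {
  stopifnot(inherits(design, "device_design"), inherits(fc, "fabrication_config"))
  cfg <- fc$config
  with_seed(fc$seed, {
    units <- tile_design(design, cfg$layout$dmd_field, cfg$layout$margin)
    if (length(units) == 0) {
      return(structure(list(units = data.frame(), cure = NULL, schedule = NULL,
                            spread = NA_real_, P_ref = NA_real_, seed = fc$seed,
                            mode = fc$mode, config = cfg),
                       class = "fabrication_report"))
    }
    schedule <- slice_schedule(units, cfg$layout$d_critical, cfg$layout$metric)
    params <- cfg_kinetics(cfg)
    profile <- cfg_profile(cfg, peak = cfg$optics$peak_intensity * cfg$sim$dose_scale)
    camera <- cfg_camera(cfg)
    h <- cfg$sim$grid_spacing
    t_exp <- cfg$sim$exposure_time
    pad <- cfg$sim$domain_pad
    reach <- exposure_reach(profile, params, t_exp)

    bb <- design$bbox
    xlim <- bb$xlim + c(-pad, pad); ylim <- bb$ylim + c(-pad, pad)
    xlim <- xlim[1] + c(0, ceiling(diff(xlim) / h) * h)
    ylim <- ylim[1] + c(0, ceiling(diff(ylim) / h) * h)
    fields <- new_species_fields(zero_light(xlim, ylim, h), params)

    by_id <- stats::setNames(schedule$units,
                             vapply(schedule$units, function(u) as.character(u$unit_id), ""))
    # spatial (y, x) projection order for the un-sliced modes; the flushing
    # modes follow the slice-major schedule order
    ctrs <- round(t(vapply(schedule$units, function(u) u$center, numeric(2))), 6)
    stg <- round(t(vapply(schedule$units, function(u) u$stage_center, numeric(2))), 6)
    uids <- vapply(schedule$units, function(u) u$unit_id, integer(1))
    flat_order <- uids[order(stg[, 2], stg[, 1], ctrs[, 2], ctrs[, 1], uids)]
    # absolute "fully cured" polymer level: the spatial maximum of an
    # isolated exposure at the full reference dose (gelation is a property
    # of the material, not of the working dose)
    P_ref <- reference_polymer_max(list(by_id[[as.character(flat_order[1])]]$shape),
                                   cfg_profile(cfg, peak = cfg$sim$reference_peak),
                                   params, h, cfg$sim$reference_time)

    expose_unit <- function(fields, u, tracked) {
      sb <- shape_bbox(u$shape)
      wi <- window_indices(fields, sb$xlim + c(-reach, reach), sb$ylim + c(-reach, reach))
      we <- window_extent(fields, wi$rows, wi$cols)
      light <- light_for_shapes(list(u$shape), profile, h, we$xlim, we$ylim)
      sub <- crop_fields(fields, wi$rows, wi$cols)
      t_cap <- if (tracked) cfg$sim$dose_cap_factor * t_exp else t_exp
      dom <- sim_domain("plan_view_2d", extent = c(diff(we$xlim), diff(we$ylim)),
                        grid_spacing = h, exposure_time = t_cap)
      tracker <- NULL
      on_frame <- NULL
      if (tracked) {
        mask <- build_tracking_mask(u$shape,
                                    list(nrow = length(wi$rows), ncol = length(wi$cols),
                                         spacing = h,
                                         origin = c(we$xlim[1], we$ylim[1])),
                                    thickness = cfg$tracker$thickness)
        tracker <- new_tracker(pattern_id = u$unit_id, cutoff = cfg$tracker$cutoff,
                               rule = cfg$tracker$rule,
                               peak_window = cfg$tracker$peak_window)
        on_frame <- function(fl, t) {
          lvl <- cure_level(fl, P_ref)
          nr <- normalize_polymer(lvl * P_ref, reference_max = P_ref)
          nr$grid_spacing <- h; nr$origin <- c(we$xlim[1], we$ylim[1])
          fr <- render_frame(nr, camera, t)
          tracker <<- update_tracker(tracker, fr, mask)
          !tracker$triggered
        }
      }
      res <- run_exposure(dom, light, params, fields = sub,
                          on_frame = on_frame, frame_dt = 1 / camera$fps)
      # inter-exposure dark interval (stage move): remaining radicals decay
      res$fields$R[] <- 0
      fields <- paste_fields(fields, res$fields, wi$rows, wi$cols)
      list(fields = fields, time_on = res$time_on, tracker = tracker)
    }

    # per-unit measurement caps: half the nearest-centre distance, so merged
    # features stay measurable from the live image
    all_ids <- vapply(schedule$units, function(u) u$unit_id, integer(1))
    all_centers <- t(vapply(schedule$units, function(u) u$center, numeric(2)))
    caps <- rep(Inf, length(all_ids))
    if (length(all_ids) > 1) {
      dmat <- as.matrix(stats::dist(all_centers))
      diag(dmat) <- Inf
      caps <- apply(dmat, 1, min) / 2
    }
    # in-situ measurement of one unit's equivalent diameter from the current
    # cure level (this is what the live image shows at that moment)
    measure_unit <- function(fields, uid) {
      j <- which(all_ids == uid)
      lvl <- cure_level(fields, P_ref)
      prof <- try(radial_profile(lvl, center = all_centers[j, ],
                                 spacing = h, origin = c(xlim[1], ylim[1]),
                                 level = params$theta_gel,
                                 r_max = min(caps[j], reach), absolute = TRUE),
                  silent = TRUE)
      if (inherits(prof, "try-error")) NA_real_ else 2 * mean(prof$radii)
    }

    rows <- list()
    if (fc$mode == "single_exposure") {
      # halos of simultaneously projected patterns superpose; the summed
      # intensity is capped at the projector peak
      shapes <- lapply(flat_order, function(id) by_id[[as.character(id)]]$shape)
      acc <- NULL
      for (s in shapes) {
        lf1 <- light_for_shapes(list(s), profile, h, xlim, ylim)
        acc <- if (is.null(acc)) lf1$values else acc + lf1$values
      }
      acc[acc > profile$peak_intensity] <- profile$peak_intensity
      light <- structure(list(values = acc, grid_spacing = h,
                              origin = c(xlim[1], ylim[1])),
                         class = "light_field")
      dom <- sim_domain("plan_view_2d", extent = c(diff(xlim), diff(ylim)),
                        grid_spacing = h, exposure_time = t_exp)
      res <- run_exposure(dom, light, params, fields = fields)
      fields <- res$fields
      for (k in seq_along(flat_order))
        rows[[k]] <- data.frame(unit_id = flat_order[k], order = k,
                                time_on = res$time_on,
                                dose = profile$peak_intensity * res$time_on,
                                triggered = NA, capped = FALSE,
                                diameter = measure_unit(fields, flat_order[k]))
    } else if (fc$mode == "sequential") {
      for (k in seq_along(flat_order)) {
        u <- by_id[[as.character(flat_order[k])]]
        ex <- expose_unit(fields, u, tracked = FALSE)
        fields <- ex$fields
        rows[[k]] <- data.frame(unit_id = u$unit_id, order = k,
                                time_on = ex$time_on,
                                dose = profile$peak_intensity * ex$time_on,
                                triggered = NA, capped = FALSE,
                                diameter = measure_unit(fields, u$unit_id))
      }
    } else {
      tracked <- fc$mode == "tracked_flush"
      k <- 0L
      for (sl in schedule$slices) {
        for (id in sl) {
          u <- by_id[[as.character(id)]]
          ex <- expose_unit(fields, u, tracked = tracked)
          fields <- ex$fields
          k <- k + 1L
          trg <- if (tracked) isTRUE(ex$tracker$triggered) else NA
          rows[[k]] <- data.frame(unit_id = u$unit_id, order = k,
                                  time_on = ex$time_on,
                                  dose = profile$peak_intensity * ex$time_on,
                                  triggered = trg,
                                  capped = tracked && !isTRUE(ex$tracker$triggered),
                                  diameter = measure_unit(fields, u$unit_id))
        }
        norm <- normalize_polymer(fields, reference_max = P_ref)
        fields <- apply_flush(fields, norm, params)
      }
    }

    cure <- cure_level(fields, P_ref)
    unit_tab <- do.call(rbind, rows)
    # designed equivalent diameter per unit (area-equivalent circle)
    des_d <- vapply(unit_tab$unit_id, function(uid) {
      j <- which(all_ids == uid)
      2 * sqrt(polygon_area(shape_vertices(schedule$units[[j]]$shape)) / pi)
    }, numeric(1))
    unit_tab$design_diameter <- des_d
    diam <- unit_tab$diameter
    spread <- if (all(is.na(diam))) NA_real_ else diff(range(diam, na.rm = TRUE))
    fidelity <- if (all(is.na(diam))) NA_real_ else
      mean(abs(diam - des_d), na.rm = TRUE)
    structure(list(units = unit_tab,
                   cure = structure(list(values = cure, grid_spacing = h,
                                         origin = c(xlim[1], ylim[1]),
                                         mode = "plan_view_2d",
                                         reference_max = P_ref),
                                    class = "norm_polymer"),
                   schedule = schedule, spread = spread,
                   fidelity = fidelity, P_ref = P_ref,
                   seed = fc$seed, mode = fc$mode, config = cfg),
              class = "fabrication_report")
  })
}

#' @export
print.fabrication_report <- function(x, ...) {
  cat(sprintf("fabrication_report: mode %s, %d units, spread %.3g um (seed %d)\n",
              x$mode, nrow(x$units), x$spread, x$seed))
  invisible(x)
}

#' In-silico d_critical calibration
#'
#' Reproduces the gap-ladder protocol: per gap, one row of `n_circles`
#' circles of `diameter` um is exposed sequentially (no flushing, no
#' tracking) and the percent change of the last circle's equivalent diameter
#' relative to the first is recorded. The calibrated d_critical is the
#' smallest gap whose deviation is at or below `tolerance` percent; when no
#' gap qualifies the largest tested gap is returned with a warning.
#'
#' @param fc A [fabrication_config()] (its mode is ignored; sequential is
#'   used).
#' @param gaps Gap ladder, um.
#' @param n_circles Circles per row.
#' @param diameter Circle diameter, um.
#' @param tolerance Acceptable deviation, percent.
#' @return A `d_critical_calibration`: `d_critical` (um), `table`
#'   (gap, deviation_pct), and per-gap broadening series.
#' @export
calibrate_d_critical <- function(fc = fabrication_config("sequential"),
                                 gaps = c(25, 50, 100, 150), n_circles = 20,
                                 diameter = 35, tolerance = 5) {
  fc$mode <- "sequential"
  series <- list()
  dev <- numeric(length(gaps))
  for (g in seq_along(gaps)) {
    pitch <- diameter + gaps[g]
    cured <- lapply(seq_len(n_circles) - 1L, function(k)
      circle_shape(c(200 + k * pitch, 200), diameter / 2))
    rep_g <- fabricate(device_design(cured = cured), fc)
    tab <- rep_g$units[order(rep_g$units$order), ]
    bs <- diameter_series(tab$diameter)
    series[[g]] <- bs
    dev[g] <- bs$pct_change[n_circles]
  }
  ok <- which(dev <= tolerance)
  if (length(ok) == 0) {
    warning("no tested gap meets the deviation tolerance; returning the largest")
    d_crit <- max(gaps)
  } else d_crit <- min(gaps[ok])
  structure(list(d_critical = d_crit,
                 table = data.frame(gap = gaps, deviation_pct = dev),
                 series = series, tolerance = tolerance),
            class = "d_critical_calibration")
}

#' @export
print.d_critical_calibration <- function(x, ...) {
  cat(sprintf("d_critical calibration: %g um (tolerance %g%%)\n",
              x$d_critical, x$tolerance))
  print(x$table)
  invisible(x)
}

#' Reference axisymmetric exposure simulation
#'
#' Solves the reaction-diffusion model in r-z for a single circular exposure
#' at the reference configuration (T = 1 s, H = 20 um, R = 17.5 um, peak
#' 22 mW/cm^2), with either perfectly uniform (top-hat) or graded
#' illumination, and reports the bottom-layer normalized profile and the
#' partial-cure zone extent beyond the pattern edge.
#'
#' @param variant "uniform" or "graded".
#' @param cfg Configuration list.
#' @param pattern_radius,height,exposure_time,peak Reference geometry/dose.
#' @param r_extent Radial domain size, um.
#' @param grid_spacing r-z cell size, um.
#' @return List with `norm` (axisymmetric `norm_polymer`), `extent` (um),
#'   `profile` (bottom-layer data.frame r, value) and `fields`.
#' @export
run_reference_simulation <- function(variant = c("graded", "uniform"),
                                     cfg = default_config(),
                                     pattern_radius = 17.5, height = 20,
                                     exposure_time = 1, peak = 22,
                                     r_extent = 220, grid_spacing = 1) {
  variant <- match.arg(variant)
  params <- cfg_kinetics(cfg)
  profile <- cfg_profile(cfg, peak = peak,
                         kind = if (variant == "uniform") "top_hat" else "graded")
  nr <- as.integer(round(r_extent / grid_spacing))
  nz <- as.integer(round(height / grid_spacing))
  r <- (seq_len(nr) - 0.5) * grid_spacing
  I_r <- numeric(nr)
  inside <- r <= pattern_radius
  I_r[inside] <- peak
  if (variant == "graded") {
    tail <- peak * exp(-(r[!inside] - pattern_radius) / profile$tail_scale)
    tail[tail < profile$tail_floor * peak] <- 0
    I_r[!inside] <- tail
  }
  light <- structure(list(values = matrix(I_r, nz, nr, byrow = TRUE),
                          grid_spacing = grid_spacing, origin = c(0, 0)),
                     class = "light_field")
  dom <- sim_domain("axisymmetric_rz", extent = c(r_extent, height),
                    grid_spacing = grid_spacing, height = height,
                    exposure_time = exposure_time)
  res <- run_exposure(dom, light, params)
  extent <- if (exposure_time <= 0) 0 else
    measure_partial_zone_extent(res$norm, pattern_radius, params$theta_partial)
  bottom <- res$norm$values[nz, ]
  list(norm = res$norm, extent = extent,
       profile = data.frame(r = r, value = bottom),
       fields = res$fields)
}

#' Closed-loop dynamic star correction against the curing simulator
#'
#' Runs the project -> simulate -> measure -> update loop on the five-point
#' star fixture (or any classified polygon): each iteration projects the
#' current pattern at a reduced dose, the newly gelled material is added to
#' the solid structure, the partially cured remainder is flushed, and the
#' cure-front contour is measured at the tips and trenches.
#'
#' @param target A `polygon_shape` (default: the star fixture).
#' @param fc A [fabrication_config()] (seed and config sections are used).
#' @param max_iters,tolerance,gain,initial_offset Loop controls (um for
#'   tolerance/offset).
#' @param dose_scale Fraction of the configured peak intensity used for the
#'   purposely slower correction exposures.
#' @return The final `correction_state` (see [run_dynamic_correction()]),
#'   with the accumulated solid cure level attached as `$cure`.
#' @export
run_star_correction <- function(target = NULL,
                                fc = fabrication_config("tracked_flush"),
                                max_iters = 6, tolerance = 5, gain = 0.8,
                                initial_offset = 25, dose_scale = 0.35) {
  cfg <- fc$config
  if (is.null(target)) {
    star <- fixture_design("star")$cured[[1]]
    target <- as_polygon_shape(star)
  } else target <- as_polygon_shape(target)
  params <- cfg_kinetics(cfg)
  profile <- cfg_profile(cfg, peak = cfg$optics$peak_intensity * dose_scale)
  h <- cfg$sim$grid_spacing
  t_exp <- cfg$sim$exposure_time
  pad <- cfg$sim$domain_pad
  P_ref <- reference_polymer_max(list(circle_shape(c(0, 0), 17.5)),
                                 cfg_profile(cfg, peak = cfg$sim$reference_peak),
                                 params, h, cfg$sim$reference_time)
  bb <- shape_bbox(structure(list(kind = "polygon", vertices = target$vertices),
                             class = "shape"))
  xlim <- bb$xlim + c(-pad, pad); ylim <- bb$ylim + c(-pad, pad)
  xlim <- xlim[1] + c(0, ceiling(diff(xlim) / h) * h)
  ylim <- ylim[1] + c(0, ceiling(diff(ylim) / h) * h)
  env <- new.env()
  env$fields <- NULL
  loop <- function(projected, iteration) {
    shp <- structure(list(kind = "polygon", vertices = projected$vertices),
                     class = "shape")
    light <- light_for_shapes(list(shp), profile, h, xlim, ylim)
    dom <- sim_domain("plan_view_2d", extent = c(diff(xlim), diff(ylim)),
                      grid_spacing = h, exposure_time = t_exp)
    res <- run_exposure(dom, light, params, fields = env$fields)
    # gel the freshly cured material against the absolute reference level
    norm <- normalize_polymer(res$fields, reference_max = P_ref)
    env$fields <- apply_flush(res$fields, norm, params)
    lvl <- ifelse(env$fields$solid, 1, 0)
    extract_contour(lvl, level = 0.5, spacing = h, origin = c(xlim[1], ylim[1]),
                    center = target$center)
  }
  state <- with_seed(fc$seed,
                     run_dynamic_correction(target, loop, max_iters = max_iters,
                                            tolerance = tolerance, gain = gain,
                                            initial_offset = initial_offset))
  state$cure <- env$fields
  state
}

#' Simultaneous multi-pattern exposure with independent edge tracking
#'
#' Projects several patterns at once, each with its own peak intensity and
#' annular tracking mask; when a pattern triggers, its contribution is
#' removed from the projected light field while the others continue.
#'
#' @param shapes List of `shape`s (pairwise non-overlapping outlines).
#' @param peaks Peak intensity per pattern, mW/cm^2.
#' @param cfg Configuration list.
#' @param t_cap Hard exposure cap, s.
#' @param seed RNG seed for camera noise.
#' @return List with per-pattern `trackers` (trigger times in
#'   `$trigger_time`), `fields` and `P_ref`.
#' @export
multi_tracked_exposure <- function(shapes, peaks, cfg = default_config(),
                                   t_cap = 5, seed = 1L) {
  stopifnot(length(shapes) == length(peaks))
  params <- cfg_kinetics(cfg)
  camera <- cfg_camera(cfg)
  h <- cfg$sim$grid_spacing
  pad <- cfg$sim$domain_pad
  bbs <- lapply(shapes, shape_bbox)
  xlim <- range(vapply(bbs, function(b) b$xlim, numeric(2))) + c(-pad, pad)
  ylim <- range(vapply(bbs, function(b) b$ylim, numeric(2))) + c(-pad, pad)
  xlim <- xlim[1] + c(0, ceiling(diff(xlim) / h) * h)
  ylim <- ylim[1] + c(0, ceiling(diff(ylim) / h) * h)
  lights <- lapply(seq_along(shapes), function(i)
    light_for_shapes(list(shapes[[i]]), cfg_profile(cfg, peak = peaks[i]),
                     h, xlim, ylim))
  P_ref <- reference_polymer_max(shapes[1],
                                 cfg_profile(cfg, peak = cfg$sim$reference_peak),
                                 params, h, cfg$sim$reference_time)
  grid <- list(nrow = nrow(lights[[1]]$values), ncol = ncol(lights[[1]]$values),
               spacing = h, origin = c(xlim[1], ylim[1]))
  masks <- lapply(shapes, build_tracking_mask, grid = grid,
                  thickness = cfg$tracker$thickness)
  if (length(masks) > 1) {
    acc <- Reduce(`+`, lapply(masks, function(m) m$mask * 1L))
    if (any(acc > 1L)) stop("tracking masks overlap")
  }
  with_seed(seed, {
    trackers <- lapply(seq_along(shapes), function(i)
      new_tracker(pattern_id = i, cutoff = cfg$tracker$cutoff,
                  rule = cfg$tracker$rule, peak_window = cfg$tracker$peak_window))
    active <- rep(TRUE, length(shapes))
    total <- function() {
      v <- lights[[1]]$values * 0
      for (i in which(active)) v <- v + lights[[i]]$values
      structure(list(values = v, grid_spacing = h, origin = c(xlim[1], ylim[1])),
                class = "light_field")
    }
    fields <- new_species_fields(lights[[1]], params)
    dt <- stability_bounds(params, h, max(unlist(peaks)))$dt
    frame_dt <- 1 / camera$fps
    t <- 0; next_frame <- frame_dt
    light <- total()
    while (t < t_cap && any(active)) {
      step <- min(dt, t_cap - t)
      fields <- step_kinetics(fields, light, params, step)
      t <- t + step
      if (t + 1e-12 >= next_frame) {
        next_frame <- next_frame + frame_dt
        nr <- normalize_polymer(cure_level(fields, P_ref) * P_ref,
                                reference_max = P_ref)
        nr$grid_spacing <- h; nr$origin <- c(xlim[1], ylim[1])
        fr <- render_frame(nr, camera, t)
        changed <- FALSE
        for (i in which(active)) {
          trackers[[i]] <- update_tracker(trackers[[i]], fr, masks[[i]])
          if (trackers[[i]]$triggered) { active[i] <- FALSE; changed <- TRUE }
        }
        if (changed) light <- total()
      }
    }
    list(trackers = trackers, fields = fields, P_ref = P_ref)
  })
}

#' Compare the four exposure modes on one design
#'
#' Runs [fabricate()] in all four modes at the comparison dose and collects
#' the fidelity figure of merit (mean absolute deviation of measured from
#' designed equivalent diameters). The comparison is run deliberately
#' overdosed so the proximity effect is visible, which is the situation the
#' closed loop exists to fix.
#'
#' @param design A [device_design()] (default: the 3x3 pillar-grid fixture).
#' @param seed RNG seed.
#' @param dose_scale Fraction of full power used for the fixed-dose
#'   comparison exposures.
#' @param config Base configuration.
#' @return Data frame with one row per mode: `mode`, `fidelity` (um),
#'   `spread` (um); the per-mode reports are attached as an attribute.
#' @export
compare_exposure_modes <- function(design = fixture_design("grid3x3"),
                                   seed = 1L, dose_scale = 0.30,
                                   config = default_config()) {
  config$sim$dose_scale <- dose_scale
  modes <- c("tracked_flush", "flush_only", "sequential", "single_exposure")
  reports <- lapply(modes, function(m)
    fabricate(design, fabrication_config(m, seed = seed, config = config)))
  out <- data.frame(mode = modes,
                    fidelity = vapply(reports, function(r) r$fidelity, numeric(1)),
                    spread = vapply(reports, function(r) r$spread, numeric(1)))
  attr(out, "reports") <- stats::setNames(reports, modes)
  out
}
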