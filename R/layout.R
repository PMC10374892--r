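# Layout compilation: device designs -> tiled projection units -> stitching
# expansion with channel protection -> d_critical slices with flush events ->
# exported masks. Distances in um throughout.

#' Device design container
#'
#' @param cured List of `shape`s to be polymerized (overlaps allowed before
#'   stitching).
#' @param channels List of `shape`s that must remain open channel voids.
#' @return A `device_design` with a cached bounding box.
#' @export
device_design <- function(cured = list(), channels = list()) {
  stopifnot(is.list(cured), is.list(channels))
  bbox <- NULL
  if (length(cured) + length(channels) > 0) {
    bb <- lapply(c(cured, channels), shape_bbox)
    bbox <- list(xlim = range(vapply(bb, function(b) b$xlim, numeric(2))),
                 ylim = range(vapply(bb, function(b) b$ylim, numeric(2))))
  }
  structure(list(cured = cured, channels = channels, bbox = bbox),
            class = "device_design")
}

#' @export
print.device_design <- function(x, ...) {
  cat(sprintf("device_design: %d cured regions, %d channel voids\n",
              length(x$cured), length(x$channels)))
  invisible(x)
}

#' DLD array specification
#'
#' Deterministic lateral displacement geometry: rows of pillars at pitch
#' `pillar_diameter + gap`, each successive row laterally displaced by
#' `row_shift`, wrapping every full pitch.
#'
#' @param pillar_diameter Pillar diameter (or triangle side), um.
#' @param gap Gap between pillar edges, um.
#' @param row_shift Lateral displacement per row, um.
#' @param extent Array extent (x, y) in um.
#' @param pillar_shape "circle" or "triangle".
#' @return A `dld_spec`.
#' @export
dld_spec <- function(pillar_diameter = 29.6, gap = 26.4, row_shift = 2,
                     extent = c(560, 560), pillar_shape = c("circle", "triangle")) {
  pillar_shape <- match.arg(pillar_shape)
  stopifnot(pillar_diameter > 0, gap > 0, row_shift >= 0,
            row_shift < pillar_diameter + gap, all(extent > 0))
  structure(list(pillar_diameter = pillar_diameter, gap = gap,
                 row_shift = row_shift, extent = as.numeric(extent),
                 pillar_shape = pillar_shape),
            class = "dld_spec")
}

#' Generate a DLD pillar array design
#'
#' @param spec A [dld_spec()].
#' @return A [device_design()] with one shape per pillar. Pillar centres
#'   start at half a pitch from the origin; row k (0-based) is shifted by
#'   `(k * row_shift) %% pitch`.
#' @export
generate_dld <- function(spec) {
  stopifnot(inherits(spec, "dld_spec"))
  pitch <- spec$pillar_diameter + spec$gap
  n_cols <- floor(spec$extent[1] / pitch)
  n_rows <- floor(spec$extent[2] / pitch)
  if (n_cols < 1 || n_rows < 1) stop("array extent smaller than one pitch")
  r <- spec$pillar_diameter / 2
  cured <- list()
  for (k in seq_len(n_rows) - 1L) {
    shift <- (k * spec$row_shift) %% pitch
    y <- (k + 0.5) * pitch
    for (j in seq_len(n_cols) - 1L) {
      x <- (j + 0.5) * pitch + shift
      if (x + r > spec$extent[1]) next
      cured <- c(cured, list(
        if (spec$pillar_shape == "circle") circle_shape(c(x, y), r)
        else polygon_shape_simple(cbind(
          x + r * cos(pi / 2 + c(0, 2, 4) * pi / 3),
          y + r * sin(pi / 2 + c(0, 2, 4) * pi / 3)))))
    }
  }
  device_design(cured = cured)
}

#' Read a device design (DXF front end)
#' @param path DXF file path.
#' @return A [device_design()].
#' @export
read_design <- function(path) read_design_dxf(path)

#' Tile a design into projection units
#'
#' A grid of cells `margin` um smaller than the projector field is laid over
#' the design bounding box; every cured shape is clipped to every cell and
#' each non-empty intersection becomes a projection unit with the cell centre
#' as its stage position. Circles are polygonized before clipping so clipped
#' pieces partition the original area exactly.
#'
#' @param design A [device_design()].
#' @param dmd_field Projector field size (x, y) at the sample plane, um.
#' @param margin Stitching margin subtracted from the field per axis, um
#'   (default 100).
#' @return List of `projection_unit`s: `shape` (clipped polygon), `center`
#'   (pattern centroid), `stage_center`, `tile_id`, `unit_id`, `slice_id`.
#' @export
tile_design <- function(design, dmd_field = c(1920, 1080), margin = 100) {
  stopifnot(inherits(design, "device_design"), all(dmd_field > margin))
  if (length(design$cured) == 0) {
    warning("empty design: no projection units")
    return(list())
  }
  cell <- dmd_field - margin
  bb <- design$bbox
  nx <- max(1L, ceiling((bb$xlim[2] - bb$xlim[1]) / cell[1] - 1e-9))
  ny <- max(1L, ceiling((bb$ylim[2] - bb$ylim[1]) / cell[2] - 1e-9))
  units <- list()
  uid <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      xlim <- bb$xlim[1] + c(ix - 1, ix) * cell[1]
      ylim <- bb$ylim[1] + c(iy - 1, iy) * cell[2]
      tile_id <- (iy - 1L) * nx + ix
      for (s in design$cured) {
        v <- shape_vertices(s, n_circle = 180)
        cv <- clip_polygon_rect(v, xlim, ylim)
        if (is.null(cv)) next
        uid <- uid + 1L
        units[[uid]] <- structure(list(
          shape = polygon_shape_simple(cv),
          center = polygon_centroid(cv),
          stage_center = c(mean(xlim), mean(ylim)),
          tile_id = tile_id, unit_id = uid, slice_id = NA_integer_,
          mask = NULL),
          class = "projection_unit")
      }
    }
  }
  units
}

#' Expand unit geometry for stitching and protect channels
#'
#' Each unit's raster mask is dilated by `expansion` um on each side, then
#' the channel voids are subtracted so the channel region stays unaffected.
#' The vector geometry is kept untouched (pre-expansion); the mask is what
#' gets projected.
#'
#' @param units Output of [tile_design()].
#' @param design The originating [device_design()] (for the channels).
#' @param expansion Dilation radius, um (default 50).
#' @param pixel_pitch Mask raster pitch, um/px.
#' @return Units with a `mask` (`pattern_mask`) attached.
#' @export
stitch_expand <- function(units, design, expansion = 50, pixel_pitch = 1) {
  stopifnot(expansion >= 0)
  lapply(units, function(u) {
    pad <- expansion + 2 * pixel_pitch
    bb <- shape_bbox(u$shape)
    xlim <- bb$xlim + c(-pad, pad)
    ylim <- bb$ylim + c(-pad, pad)
    m <- rasterize_pattern(u$shape, pixel_pitch, xlim = xlim, ylim = ylim)
    on <- m$grid > 0
    if (expansion > 0 && any(on)) on <- dilate_mask(on, expansion, pixel_pitch)
    if (length(design$channels) > 0 && any(on)) {
      xs <- grid_x(ncol(on), pixel_pitch, m$origin)
      ys <- grid_y(nrow(on), pixel_pitch, m$origin)
      pts <- cbind(rep(xs, each = nrow(on)), rep(ys, times = ncol(on)))
      for (ch in design$channels) {
        vch <- shape_vertices(ch, n_circle = 180)
        inside <- matrix(points_in_polygon(pts, vch), nrow(on), ncol(on))
        on <- on & !inside
      }
    }
    m$grid <- matrix(as.integer(on), nrow(on), ncol(on))
    m$empty <- !any(on)
    if (!m$empty) {
      xs <- grid_x(ncol(on), pixel_pitch, m$origin)
      ys <- grid_y(nrow(on), pixel_pitch, m$origin)
      idx <- which(on, arr.ind = TRUE)
      m$center <- c(mean(xs[idx[, 2]]), mean(ys[idx[, 1]]))
    }
    u$mask <- m
    u
  })
}

# Minimum distance between two unit geometries (boundary metric).
unit_boundary_distance <- function(a, b) {
  va <- shape_vertices(a$shape)
  vb <- shape_vertices(b$shape)
  # densify edges so vertex-to-edge distance approximates edge-to-edge
  min(min(dist_to_polygon_edge(va, vb)), min(dist_to_polygon_edge(vb, va)))
}

#' Partition projection units into d_critical slices
#'
#' Builds the conflict graph (two units conflict when closer than
#' `d_critical` under the chosen metric) and colors it greedily in a
#' deterministic (y, x) order of unit centres; each color class becomes one
#' slice, with a flush event between consecutive slices.
#'
#' @param units List of `projection_unit`s.
#' @param d_critical Critical distance, um.
#' @param metric "center" (centre-to-centre, the operative scheduling rule)
#'   or "boundary" (gap between pattern boundaries).
#' @return A `slice_schedule`: `slices` (list of unit-id vectors in
#'   projection order), `flush_after` (logical per slice), `d_critical`,
#'   `metric`, and the (re-ordered) `units` with `slice_id` set.
#' @export
slice_schedule <- function(units, d_critical, metric = c("center", "boundary")) {
  metric <- match.arg(metric)
  stopifnot(d_critical > 0)
  n <- length(units)
  if (n == 0) {
    return(structure(list(slices = list(), flush_after = logical(0),
                          d_critical = d_critical, metric = metric,
                          units = units),
                     class = "slice_schedule"))
  }
  centers <- t(vapply(units, function(u) u$center, numeric(2)))
  stage <- t(vapply(units, function(u) u$stage_center, numeric(2)))
  ids <- vapply(units, function(u) u$unit_id, integer(1))
  # snap sort keys so floating noise in centroids cannot scramble the
  # deterministic (y, x) projection order
  ord <- order(round(stage[, 2], 6), round(stage[, 1], 6),
               round(centers[, 2], 6), round(centers[, 1], 6), ids)
  conflict <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- if (metric == "center")
          sqrt(sum((centers[i, ] - centers[j, ])^2))
        else unit_boundary_distance(units[[i]], units[[j]])
        conflict[i, j] <- conflict[j, i] <- d < d_critical
      }
    }
  }
  color <- integer(n)
  for (k in ord) {
    used <- color[conflict[k, ] & color > 0]
    c_try <- 1L
    while (c_try %in% used) c_try <- c_try + 1L
    color[k] <- c_try
  }
  n_slices <- max(color)
  slices <- vector("list", n_slices)
  for (sl in seq_len(n_slices)) {
    members <- ord[color[ord] == sl]
    slices[[sl]] <- ids[members]
  }
  for (i in seq_len(n)) units[[i]]$slice_id <- color[i]
  structure(list(slices = slices,
                 flush_after = c(rep(TRUE, n_slices - 1), FALSE),
                 d_critical = d_critical, metric = metric, units = units),
            class = "slice_schedule")
}

#' @export
print.slice_schedule <- function(x, ...) {
  cat(sprintf("slice_schedule: %d units in %d slices (d_critical %.4g um, %s metric)\n",
              length(x$units), length(x$slices), x$d_critical, x$metric))
  invisible(x)
}

#' Verify a schedule by an independent all-pairs distance check
#'
#' @param schedule A [slice_schedule()].
#' @return TRUE when every within-slice pair is at least `d_critical` apart;
#'   otherwise a description of the first violation is attached as an
#'   attribute and FALSE returned.
#' @export
verify_schedule <- function(schedule) {
  by_id <- stats::setNames(schedule$units,
                           vapply(schedule$units, function(u) as.character(u$unit_id), ""))
  for (sl in schedule$slices) {
    if (length(sl) < 2) next
    for (i in seq_len(length(sl) - 1)) {
      for (j in seq(i + 1, length(sl))) {
        a <- by_id[[as.character(sl[i])]]
        b <- by_id[[as.character(sl[j])]]
        d <- if (schedule$metric == "center")
          sqrt(sum((a$center - b$center)^2))
        else unit_boundary_distance(a, b)
        if (d < schedule$d_critical) {
          res <- FALSE
          attr(res, "violation") <- sprintf("units %d and %d at %.3f um", sl[i], sl[j], d)
          return(res)
        }
      }
    }
  }
  TRUE
}

#' Export schedule masks and the projection index
#'
#' Writes one 8-bit PNG (0/255) per unit plus `index.csv` listing unit id,
#' slice id, stage centre, tile id and the mask's um geometry, ordered
#' slice-major in projection order.
#'
#' @param schedule A [slice_schedule()] whose units carry masks (run
#'   [stitch_expand()] first; units without masks are rasterized at
#'   `pixel_pitch`).
#' @param outdir Output directory (created if missing).
#' @param pixel_pitch Fallback raster pitch, um/px.
#' @return Invisibly, the index data frame.
#' @export
export_masks <- function(schedule, outdir, pixel_pitch = 1) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  if (length(schedule$units) == 0) {
    warning("empty schedule: writing empty index")
    idx <- data.frame(unit_id = integer(0), slice_id = integer(0),
                      stage_x = numeric(0), stage_y = numeric(0),
                      tile_id = integer(0), file = character(0),
                      origin_x = numeric(0), origin_y = numeric(0),
                      pixel_pitch = numeric(0))
    utils::write.csv(idx, file.path(outdir, "index.csv"), row.names = FALSE)
    return(invisible(idx))
  }
  by_id <- stats::setNames(schedule$units,
                           vapply(schedule$units, function(u) as.character(u$unit_id), ""))
  rows <- list()
  for (sl_i in seq_along(schedule$slices)) {
    for (id in schedule$slices[[sl_i]]) {
      u <- by_id[[as.character(id)]]
      m <- u$mask
      if (is.null(m)) {
        bb <- shape_bbox(u$shape)
        m <- rasterize_pattern(u$shape, pixel_pitch,
                               xlim = bb$xlim + c(-2, 2) * pixel_pitch,
                               ylim = bb$ylim + c(-2, 2) * pixel_pitch)
      }
      file <- sprintf("unit_%04d.png", u$unit_id)
      write_mask_png(m, file.path(outdir, file))
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u$unit_id, slice_id = sl_i,
        stage_x = u$stage_center[1], stage_y = u$stage_center[2],
        tile_id = u$tile_id, file = file,
        origin_x = m$origin[1], origin_y = m$origin[2],
        pixel_pitch = m$pixel_pitch)
    }
  }
  idx <- do.call(rbind, rows)
  utils::write.csv(idx, file.path(outdir, "index.csv"), row.names = FALSE)
  invisible(idx)
}
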