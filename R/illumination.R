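# Rasterization of vector shapes to projector-pixel masks and construction of
# UV intensity fields. Image convention: matrices are [row, col] with row 1 at
# the top; the um origin is the lower-left corner of the domain, so
#   x = origin[1] + (col - 0.5) * pitch
#   y = origin[2] + (nrow - row + 0.5) * pitch
# which makes the um -> pixel mapping explicit and round-trippable.

DMD_NATIVE <- c(1920L, 1080L)  # native micromirror resolution (cols x rows)

grid_x <- function(ncol, pitch, origin) origin[1] + (seq_len(ncol) - 0.5) * pitch
grid_y <- function(nrow, pitch, origin) origin[2] + (nrow - seq_len(nrow) + 0.5) * pitch

#' Rasterize shapes to a binary projector mask
#'
#' A pixel is "on" iff its centre lies inside a shape. The mask records the
#' um <-> pixel mapping and the centroid of the on-region.
#'
#' @param shapes A `shape` or list of shapes (um coordinates). An empty list
#'   produces an all-zero mask flagged empty.
#' @param pixel_pitch Projector pixel pitch, um per pixel.
#' @param xlim,ylim Domain extents in um; default is the joint bounding box of
#'   the shapes padded by `pad` um.
#' @param pad Padding added to the automatic bounding box (um).
#' @return A `pattern_mask`: list with `grid` (0/1 matrix), `pixel_pitch`,
#'   `origin` (um of the lower-left domain corner), `center` (um centroid of
#'   the on-region or NA when empty) and `empty`.
#' @export
rasterize_pattern <- function(shapes, pixel_pitch = 1, xlim = NULL, ylim = NULL,
                              pad = 2 * pixel_pitch) {
  if (inherits(shapes, "shape")) shapes <- list(shapes)
  stopifnot(pixel_pitch > 0)
  if (length(shapes) == 0) {
    if (is.null(xlim)) xlim <- c(0, 8 * pixel_pitch)
    if (is.null(ylim)) ylim <- c(0, 8 * pixel_pitch)
  } else {
    for (s in shapes) {
      if (s$kind == "circle" && s$radius <= 1e-6) stop("degenerate circle shape")
      if (s$kind == "polygon" && polygon_area(s$vertices) < 1e-9)
        stop("degenerate (zero-area) polygon shape")
    }
    bb <- lapply(shapes, shape_bbox)
    if (is.null(xlim)) xlim <- range(vapply(bb, function(b) b$xlim, numeric(2))) + c(-pad, pad)
    if (is.null(ylim)) ylim <- range(vapply(bb, function(b) b$ylim, numeric(2))) + c(-pad, pad)
  }
  nx <- max(1L, as.integer(ceiling((xlim[2] - xlim[1]) / pixel_pitch - 1e-9)))
  ny <- max(1L, as.integer(ceiling((ylim[2] - ylim[1]) / pixel_pitch - 1e-9)))
  if (nx > DMD_NATIVE[1] || ny > DMD_NATIVE[2])
    stop(sprintf("mask of %d x %d px exceeds the DMD native resolution (%d x %d)",
                 nx, ny, DMD_NATIVE[1], DMD_NATIVE[2]))
  origin <- c(xlim[1], ylim[1])
  xs <- grid_x(nx, pixel_pitch, origin)
  ys <- grid_y(ny, pixel_pitch, origin)
  grid <- matrix(0L, nrow = ny, ncol = nx)
  if (length(shapes) > 0) {
    px <- cbind(rep(xs, each = ny), rep(ys, times = nx))
    on <- rep(FALSE, nrow(px))
    for (s in shapes) {
      if (s$kind == "circle") {
        on <- on | ((px[, 1] - s$center[1])^2 + (px[, 2] - s$center[2])^2 <=
                      s$radius^2)
      } else {
        on <- on | points_in_polygon(px, s$vertices)
      }
    }
    grid[] <- as.integer(on)
  }
  empty <- !any(grid > 0)
  center <- if (empty) c(NA_real_, NA_real_) else {
    idx <- which(grid > 0, arr.ind = TRUE)
    c(mean(xs[idx[, 2]]), mean(ys[idx[, 1]]))
  }
  structure(list(grid = grid, pixel_pitch = pixel_pitch, origin = origin,
                 center = center, empty = empty),
            class = "pattern_mask")
}

#' @export
print.pattern_mask <- function(x, ...) {
  cat(sprintf("pattern_mask: %d x %d px @ %.3g um/px, %d on-pixels%s\n",
              ncol(x$grid), nrow(x$grid), x$pixel_pitch, sum(x$grid > 0),
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Illumination profile parameters
#'
#' The top-hat profile is exactly zero outside the pattern; the graded profile
#' decays as exp(-d / tail_scale) with Euclidean distance d outside the
#' pattern boundary, clamped to zero below `tail_floor * peak`. The graded
#' tail is a phenomenological stand-in for the measured decay of projector
#' intensity outside the illumination zone.
#'
#' @param peak_intensity Peak intensity, mW/cm^2 (default 22, the maximum
#'   power of the reference UV LED).
#' @param kind "top_hat" or "graded".
#' @param tail_scale Decay length of the graded tail, um. The default 33.4 um
#'   puts the intensity at 5% of peak 100 um outside the pattern edge.
#' @param tail_floor Fraction of peak below which the tail is clamped to 0.
#' @return An `illumination_profile` object.
#' @export
illumination_profile <- function(peak_intensity = 22,
                                 kind = c("graded", "top_hat"),
                                 tail_scale = 33.4, tail_floor = 0.01) {
  kind <- match.arg(kind)
  stopifnot(peak_intensity > 0, tail_floor >= 0)
  if (kind == "graded") stopifnot(tail_scale > 0)
  structure(list(peak_intensity = peak_intensity, kind = kind,
                 tail_scale = tail_scale, tail_floor = tail_floor),
            class = "illumination_profile")
}

#' Build a UV intensity field from a mask and an illumination profile
#'
#' @param mask A [rasterize_pattern()] mask.
#' @param profile An [illumination_profile()].
#' @param grid_spacing Simulation grid spacing, um (defaults to the mask pixel
#'   pitch). When it differs from the pixel pitch the mask is resampled by
#'   nearest pixel centre.
#' @return A `light_field`: list with `values` (matrix, mW/cm^2),
#'   `grid_spacing` and `origin`.
#' @export
build_light_field <- function(mask, profile = illumination_profile(),
                              grid_spacing = mask$pixel_pitch) {
  stopifnot(inherits(mask, "pattern_mask"), inherits(profile, "illumination_profile"))
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (isTRUE(all.equal(grid_spacing, mask$pixel_pitch))) {
    on <- mask$grid > 0
  } else {
    # resample: a sim cell is on iff its centre falls in an on mask pixel
    wx <- ncol(mask$grid) * mask$pixel_pitch
    wy <- nrow(mask$grid) * mask$pixel_pitch
    nx <- as.integer(round(wx / grid_spacing))
    ny <- as.integer(round(wy / grid_spacing))
    xs <- grid_x(nx, grid_spacing, mask$origin)
    ys <- grid_y(ny, grid_spacing, mask$origin)
    jx <- pmin(ncol(mask$grid), pmax(1L, ceiling((xs - mask$origin[1]) / mask$pixel_pitch)))
    iy <- pmin(nrow(mask$grid), pmax(1L, nrow(mask$grid) - floor((ys - mask$origin[2]) / mask$pixel_pitch)))
    on <- matrix(mask$grid[cbind(rep(iy, times = nx), rep(jx, each = ny))] > 0,
                 nrow = ny, ncol = nx)
  }
  vals <- matrix(0, nrow(on), ncol(on))
  if (any(on)) {
    vals[on] <- profile$peak_intensity
    if (profile$kind == "graded") {
      d <- distance_transform(on, grid_spacing)
      tail <- profile$peak_intensity * exp(-d / profile$tail_scale)
      tail[tail < profile$tail_floor * profile$peak_intensity] <- 0
      vals[!on] <- tail[!on]
    }
  }
  structure(list(values = vals, grid_spacing = grid_spacing, origin = mask$origin),
            class = "light_field")
}

#' @export
print.light_field <- function(x, ...) {
  cat(sprintf("light_field: %d x %d @ %.3g um, max %.3g mW/cm^2\n",
              ncol(x$values), nrow(x$values), x$grid_spacing, max(x$values)))
  invisible(x)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask A `pattern_mask`.
#' @param path Output file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask$grid > 0, 1, 0), target = path)
  invisible(path)
}

#' Read a binary mask written by [write_mask_png()]
#' @param path PNG path.
#' @param pixel_pitch um per pixel of the stored mask.
#' @param origin um coordinates of the lower-left corner.
#' @return A `pattern_mask`.
#' @export
read_mask_png <- function(path, pixel_pitch = 1, origin = c(0, 0)) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  grid <- matrix(as.integer(img > 0.5), nrow(img), ncol(img))
  empty <- !any(grid > 0)
  center <- if (empty) c(NA_real_, NA_real_) else {
    xs <- grid_x(ncol(grid), pixel_pitch, origin)
    ys <- grid_y(nrow(grid), pixel_pitch, origin)
    idx <- which(grid > 0, arr.ind = TRUE)
    c(mean(xs[idx[, 2]]), mean(ys[idx[, 1]]))
  }
  structure(list(grid = grid, pixel_pitch = pixel_pitch, origin = origin,
                 center = center, empty = empty),
            class = "pattern_mask")
}

#' Write a light field (or any field matrix) as 32-bit float TIFF
#' @param field A `light_field` or numeric matrix.
#' @param path Output file path.
#' @export
write_field_tiff <- function(field, path) {
  m <- if (inherits(field, "light_field")) field$values else field
  tiff::writeTIFF(m / max(1, max(m)), path, bits.per.sample = 32L)
  invisible(path)
}
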