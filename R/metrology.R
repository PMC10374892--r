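# Feature-fidelity metrology: radial edge profiles at 3.6 degree intervals,
# pooled RMS roughness, diameter-broadening series and DLD row-shift
# recovery. Inputs are field matrices (binary or greyscale cure fields) using
# the package image convention (row 1 at top, um origin at lower-left).

# Bilinear sample of matrix m at um points; outside the grid returns 0.
sample_bilinear <- function(m, spacing, origin, pts) {
  nr <- nrow(m); nc <- ncol(m)
  cx <- (pts[, 1] - origin[1]) / spacing + 0.5
  ry <- nr + 0.5 - (pts[, 2] - origin[2]) / spacing
  j0 <- floor(cx); i0 <- floor(ry)
  fx <- cx - j0; fy <- ry - i0
  out <- numeric(nrow(pts))
  ok <- j0 >= 1 & j0 < nc & i0 >= 1 & i0 < nr
  if (any(ok)) {
    j0k <- j0[ok]; i0k <- i0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    v00 <- m[cbind(i0k, j0k)]
    v01 <- m[cbind(i0k, j0k + 1)]
    v10 <- m[cbind(i0k + 1, j0k)]
    v11 <- m[cbind(i0k + 1, j0k + 1)]
    out[ok] <- v00 * (1 - fxk) * (1 - fyk) + v01 * fxk * (1 - fyk) +
      v10 * (1 - fxk) * fyk + v11 * fxk * fyk
  }
  out
}

#' Intensity-weighted centroid of a thresholded feature
#'
#' @param image Matrix (binary or greyscale).
#' @param spacing,origin Grid geometry (um).
#' @param level Threshold as a fraction of the image maximum.
#' @return Length-2 numeric centre in um.
#' @export
feature_centroid <- function(image, spacing = 1, origin = c(0, 0), level = 0.5) {
  thr <- level * max(image)
  idx <- which(image >= thr, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no pixels above the threshold level")
  w <- image[idx]
  xs <- grid_x(ncol(image), spacing, origin)
  ys <- grid_y(nrow(image), spacing, origin)
  c(sum(xs[idx[, 2]] * w), sum(ys[idx[, 1]] * w)) / sum(w)
}

#' Radial edge profile of a feature
#'
#' Casts `n_angles` rays (default 100, i.e. 3.6 degree spacing) from the
#' feature centre and finds the sub-pixel half-maximum edge crossing along
#' each by linear interpolation.
#'
#' @param image Matrix (binary mask or greyscale cure field), or a
#'   `norm_polymer` object carrying its own grid metadata.
#' @param center Feature centre in um; default is the intensity-weighted
#'   centroid.
#' @param spacing,origin Grid geometry, ignored when `image` is a
#'   `norm_polymer`.
#' @param n_angles Number of rays.
#' @param level Edge threshold as a fraction of the image maximum
#'   (half-maximum by default), or an absolute level when `absolute = TRUE`
#'   (used for cure fields already normalized to the fully cured level).
#' @param r_max Optional cap on the ray length in um. Without a cap, a ray
#'   that never crosses the edge is an error; with a cap the radius saturates
#'   at `r_max` (used for merged features).
#' @return A `radial_profile`: list with `angles` (radians), `radii` (um) and
#'   `center`.
#' @export
radial_profile <- function(image, center = NULL, spacing = 1, origin = c(0, 0),
                           n_angles = 100, level = 0.5, r_max = NULL,
                           absolute = FALSE) {
  if (inherits(image, "norm_polymer")) {
    spacing <- image$grid_spacing
    origin <- image$origin
    image <- image$values
  }
  stopifnot(is.matrix(image), n_angles >= 3)
  if (is.null(center)) center <- feature_centroid(image, spacing, origin)
  thr <- if (absolute) level else level * max(image)
  if (thr <= 0) stop("image has no signal")
  domain_r <- sqrt((ncol(image) * spacing)^2 + (nrow(image) * spacing)^2)
  cap <- if (is.null(r_max)) domain_r else r_max
  step <- spacing / 4
  ns <- as.integer(ceiling(cap / step))
  rs <- seq_len(ns) * step
  angles <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  radii <- numeric(n_angles)
  x_max <- origin[1] + ncol(image) * spacing
  y_max <- origin[2] + nrow(image) * spacing
  for (k in seq_len(n_angles)) {
    dirx <- cos(angles[k]); diry <- sin(angles[k])
    pts <- cbind(center[1] + rs * dirx, center[2] + rs * diry)
    ingrid <- pts[, 1] > origin[1] + spacing & pts[, 1] < x_max - spacing &
      pts[, 2] > origin[2] + spacing & pts[, 2] < y_max - spacing
    v <- sample_bilinear(image, spacing, origin, pts)
    below <- which(v < thr & ingrid)
    if (length(below) == 0) {
      if (is.null(r_max))
        stop(sprintf("ray at %.1f degrees never crosses the edge", angles[k] * 180 / pi))
      radii[k] <- cap
      next
    }
    j <- below[1]
    if (j == 1) { radii[k] <- 0; next }
    # linear interpolation between the last sample above and first below
    fr <- (v[j - 1] - thr) / (v[j - 1] - v[j])
    radii[k] <- rs[j - 1] + fr * step
  }
  structure(list(angles = angles, radii = radii, center = center),
            class = "radial_profile")
}

#' Pooled RMS roughness of radial profiles
#'
#' RMS of the deviation of each sampled radius from its feature's mean
#' radius, pooled over all features (a single RMS per device, matching how a
#' device-level roughness number is reported).
#'
#' @param profiles A `radial_profile` or list of them.
#' @return A `roughness_report`: `rms_deviation` (um), `mean_radius` (um),
#'   `n_features`.
#' @export
rms_roughness <- function(profiles) {
  if (inherits(profiles, "radial_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  dev <- unlist(lapply(profiles, function(p) p$radii - mean(p$radii)))
  structure(list(rms_deviation = sqrt(mean(dev^2)),
                 mean_radius = mean(unlist(lapply(profiles, function(p) p$radii))),
                 n_features = length(profiles)),
            class = "roughness_report")
}

#' @export
print.roughness_report <- function(x, ...) {
  cat(sprintf("roughness: RMS %.3g um over %d features (mean radius %.3g um)\n",
              x$rms_deviation, x$n_features, x$mean_radius))
  invisible(x)
}

#' Diameter broadening series
#'
#' Equivalent diameter (2 x mean radius) per feature and percent change
#' relative to the first feature, for sequential-exposure overgrowth
#' analysis.
#'
#' @param features List of `radial_profile`s in exposure order, or a numeric
#'   vector of diameters (um).
#' @return A `broadening_series` data.frame with columns `feature`,
#'   `diameter` (um) and `pct_change` (%).
#' @export
diameter_series <- function(features) {
  d <- if (is.numeric(features)) features
       else vapply(features, function(p) 2 * mean(p$radii), numeric(1))
  stopifnot(length(d) >= 2)
  out <- data.frame(feature = seq_along(d), diameter = d,
                    pct_change = 100 * (d - d[1]) / d[1])
  class(out) <- c("broadening_series", "data.frame")
  out
}

#' Recover the row shift of a pillar lattice
#'
#' Pillar centres are clustered into rows by y; the lateral shift is the mean
#' offset in x between consecutive rows, folded modulo the column pitch into
#' `(-pitch/2, pitch/2]` and reported as a magnitude.
#'
#' @param centers m x 2 matrix of detected pillar centres (um).
#' @param pitch Column pitch in um; estimated from within-row spacing when
#'   NULL.
#' @return Row shift in um.
#' @export
measure_row_shift <- function(centers, pitch = NULL) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, nrow(centers) >= 6)
  ord <- order(centers[, 2])
  y <- centers[ord, 2]; x <- centers[ord, 1]
  dy <- diff(y)
  if (max(dy) <= 4 * stats::median(dy) || max(dy) <= 0)
    stop("ambiguous row clustering: no clear gap in y spacing")
  breaks <- which(dy > max(dy) / 2)
  row_id <- cumsum(c(1L, as.integer(seq_along(dy) %in% breaks)))
  rows <- split(x, row_id)
  if (length(rows) < 2 || any(lengths(rows) < 3))
    stop("need at least 2 rows of at least 3 pillars")
  if (is.null(pitch)) {
    pitch <- stats::median(unlist(lapply(rows, function(r) diff(sort(r)))))
  }
  offs <- vapply(seq_len(length(rows) - 1L), function(i) {
    a <- sort(rows[[i]]); b <- sort(rows[[i + 1L]])
    d <- vapply(b, function(xb) {
      del <- xb - a[which.min(abs(xb - a))]
      del - pitch * round(del / pitch)
    }, numeric(1))
    mean(d)
  }, numeric(1))
  mean(abs(offs))
}
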