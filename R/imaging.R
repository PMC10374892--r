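# Virtual camera and the annular-mask greyscale edge tracker. The camera is
# phenomenological: during curing the microscope image shows a white halo of
# partially cured material leading a dark edge at the steep cure front, with
# a bright rim of fresh gel just behind it (deep, aged solid relaxes back to
# background contrast). Frames are synthesized from the normalized polymer
# field as
#   background + halo_gain * halo(v) - edge_darkness * front(|grad v|)
#              + rim_gain * rim(v)
# followed by Gaussian blur, seeded Gaussian noise, and clipping to [0, 255].
# Tracking the mean greyscale of an annular mask over such frames yields the
# characteristic two-peak curve: the first maximum when the halo reaches the
# mask, the second when the dark edge and fresh-gel rim cross it.

#' Virtual camera parameters
#'
#' @param background_level Background grey level (0-255).
#' @param halo_gain Grey added at full halo strength.
#' @param edge_darkness Grey subtracted at the cure front.
#' @param rim_gain Grey added over the fresh-gel rim just behind the front.
#' @param grad_ref Cure-level gradient (per px) rendered as a fully dark
#'   edge; shallower gradients darken proportionally.
#' @param blur_sigma Gaussian blur sigma in px.
#' @param noise_sigma Gaussian noise sigma in grey levels (drawn from the
#'   session RNG; seed the run for reproducible streams).
#' @param fps Frame rate, frames/s.
#' @return A `camera_model`.
#' @export
camera_model <- function(background_level = 40, halo_gain = 60,
                         edge_darkness = 40, rim_gain = 150, grad_ref = 0.04,
                         blur_sigma = 1, noise_sigma = 0, fps = 100) {
  stopifnot(fps > 0, background_level >= 0, background_level <= 255,
            noise_sigma >= 0, grad_ref > 0)
  structure(list(background_level = background_level, halo_gain = halo_gain,
                 edge_darkness = edge_darkness, rim_gain = rim_gain,
                 grad_ref = grad_ref, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, fps = fps),
            class = "camera_model")
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(mm) {
    nr <- nrow(mm)
    top <- mm[rep(1L, r), , drop = FALSE]
    bot <- mm[rep(nr, r), , drop = FALSE]
    ext <- rbind(top, mm, bot)
    out <- matrix(0, nr, ncol(mm))
    for (i in seq_along(k)) out <- out + k[i] * ext[i:(i + nr - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

# Gradient magnitude by central differences (px units).
grad_mag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- (cbind(m[, -1, drop = FALSE], m[, nc, drop = FALSE]) -
           cbind(m[, 1, drop = FALSE], m[, -nc, drop = FALSE])) / 2
  gy <- (rbind(m[-1, , drop = FALSE], m[nr, , drop = FALSE]) -
           rbind(m[1, , drop = FALSE], m[-nr, , drop = FALSE])) / 2
  sqrt(gx^2 + gy^2)
}

#' Render a camera frame from a normalized polymer field
#'
#' @param norm A [normalize_polymer()] field (values in `[0, 1]`).
#' @param camera A [camera_model()].
#' @param t Timestamp in s.
#' @return A `frame`: list with 8-bit `image` matrix and `timestamp`.
#' @export
render_frame <- function(norm, camera, t = 0) {
  v <- if (inherits(norm, "norm_polymer")) norm$values else norm
  v[v > 1] <- 1
  # white halo: partially cured band below the gel level, brightest mid-band
  halo <- ifelse(v > 0.05 & v < 0.5, sin(pi * (v - 0.05) / 0.45), 0)
  # black edge: proportional to the cure gradient (absolute scale, so faint
  # early-exposure gradients render faintly)
  g <- grad_mag(v)
  front <- pmin(1, g / camera$grad_ref)
  # fresh-gel rim just behind the front: gelation is an abrupt optical
  # transition, so the rim switches on at the gel level and fades as the
  # solid ages (cures further)
  rim <- ifelse(v >= 0.5 & v < 0.8, pmin(1, (0.8 - v) / 0.1), 0)
  img <- camera$background_level + camera$halo_gain * halo -
    camera$edge_darkness * front + camera$rim_gain * rim
  img <- gaussian_blur(img, camera$blur_sigma)
  if (camera$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, camera$noise_sigma),
                        nrow(img), ncol(img))
  img[img < 0] <- 0
  img[img > 255] <- 255
  img <- round(img)
  structure(list(image = img, timestamp = t), class = "frame")
}

#' Build an annular tracking mask centred on a target outline
#'
#' Pixels whose distance to the outline is at most `thickness / 2` pixels
#' form a closed band around the desired pattern boundary.
#'
#' @param outline A `shape` (the target outline, um).
#' @param grid List with `nrow`, `ncol`, `spacing`, `origin` describing the
#'   frame geometry (a `light_field` or `norm_polymer` also works).
#' @param thickness Band thickness in px (default 10).
#' @return A `tracking_mask`: logical `mask` matrix plus the outline.
#' @export
build_tracking_mask <- function(outline, grid, thickness = 10) {
  stopifnot(inherits(outline, "shape"), thickness >= 2)
  if (inherits(grid, "light_field"))
    grid <- list(nrow = nrow(grid$values), ncol = ncol(grid$values),
                 spacing = grid$grid_spacing, origin = grid$origin)
  if (inherits(grid, "norm_polymer"))
    grid <- list(nrow = nrow(grid$values), ncol = ncol(grid$values),
                 spacing = grid$grid_spacing, origin = grid$origin)
  v <- shape_vertices(outline)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  x_max <- grid$origin[1] + grid$ncol * grid$spacing
  y_max <- grid$origin[2] + grid$nrow * grid$spacing
  if (xr[1] < grid$origin[1] || yr[1] < grid$origin[2] || xr[2] > x_max || yr[2] > y_max)
    stop("outline exceeds the frame")
  xs <- grid_x(grid$ncol, grid$spacing, grid$origin)
  ys <- grid_y(grid$nrow, grid$spacing, grid$origin)
  pts <- cbind(rep(xs, each = grid$nrow), rep(ys, times = grid$ncol))
  d_px <- dist_to_polygon_edge(pts, v) / grid$spacing
  mask <- matrix(d_px <= thickness / 2, grid$nrow, grid$ncol)
  if (!any(mask)) stop("tracking mask is empty at this grid resolution")
  structure(list(mask = mask, thickness = thickness, outline = outline),
            class = "tracking_mask")
}

#' Create an empty tracker state
#'
#' @param pattern_id Identifier carried into reports.
#' @param cutoff Cutoff grey level; NULL selects the adaptive rule
#'   (mean + max(4 sd, 10) of the first `n_baseline` frames).
#' @param rule Trigger rule: "cutoff", "first_peak" or "second_peak".
#' @param peak_window Frames a value must keep falling to confirm a peak.
#' @param n_baseline Frames used for the adaptive cutoff estimate.
#' @return A `tracker_state`.
#' @export
new_tracker <- function(pattern_id = 1L, cutoff = NULL,
                        rule = c("cutoff", "first_peak", "second_peak"),
                        peak_window = 5L, n_baseline = 5L) {
  rule <- match.arg(rule)
  structure(list(pattern_id = pattern_id, series = numeric(0),
                 times = numeric(0), cutoff = cutoff, rule = rule,
                 peak_window = as.integer(peak_window),
                 n_baseline = as.integer(n_baseline),
                 triggered = FALSE, trigger_time = NA_real_,
                 peaks = data.frame(time = numeric(0), value = numeric(0))),
            class = "tracker_state")
}

#' Confirmed local maxima of a greyscale series
#'
#' A sample is a confirmed peak when it is not below its predecessor, no
#' later sample within the confirmation window exceeds it, and the series
#' drops by at least `prominence` within that window.
#'
#' @param v Numeric series.
#' @param w Confirmation window in frames.
#' @param prominence Minimum drop (grey levels) required after the peak.
#' @return Integer indices of confirmed peaks.
#' @export
find_peaks <- function(v, w = 5L, prominence = 1) {
  n <- length(v)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - w) {
    win <- v[(i + 1L):(i + w)]
    if (v[i] >= v[i - 1L] && all(win <= v[i]) &&
        (v[i] - min(win)) >= prominence) {
      peaks <- c(peaks, i)
      i <- i + w  # skip the confirmation window
    }
    i <- i + 1L
  }
  peaks
}

#' Append a frame to a tracker and evaluate its trigger rule
#'
#' The appended value is the exact mean greyscale over the mask pixels,
#' sum(image * mask) / sum(mask).
#'
#' @param state A [new_tracker()] state.
#' @param frame A [render_frame()] frame.
#' @param mask A [build_tracking_mask()] mask of identical geometry.
#' @return Updated `tracker_state`.
#' @export
update_tracker <- function(state, frame, mask) {
  stopifnot(inherits(state, "tracker_state"), inherits(mask, "tracking_mask"))
  if (!all(dim(frame$image) == dim(mask$mask)))
    stop("frame and tracking mask geometries differ")
  val <- sum(frame$image * mask$mask) / sum(mask$mask)
  state$series <- c(state$series, val)
  state$times <- c(state$times, frame$timestamp)
  if (!state$triggered && check_trigger(state, state$rule)) {
    state$triggered <- TRUE
    state$trigger_time <- frame$timestamp
  }
  idx <- find_peaks(state$series, state$peak_window)
  state$peaks <- data.frame(time = state$times[idx], value = state$series[idx])
  state
}

#' Evaluate a trigger rule on the current series
#'
#' @param state A `tracker_state` with a non-empty series.
#' @param rule "cutoff" (latest value at or above the cutoff, evaluated only
#'   after the baseline window), "first_peak" or "second_peak" (fires once
#'   the n-th local maximum is confirmed).
#' @return Logical decision.
#' @export
check_trigger <- function(state, rule = state$rule) {
  n <- length(state$series)
  if (n == 0) stop("tracker series is empty")
  if (rule == "cutoff") {
    if (n <= state$n_baseline) return(FALSE)
    cutoff <- state$cutoff
    if (is.null(cutoff)) {
      base <- state$series[seq_len(state$n_baseline)]
      cutoff <- mean(base) + max(4 * stats::sd(base), 10)
    }
    return(state$series[n] >= cutoff)
  }
  need <- if (rule == "first_peak") 1L else 2L
  length(find_peaks(state$series, state$peak_window)) >= need
}

#' Track several patterns independently over one frame stream
#'
#' @param frames List of `frame`s (a shared field of view).
#' @param masks List of pairwise non-overlapping [build_tracking_mask()]s.
#' @param ... Arguments forwarded to [new_tracker()] (cutoff, rule, ...).
#' @return List of `tracker_state`s, one per mask.
#' @export
multi_pattern_tracking <- function(frames, masks, ...) {
  stopifnot(length(masks) >= 1)
  if (length(masks) > 1) {
    acc <- Reduce(`+`, lapply(masks, function(m) m$mask * 1L))
    if (any(acc > 1L)) stop("tracking masks overlap")
  }
  states <- lapply(seq_along(masks), function(i) new_tracker(pattern_id = i, ...))
  for (f in frames)
    for (i in seq_along(masks))
      states[[i]] <- update_tracker(states[[i]], f, masks[[i]])
  states
}

#' Write a tracker series as CSV (time, value, triggered)
#' @param state A `tracker_state`.
#' @param path Output CSV path.
#' @export
write_tracker_csv <- function(state, path) {
  df <- data.frame(time = state$times, value = state$series,
                   triggered = !is.na(state$trigger_time) &
                     state$times >= state$trigger_time)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a frame stream as a multi-page TIFF
#' @param frames List of `frame`s.
#' @param path Output TIFF path.
#' @export
write_frames_tiff <- function(frames, path) {
  pages <- lapply(frames, function(f) f$image / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
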