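# Offline optical proximity correction (OPC) of polygon corners via squircle
# transforms, and the online iterative tip/trench dynamic pattern-correction
# loop. Corner vocabulary: a tip is a locally convex vertex, a trench a
# locally concave one; during dynamic correction the cured edge is tracked
# along the ray from the shape centre through each classified vertex, a
# leading edge (positive deviation) means overfill and a trailing edge
# (negative) underfill.

#' Classified polygon for shape correction
#'
#' @param vertices n x 2 matrix of um coordinates (counter-clockwise order is
#'   enforced).
#' @param center Optional centre; default is the polygon centroid.
#' @return A `polygon_shape` with `vertices`, `vertex_class` (tip / trench /
#'   regular) and `center`.
#' @export
polygon_shape <- function(vertices, center = NULL) {
  vertices <- ensure_ccw(as.matrix(vertices))
  if (!polygon_is_simple(vertices)) stop("polygon is self-intersecting")
  obj <- structure(list(vertices = vertices,
                        vertex_class = rep("regular", nrow(vertices)),
                        center = if (is.null(center)) polygon_centroid(vertices) else center),
                   class = "polygon_shape")
  obj$vertex_class <- classify_tips_trenches(obj)
  obj
}

#' @export
print.polygon_shape <- function(x, ...) {
  tab <- table(factor(x$vertex_class, levels = c("tip", "trench", "regular")))
  cat(sprintf("polygon_shape: %d vertices (%d tips, %d trenches, %d regular)\n",
              nrow(x$vertices), tab[["tip"]], tab[["trench"]], tab[["regular"]]))
  invisible(x)
}

# Convert a plain `shape` to a classified polygon_shape.
as_polygon_shape <- function(shape) {
  if (inherits(shape, "polygon_shape")) return(shape)
  stopifnot(inherits(shape, "shape"))
  polygon_shape(shape_vertices(shape))
}

#' Classify polygon vertices as tips or trenches
#'
#' With counter-clockwise orientation, the z component of the cross product
#' of the incoming and outgoing edge is positive at convex vertices (tips)
#' and negative at concave ones (trenches); near-collinear vertices are
#' regular.
#'
#' @param shape A `polygon_shape` (or vertex matrix).
#' @param tol Relative collinearity tolerance.
#' @return Character vector of per-vertex labels.
#' @export
classify_tips_trenches <- function(shape, tol = 1e-6) {
  v <- if (inherits(shape, "polygon_shape")) shape$vertices else ensure_ccw(as.matrix(shape))
  if (!polygon_is_simple(v)) stop("polygon is self-intersecting")
  n <- nrow(v)
  prv <- v[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- v[c(seq_len(n)[-1], 1L), , drop = FALSE]
  e1 <- v - prv
  e2 <- nxt - v
  cr <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  scale <- sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2))
  rel <- cr / pmax(scale, 1e-300)
  ifelse(abs(rel) <= tol, "regular", ifelse(cr > 0, "tip", "trench"))
}

#' Squircle corner-correction parameters
#'
#' The correction family is the Fernandez-Guasti squircle
#' x^2 + y^2 - (s^2 / r^2) x^2 y^2 = r^2, which interpolates between a circle
#' (s = 0) and a square (s = 1). Each polygon corner is remapped through the
#' right-angle squircle solution in a local corner frame, scaled by the
#' corner's half-angle ratio, so that s = 0 leaves the shape unchanged and
#' s = 1 pushes the corner fully outward (through the square's corner point
#' (r, r) in the unit frame).
#'
#' @param s Squareness in `[0, 1]`.
#' @param corner_window Arc length (um) of each adjacent edge remapped per
#'   corner.
#' @return A `squircle_params` object.
#' @export
squircle_params <- function(s = 0.8, corner_window = 20) {
  stopifnot(s >= 0, s <= 1, corner_window > 0)
  structure(list(s = s, corner_window = corner_window), class = "squircle_params")
}

#' Radial gain of the right-angle Fernandez-Guasti squircle
#'
#' rho(theta) / r for the squircle of squareness `s`, i.e. the factor by
#' which a circle radius is stretched at polar angle `theta` (radians,
#' 0..pi/2). Equals 1 at the axes and sqrt(2) at theta = pi/4 for s = 1.
#'
#' @param theta Polar angle(s), radians.
#' @param s Squareness in `[0, 1]`.
#' @return Numeric gain(s) >= 1.
#' @export
squircle_gain <- function(theta, s) {
  u <- s * sin(2 * theta)
  g <- rep(1, length(u))
  big <- abs(u) > 1e-6
  g[big] <- sqrt(2 * (1 - sqrt(1 - u[big]^2))) / abs(u[big])
  small <- !big & abs(u) > 0
  g[small] <- 1 + u[small]^2 / 8
  g
}

# Remap one corner through the squircle family. Returns the replacement
# points for vertex V (including the window endpoints A1, B1).
remap_corner <- function(A, V, B, s, window, n_samples = 9L) {
  la <- sqrt(sum((A - V)^2)); lb <- sqrt(sum((B - V)^2))
  wa <- min(window, 0.45 * la); wb <- min(window, 0.45 * lb)
  A1 <- V + (A - V) * (wa / la)
  B1 <- V + (B - V) * (wb / lb)
  O <- (A1 + B1) / 2
  ts <- seq(0, 1, length.out = n_samples)
  pts <- matrix(0, n_samples, 2)
  for (i in seq_along(ts)) {
    t <- ts[i]
    P <- if (t <= 0.5) A1 + (V - A1) * (t / 0.5) else V + (B1 - V) * ((t - 0.5) / 0.5)
    g <- squircle_gain(t * pi / 2, s)
    pts[i, ] <- O + g * (P - O)
  }
  pts
}

#' Apply squircle optical proximity correction to polygon corners
#'
#' Each tip and trench corner is replaced by a squircle arc that pushes the
#' corner outward (tips) or deeper (trenches) to pre-compensate the rounding
#' of the curing process. If the remap self-intersects, the corner window is
#' halved and the remap retried.
#'
#' @param shape A `polygon_shape` (or `shape`).
#' @param params [squircle_params()].
#' @param n_samples Points per corner arc.
#' @return A corrected `polygon_shape`. `s = 0` returns the input unchanged.
#' @export
apply_opc <- function(shape, params = squircle_params(), n_samples = 9L) {
  shape <- as_polygon_shape(shape)
  if (params$s == 0) return(shape)
  window <- params$corner_window
  for (attempt in 1:4) {
    v <- shape$vertices
    n <- nrow(v)
    cls <- shape$vertex_class
    out <- vector("list", n)
    for (i in seq_len(n)) {
      if (cls[i] == "regular") { out[[i]] <- v[i, , drop = FALSE]; next }
      A <- v[if (i == 1L) n else i - 1L, ]
      B <- v[if (i == n) 1L else i + 1L, ]
      out[[i]] <- remap_corner(A, v[i, ], B, params$s, window, n_samples)
    }
    vv <- do.call(rbind, out)
    # drop consecutive duplicates
    keep <- c(TRUE, rowSums((vv[-1, , drop = FALSE] - vv[-nrow(vv), , drop = FALSE])^2) > 1e-12)
    vv <- vv[keep, , drop = FALSE]
    if (polygon_is_simple(vv)) {
      res <- polygon_shape(vv, center = shape$center)
      return(res)
    }
    window <- window / 2
  }
  stop("squircle remap produced a self-intersecting polygon even after reducing the corner window")
}

#' Extract a closed iso-contour from a field matrix
#'
#' Wraps [grDevices::contourLines()] on the package image convention and
#' returns the contour ring nearest to `center` (largest ring when no centre
#' is given).
#'
#' @param values Field matrix.
#' @param level Contour level.
#' @param spacing,origin Grid geometry (um).
#' @param center Optional point the wanted ring should enclose.
#' @return n x 2 matrix of contour vertices (um).
#' @export
extract_contour <- function(values, level = 0.5, spacing = 1, origin = c(0, 0),
                            center = NULL) {
  nr <- nrow(values); nc <- ncol(values)
  xs <- grid_x(nc, spacing, origin)
  ys_asc <- origin[2] + (seq_len(nr) - 0.5) * spacing
  z <- t(values[nr:1, , drop = FALSE])  # [x, y] with y ascending
  cl <- grDevices::contourLines(x = xs, y = ys_asc, z = z, levels = level)
  if (length(cl) == 0) stop("no contour at the requested level")
  rings <- lapply(cl, function(cc) cbind(cc$x, cc$y))
  if (!is.null(center)) {
    enclosing <- vapply(rings, function(r)
      nrow(r) >= 3 && points_in_polygon(matrix(center, 1), r), logical(1))
    if (any(enclosing)) {
      rings <- rings[enclosing]
    }
  }
  areas <- vapply(rings, function(r) if (nrow(r) >= 3) polygon_area(r) else 0, numeric(1))
  rings[[which.max(areas)]]
}

#' Signed radial deviation of an observed edge at tips and trenches
#'
#' Along the ray from the shape centre through each classified vertex, the
#' deviation is the radial position of the observed edge minus that of the
#' desired vertex: positive (leading) means overfill, negative (trailing)
#' underfill.
#'
#' @param contour n x 2 matrix, the observed closed cure-front contour (um).
#' @param shape The desired `polygon_shape`.
#' @return Data frame with `vertex`, `class`, `desired_r`, `observed_r`,
#'   `deviation` (um) for every tip and trench.
#' @export
measure_vertex_deviation <- function(contour, shape) {
  shape <- as_polygon_shape(shape)
  ctr <- shape$center
  idx <- which(shape$vertex_class %in% c("tip", "trench"))
  if (length(idx) == 0) stop("shape has no tips or trenches")
  res <- lapply(idx, function(i) {
    v <- shape$vertices[i, ]
    r_des <- sqrt(sum((v - ctr)^2))
    dir <- (v - ctr) / r_des
    hits <- ray_polygon_hits(ctr, dir, contour)
    if (length(hits) == 0)
      stop(sprintf("ray through vertex %d fails to intersect the contour", i))
    r_obs <- hits[which.min(abs(hits - r_des))]
    data.frame(vertex = i, class = shape$vertex_class[i],
               desired_r = r_des, observed_r = r_obs,
               deviation = r_obs - r_des)
  })
  do.call(rbind, res)
}

#' Create the state of a dynamic-correction run
#'
#' @param target Desired `polygon_shape`.
#' @param gain Fraction of the measured deviation applied per iteration.
#' @param tolerance Convergence tolerance on |deviation|, um.
#' @param initial_offset Radial shrink of the initial projection, um (the
#'   first projected pattern is smaller than the final desired size).
#' @return A `correction_state`.
#' @export
correction_state <- function(target, gain = 0.8, tolerance = 5,
                             initial_offset = 15) {
  target <- as_polygon_shape(target)
  ctr <- target$center
  v <- target$vertices
  proj <- v
  for (i in seq_len(nrow(v))) {
    r <- sqrt(sum((v[i, ] - ctr)^2))
    proj[i, ] <- ctr + (v[i, ] - ctr) * max(0.05, (r - initial_offset) / r)
  }
  structure(list(iteration = 0L, target = target,
                 projected = polygon_shape(proj, center = ctr),
                 deviations = NULL, converged = FALSE,
                 gain = gain, tolerance = tolerance,
                 history = list()),
            class = "correction_state")
}

#' One pattern update of the dynamic-correction loop
#'
#' Classified vertices whose deviation exceeds the tolerance are moved
#' radially by `-gain * deviation`: a leading trench is cut deeper, a
#' trailing tip extended, implementing the tip/trench angle rule. Vertices
#' within tolerance are untouched; the state converges when all deviations
#' are within tolerance.
#'
#' @param state A `correction_state` whose `deviations` are populated.
#' @return Updated `correction_state`.
#' @export
update_pattern <- function(state) {
  stopifnot(inherits(state, "correction_state"), !is.null(state$deviations))
  dev <- state$deviations
  if (all(abs(dev$deviation) <= state$tolerance)) {
    state$converged <- TRUE
    return(state)
  }
  ctr <- state$target$center
  proj <- state$projected$vertices
  for (k in seq_len(nrow(dev))) {
    if (abs(dev$deviation[k]) <= state$tolerance) next
    i <- dev$vertex[k]
    p <- proj[i, ]
    r <- sqrt(sum((p - ctr)^2))
    r_new <- max(1e-3, r - state$gain * dev$deviation[k])
    proj[i, ] <- ctr + (p - ctr) * (r_new / r)
  }
  state$projected <- polygon_shape(proj, center = ctr)
  state$converged <- FALSE
  state
}

#' Run the closed-loop dynamic pattern correction
#'
#' Alternates project -> simulate/observe -> measure -> update against a
#' simulator handle until every tip and trench deviation is within tolerance
#' or `max_iters` is reached.
#'
#' @param design Desired `polygon_shape` (or `shape`).
#' @param loop Simulator handle: `function(projected, iteration)` returning
#'   the observed cure-front contour as an n x 2 matrix (um). The handle owns
#'   exposure and flushing semantics.
#' @param max_iters Maximum iterations.
#' @param tolerance Convergence tolerance, um.
#' @param gain Correction gain.
#' @param initial_offset Radial shrink of the first projection, um.
#' @return Final `correction_state`; `$history` holds each iteration's
#'   deviation table.
#' @export
run_dynamic_correction <- function(design, loop, max_iters = 6, tolerance = 5,
                                   gain = 0.8, initial_offset = 15) {
  stopifnot(is.function(loop), max_iters >= 1)
  state <- correction_state(design, gain = gain, tolerance = tolerance,
                            initial_offset = initial_offset)
  for (it in seq_len(max_iters)) {
    state$iteration <- it
    contour <- loop(state$projected, it)
    state$deviations <- measure_vertex_deviation(contour, state$target)
    state$history[[it]] <- state$deviations
    if (all(abs(state$deviations$deviation) <= tolerance)) {
      state$converged <- TRUE
      break
    }
    state <- update_pattern(state)
  }
  state
}
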