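# Vector shape constructors and the built-in test fixtures. A `shape` is
# either a circle (centre + radius) or a simple closed polygon; both carry
# coordinates in micrometres.

#' Create a circle shape
#' @param center Length-2 numeric, centre in um.
#' @param radius Radius in um.
#' @return A `shape` object of kind "circle".
#' @export
circle_shape <- function(center, radius) {
  stopifnot(radius > 0)
  structure(list(kind = "circle", center = as.numeric(center), radius = radius),
            class = "shape")
}

#' Create a polygon shape from a vertex matrix
#' @param vertices n x 2 matrix of um coordinates (not closed).
#' @return A `shape` object of kind "polygon".
#' @export
polygon_shape_simple <- function(vertices) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  if (polygon_area(vertices) < 1e-9)
    stop("degenerate (zero-area) polygon shape")
  structure(list(kind = "polygon", vertices = ensure_ccw(vertices)),
            class = "shape")
}

#' Axis-aligned rectangle shape
#' @param center Length-2 numeric centre (um).
#' @param w,h Width and height (um).
#' @export
rect_shape <- function(center, w, h) {
  cx <- center[1]; cy <- center[2]
  polygon_shape_simple(cbind(
    c(cx - w / 2, cx + w / 2, cx + w / 2, cx - w / 2),
    c(cy - h / 2, cy - h / 2, cy + h / 2, cy + h / 2)))
}

#' Regular star polygon
#'
#' @param center Length-2 numeric centre (um).
#' @param n_points Number of tips (default 5).
#' @param r_outer,r_inner Outer (tip) and inner (trench) radii in um.
#' @param phase Rotation of the first tip, radians.
#' @return A polygon `shape` with 2 * n_points vertices.
#' @export
star_shape <- function(center = c(0, 0), n_points = 5, r_outer = 150,
                       r_inner = 60, phase = pi / 2) {
  ang <- phase + seq(0, 2 * pi, length.out = 2 * n_points + 1)[-(2 * n_points + 1)]
  r <- rep(c(r_outer, r_inner), n_points)
  polygon_shape_simple(cbind(center[1] + r * cos(ang), center[2] + r * sin(ang)))
}

#' Polygonal approximation of a shape
#' @param shape A `shape`.
#' @param n_circle Vertices used to approximate circles.
#' @return n x 2 vertex matrix.
#' @export
shape_vertices <- function(shape, n_circle = 96) {
  if (shape$kind == "circle") {
    th <- seq(0, 2 * pi, length.out = n_circle + 1)[-(n_circle + 1)]
    cbind(shape$center[1] + shape$radius * cos(th),
          shape$center[2] + shape$radius * sin(th))
  } else shape$vertices
}

#' Shape centroid
#' @param shape A `shape`.
#' @return Length-2 numeric (um).
#' @export
shape_center <- function(shape) {
  if (shape$kind == "circle") shape$center else polygon_centroid(shape$vertices)
}

#' Shape bounding box
#' @param shape A `shape`.
#' @return List with `xlim` and `ylim`.
#' @keywords internal
shape_bbox <- function(shape) {
  v <- shape_vertices(shape)
  list(xlim = range(v[, 1]), ylim = range(v[, 2]))
}

# Block-letter bars (axis-aligned rectangles) for the text demo. Each letter
# occupies a width x height box anchored at (x0, y0) lower-left.
letter_bars <- function(letter, x0, y0, w = 60, h = 100, t = 16) {
  bar <- function(cx, cy, bw, bh) rect_shape(c(x0 + cx, y0 + cy), bw, bh)
  switch(toupper(letter),
    "L" = list(bar(t / 2, h / 2, t, h), bar(w / 2, t / 2, w, t)),
    "E" = list(bar(t / 2, h / 2, t, h), bar(w / 2, h - t / 2, w, t),
               bar(w / 2, h / 2, w, t), bar(w / 2, t / 2, w, t)),
    "H" = list(bar(t / 2, h / 2, t, h), bar(w - t / 2, h / 2, t, h),
               bar(w / 2, h / 2, w, t)),
    "I" = list(bar(w / 2, h / 2, t, h)),
    "G" = list(bar(t / 2, h / 2, t, h), bar(w / 2, h - t / 2, w, t),
               bar(w / 2, t / 2, w, t), bar(w - t / 2, h / 4, t, h / 2),
               bar(3 * w / 4, h / 2, w / 2, t)),
    stop("unsupported letter: ", letter)
  )
}

#' Built-in device fixtures
#'
#' Programmatic designs used throughout the tests and examples: a five-point
#' star, a small DLD array, a 3x3 grid of circular pillars, and a block-letter
#' text design compiled like any other device.
#'
#' @param name One of "star", "dld", "grid3x3", "lehigh".
#' @param ... Overrides passed to the underlying generator:
#'   for "grid3x3", `diameter` (um, default 25) and `gap` (um, default 30);
#'   for "dld", fields of [dld_spec()]; for "star", arguments of
#'   [star_shape()].
#' @return A [device_design()] object.
#' @export
fixture_design <- function(name = c("star", "dld", "grid3x3", "lehigh"), ...) {
  name <- match.arg(name)
  opts <- list(...)
  if (name == "star") {
    sh <- do.call(star_shape, c(list(center = c(200, 200)), opts))
    return(device_design(cured = list(sh)))
  }
  if (name == "grid3x3") {
    d <- if (is.null(opts$diameter)) 25 else opts$diameter
    g <- if (is.null(opts$gap)) 30 else opts$gap
    pitch <- d + g
    cent <- expand.grid(x = (0:2) * pitch, y = (0:2) * pitch)
    cured <- lapply(seq_len(nrow(cent)), function(i)
      circle_shape(c(cent$x[i] + 200, cent$y[i] + 200), d / 2))
    return(device_design(cured = cured))
  }
  if (name == "dld") {
    spec <- do.call(dld_spec, opts)
    return(generate_dld(spec))
  }
  # "lehigh": block letters inside a channel strip
  letters <- c("L", "E", "H", "I", "G", "H")
  adv <- 80
  cured <- list()
  for (i in seq_along(letters))
    cured <- c(cured, letter_bars(letters[i], 100 + (i - 1) * adv, 100))
  chan <- rect_shape(c(100 + length(letters) * adv / 2, 250), length(letters) * adv + 200, 60)
  device_design(cured = cured, channels = list(chan))
}
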