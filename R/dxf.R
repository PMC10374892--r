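# Minimal ASCII DXF reader/writer for the device-design dialect: closed
# LWPOLYLINE and CIRCLE entities on layers named CURE and CHANNEL. No
# installed R package parses DXF, so the group-code/value scan is implemented
# here; everything outside the dialect is rejected loudly.

#' Write a device design as an ASCII DXF file
#'
#' Cured regions go to layer CURE, channel voids to layer CHANNEL; polygons
#' become closed LWPOLYLINEs and circles CIRCLE entities. Units are um.
#'
#' @param design A [device_design()].
#' @param path Output file path.
#' @export
write_design_dxf <- function(design, path) {
  lines <- c("0", "SECTION", "2", "ENTITIES")
  emit_shape <- function(s, layer) {
    if (s$kind == "circle") {
      c("0", "CIRCLE", "8", layer,
        "10", format(s$center[1], digits = 17),
        "20", format(s$center[2], digits = 17),
        "40", format(s$radius, digits = 17))
    } else {
      v <- s$vertices
      c("0", "LWPOLYLINE", "8", layer,
        "90", as.character(nrow(v)), "70", "1",
        unlist(lapply(seq_len(nrow(v)), function(i)
          c("10", format(v[i, 1], digits = 17), "20", format(v[i, 2], digits = 17)))))
    }
  }
  for (s in design$cured) lines <- c(lines, emit_shape(s, "CURE"))
  for (s in design$channels) lines <- c(lines, emit_shape(s, "CHANNEL"))
  lines <- c(lines, "0", "ENDSEC", "0", "EOF")
  writeLines(lines, path)
  invisible(path)
}

#' Read a device design from a DXF file
#'
#' Accepts closed LWPOLYLINE and CIRCLE entities on layers CURE (regions to
#' polymerize) and CHANNEL (voids that must stay open). Open polylines are
#' rejected with their entity handle or index; unsupported entity types or
#' layers are listed in the error.
#'
#' @param path DXF file path.
#' @return A [device_design()].
#' @export
read_design_dxf <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  if (length(raw) %% 2 != 0) raw <- raw[-length(raw)]
  codes <- suppressWarnings(as.integer(raw[seq(1, length(raw), 2)]))
  vals <- raw[seq(2, length(raw), 2)]
  n <- length(codes)
  cured <- list(); channels <- list()
  unsupported <- character(0)
  i <- 1L
  ent_idx <- 0L
  in_entities <- FALSE
  while (i <= n) {
    if (codes[i] == 0L && vals[i] == "SECTION") {
      in_entities <- i + 1L <= n && codes[i + 1L] == 2L && vals[i + 1L] == "ENTITIES"
      i <- i + 2L
      next
    }
    if (codes[i] == 0L && vals[i] %in% c("ENDSEC", "EOF")) { in_entities <- FALSE; i <- i + 1L; next }
    if (!in_entities || codes[i] != 0L) { i <- i + 1L; next }
    etype <- vals[i]
    ent_idx <- ent_idx + 1L
    # collect this entity's records
    j <- i + 1L
    while (j <= n && codes[j] != 0L) j <- j + 1L
    ec <- codes[seq(i + 1L, length.out = max(0L, j - i - 1L))]
    ev <- vals[seq(i + 1L, length.out = max(0L, j - i - 1L))]
    layer <- if (any(ec == 8L)) ev[which(ec == 8L)[1]] else ""
    handle <- if (any(ec == 5L)) ev[which(ec == 5L)[1]] else sprintf("#%d", ent_idx)
    if (!etype %in% c("LWPOLYLINE", "CIRCLE")) {
      unsupported <- c(unsupported, sprintf("%s (%s)", etype, handle))
      i <- j
      next
    }
    if (!layer %in% c("CURE", "CHANNEL")) {
      unsupported <- c(unsupported, sprintf("%s on layer '%s' (%s)", etype, layer, handle))
      i <- j
      next
    }
    shape <- if (etype == "CIRCLE") {
      cx <- as.numeric(ev[which(ec == 10L)[1]])
      cy <- as.numeric(ev[which(ec == 20L)[1]])
      r <- as.numeric(ev[which(ec == 40L)[1]])
      circle_shape(c(cx, cy), r)
    } else {
      closed <- any(ec == 70L) && bitwAnd(as.integer(ev[which(ec == 70L)[1]]), 1L) == 1L
      if (!closed)
        stop(sprintf("open LWPOLYLINE rejected (entity handle %s)", handle))
      xs <- as.numeric(ev[ec == 10L])
      ys <- as.numeric(ev[ec == 20L])
      polygon_shape_simple(cbind(xs, ys))
    }
    if (layer == "CURE") cured <- c(cured, list(shape)) else channels <- c(channels, list(shape))
    i <- j
  }
  if (length(unsupported) > 0)
    stop("unsupported DXF entities: ", paste(unsupported, collapse = ", "))
  device_design(cured = cured, channels = channels)
}
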