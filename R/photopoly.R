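# Finite-difference reaction-diffusion model of free-radical UV
# photopolymerization. Species (per grid cell, monomer-equivalent
# concentration units): S photoinitiator, R radical, M monomer, P polymer.
#
#   dS/dt = -k_i * I * S
#   dR/dt = D_R lap R + k_i * I * S - 2 * k_t_eff * R^2
#   dM/dt = D_M lap M - k_p * R * M
#   dP/dt =             k_p * R * M
#
# with no-flux boundaries and k_t_eff = k_t / (1 + gamma_t * P / M0)^2: the
# termination coefficient drops with local conversion (Trommsdorff gel
# effect), which turns the cure-vs-dose response into a sharp ignition
# sigmoid -- a steep gel front with a long shallow partial-cure tail -- and
# makes pre-dosed regions cure visibly faster under a subsequent exposure.
# gamma_t = 0 recovers constant-coefficient kinetics.
# Cells marked solid (cured and retained through a flush) are frozen: no
# reaction and no diffusive flux across them.

#' Kinetic and material parameters
#'
#' Defaults are a calibrated operating point, not literature constants: the
#' rate coefficients, diffusivity and illumination tail are jointly tuned so
#' the in-silico critical-distance calibration returns 150 um and the graded
#' single-exposure partial-cure zone extends beyond 70 um (see the methods
#' vignette).
#'
#' @param k_i Photolysis rate per unit intensity, 1/(s * mW/cm^2).
#' @param k_p Propagation rate coefficient, 1/(s * conc).
#' @param k_t Termination rate coefficient at zero conversion, 1/(s * conc).
#' @param gamma_t Dimensionless gel-effect strength; termination is divided by
#'   (1 + gamma_t * P / M0)^2.
#' @param D_R Radical diffusivity, um^2/s.
#' @param D_M Monomer diffusivity, um^2/s (0 by default).
#' @param S0,M0 Initial photoinitiator and monomer concentrations (arbitrary
#'   units).
#' @param theta_gel Normalized cure level at and above which material gels and
#'   survives a flush.
#' @param theta_partial Normalized cure level that counts as detectable
#'   partial cure.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(k_i = 0.08, k_p = 3, k_t = 0.5, gamma_t = 0,
                           D_R = 30, D_M = 0, S0 = 1, M0 = 1,
                           theta_gel = 0.5, theta_partial = 0.05) {
  stopifnot(k_i >= 0, k_p >= 0, k_t >= 0, gamma_t >= 0, D_R >= 0, D_M >= 0,
            S0 > 0, M0 > 0, theta_partial > 0, theta_partial < theta_gel,
            theta_gel <= 1)
  structure(list(k_i = k_i, k_p = k_p, k_t = k_t, gamma_t = gamma_t,
                 D_R = D_R, D_M = D_M, S0 = S0, M0 = M0,
                 theta_gel = theta_gel, theta_partial = theta_partial),
            class = "kinetic_params")
}

#' Simulation domain
#'
#' @param mode "plan_view_2d" (depth-averaged x-y film) or "axisymmetric_rz"
#'   (r-z cut through a circular exposure).
#' @param extent Length-2 numeric, domain size per axis in um: (x, y) or
#'   (r_max, H).
#' @param grid_spacing Cell pitch, um.
#' @param height Film height H, um (records the film thickness; the plan-view
#'   model is depth-averaged).
#' @param exposure_time Exposure duration T, s.
#' @param dt Time step, s; NULL selects 0.9x the stability bound.
#' @return A `sim_domain` object.
#' @export
sim_domain <- function(mode = c("plan_view_2d", "axisymmetric_rz"),
                       extent, grid_spacing = 1, height = 20,
                       exposure_time = 1, dt = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(extent) == 2, all(extent > 0), grid_spacing > 0,
            height > 0, exposure_time >= 0)
  structure(list(mode = mode, extent = as.numeric(extent),
                 grid_spacing = grid_spacing, height = height,
                 exposure_time = exposure_time, dt = dt),
            class = "sim_domain")
}

#' Stability bounds for the explicit scheme
#'
#' The diffusion (FTCS) bound is h^2 / (4 * max(D_R, D_M)); the reaction bound
#' keeps the explicit update of the stiffest local rate positive.
#'
#' @param params [kinetic_params()].
#' @param grid_spacing Cell pitch, um.
#' @param I_max Peak intensity the field will see, mW/cm^2.
#' @return List with `diffusion`, `reaction` and the selected `dt`
#'   (0.9 x the binding bound).
#' @export
stability_bounds <- function(params, grid_spacing, I_max) {
  dmax <- max(params$D_R, params$D_M)
  b_diff <- if (dmax > 0) grid_spacing^2 / (4 * dmax) else Inf
  rates <- c(params$k_i * I_max)
  if (params$k_t > 0 && params$k_i * I_max > 0) {
    # radical level near quasi-steady state, at the strongest gel boost
    # (termination itself is integrated semi-implicitly and needs no bound)
    kt_min <- params$k_t / (1 + params$gamma_t)
    r_qss <- sqrt(params$k_i * I_max * params$S0 / (2 * max(kt_min, 1e-12)))
    rates <- c(rates, params$k_p * r_qss)
  }
  b_react <- if (any(rates > 0)) 0.5 / max(rates) else Inf
  list(diffusion = b_diff, reaction = b_react, dt = 0.9 * min(b_diff, b_react))
}

# Fresh species state on the grid of a light field.
new_species_fields <- function(light, params, mode = "plan_view_2d") {
  dims <- dim(light$values)
  z <- matrix(0, dims[1], dims[2])
  structure(list(S = z + params$S0, R = z, M = z + params$M0, P = z,
                 solid = matrix(FALSE, dims[1], dims[2]),
                 grid_spacing = light$grid_spacing,
                 origin = light$origin, mode = mode, n_clipped = 0L),
            class = "species_fields")
}

#' @export
print.species_fields <- function(x, ...) {
  cat(sprintf("species_fields (%s): %d x %d @ %.3g um; max P %.4g; %d solid cells\n",
              x$mode, ncol(x$S), nrow(x$S), x$grid_spacing, max(x$P), sum(x$solid)))
  invisible(x)
}

# Neighbour shifts with no-flux walls: returns the sum of (neighbour - centre)
# over the 4 neighbours, with fluxes into solid cells (and across the domain
# wall) suppressed. Plan-view Cartesian Laplacian * h^2.
lap_sum_2d <- function(f, solid) {
  nr <- nrow(f); nc <- ncol(f)
  up    <- rbind(f[1, , drop = FALSE], f[-nr, , drop = FALSE])
  down  <- rbind(f[-1, , drop = FALSE], f[nr, , drop = FALSE])
  left  <- cbind(f[, 1, drop = FALSE], f[, -nc, drop = FALSE])
  right <- cbind(f[, -1, drop = FALSE], f[, nc, drop = FALSE])
  if (any(solid)) {
    s_up    <- rbind(solid[1, , drop = FALSE], solid[-nr, , drop = FALSE])
    s_down  <- rbind(solid[-1, , drop = FALSE], solid[nr, , drop = FALSE])
    s_left  <- cbind(solid[, 1, drop = FALSE], solid[, -nc, drop = FALSE])
    s_right <- cbind(solid[, -1, drop = FALSE], solid[, nc, drop = FALSE])
    du <- (up - f);    du[s_up]    <- 0
    dd <- (down - f);  dd[s_down]  <- 0
    dl <- (left - f);  dl[s_left]  <- 0
    dr <- (right - f); dr[s_right] <- 0
    du + dd + dl + dr
  } else {
    (up - f) + (down - f) + (left - f) + (right - f)
  }
}

# Cylindrical (r-z) Laplacian * h^2 in conservative finite-volume form.
# Columns are radial cells at r_j = (j - 1/2) h (so the axis face flux is
# exactly zero); rows are z with row 1 at the top.
lap_sum_rz <- function(f, solid, h) {
  nr <- nrow(f); nc <- ncol(f)
  rj <- (seq_len(nc) - 0.5)
  r_in <- rj - 0.5   # inner face radius / h
  r_out <- rj + 0.5
  left  <- cbind(f[, 1, drop = FALSE], f[, -nc, drop = FALSE])
  right <- cbind(f[, -1, drop = FALSE], f[, nc, drop = FALSE])
  up    <- rbind(f[1, , drop = FALSE], f[-nr, , drop = FALSE])
  down  <- rbind(f[-1, , drop = FALSE], f[nr, , drop = FALSE])
  dl <- sweep(left - f, 2, r_in / rj, `*`)
  dr <- sweep(right - f, 2, r_out / rj, `*`)
  # outer radial wall: no flux
  dr[, nc] <- 0
  dl[, 1] <- 0  # axis (r_in = 0 there anyway)
  du <- up - f
  dd <- down - f
  if (any(solid)) {
    s_left  <- cbind(solid[, 1, drop = FALSE], solid[, -nc, drop = FALSE])
    s_right <- cbind(solid[, -1, drop = FALSE], solid[, nc, drop = FALSE])
    s_up    <- rbind(solid[1, , drop = FALSE], solid[-nr, , drop = FALSE])
    s_down  <- rbind(solid[-1, , drop = FALSE], solid[nr, , drop = FALSE])
    dl[s_left] <- 0; dr[s_right] <- 0; du[s_up] <- 0; dd[s_down] <- 0
  }
  dl + dr + du + dd
}

#' One explicit time step of the photopolymerization kinetics
#'
#' @param fields A `species_fields` state.
#' @param light A [build_light_field()] field on the same grid.
#' @param params [kinetic_params()].
#' @param dt Time step, s. Must satisfy the FTCS stability bound
#'   h^2 / (4 max(D_R, D_M)); violations are refused with the admissible
#'   bound in the error message.
#' @return Updated `species_fields`; the count of negativity clips is
#'   accumulated in `$n_clipped`.
#' @export
step_kinetics <- function(fields, light, params, dt) {
  stopifnot(inherits(fields, "species_fields"))
  if (!all(dim(fields$S) == dim(light$values)))
    stop("light field and species grids differ")
  dmax <- max(params$D_R, params$D_M)
  if (dmax > 0) {
    bound <- fields$grid_spacing^2 / (4 * dmax)
    if (dt > bound * (1 + 1e-9))
      stop(sprintf("dt = %g s violates the explicit stability bound; admissible dt <= %g s",
                   dt, bound))
  }
  I <- light$values
  h2 <- fields$grid_spacing^2
  solid <- fields$solid
  live <- !solid
  S <- fields$S; R <- fields$R; M <- fields$M; P <- fields$P
  kt_eff <- params$k_t / (1 + params$gamma_t * P / params$M0)^2
  lap <- if (fields$mode == "axisymmetric_rz") {
    function(f) lap_sum_rz(f, solid, fields$grid_spacing)
  } else {
    function(f) lap_sum_2d(f, solid)
  }
  gen <- params$k_i * I * S
  prop <- params$k_p * R * M
  dS <- -gen
  # radical production + diffusion explicit; the stiff quadratic termination
  # sink is folded in semi-implicitly, which preserves positivity at any dt
  dR_expl <- gen
  if (params$D_R > 0) dR_expl <- dR_expl + params$D_R * lap(R) / h2
  dM <- -prop
  if (params$D_M > 0) dM <- dM + params$D_M * lap(M) / h2
  dP <- prop
  # frozen solid: no reaction inside
  Sn <- S; Rn <- R; Mn <- M; Pn <- P
  Sn[live] <- S[live] + dt * dS[live]
  Rn[live] <- (R[live] + dt * dR_expl[live]) /
    (1 + 2 * dt * kt_eff[live] * R[live])
  Mn[live] <- M[live] + dt * dM[live]
  Pn[live] <- P[live] + dt * dP[live]
  nclip <- sum(Sn < 0) + sum(Rn < 0) + sum(Mn < 0)
  if (nclip > 0) { Sn[Sn < 0] <- 0; Rn[Rn < 0] <- 0; Mn[Mn < 0] <- 0 }
  fields$S <- Sn; fields$R <- Rn; fields$M <- Mn; fields$P <- Pn
  fields$n_clipped <- fields$n_clipped + nclip
  fields
}

#' Run a full exposure
#'
#' Integrates `exposure_time / dt` explicit steps of [step_kinetics()] under a
#' fixed light field and returns the raw species state plus the normalized
#' polymer field. An optional per-frame callback supports closed-loop control:
#' it is called every `frame_dt` of simulated time with `(fields, t)` and may
#' return FALSE to switch the light off (the run then stops and records the
#' trigger time).
#'
#' @param domain A [sim_domain()].
#' @param light A light field whose grid matches the domain
#'   (`extent / grid_spacing` cells per axis).
#' @param params [kinetic_params()].
#' @param fields Optional pre-existing `species_fields` to continue from
#'   (e.g. carrying solidified material); default is fresh pre-polymer.
#' @param on_frame Optional callback `function(fields, t)`.
#' @param frame_dt Simulated seconds between callback invocations.
#' @return List with `fields`, `norm` ([normalize_polymer()] of P),
#'   `time_on` (seconds of light actually delivered) and `dt`.
#' @export
run_exposure <- function(domain, light, params, fields = NULL,
                         on_frame = NULL, frame_dt = 0.01) {
  stopifnot(inherits(domain, "sim_domain"))
  nx <- as.integer(round(domain$extent[1] / domain$grid_spacing))
  ny <- as.integer(round(domain$extent[2] / domain$grid_spacing))
  if (domain$mode == "axisymmetric_rz") { nc <- nx; nr <- ny } else { nc <- nx; nr <- ny }
  if (!all(dim(light$values) == c(nr, nc)))
    stop(sprintf("light field grid (%d x %d) inconsistent with domain (%d x %d)",
                 nrow(light$values), ncol(light$values), nr, nc))
  if (is.null(fields)) fields <- new_species_fields(light, params, domain$mode)
  dt <- domain$dt
  if (is.null(dt)) dt <- stability_bounds(params, domain$grid_spacing, max(light$values, 1e-9))$dt
  t_end <- domain$exposure_time
  if (t_end <= 0 || max(light$values) <= 0)
    return(list(fields = fields, norm = normalize_polymer(fields), time_on = 0, dt = dt))
  n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  t <- 0
  next_frame <- frame_dt
  for (k in seq_len(n_steps)) {
    step <- min(dt, t_end - t)
    fields <- step_kinetics(fields, light, params, step)
    t <- t + step
    if (!is.null(on_frame) && (t + 1e-12 >= next_frame || k == n_steps)) {
      next_frame <- next_frame + frame_dt
      keep_going <- on_frame(fields, t)
      if (identical(keep_going, FALSE)) break
    }
  }
  list(fields = fields, norm = normalize_polymer(fields), time_on = t, dt = dt)
}

#' Normalize a polymer field to its spatial maximum
#'
#' The highest spatial polymer concentration is scaled to 1; an all-zero
#' field stays all-zero with `reference_max = 0`.
#'
#' @param P Polymer matrix, or a `species_fields` state (its `$P` is used and
#'   the grid metadata is carried over).
#' @param reference_max Optional externally supplied normalization constant
#'   (e.g. the maximum of a reference exposure) overriding the spatial max.
#' @return A `norm_polymer`: list with `values` in `[0, 1]` (possibly above 1
#'   when `reference_max` is supplied), `reference_max` and grid metadata.
#' @export
normalize_polymer <- function(P, reference_max = NULL) {
  meta <- list(grid_spacing = NA_real_, origin = c(NA_real_, NA_real_),
               mode = "plan_view_2d")
  if (inherits(P, "species_fields")) {
    meta <- P[c("grid_spacing", "origin", "mode")]
    P <- P$P
  }
  if (any(P < 0)) stop("polymer field must be non-negative")
  ref <- if (is.null(reference_max)) max(P) else reference_max
  vals <- if (ref > 0) P / ref else P * 0
  structure(c(list(values = vals, reference_max = ref), meta),
            class = "norm_polymer")
}

#' Radial extent of the partial-cure zone beyond the pattern edge
#'
#' The farthest distance outside the pattern boundary at which the normalized
#' polymer level still reaches `theta`. In axisymmetric mode the bottom layer
#' (last z row) is used and `pattern` is the pattern radius in um; in plan
#' view `pattern` is a `shape` and distances are Euclidean distances to its
#' boundary.
#'
#' @param norm A [normalize_polymer()] result.
#' @param pattern Pattern radius (um, axisymmetric) or a `shape` (plan view).
#' @param theta Detection level in (0, 1); defaults to the partial-cure
#'   threshold 0.05.
#' @return Extent in um (0 when no cell outside the pattern reaches theta).
#' @export
measure_partial_zone_extent <- function(norm, pattern, theta = 0.05) {
  stopifnot(inherits(norm, "norm_polymer"))
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (norm$mode == "axisymmetric_rz") {
    stopifnot(is.numeric(pattern), length(pattern) == 1)
    prof <- norm$values[nrow(norm$values), ]  # bottom layer
    r <- (seq_along(prof) - 0.5) * norm$grid_spacing
    out <- which(prof >= theta & r > pattern)
    if (length(out) == 0) return(0)
    r_hit <- r[max(out)]
    # sub-cell refinement: linear interpolation to the theta crossing
    j <- max(out)
    if (j < length(prof) && prof[j + 1] < theta && prof[j] > prof[j + 1]) {
      fr <- (prof[j] - theta) / (prof[j] - prof[j + 1])
      r_hit <- r[j] + fr * norm$grid_spacing
    }
    return(max(0, r_hit - pattern))
  }
  # plan view
  stopifnot(inherits(pattern, "shape"))
  nr <- nrow(norm$values); nc <- ncol(norm$values)
  xs <- grid_x(nc, norm$grid_spacing, norm$origin)
  ys <- grid_y(nr, norm$grid_spacing, norm$origin)
  idx <- which(norm$values >= theta, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  pts <- cbind(xs[idx[, 2]], ys[idx[, 1]])
  v <- shape_vertices(pattern)
  inside <- points_in_polygon(pts, v)
  if (all(inside)) return(0)
  max(dist_to_polygon_edge(pts[!inside, , drop = FALSE], v))
}

#' Flush partially cured material
#'
#' Cells at or above the gel threshold are retained and marked solid (frozen
#' out of further reaction and diffusion); everywhere else the device is
#' refilled with fresh pre-polymer: S -> S0, M -> M0, R -> 0, P -> 0.
#'
#' @param fields `species_fields` state.
#' @param norm [normalize_polymer()] of the same grid (supply a
#'   `reference_max` normalization when comparing across exposures).
#' @param params [kinetic_params()] providing `theta_gel`.
#' @return Flushed `species_fields`.
#' @export
apply_flush <- function(fields, norm, params) {
  stopifnot(inherits(fields, "species_fields"), inherits(norm, "norm_polymer"))
  if (!all(dim(norm$values) == dim(fields$P)))
    stop("normalized field and species grids differ")
  gel <- norm$values >= params$theta_gel
  solid <- fields$solid | gel
  fresh <- !solid
  fields$S[fresh] <- params$S0
  fields$M[fresh] <- params$M0
  fields$P[fresh] <- 0
  fields$R[] <- 0
  fields$solid <- solid
  fields
}

#' Export species snapshots as 32-bit TIFF plus JSON metadata
#'
#' Each field is scaled to `[0, 1]` for storage; the JSON sidecar records the
#' scale factors, grid spacing, origin and time so values round-trip.
#'
#' @param fields `species_fields`.
#' @param path_prefix Output prefix; writes `<prefix>_<species>.tif` and
#'   `<prefix>.json`.
#' @param time Simulation time to record, s.
#' @export
write_species_snapshot <- function(fields, path_prefix, time = NA_real_) {
  scales <- list()
  for (nm in c("S", "R", "M", "P")) {
    m <- fields[[nm]]
    sc <- max(m, 1e-300)
    tiff::writeTIFF(m / sc, paste0(path_prefix, "_", nm, ".tif"),
                    bits.per.sample = 32L)
    scales[[nm]] <- sc
  }
  meta <- list(grid_spacing = fields$grid_spacing, origin = fields$origin,
               mode = fields$mode, time = time, scales = scales)
  jsonlite::write_json(meta, paste0(path_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path_prefix)
}
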