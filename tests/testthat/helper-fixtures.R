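# Shared fixtures and independent oracles used across the suite.

# Independent stiff-ODE integration of the zero-diffusion kinetics
# (deSolve::lsoda), used as the oracle for the explicit scheme.
ode_oracle <- function(params, I, t_end) {
  rhs <- function(t, y, p) {
    kt_eff <- p$k_t / (1 + p$gamma_t * y[4] / p$M0)^2
    gen <- p$k_i * I * y[1]
    prop <- p$k_p * y[2] * y[3]
    list(c(-gen, gen - 2 * kt_eff * y[2]^2, -prop, prop))
  }
  y0 <- c(S = params$S0, R = 0, M = params$M0, P = 0)
  out <- deSolve::lsoda(y0, c(0, t_end), rhs, params,
                        rtol = 1e-10, atol = 1e-12)
  out[nrow(out), c("S", "R", "M", "P")]
}

# Run the explicit scheme on a single cell with zero diffusion.
single_cell_run <- function(params, I, t_end, dt) {
  light <- structure(list(values = matrix(I, 1, 1), grid_spacing = 1,
                          origin = c(0, 0)),
                     class = "light_field")
  fields <- igisml:::new_species_fields(light, params)
  n <- ceiling(t_end / dt)
  for (k in seq_len(n)) {
    step <- min(dt, t_end - (k - 1) * dt)
    fields <- step_kinetics(fields, light, params, step)
  }
  c(S = fields$S[1, 1], R = fields$R[1, 1], M = fields$M[1, 1], P = fields$P[1, 1])
}

# Exhaustive chromatic number of a small conflict graph (adjacency matrix),
# by branch and bound over color assignments. Oracle for the greedy slicer.
chromatic_number <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  for (k in 1:n) {
    colors <- integer(n)
    feasible <- function(i) {
      if (i > n) return(TRUE)
      for (c in seq_len(k)) {
        if (any(adj[i, ] & colors == c)) next
        colors[i] <<- c
        if (feasible(i + 1)) return(TRUE)
        colors[i] <<- 0L
      }
      FALSE
    }
    if (feasible(1L)) return(k)
  }
  n
}

# Conflict adjacency of a unit set under the centre metric.
units_conflict_adj <- function(units, d_critical) {
  centers <- t(vapply(units, function(u) u$center, numeric(2)))
  d <- as.matrix(stats::dist(centers))
  adj <- d < d_critical
  diag(adj) <- FALSE
  adj
}

# A quick single-circle exposure returning cure fields (shared by several
# photopolymerization tests).
quick_exposure <- function(params = kinetic_params(), peak = 22 * 0.24,
                           radius = 12.5, t_end = 1, h = 2, half = 80,
                           kind = "graded") {
  pr <- illumination_profile(peak, kind)
  m <- rasterize_pattern(circle_shape(c(0, 0), radius), h,
                         xlim = c(-half, half), ylim = c(-half, half), pad = 0)
  lf <- build_light_field(m, pr)
  dom <- sim_domain("plan_view_2d", extent = c(2 * half, 2 * half),
                    grid_spacing = h, exposure_time = t_end)
  run_exposure(dom, lf, params)
}
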