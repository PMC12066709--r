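# Single-grain flow and reactive transport.
#
# Geometry: a circular grain of radius r with a 5 um reactive rim, embedded
# in a concentric annular fluid cell (outer radius 8 r by default) on a
# boundary-fitted polar grid whose radial spacing resolves the rim with
# ~1 um cells.  The creeping-flow field is the analytic Stokes cell-model
# solution (streamfunction psi = U f(r) sin(theta) with no-slip on the
# grain and uniform streamwise velocity / zero vorticity on the outer cell
# boundary), so the advecting field is exactly divergence-free and
# satisfies the Stokes equations to machine precision.  O2 and N2 obey
# stationary advection-diffusion-reaction equations discretised by a
# conservative finite-volume scheme (upwind advection on streamfunction
# face fluxes, central diffusion) and solved with sparse LU; the
# Michaelis-Menten O2 limitation is handled by a damped semi-implicit
# Picard iteration.

#' Configuration for the single-grain model
#'
#' All lengths in micrometres, times in hours internally; rates in
#' mmol L^-1 h^-1 as printed.  The sinusoidal surface reaction alternates
#' `colony_pairs` net O2 consuming colonies (arc `consumer_arc_um`, minima
#' at `R_c_min`) and producing colonies (arc `producer_arc_um`, maxima at
#' `R_c_max`) with bare sediment between them.
#'
#' @param grain_radius_um grain radius (default 145, a 290 um grain).
#' @param rim_thickness_um reactive rim thickness on the grain surface.
#' @param colony_pairs number of consumer/producer colony pairs.
#' @param R_c_min peak volumetric O2 consumption, mmol O2 L^-1 h^-1 (< 0).
#' @param R_c_max peak volumetric O2 production, mmol O2 L^-1 h^-1 (> 0).
#' @param consumer_arc_um,producer_arc_um colony arc lengths on the grain
#'   surface (defaults 76 and 38 um).
#' @param K_m Michaelis-Menten half-saturation of O2 consumption, umol L^-1.
#' @param C_inh O2 inhibition constant of denitrification, umol L^-1.
#' @param N_to_O2_ratio N produced per O2 consumed (default 1/10).
#' @param D_O2_m2_s,D_N2_m2_s free-water diffusion coefficients, m^2 s^-1.
#' @param rim_diffusivity_factor multiplier on diffusivities inside the rim
#'   (1 = free water; ~0.8 emulates EPS-filled colonies).
#' @param viscosity_Pa_s dynamic viscosity of the pore water.
#' @param inflow_velocity_um_s far-field pore-water velocity U (>= 0).
#' @param inflow_O2_umol_L bulk O2 concentration C0 (>= 0).
#' @param domain_radius_factor outer cell radius as a multiple of the
#'   grain radius.
#' @param n_radial_rim,n_radial_outer,n_theta grid resolution: radial cells
#'   across the rim, radial cells outside it (geometrically stretched), and
#'   angular cells.
#' @param anoxia_threshold_umol_L O2 concentration below which a cell
#'   counts as anoxic.
#' @param extrusion_depth_um depth by which the 2D solution is extruded to
#'   report per-grain 3D quantities (default one grain diameter).
#' @param production_on if `FALSE`, positive (production) parts of the
#'   surface reaction are set to zero.
#' @param outer_bc `"inflow_outflow"` (default): the inflow half of the
#'   outer boundary holds the bulk concentrations and the outflow half is
#'   advective-only, mirroring the inlet/outlet of a flow-through domain;
#'   `"dirichlet"`: bulk concentrations held on the whole outer ring
#'   (radially symmetric diffusive supply, useful for stagnant studies).
#' @param reaction_shape `"sinusoidal"` (rates taper from colony core to
#'   edge) or `"uniform"` (constant rate across each colony).
#' @param picard_max,picard_relax,tol_residual nonlinear solver controls.
#' @return validated list of class `grain_model_config`.
#' @export
grain_model_config <- function(grain_radius_um = 145,
                               rim_thickness_um = 5,
                               colony_pairs = 4,
                               R_c_min = -955,
                               R_c_max = 514,
                               consumer_arc_um = 76,
                               producer_arc_um = 38,
                               K_m = 0.1,
                               C_inh = 0.1,
                               N_to_O2_ratio = 0.1,
                               D_O2_m2_s = 1.1e-9,
                               D_N2_m2_s = 2.1e-9,
                               rim_diffusivity_factor = 1.0,
                               viscosity_Pa_s = 1.22e-3,
                               inflow_velocity_um_s = 100,
                               inflow_O2_umol_L = 50,
                               domain_radius_factor = 8,
                               n_radial_rim = 6,
                               n_radial_outer = 50,
                               n_theta = 180,
                               anoxia_threshold_umol_L = 1,
                               extrusion_depth_um = 2 * grain_radius_um,
                               production_on = TRUE,
                               reaction_shape = c("sinusoidal", "uniform"),
                               outer_bc = c("inflow_outflow", "dirichlet"),
                               picard_max = 300,
                               picard_relax = 1.0,
                               tol_residual = 1e-8) {
  cfg <- list(grain_radius_um = grain_radius_um,
              rim_thickness_um = rim_thickness_um,
              colony_pairs = as.integer(colony_pairs),
              R_c_min = R_c_min, R_c_max = R_c_max,
              consumer_arc_um = consumer_arc_um,
              producer_arc_um = producer_arc_um,
              K_m = K_m, C_inh = C_inh, N_to_O2_ratio = N_to_O2_ratio,
              D_O2_m2_s = D_O2_m2_s, D_N2_m2_s = D_N2_m2_s,
              rim_diffusivity_factor = rim_diffusivity_factor,
              viscosity_Pa_s = viscosity_Pa_s,
              inflow_velocity_um_s = inflow_velocity_um_s,
              inflow_O2_umol_L = inflow_O2_umol_L,
              domain_radius_factor = domain_radius_factor,
              n_radial_rim = as.integer(n_radial_rim),
              n_radial_outer = as.integer(n_radial_outer),
              n_theta = as.integer(n_theta),
              anoxia_threshold_umol_L = anoxia_threshold_umol_L,
              extrusion_depth_um = extrusion_depth_um,
              production_on = isTRUE(production_on),
              reaction_shape = match.arg(reaction_shape),
              outer_bc = match.arg(outer_bc),
              picard_max = picard_max, picard_relax = picard_relax,
              tol_residual = tol_residual)
  validate_grain_config(cfg)
  class(cfg) <- "grain_model_config"
  cfg
}

validate_grain_config <- function(cfg) {
  with(cfg, {
    if (!(grain_radius_um > rim_thickness_um && rim_thickness_um > 0))
      stop("need grain_radius_um > rim_thickness_um > 0", call. = FALSE)
    if (!(K_m > 0 && C_inh > 0))
      stop("K_m and C_inh must be positive", call. = FALSE)
    if (!(R_c_min <= 0 && R_c_max >= 0))
      stop("need R_c_min <= 0 <= R_c_max", call. = FALSE)
    if (inflow_velocity_um_s < 0 || inflow_O2_umol_L < 0)
      stop("inflow velocity and O2 must be >= 0", call. = FALSE)
    if (domain_radius_factor <= 1.2)
      stop("outer cell boundary too close to the grain", call. = FALSE)
    if (n_radial_rim < 2)
      stop("need at least 2 radial cells across the rim", call. = FALSE)
    per_pair <- 2 * pi * grain_radius_um / colony_pairs
    if (consumer_arc_um + producer_arc_um > per_pair + 1e-9)
      stop("colony arcs exceed the available perimeter per pair",
           call. = FALSE)
  })
  invisible(cfg)
}

# --- grid -------------------------------------------------------------------

# radial faces: uniform cells across the rim, geometric stretching outside
build_grid <- function(cfg) {
  a <- cfg$grain_radius_um
  w <- cfg$rim_thickness_um
  b <- cfg$domain_radius_factor * a
  h0 <- w / cfg$n_radial_rim
  n_out <- cfg$n_radial_outer
  L <- b - a - w
  grow <- function(q) h0 * q * (q^n_out - 1) / (q - 1) - L
  q <- stats::uniroot(grow, c(1 + 1e-9, 4), tol = 1e-12)$root
  rf <- c(a + h0 * (0:cfg$n_radial_rim),
          a + w + cumsum(h0 * q^(seq_len(n_out))))
  rf[length(rf)] <- b  # absorb rounding
  tf <- seq(0, 2 * pi, length.out = cfg$n_theta + 1L)
  rc <- (rf[-1] + rf[-length(rf)]) / 2
  tc <- (tf[-1] + tf[-length(tf)]) / 2
  dth <- tf[2] - tf[1]
  vol <- outer(0.5 * (rf[-1]^2 - rf[-length(rf)]^2), rep(dth, cfg$n_theta))
  list(rf = rf, tf = tf, rc = rc, tc = tc, dtheta = dth, vol = vol,
       n_r = length(rc), n_t = length(tc), a = a, b = b,
       rim = rc < a + w)
}

# --- analytic Stokes cell-model flow ---------------------------------------

# streamfunction radial profile psi = U f(r) sin(theta),
# f = A/r + B r + C r log r + D r^3 with no slip at r=a, uniform flow and
# zero vorticity at r=b
stokes_cell_coefficients <- function(a, b) {
  # solved in grain-radius units for conditioning; rescaled on return so
  # f(r) keeps length units (A in um^2, B dimensionless, C, D in um^-0/um^-2)
  bb <- b / a
  M <- rbind(c(1, 1, 0, 1),
             c(-1, 1, 1, 3),
             c(1 / bb, bb, bb * log(bb), bb^3),
             c(0, 0, 2 / bb, 8 * bb))
  co <- solve(M, c(0, 0, bb, 0))
  # psi = U f(r), f(r) = a * ftilde(r/a)
  c(co[1] * a^2, co[2] - co[3] * log(a), co[3], co[4] / a^2)
}

#' Solve the creeping-flow field around the grain
#'
#' Evaluates the analytic Stokes cell-model solution on the polar grid:
#' streamfunction at the grid nodes, cell-centre velocities, pressure, and
#' the face volume fluxes used by the solute solver (differences of the
#' streamfunction between face corners, hence exactly divergence-free cell
#' by cell).
#'
#' @param cfg a [grain_model_config()].
#' @return object of class `grain_flow` with the grid, streamfunction
#'   (`psi`, um^2 s^-1 at nodes), velocities `u_r`/`u_theta` (um s^-1 at
#'   cell centres), `pressure_Pa`, and face fluxes `Q_r`/`Q_t` (um^2 h^-1
#'   per unit depth).
#' @export
solve_flow <- function(cfg) {
  stopifnot(inherits(cfg, "grain_model_config"))
  grid <- build_grid(cfg)
  co <- stokes_cell_coefficients(grid$a, grid$b)
  U <- cfg$inflow_velocity_um_s
  f_of <- function(r) co[1] / r + co[2] * r + co[3] * r * log(r) + co[4] * r^3
  fp_of <- function(r) -co[1] / r^2 + co[2] + co[3] * (log(r) + 1) +
    3 * co[4] * r^2
  psi_n <- U * outer(f_of(grid$rf), sin(grid$tf))          # um^2 s^-1
  u_r <- U * outer(f_of(grid$rc) / grid$rc, cos(grid$tc))  # um s^-1
  u_t <- -U * outer(fp_of(grid$rc), sin(grid$tc))
  pressure <- cfg$viscosity_Pa_s * U *
    outer(8 * co[4] * grid$rc - 2 * co[3] / grid$rc, cos(grid$tc))
  psi_h <- psi_n * S_PER_H
  n_t <- grid$n_t
  # outward flux through radial face i spanning theta_j..theta_{j+1}
  Q_r <- psi_h[, -1, drop = FALSE] - psi_h[, -(n_t + 1L), drop = FALSE]
  # +theta flux through angular face at tf[j] spanning rf[i]..rf[i+1]
  Q_t <- psi_h[-nrow(psi_h), , drop = FALSE] - psi_h[-1, , drop = FALSE]
  Q_t <- Q_t[, -(n_t + 1L), drop = FALSE]  # face n_t+1 duplicates face 1
  structure(list(config = cfg, grid = grid, coefficients = co,
                 psi = psi_n, u_r = u_r, u_theta = u_t,
                 pressure_Pa = pressure, Q_r = Q_r, Q_t = Q_t),
            class = "grain_flow")
}

# --- surface reaction field -------------------------------------------------

#' Volumetric O2 reaction rate on the grain surface rim
#'
#' Shifted-sinusoid colony pattern: `colony_pairs` periods of
#' sin(colony_pairs * theta) are thresholded so the arcs where the field is
#' negative (net consumption) and positive (net production) have exactly
#' the configured lengths on the grain surface, with bare sediment between
#' them.  Within a colony the rate tapers from the peak at the colony core
#' (`R_c_min` for consumers, `R_c_max` for producers) to zero at the edges
#' (`reaction_shape = "sinusoidal"`), or is constant
#' (`reaction_shape = "uniform"`).  Zero outside the rim annulus.
#'
#' @param cfg a [grain_model_config()].
#' @param r_um,theta_rad point coordinates (vectors recycle).
#' @return volumetric O2 rate, mmol O2 L^-1 h^-1 (negative = consumption).
#' @export
surface_reaction_field <- function(cfg, r_um, theta_rad) {
  stopifnot(inherits(cfg, "grain_model_config"))
  n <- max(length(r_um), length(theta_rad))
  r_um <- rep_len(r_um, n); theta_rad <- rep_len(theta_rad, n)
  out <- numeric(n)
  a <- cfg$grain_radius_um
  in_rim <- r_um >= a - 1e-9 & r_um <= a + cfg$rim_thickness_um + 1e-9
  if (!any(in_rim)) return(out)
  per_pair <- 2 * pi * a / cfg$colony_pairs
  p_c <- cfg$consumer_arc_um / per_pair
  p_p <- cfg$producer_arc_um / per_pair
  tau <- -cos(pi * p_c)   # consumer where sin < tau
  s_p <- cos(pi * p_p)    # producer where sin > s_p
  w <- sin(cfg$colony_pairs * theta_rad[in_rim])
  v <- numeric(sum(in_rim))
  cons <- w < tau
  prod <- w > s_p
  if (cfg$reaction_shape == "sinusoidal") {
    if (any(cons)) v[cons] <- cfg$R_c_min * (w[cons] - tau) / (-1 - tau)
    if (any(prod)) v[prod] <- cfg$R_c_max * (w[prod] - s_p) / (1 - s_p)
  } else {
    v[cons] <- cfg$R_c_min
    v[prod] <- cfg$R_c_max
  }
  if (!cfg$production_on) v[v > 0] <- 0
  out[in_rim] <- v
  out
}

# consumer colony index (1..colony_pairs) for angles; NA outside consumer arcs
consumer_colony_index <- function(cfg, theta_rad) {
  a_p <- cfg$colony_pairs
  per_pair <- 2 * pi * cfg$grain_radius_um / a_p
  tau <- -cos(pi * cfg$consumer_arc_um / per_pair)
  w <- sin(a_p * theta_rad)
  k <- round((a_p * theta_rad - 3 * pi / 2) / (2 * pi))
  idx <- (as.integer(k) %% a_p) + 1L
  idx[w >= tau] <- NA_integer_
  idx
}

# --- solute transport -------------------------------------------------------

# Assemble the constant part of the finite-volume operator for one solute.
# Returns triplet lists for the transport matrix, plus the boundary rhs
# coefficient (per unit inflow concentration) and boundary bookkeeping.
assemble_transport <- function(flow, D_cell_um2_h,
                               outer_bc = "inflow_outflow") {
  g <- flow$grid
  n_r <- g$n_r; n_t <- g$n_t
  idx <- function(i, j) i + (j - 1L) * n_r
  dth <- g$dtheta
  ii <- jj <- xx <- list(); kk <- 0L
  add <- function(i, j, x) {
    kk <<- kk + 1L
    ii[[kk]] <<- i; jj[[kk]] <<- j; xx[[kk]] <<- x
  }
  # radial interior faces between cells (i-1, j) and (i, j), i = 2..n_r
  for (i in 2:n_r) {
    m <- idx(i - 1L, seq_len(n_t)); n <- idx(i, seq_len(n_t))
    Q <- flow$Q_r[i, ]                       # flux m -> n
    A_face <- g$rf[i] * dth
    G <- A_face / ((g$rf[i] - g$rc[i - 1]) / D_cell_um2_h[i - 1] +
                     (g$rc[i] - g$rf[i]) / D_cell_um2_h[i])
    add(m, m, pmax(Q, 0) + G); add(m, n, pmin(Q, 0) - G)
    add(n, n, pmax(-Q, 0) + G); add(n, m, pmin(-Q, 0) - G)
  }
  # angular faces between cells (i, j-1) and (i, j), periodic in j
  jm <- c(n_t, seq_len(n_t - 1L))
  for (i in seq_len(n_r)) {
    m <- idx(i, jm); n <- idx(i, seq_len(n_t))
    Q <- flow$Q_t[i, ]                       # flux m -> n (+theta)
    G <- D_cell_um2_h[i] * (g$rf[i + 1] - g$rf[i]) / (g$rc[i] * dth)
    add(m, m, pmax(Q, 0) + G); add(m, n, pmin(Q, 0) - G)
    add(n, n, pmax(-Q, 0) + G); add(n, m, pmin(-Q, 0) - G)
  }
  # Outer boundary faces of cells (n_r, j), mirroring the inlet/outlet of a
  # flow-through domain: the inflow half holds the bulk concentration
  # (advective influx + diffusive contact), the outflow half carries
  # solutes out advectively with zero diffusive flux.  In the stagnant
  # limit (U = 0) the upstream semicircle acts as the inlet.
  m <- idx(n_r, seq_len(n_t))
  Q_out <- flow$Q_r[n_r + 1L, ]
  A_face <- g$rf[n_r + 1L] * dth
  G_b <- D_cell_um2_h[n_r] * A_face / (g$rf[n_r + 1L] - g$rc[n_r])
  diffusive <- if (outer_bc == "dirichlet") rep(TRUE, n_t)
  else if (all(Q_out == 0)) cos(g$tc) < 0
  else Q_out < 0
  add(m, m, pmax(Q_out, 0) + ifelse(diffusive, G_b, 0))
  rhs_coef <- numeric(n_r * n_t)             # times inflow concentration
  rhs_coef[m] <- pmax(-Q_out, 0) + ifelse(diffusive, G_b, 0)
  A0 <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                             dims = c(n_r * n_t, n_r * n_t), repr = "C")
  list(A0 = A0, rhs_coef = rhs_coef, boundary_cells = m, Q_out = Q_out,
       G_b = ifelse(diffusive, G_b, 0))
}

# boundary influx (per unit depth, umol/L * um^2 / h) given a solution
boundary_influx <- function(asm, C, C_in) {
  Cb <- C[asm$boundary_cells]
  sum(pmax(-asm$Q_out, 0) * C_in - pmax(asm$Q_out, 0) * Cb +
        asm$G_b * (C_in - Cb))
}

#' Solve the stationary O2 and N2 fields
#'
#' O2: advection-diffusion with the surface reaction, consumption limited
#' by Michaelis-Menten kinetics f_O2(C) = C / (K_m + C) and production
#' applied as a source.  N2 (tracked as dissolved N in umol N L^-1 in
#' excess of background): source = `N_to_O2_ratio` times the magnitude of
#' the local potential O2 consumption, gated by the O2 inhibition
#' f_N(C) = C_inh / (C_inh + C_O2), inside consuming colonies.  Bulk
#' (inflow) concentrations: `inflow_O2_umol_L` for O2 and 0 for N2.
#'
#' @param cfg a [grain_model_config()].
#' @param flow optional precomputed [solve_flow()] result for `cfg`'s
#'   geometry and velocity.
#' @return object of class `field_solution`: concentration matrices `C_O2`
#'   and `C_N2` (radial x angular, umol L^-1), the realized O2 sink and N2
#'   source fields, residual norms, Picard iteration count, and mass-balance
#'   diagnostics (`o2_balance`, `n2_balance`: boundary influx, net reaction
#'   and relative closure error).
#' @export
solve_solutes <- function(cfg, flow = NULL) {
  stopifnot(inherits(cfg, "grain_model_config"))
  if (is.null(flow)) flow <- solve_flow(cfg)
  g <- flow$grid
  n_r <- g$n_r; n_t <- g$n_t; N <- n_r * n_t
  D_O2 <- rep(cfg$D_O2_m2_s * 1e12 * S_PER_H, n_r)   # um^2 h^-1
  D_N2 <- rep(cfg$D_N2_m2_s * 1e12 * S_PER_H, n_r)
  rim_i <- g$rc < g$a + cfg$rim_thickness_um
  D_O2[rim_i] <- D_O2[rim_i] * cfg$rim_diffusivity_factor
  D_N2[rim_i] <- D_N2[rim_i] * cfg$rim_diffusivity_factor

  Rc <- outer(g$rc, g$tc, function(r, th)
    surface_reaction_field(cfg, r, th)) * 1e3         # umol L^-1 h^-1
  R_pot_sink <- pmax(-Rc, 0)                          # consumption magnitude
  R_source <- pmax(Rc, 0)
  V <- g$vol
  C0 <- cfg$inflow_O2_umol_L

  asm <- assemble_transport(flow, D_O2, cfg$outer_bc)
  b0 <- asm$rhs_coef * C0 + as.vector(R_source * V)
  C <- rep(C0, N)
  sinkV <- as.vector(R_pot_sink * V)
  # damped Picard with Irons-Tuck (Aitken) adaptive relaxation on the
  # fixed-point residual; the semi-implicit sink keeps iterates positive
  omega <- cfg$picard_relax
  delta_prev <- NULL
  iter <- 0L; change <- Inf
  scale <- max(C0, 1)
  while (iter < cfg$picard_max && change > 1e-11) {
    iter <- iter + 1L
    sigma <- sinkV / (cfg$K_m + C)
    A <- asm$A0 + Matrix::Diagonal(N, sigma)
    C_new <- pmax(as.numeric(Matrix::solve(A, b0)), 0)
    delta <- C_new - C
    if (!is.null(delta_prev)) {
      dd <- delta - delta_prev
      den <- sum(dd^2)
      if (den > 0) omega <- clamp(-omega * sum(delta_prev * dd) / den,
                                  0.2, 50)
    }
    C <- pmax(C + omega * delta, 0)
    delta_prev <- delta
    change <- max(abs(delta)) / scale
  }
  sigma <- sinkV / (cfg$K_m + C)
  res <- as.numeric((asm$A0 + Matrix::Diagonal(N, sigma)) %*% C - b0)
  denom <- max(sqrt(sum(b0^2)), sqrt(sum((sigma * C)^2)), 1e-30)
  res_rel <- sqrt(sum(res^2)) / denom
  if (res_rel > cfg$tol_residual)
    stop(sprintf(paste0("O2 solve did not converge: relative residual ",
                        "%.3g after %d Picard iterations"), res_rel, iter),
         call. = FALSE)
  C_O2 <- matrix(C, n_r, n_t)
  realized_sink <- R_pot_sink * C_O2 / (cfg$K_m + C_O2)  # umol L^-1 h^-1

  # N2 source: potential consumption rate scaled by N:O2 and O2 inhibition
  f_N <- cfg$C_inh / (cfg$C_inh + C_O2)
  src_N <- cfg$N_to_O2_ratio * R_pot_sink * f_N          # umol N L^-1 h^-1
  asm_N <- assemble_transport(flow, D_N2, cfg$outer_bc)
  b_N <- as.vector(src_N * V)                            # inflow N2 = 0
  C_N <- as.numeric(Matrix::solve(asm_N$A0, b_N))
  C_N2 <- matrix(C_N, n_r, n_t)

  in_O2 <- boundary_influx(asm, C, C0)
  net_rx_O2 <- sum(R_source * V) - sum(realized_sink * V)
  err_O2 <- abs(in_O2 + net_rx_O2) /
    max(abs(in_O2), sum(realized_sink * V), sum(R_source * V), 1e-30)
  in_N2 <- boundary_influx(asm_N, C_N, 0)
  err_N2 <- abs(in_N2 + sum(src_N * V)) / max(sum(src_N * V), 1e-30)

  if (min(C_O2) < -1e-8 * scale || min(C_N2) < -1e-8)
    stop("negative concentrations beyond tolerance", call. = FALSE)

  structure(list(config = cfg, flow = flow, grid = g,
                 C_O2 = C_O2, C_N2 = C_N2,
                 realized_o2_sink = realized_sink, n2_source = src_N,
                 potential_o2_sink = R_pot_sink, o2_source = R_source,
                 picard_iterations = iter, residual_rel = res_rel,
                 o2_balance = list(boundary_influx = in_O2,
                                   net_reaction = net_rx_O2,
                                   rel_error = err_O2),
                 n2_balance = list(boundary_influx = in_N2,
                                   net_source = sum(src_N * V),
                                   rel_error = err_N2)),
            class = "field_solution")
}

#' Summarise anoxic microenvironments and N2 production
#'
#' Anoxic fraction: area of consuming-colony rim cells with O2 below
#' `anoxia_threshold_umol_L` over the total consuming rim area.  A colony
#' counts as anoxic when more than half of its rim area is anoxic.  N2
#' production is the N2 source integrated over the rim, extruded by
#' `extrusion_depth_um` and converted to nmol N per day.
#'
#' @param cfg a [grain_model_config()].
#' @param sol a [solve_solutes()] solution for `cfg`.
#' @return list of class `microenv_summary`: `anoxic_rim_volume_fraction`,
#'   `anoxic_colony_count`, `anoxic_colony_fraction`,
#'   `n2_per_colony_nmol_d` (named vector), `n2_per_grain_nmol_d`, and O2
#'   boundary fluxes in mol h^-1 (`o2_flux_domain_mol_h`,
#'   `o2_flux_grain_mol_h` -- zero by the no-flux grain condition).
#' @export
summarize_microenv <- function(cfg, sol) {
  stopifnot(inherits(sol, "field_solution"))
  g <- sol$grid
  rim_i <- which(g$rc < g$a + cfg$rim_thickness_um)
  col_idx <- consumer_colony_index(cfg, g$tc)
  V <- g$vol
  anox <- sol$C_O2 < cfg$anoxia_threshold_umol_L
  cons_cells <- matrix(FALSE, g$n_r, g$n_t)
  cons_cells[rim_i, ] <- matrix(rep(!is.na(col_idx), each = length(rim_i)),
                                length(rim_i), g$n_t)
  # restrict to cells with an actual consumption rate (guards uniform off)
  cons_cells <- cons_cells & sol$potential_o2_sink > 0
  A_cons <- sum(V[cons_cells])
  frac <- if (A_cons > 0) sum(V[cons_cells & anox]) / A_cons else 0
  # per-colony bookkeeping
  n_col <- cfg$colony_pairs
  n2_col <- numeric(n_col)
  anox_col <- logical(n_col)
  vol_to_L <- cfg$extrusion_depth_um * L_PER_UM3
  for (k in seq_len(n_col)) {
    sel_t <- which(!is.na(col_idx) & col_idx == k)
    sel <- matrix(FALSE, g$n_r, g$n_t)
    sel[rim_i, sel_t] <- TRUE
    sel <- sel & sol$potential_o2_sink > 0
    A_k <- sum(V[sel])
    anox_col[k] <- A_k > 0 && sum(V[sel & anox]) / A_k > 0.5
    # umol N L^-1 h^-1 * L -> umol N h^-1 -> nmol N d^-1
    n2_col[k] <- sum(sol$n2_source[sel] * V[sel]) * vol_to_L * 24 * 1e3
  }
  # whole-rim N2 (includes any source outside labelled colonies; none by
  # construction, kept as the integral actually solved)
  n2_grain <- sum(sol$n2_source * V) * vol_to_L * 24 * 1e3
  flux_domain <- sol$o2_balance$boundary_influx * cfg$extrusion_depth_um *
    L_PER_UM3 * 1e-6                     # mol O2 h^-1 into the domain
  structure(list(anoxic_rim_volume_fraction = frac,
                 anoxic_colony_count = sum(anox_col),
                 anoxic_colony_fraction = mean(anox_col),
                 n2_per_colony_nmol_d = n2_col,
                 n2_per_grain_nmol_d = n2_grain,
                 o2_flux_domain_mol_h = flux_domain,
                 o2_flux_grain_mol_h = 0),
            class = "microenv_summary")
}

#' @export
print.microenv_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Microenvironment summary: anoxic rim fraction %.3f ",
           "(%d/%d colonies anoxic); N2 %.3g nmol N d^-1 per grain\n"),
    x$anoxic_rim_volume_fraction, x$anoxic_colony_count,
    length(x$n2_per_colony_nmol_d), x$n2_per_grain_nmol_d))
  invisible(x)
}

#' Run a (U, C0) ensemble of single-grain solves
#'
#' Solves the model over the grid of pore-water velocities and bulk O2
#' concentrations, with or without the production (photosynthesis) arcs,
#' and tabulates the anoxic fractions, per-grain N2 production, Sand_DBL
#' number and mass-balance diagnostics.  Failed runs are recorded with
#' `converged = FALSE` rather than dropped.
#'
#' @param cfg a [grain_model_config()] template.
#' @param U_values_um_s pore-water velocities, um s^-1.
#' @param C0_values_umol_L bulk O2 concentrations, umol L^-1.
#' @param production_on logical vector of production scenarios to run.
#' @return data frame with one row per (U, C0, production) combination.
#' @export
run_ensemble <- function(cfg, U_values_um_s, C0_values_umol_L,
                         production_on = TRUE) {
  stopifnot(inherits(cfg, "grain_model_config"))
  runs <- expand.grid(U_um_s = U_values_um_s, C0_umol_L = C0_values_umol_L,
                      production_on = production_on,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(runs)) {
    return(data.frame(U_um_s = numeric(), C0_umol_L = numeric(),
                      production_on = logical(), sanddbl = numeric(),
                      anoxic_fraction = numeric(),
                      anoxic_colony_fraction = numeric(),
                      n2_per_grain_nmol_d = numeric(),
                      o2_balance_rel_err = numeric(),
                      picard_iterations = integer(),
                      converged = logical(), error = character()))
  }
  nu <- cfg$viscosity_Pa_s / 1000                     # ~ rho = 1000 kg m^-3
  r_m <- cfg$grain_radius_um * 1e-6
  R_si <- abs(cfg$R_c_min) / S_PER_H                  # mol m^-3 s^-1
  flow_cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(runs)), function(k) {
    U <- runs$U_um_s[k]; C0 <- runs$C0_umol_L[k]
    cfg_k <- cfg
    cfg_k$inflow_velocity_um_s <- U
    cfg_k$inflow_O2_umol_L <- C0
    cfg_k$production_on <- runs$production_on[k]
    key <- format(U, digits = 15)
    if (is.null(flow_cache[[key]]))
      flow_cache[[key]] <- solve_flow(cfg_k)
    sdbl <- if (C0 > 0) {
      delta <- as.numeric(dbl_thickness(r_m, U * 1e-6, nu, cfg$D_O2_m2_s))
      sanddbl(delta, cfg$D_O2_m2_s, R_si, C0 * MOLM3_PER_UM)
    } else NA_real_
    out <- data.frame(U_um_s = U, C0_umol_L = C0,
                      production_on = runs$production_on[k],
                      sanddbl = sdbl, anoxic_fraction = NA_real_,
                      anoxic_colony_fraction = NA_real_,
                      n2_per_grain_nmol_d = NA_real_,
                      o2_balance_rel_err = NA_real_,
                      picard_iterations = NA_integer_,
                      converged = FALSE, error = NA_character_)
    tryCatch({
      sol <- solve_solutes(cfg_k, flow_cache[[key]])
      sm <- summarize_microenv(cfg_k, sol)
      out$anoxic_fraction <- sm$anoxic_rim_volume_fraction
      out$anoxic_colony_fraction <- sm$anoxic_colony_fraction
      out$n2_per_grain_nmol_d <- sm$n2_per_grain_nmol_d
      out$o2_balance_rel_err <- sol$o2_balance$rel_error
      out$picard_iterations <- sol$picard_iterations
      out$converged <- TRUE
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.grain_model_config <- function(x, ...) {
  cat(sprintf(
    paste0("Single-grain model: r = %g um, rim %g um, %d colony pairs ",
           "(%g/%g um arcs, R_c in [%g, %g] mmol/L/h)\n",
           "  U = %g um/s, C0 = %g umol/L, grid %d x %d (annulus to %g r)\n"),
    x$grain_radius_um, x$rim_thickness_um, x$colony_pairs,
    x$consumer_arc_um, x$producer_arc_um, x$R_c_min, x$R_c_max,
    x$inflow_velocity_um_s, x$inflow_O2_umol_L,
    x$n_radial_rim + x$n_radial_outer, x$n_theta, x$domain_radius_factor))
  invisible(x)
}
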