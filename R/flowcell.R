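#' Flow-cell geometry and mesh
#'
#' A flat rectangular channel (length along the flow, height between the
#' plates) whose floor is the reactive sensor.  The default extents,
#' 2400 x 500 x 20 um, describe the DNA-coated GMR sensor chip the
#' binding model was built for.  The transport problem is reduced to 2D
#' (length x height): at this aspect ratio the Stokes flow between the
#' plates is plane Poiseuille and the width enters only as a multiplier
#' in the mole bookkeeping.
#'
#' The mesh is uniform in x and geometrically graded in z toward the
#' floor so that the thin mass-transport boundary layer (a few um at
#' Peclet ~ 1e5-1e6) is resolved: with the defaults the wall cell is
#' ~11 nm high and more than ten cells lie within the bottom micron.
#'
#' @param length,width,height Channel extents (m).
#' @param nx,nz Cell counts along the flow and across the gap, >= 4.
#' @param grading Geometric stretching factor of the z mesh (1 = uniform).
#' @return A `flow_cell_geometry` list with the mesh (`dx`, `dz`, `zc`).
#' @export
flow_cell_geometry <- function(length = 2.4e-3, width = 5e-4,
                               height = 2e-5, nx = 120, nz = 40,
                               grading = 1.15) {
  stopifnot(length > 0, width > 0, height > 0, nx >= 4, nz >= 4,
            grading >= 1)
  dz0 <- if (grading == 1) height / nz
         else height * (grading - 1) / (grading^nz - 1)
  dz <- dz0 * grading^(0:(nz - 1))
  dz <- dz * height / sum(dz)          # kill rounding drift
  zc <- cumsum(dz) - dz / 2
  structure(list(length = length, width = width, height = height,
                 nx = as.integer(nx), nz = as.integer(nz),
                 grading = grading, dx = length / nx, dz = dz, zc = zc),
            class = "flow_cell_geometry")
}

#' Transport parameters
#'
#' @param D Analyte diffusion coefficient (m^2/s); the default 1e-10 is
#'   the Stokes-Einstein value for a 2 nm protein in water at 20 C.
#' @param eta Fluid viscosity (Pa s).
#' @param u_mean Depth-averaged flow speed (m/s); default 3.3 cm/s.
#' @return A `transport_params` list.
#' @export
transport_params <- function(D = 1e-10, eta = 1.002e-3, u_mean = 3.3e-2) {
  stopifnot(D > 0, eta > 0, u_mean >= 0)
  structure(list(D = D, eta = eta, u_mean = u_mean),
            class = "transport_params")
}

#' Plane-Poiseuille velocity profile
#'
#' The steady Stokes flow between parallel plates with no-slip walls:
#' \eqn{u(z) = 6\,\bar u\,(z/h)(1 - z/h)}, zero at both walls, centerline
#' velocity 1.5 times the mean.
#'
#' @param geom [flow_cell_geometry()].
#' @param transport [transport_params()].
#' @param z Heights (m) at which to evaluate; default the cell centers.
#' @return Streamwise velocity (m/s) at `z`.
#' @export
poiseuille_profile <- function(geom, transport, z = geom$zc) {
  h <- geom$height
  6 * transport$u_mean * (z / h) * (1 - z / h)
}

# stable step for explicit advection + explicit x diffusion
flowcell_dt <- function(geom, transport, schedule = NULL) {
  u_max <- 1.5 * transport$u_mean
  cand <- c(if (u_max > 0) 0.8 * geom$dx / u_max,
            0.25 * geom$dx^2 / transport$D)
  if (!is.null(schedule)) {
    r <- c(schedule$ramp_up, schedule$ramp_down)
    cand <- c(cand, r[r > 0] / 10)
  }
  min(cand)
}

#' Simulate an injection over the sensor
#'
#' Couples advection-diffusion transport of the analyte (upwind in x,
#' implicit in z on the wall-graded mesh, plane-Poiseuille advection)
#' to the Langmuir surface reaction through a Robin boundary at the
#' floor: the diffusive wall flux equals the surface reaction rate,
#' \eqn{D\,\partial c/\partial z|_{wall} = k_a c_w (1 - n/n_A) + k_d n/n_A}
#' (sign per the inward normal), and the coverage ODE is advanced with
#' the identical discrete flux, so fluid and surface moles balance
#' exactly.  Initial state c = 0, n = 0 unless overridden.
#'
#' @param geom [flow_cell_geometry()].
#' @param transport [transport_params()].
#' @param schedule [injection_schedule()].
#' @param binding [binding_params()].
#' @param dt Time step (s); `NULL` picks the largest stable step
#'   (advective CFL 0.4, explicit x-diffusion number 0.25, at least ten
#'   steps per ramp).
#' @param t_end End time (s); default schedule end plus five surface
#'   dissociation time constants.
#' @param record_every Sampling interval in steps (`NULL`: ~1000 samples).
#' @param c0 Optional initial concentration field, nz x nx (mol/m^3).
#' @param n0 Optional initial coverage along the floor, length nx.
#' @param inlet `"open"` (default): the inlet face carries the advective
#'   influx plus a diffusive Dirichlet exchange with the reservoir at
#'   `c_in(t)` -- the diffusive part is what feeds the cell in the
#'   `u_mean = 0` well-mixed limit.  `"closed"` seals the inlet
#'   (closed-box verification runs).
#' @return A `sensorgram` data frame `t, n_mean, c_outlet, c_wall`
#'   (coverage in mol/m^2, concentrations in mol/m^3) with attributes
#'   `mass` (mole ledger: in, out, stored, bound, initial, residual),
#'   `fields` (final c and n), `geom`, `binding`, `schedule`, and
#'   `clip_events` (times the positivity/saturation clip fired; 0 in a
#'   healthy run).
#' @export
simulate_injection <- function(geom, transport, schedule,
                               binding = binding_params(), dt = NULL,
                               t_end = NULL, record_every = NULL,
                               c0 = NULL, n0 = NULL,
                               inlet = c("open", "closed")) {
  inlet <- match.arg(inlet)
  stopifnot(inherits(geom, "flow_cell_geometry"),
            inherits(transport, "transport_params"),
            inherits(schedule, "injection_schedule"))
  if (is.null(t_end))
    t_end <- schedule$t_end +
      if (binding$k_off > 0) 5 / binding$k_off else 1
  if (is.null(dt)) dt <- flowcell_dt(geom, transport, schedule)
  n_steps <- as.integer(ceiling(t_end / dt))
  if (is.null(record_every))
    record_every <- max(1L, n_steps %/% 1000L)
  u <- poiseuille_profile(geom, transport)
  if (transport$u_mean == 0) u <- rep(0, geom$nz)
  if (is.null(c0)) c0 <- matrix(0, geom$nz, geom$nx)
  if (is.null(n0)) n0 <- rep(0, geom$nx)
  stopifnot(nrow(c0) == geom$nz, ncol(c0) == geom$nx,
            length(n0) == geom$nx)
  cin <- inlet_concentration(schedule, (0:(n_steps - 1)) * dt)
  res <- cpp_flowcell_run(c0, n0, geom$dx, geom$dz, geom$zc, u,
                          transport$D, dt, n_steps, 0, cin,
                          binding$ka, binding$kd, binding$nA,
                          geom$width, as.integer(record_every),
                          as.integer(inlet == "open"))
  out <- data.frame(t = res$t, n_mean = res$n_mean,
                    c_outlet = res$c_outlet, c_wall = res$c_wall)
  class(out) <- c("sensorgram", "data.frame")
  inflow <- res$moles_in + res$moles_initial
  attr(out, "mass") <- list(
    moles_in = res$moles_in, moles_out = res$moles_out,
    moles_stored = res$moles_stored, moles_bound = res$moles_bound,
    moles_initial = res$moles_initial,
    residual = abs(inflow - res$moles_out - res$moles_stored -
                   res$moles_bound) / max(inflow, .Machine$double.eps))
  attr(out, "fields") <- list(c = res$c, n = res$n)
  attr(out, "geom") <- geom
  attr(out, "binding") <- binding
  attr(out, "schedule") <- schedule
  attr(out, "clip_events") <- res$clip_events
  out
}

#' Mass-balance residual of a simulated injection
#'
#' \eqn{|in + initial - out - stored - bound| / \max(in + initial, \epsilon)}
#' with every term a time-integrated mole count taken from the same
#' discrete fluxes the solver used.
#'
#' @param sensorgram Output of [simulate_injection()].
#' @return Residual fraction (dimensionless).
#' @export
mass_balance <- function(sensorgram) {
  m <- attr(sensorgram, "mass")
  if (is.null(m)) stop("no mass ledger attached (well-mixed sensorgram?)")
  m$residual
}

#' Read/write sensorgram CSV
#'
#' Columns `t, n_mean, c_outlet[, c_wall]`, 17 significant digits.
#'
#' @param sensorgram A sensorgram data frame.
#' @param path File path.
#' @return `write_sensorgram`: `path`, invisibly. `read_sensorgram`: a
#'   `sensorgram` data frame.
#' @export
write_sensorgram <- function(sensorgram, path) {
  write_csv17(as.data.frame(sensorgram), path)
  invisible(path)
}

#' @rdname write_sensorgram
#' @export
read_sensorgram <- function(path) {
  df <- read.csv(path)
  if (!all(c("t", "n_mean") %in% names(df)))
    stop("sensorgram CSV needs columns t, n_mean")
  class(df) <- c("sensorgram", "data.frame")
  df
}
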