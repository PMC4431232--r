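#' Molecular-dynamics parameters
#'
#' Translational motion is overdamped Langevin dynamics (the matrix is a
#' viscous liquid gel; inertia is irrelevant at these sizes):
#' \deqn{\dot x = F/\zeta + \sqrt{2 k_B T/\zeta}\,\xi(t)}
#' with per-particle drag \eqn{\zeta = 6\pi\eta r} (Stokes).  When `dt`
#' is `NULL` it is chosen so that the drift displacement per step at the
#' typical contact dipolar force is below `diameter/100`, and the
#' integrator aborts if any realized step exceeds `max_disp_frac`
#' diameters.
#'
#' @param dt Time step (s), or `NULL` for the automatic choice.
#' @param drag Drag coefficient (kg/s), or `NULL` for Stokes drag.
#' @param eta Matrix viscosity (Pa s) for the Stokes default.  Default
#'   1.0, a gel-like value three decades above water.
#' @param temperature Kelvin for the translational noise (default 298;
#'   set 0 for deterministic descent).
#' @param seed Integer seed.
#' @param max_disp_frac Stability guard, fraction of a diameter.
#' @return An `md_params` list.
#' @export
md_params <- function(dt = NULL, drag = NULL, eta = 1.0, temperature = 298,
                      seed = 1, max_disp_frac = 0.5) {
  stopifnot(is.null(dt) || dt > 0, is.null(drag) || drag >= 0, eta > 0,
            temperature >= 0, max_disp_frac > 0)
  structure(list(dt = dt, drag = drag, eta = eta,
                 temperature = temperature, seed = seed,
                 max_disp_frac = max_disp_frac), class = "md_params")
}

# resolve NULL dt / drag against a concrete ensemble
md_resolve <- function(params, ensemble, constants = si_constants()) {
  d <- min(ensemble$diameters)
  if (is.null(params$drag))
    params$drag <- 6 * pi * params$eta * d / 2
  if (is.null(params$dt)) {
    m <- moment_magnitude(d, ensemble$Ms)
    f_contact <- 3 * constants$mu0 * m^2 / (2 * pi * d^4)
    params$dt <- 0.01 * d * params$drag / f_contact
  }
  params
}

#' Advance particle positions at fixed moments
#'
#' Overdamped Langevin integration under dipolar plus WCA forces inside
#' the reflective box, restricted to the ensemble's `motion_dim`.  A
#' uniform external field exerts no net force on a dipole and is
#' accepted for interface symmetry only.
#'
#' @param ensemble An `np_ensemble`.
#' @param params [md_params()].
#' @param n_steps Number of steps, >= 1.
#' @param B_ext Ignored for forces (uniform field); kept for symmetry.
#' @param epsilon WCA well depth (J).
#' @return The ensemble with updated positions; attribute
#'   `min_scaled_dist` records the smallest pair distance seen, in units
#'   of the contact distance.
#' @export
md_integrate <- function(ensemble, params = md_params(), n_steps,
                         B_ext = c(0, 0, 0),
                         epsilon = contact_epsilon(ensemble)) {
  stopifnot(n_steps >= 1)
  cst <- si_constants()
  params <- md_resolve(params, ensemble, cst)
  res <- cpp_md_run(ensemble$positions, ensemble$moments,
                    ensemble$diameters, epsilon, cst$mu0, params$drag,
                    cst$kB, params$temperature, params$dt,
                    as.integer(n_steps), ensemble$box$extents,
                    as.integer(ensemble$motion_dim),
                    as.numeric(params$seed), params$max_disp_frac)
  ensemble$positions <- res$positions
  attr(ensemble, "min_scaled_dist") <- res$min_scaled_dist
  ensemble
}

#' Hybrid SD/MD schedule
#'
#' The separation of time scales between moment reorientation (fast) and
#' particle translation (slow) lets the two be decoupled: moments are
#' relaxed to their ground state at fixed positions, then positions are
#' advanced at fixed moments, alternating until `total_steps` MD steps
#' have been taken.
#'
#' @param total_steps Total MD steps, >= `sd_every`.
#' @param sd_every MD steps between spin relaxations, >= 1.
#' @param sd_window,sd_max_windows Relaxation budget per SD phase (see
#'   [relax()]).
#' @return A `hybrid_schedule` list.
#' @export
hybrid_schedule <- function(total_steps, sd_every, sd_window = 1000L,
                            sd_max_windows = 20L) {
  stopifnot(total_steps >= sd_every, sd_every >= 1)
  structure(list(total_steps = as.integer(total_steps),
                 sd_every = as.integer(sd_every),
                 sd_window = as.integer(sd_window),
                 sd_max_windows = as.integer(sd_max_windows)),
            class = "hybrid_schedule")
}

#' Run a hybrid spin-dynamics / molecular-dynamics assembly simulation
#'
#' Alternates [relax()] (moments at fixed positions) with blocks of
#' [md_integrate()] (positions at fixed moments).  In zero external
#' field this drives the ensemble toward chain fragments and small
#' vortex islands while the magnetic energy decreases.
#'
#' @param ensemble An `np_ensemble`.
#' @param schedule A [hybrid_schedule()].
#' @param md [md_params()].
#' @param sd [sd_params()] used for the relaxation phases.
#' @param epsilon WCA well depth (J).
#' @param relax_tol Relaxation tolerance (J).
#' @param keep_snapshots Keep a copy of the ensemble at each SD point.
#' @return A list with the final `ensemble`, a `trajectory` data frame
#'   (`t, E_dipolar, E_wca, E_zeeman, Mx, My, Mz, mean_nn`) sampled at
#'   each SD point, and (optionally) `snapshots`.
#' @export
hybrid_run <- function(ensemble, schedule, md = md_params(),
                       sd = sd_params(alpha = 0.5, dt = 1e-12),
                       epsilon = contact_epsilon(ensemble),
                       relax_tol = 1e-24,
                       keep_snapshots = FALSE) {
  stopifnot(inherits(schedule, "hybrid_schedule"))
  md <- md_resolve(md, ensemble)
  n_blocks <- schedule$total_steps %/% schedule$sd_every
  rows <- vector("list", n_blocks + 1)
  snaps <- if (keep_snapshots) vector("list", n_blocks + 1) else NULL
  ens <- ensemble
  t_md <- 0
  for (b in seq_len(n_blocks + 1)) {
    sd_b <- sd
    sd_b$seed <- sd$seed + b - 1
    r <- suppressWarnings(relax(ens, params = sd_b, tol = relax_tol,
                                window = schedule$sd_window,
                                max_windows = schedule$sd_max_windows))
    ens <- r$ensemble
    e <- total_energy(ens, epsilon = epsilon)
    mtot <- sum(sqrt(rowSums(ens$moments^2)))
    M <- colSums(ens$moments) / mtot
    rows[[b]] <- data.frame(t = t_md, E_dipolar = e$dipolar, E_wca = e$wca,
                            E_zeeman = e$zeeman, Mx = M[1], My = M[2],
                            Mz = M[3], mean_nn = mean_nn_distance(ens))
    if (keep_snapshots) snaps[[b]] <- ens
    if (b > n_blocks) break
    md_b <- md
    md_b$seed <- md$seed + b - 1
    ens <- md_integrate(ens, params = md_b,
                        n_steps = schedule$sd_every, epsilon = epsilon)
    t_md <- t_md + schedule$sd_every * md$dt
  }
  out <- list(ensemble = ens, trajectory = do.call(rbind, rows))
  if (keep_snapshots) out$snapshots <- snaps
  out
}

#' Mean nearest-neighbour distance
#'
#' @param ensemble An `np_ensemble`.
#' @return Mean over particles of the distance to the nearest other
#'   particle (m); a decreasing value signals aggregation.
#' @export
mean_nn_distance <- function(ensemble) {
  pos <- ensemble$positions
  n <- nrow(pos)
  if (n < 2) return(NA_real_)
  dm <- as.matrix(stats::dist(pos))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

# Contact-graph cluster proxy used in tests only: particles are
# neighbours when closer than `factor` contact distances.  Returns
# component sizes and the fraction of particles with >= 1 neighbour.
contact_clusters <- function(ensemble, factor = 1.1) {
  pos <- ensemble$positions
  n <- nrow(pos)
  dm <- as.matrix(stats::dist(pos))
  sig <- outer(ensemble$diameters, ensemble$diameters, "+") / 2
  adj <- dm < factor * sig & dm > 0
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(comp[c(i, nb)])
        if (any(comp[c(i, nb)] != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sizes <- as.integer(table(comp))
  list(sizes = sizes,
       bonded_fraction = mean(rowSums(adj) > 0))
}
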