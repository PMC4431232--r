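#' Magnetic dipole-dipole pair energy
#'
#' \deqn{H_{DD} = -\frac{\mu_0}{4\pi |r|^3}\left[3 (m_1\cdot\hat r)(m_2\cdot\hat r) - m_1\cdot m_2\right]}
#' with \eqn{r} the vector joining the two particle centers.  Symmetric
#' under particle exchange.
#'
#' @param m1,m2 Length-3 moment vectors (A m^2).
#' @param r12 Length-3 separation vector (m), non-zero.
#' @param constants Output of [si_constants()].
#' @return Energy in J.
#' @export
pair_dipole_energy <- function(m1, m2, r12, constants = si_constants()) {
  r2 <- sum(r12^2)
  if (r2 == 0) stop("coincident particles: |r12| = 0")
  r <- sqrt(r2)
  u <- r12 / r
  -constants$mu0 / (4 * pi * r^3) *
    (3 * sum(m1 * u) * sum(m2 * u) - sum(m1 * m2))
}

#' Dipolar field at each particle
#'
#' The effective field conjugate to the moments,
#' \eqn{B_i = -\partial H_{DD}/\partial m_i =
#' \sum_{j\ne i} \frac{\mu_0}{4\pi r^3}[3\hat r (m_j\cdot\hat r) - m_j]},
#' so that \eqn{H_{DD} = -\tfrac12\sum_i m_i\cdot B_i}.
#'
#' @param ensemble An `np_ensemble`.
#' @param i Optional particle index; omit for the full n x 3 field matrix.
#' @param constants Output of [si_constants()].
#' @return n x 3 matrix of fields (T), or a length-3 vector if `i` given.
#' @export
dipolar_field <- function(ensemble, i = NULL, constants = si_constants()) {
  B <- cpp_dipolar_fields(ensemble$positions, ensemble$moments,
                          constants$mu0)
  if (is.null(i)) B else B[i, ]
}

#' Weeks-Chandler-Andersen repulsion
#'
#' Truncated-shifted Lennard-Jones, purely repulsive:
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma}, exactly zero beyond.  With
#' \eqn{\sigma} set to the contact distance this makes the particles
#' behave as hard spheres, removing the dipolar collision singularity.
#'
#' @param r Center distance (m), > 0. Vectorized.
#' @param epsilon Well depth (J); see [contact_epsilon()] for the
#'   package default scale.
#' @param sigma Zero-crossing distance (m).
#' @return Energy in J.
#' @export
wca_energy <- function(r, epsilon, sigma) {
  if (any(r <= 0)) stop("r must be positive")
  stopifnot(epsilon > 0, sigma > 0)
  sr6 <- (sigma / r)^6
  ifelse(r < 2^(1 / 6) * sigma, 4 * epsilon * (sr6^2 - sr6) + epsilon, 0)
}

#' Default WCA energy scale of an ensemble
#'
#' The hard-sphere model fixes only the contact *location* (the particle
#' diameters); the well depth epsilon sets how stiff the effective hard
#' sphere is and must be commensurate with the attraction it opposes.
#' For 20 nm Co macrospins the dipolar contact energy is hundreds of
#' kBT, so a thermal-scale epsilon would let bound pairs interpenetrate.
#' The package default is therefore the dipolar contact energy of the
#' smallest particle,
#' \eqn{\epsilon = \mu_0 m^2 / (2\pi d^3)},
#' which places the bound-pair separation at ~1.09 contact distances,
#' inside the hard-sphere band \eqn{[\sigma, 2^{1/6}\sigma]}.
#'
#' @param ensemble An `np_ensemble`.
#' @param constants Output of [si_constants()].
#' @return Energy in J.
#' @export
contact_epsilon <- function(ensemble, constants = si_constants()) {
  d <- min(ensemble$diameters)
  m <- moment_magnitude(d, ensemble$Ms)
  constants$mu0 * m^2 / (2 * pi * d^3)
}

#' Pairwise forces on every particle
#'
#' \eqn{F_i = -\nabla_{r_i} (H_{DD} + H_{WCA})} with the analytic dipolar
#' force and the WCA force using per-pair \eqn{\sigma_{ij} = (d_i+d_j)/2}.
#' Forces sum to zero (isolated system).
#'
#' @param ensemble An `np_ensemble`.
#' @param epsilon WCA well depth (J).
#' @param constants Output of [si_constants()].
#' @return n x 3 matrix of forces (N).
#' @export
pair_forces <- function(ensemble, epsilon = contact_epsilon(ensemble),
                        constants = si_constants()) {
  cpp_forces(ensemble$positions, ensemble$moments, ensemble$diameters,
             epsilon, constants$mu0)$forces
}

#' Total energy breakdown of an ensemble
#'
#' Dipole-dipole and WCA energies summed over all unordered pairs plus
#' the Zeeman energy \eqn{-\sum_i m_i \cdot B_{ext}}.
#'
#' @param ensemble An `np_ensemble`.
#' @param B_ext External field, length-3 vector (T).
#' @param epsilon WCA well depth (J).
#' @param constants Output of [si_constants()].
#' @return An `energy_breakdown` list with `dipolar`, `wca`, `zeeman`,
#'   `total` (J); `total` is the exact sum of the three parts.
#' @export
total_energy <- function(ensemble, B_ext = c(0, 0, 0),
                         epsilon = contact_epsilon(ensemble),
                         constants = si_constants()) {
  e <- cpp_pair_energies(ensemble$positions, ensemble$moments,
                         ensemble$diameters, epsilon, constants$mu0)
  zee <- -sum(ensemble$moments %*% B_ext)
  energy_breakdown(dipolar = e[1], wca = e[2], zeeman = zee)
}

energy_breakdown <- function(dipolar, wca, zeeman) {
  structure(list(dipolar = dipolar, wca = wca, zeeman = zeeman,
                 total = dipolar + wca + zeeman),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy> dipolar %.6g J, wca %.6g J, zeeman %.6g J, total %.6g J\n",
              x$dipolar, x$wca, x$zeeman, x$total))
  invisible(x)
}

#' Exhaustive in-plane ground-state search (oracle)
#'
#' Enumerates every combination of per-moment in-plane angles on a
#' `step_deg` grid (2 to 4 particles) and returns the minimum total
#' dipolar energy.  This brute-force search is deliberately independent
#' of the relaxation integrator and is used to validate it.
#'
#' @param ensemble An `np_ensemble` whose particles lie in the xy plane.
#' @param step_deg Grid step in degrees (default 1).
#' @param constants Output of [si_constants()].
#' @return List with `energy` (J) and `angles_deg`.
#' @export
brute_force_ground_state <- function(ensemble, step_deg = 1,
                                     constants = si_constants()) {
  mmag <- sqrt(rowSums(ensemble$moments^2))
  cpp_brute_force_inplane(ensemble$positions, mmag, constants$mu0, step_deg)
}
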