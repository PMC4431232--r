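#' Physical constants used throughout the package
#'
#' Returns the vacuum permeability, Boltzmann constant and gyromagnetic
#' ratio as a validated list.  `mu0` and `kB` are fixed to their defined
#' SI values; the gyromagnetic ratio defaults to the free-electron value
#' and may be overridden for other materials.
#'
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#' @return A list with elements `mu0` (T m/A), `kB` (J/K), `gamma`.
#' @examples
#' si_constants()$mu0  # 4*pi*1e-7
#' @export
si_constants <- function(gamma = 1.76e11) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0)
  list(mu0 = 4 * pi * 1e-7, kB = 1.380649e-23, gamma = gamma)
}

#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (6 \pi \eta r)} for a sphere of hydrodynamic radius
#' `radius` in a fluid of viscosity `eta`.  With the defaults (water at
#' 20 degrees C) a 2 nm protein has \eqn{D \approx 1\times 10^{-10}}
#' m^2/s, the transport coefficient used by the flow-cell module.
#'
#' @param radius Hydrodynamic radius (m).
#' @param temperature Absolute temperature (K), default 293.15.
#' @param eta Dynamic viscosity (Pa s), default water at 20 C.
#' @return Diffusion coefficient (m^2/s).
#' @examples
#' stokes_einstein_diffusivity(2e-9)
#' @export
stokes_einstein_diffusivity <- function(radius, temperature = 293.15,
                                        eta = 1.002e-3) {
  stopifnot(radius > 0, temperature > 0, eta > 0)
  kB <- si_constants()$kB
  kB * temperature / (6 * pi * eta * radius)
}
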