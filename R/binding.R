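#' 1:1 Langmuir surface-binding parameters
#'
#' Parameters of the surface reaction between an analyte at
#' concentration c (mol/m^3) near the wall and acceptor sites of areal
#' density `nA` (mol/m^2):
#' \deqn{\frac{dn}{dt} = k_a c \left(1 - \frac{n}{n_A}\right) - k_d \frac{n}{n_A}}
#' `kd` carries flux units (mol m^-2 s^-1) and `KD = kd/ka` concentration
#' units; the conventional first-order off-rate is the derived
#' `k_off = kd/nA` (s^-1), about 0.586 s^-1 at the defaults.  Exactly two
#' of `ka`, `kd`, `KD` must be given; the third is filled in from
#' \eqn{k_a = k_d / K_D}.
#'
#' Defaults describe wildtype PhoB protein binding to a DNA-coated
#' sensor floor: `nA = 2.56e-8` mol/m^2, `KD = 21e-3` mol/m^3,
#' `kd = 1.5e-8` mol m^-2 s^-1, hence `ka ~ 7.14e-7` m/s.
#'
#' @param ka Association rate constant (m/s) or `NULL`.
#' @param kd Dissociation rate constant (mol m^-2 s^-1).
#' @param KD Equilibrium dissociation constant (mol/m^3).
#' @param nA Acceptor site density (mol/m^2).
#' @return A `binding_params` list with all four values plus `k_off`.
#' @export
binding_params <- function(ka = NULL, kd = 1.5e-8, KD = 21e-3,
                           nA = 2.56e-8) {
  stopifnot(nA > 0)
  given <- !c(ka = is.null(ka), kd = is.null(kd), KD = is.null(KD))
  if (sum(given) < 2)
    stop("need at least two of ka, kd, KD")
  if (is.null(ka)) ka <- kd / KD
  if (is.null(kd)) kd <- ka * KD
  if (is.null(KD)) KD <- if (ka > 0) kd / ka else Inf
  stopifnot(ka >= 0, kd >= 0, KD >= 0)
  if (all(given) && ka > 0 && abs(ka - kd / KD) / ka >= 1e-9)
    stop("inconsistent rate constants: ka != kd/KD")
  structure(list(ka = ka, kd = kd, KD = KD, nA = nA, k_off = kd / nA),
            class = "binding_params")
}

#' Surface reaction rate
#'
#' dn/dt of the 1:1 Langmuir model at near-wall concentration `c` and
#' coverage `n`.  Linear in `n` at fixed `c`; its unique root in
#' \[0, nA\] is [equilibrium_coverage()].
#'
#' @param c Near-wall analyte concentration (mol/m^3), >= 0.
#' @param n Surface coverage (mol/m^2) in \[0, nA\].
#' @param p [binding_params()].
#' @return dn/dt in mol m^-2 s^-1.
#' @export
surface_rate <- function(c, n, p = binding_params()) {
  if (any(c < 0)) stop("c must be non-negative")
  if (any(n < 0) || any(n > p$nA * (1 + 1e-12)))
    stop("n must lie in [0, nA]")
  p$ka * c * (1 - n / p$nA) - p$kd * n / p$nA
}

#' Equilibrium surface coverage (one-site binding isotherm)
#'
#' Setting the surface rate to zero gives the Langmuir isotherm
#' \eqn{n_{eq}(c) = n_A c / (c + K_D)}: half saturation at c = KD,
#' monotone increasing and concave, approaching nA as c grows.
#'
#' @param c Bulk concentration(s) (mol/m^3), >= 0.
#' @param p [binding_params()].
#' @return Equilibrium coverage (mol/m^2).
#' @export
equilibrium_coverage <- function(c, p = binding_params()) {
  if (any(c < 0)) stop("c must be non-negative")
  p$nA * c / (c + p$KD)
}

#' Association rate constant from equilibrium and dissociation constants
#'
#' \eqn{k_a = k_d / K_D}.  With the default PhoB/DNA parameters this is
#' approximately 7.14e-7 m/s.
#'
#' @param kd Dissociation rate constant (mol m^-2 s^-1).
#' @param KD Equilibrium dissociation constant (mol/m^3), > 0.
#' @return ka in m/s.
#' @export
association_from_equilibrium <- function(kd, KD) {
  if (any(KD <= 0)) stop("KD must be positive")
  stopifnot(all(kd >= 0))
  kd / KD
}

#' Injection schedule of the flow cell
#'
#' The inlet concentration is raised smoothly (cosine smoothstep) from 0
#' to `c_in` over `ramp_up`, held for `hold`, and lowered back to 0 over
#' `ramp_down`.  Defaults: 0.5 s ramps around a 20 s hold.
#'
#' @param c_in Plateau inlet concentration (mol/m^3).
#' @param ramp_up,hold,ramp_down Durations (s), >= 0.
#' @return An `injection_schedule` list; use [inlet_concentration()] to
#'   evaluate it.
#' @export
injection_schedule <- function(c_in, ramp_up = 0.5, hold = 20,
                               ramp_down = 0.5) {
  stopifnot(c_in >= 0, ramp_up >= 0, hold >= 0, ramp_down >= 0)
  structure(list(c_in = c_in, ramp_up = ramp_up, hold = hold,
                 ramp_down = ramp_down,
                 t_end = ramp_up + hold + ramp_down),
            class = "injection_schedule")
}

#' Evaluate an injection schedule
#'
#' @param schedule An [injection_schedule()].
#' @param t Time(s) in s.
#' @return Inlet concentration(s) (mol/m^3).
#' @export
inlet_concentration <- function(schedule, t) {
  s <- schedule
  ramp <- function(x) (1 - cos(pi * pmin(pmax(x, 0), 1))) / 2
  up <- if (s$ramp_up > 0) ramp(t / s$ramp_up) else as.numeric(t >= 0)
  dn <- if (s$ramp_down > 0)
    ramp((t - s$ramp_up - s$hold) / s$ramp_down) else
    as.numeric(t >= s$ramp_up + s$hold)
  s$c_in * (up - dn)
}

#' Well-mixed (transport-free) sensorgram
#'
#' Integrates the Langmuir rate law with the near-wall concentration
#' equal to the inlet schedule -- the limit of the coupled flow-cell
#' solver when transport is infinitely fast.  Each sub-interval uses the
#' exact exponential update of the linear-in-n ODE, so piecewise-constant
#' schedules are integrated without truncation error; for constant c the
#' solution is \eqn{n(t) = n_{eq}(1 - e^{-(k_a c + k_d) t / n_A})}.
#'
#' @param schedule An [injection_schedule()].
#' @param p [binding_params()].
#' @param dt Output sampling interval (s).
#' @param t_end End time (s), default schedule end + 5 dissociation
#'   time constants.
#' @param n0 Initial coverage (mol/m^2).
#' @return A `sensorgram` data frame `t, n_mean, c_wall`.
#' @export
wellmixed_sensorgram <- function(schedule, p = binding_params(),
                                 dt = 0.01, t_end = NULL, n0 = 0) {
  if (is.null(t_end))
    t_end <- schedule$t_end + if (p$k_off > 0) 5 / p$k_off else 1
  times <- seq(0, t_end, by = dt)
  cs <- inlet_concentration(schedule, times)
  # midpoint sampling of c over each step: second order on the smooth
  # ramps and exact for piecewise-constant schedules aligned to the grid
  cmids <- inlet_concentration(schedule, times[-length(times)] + dt / 2)
  n <- numeric(length(times))
  n[1] <- n0
  for (k in seq_len(length(times) - 1)) {
    cmid <- cmids[k]
    A <- p$ka * cmid
    B <- (p$ka * cmid + p$kd) / p$nA
    n[k + 1] <- if (B > 0)
      A / B + (n[k] - A / B) * exp(-B * dt) else n[k] + A * dt
  }
  structure(data.frame(t = times, n_mean = n, c_wall = cs),
            class = c("sensorgram", "data.frame"))
}
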