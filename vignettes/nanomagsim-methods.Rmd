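---
title: "Models, numerics and design choices in nanomagsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in nanomagsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
integrates, the parameters that matter, the numerical choices behind the
solvers, and what the test suite does and does not establish.

## 1. The magnetic model

Each nanoparticle is a **single-domain macrospin**: a rigid moment of
magnitude $|m| = M_s \pi d^3/6$ attached to the particle center.  Two
couplings act between particles:

* the full magnetic dipole–dipole energy,
  $H_{DD} = -\frac{\mu_0}{4\pi r^3}\left[3(m_1\cdot\hat r)(m_2\cdot\hat r)
  - m_1\cdot m_2\right]$, summed over **all** pairs with no cutoff
  (the systems of interest are a few hundred particles, so the $O(n^2)$
  sum is exact and affordable; this is a documented scaling limit);
* a Weeks–Chandler–Andersen repulsion with per-pair
  $\sigma_{ij} = (d_i + d_j)/2$, cut and shifted to zero at
  $2^{1/6}\sigma_{ij}$, which converts point particles into effective
  hard spheres and removes the dipolar collision singularity.

Exchange coupling and magnetocrystalline anisotropy are deliberately
absent: at these sizes and separations the dipolar term dominates, and
carbon-shell particles do not exchange-couple.

**The WCA energy scale.**  The hard-sphere model is conventionally
stated in reduced units ($\epsilon = \sigma = 1$), which leaves the SI
energy scale open.  We set the default
$\epsilon = \mu_0 m^2/(2\pi d^3)$ — the dipolar contact energy of the
smallest particle (`contact_epsilon()`).  The choice matters: for 20 nm
cobalt particles the dipolar contact energy is roughly 220 $k_BT$, so a
thermal-scale $\epsilon$ would let bound pairs interpenetrate to
0.74 contact distances, destroying the hard-sphere behaviour the
potential exists to provide.  With the contact-scaled default, a bound
head-to-tail pair equilibrates at $\approx 1.09\,\sigma$, inside the
well $[\sigma, 2^{1/6}\sigma]$, and the minimum pair distance stays
above $0.9\sigma$ throughout assembly runs.  $\epsilon$ remains a plain
argument everywhere.

## 2. Spin dynamics

Moment orientations evolve under the stochastic
Landau–Lifshitz–Gilbert equation,
$$\dot m = -\frac{\gamma}{1+\alpha^2}\left[m\times B
  + \frac{\alpha}{|m|}\, m\times(m\times B)\right],$$
with $B$ the external plus dipolar plus thermal field; the Langevin
thermal field has per-component variance
$2\alpha k_B T/(\gamma|m|\Delta t)$.  Integration is Heun
(predictor–corrector, same noise realization in both stages) followed by
renormalization of each $|m_i|$ — the macrospin magnitude is a material
constant, and the tests hold it to $10^{-10}$ relative.

Defaults: $\alpha = 0.1$, $\gamma = 1.76\times10^{11}$ rad s⁻¹ T⁻¹,
$\Delta t = 10^{-13}$ s.  The step resolves the fastest precession in
the problem (contact dipolar fields reach $\sim$0.15 T for 20 nm Co,
i.e. a 0.24 ns period) by three orders of magnitude.  Relaxation-style
runs use $\alpha = 0.5$, $\Delta t = 10^{-12}$ s: still >200 steps per
precession period, ten times cheaper, and convergence to ground states
is what matters there, not trajectory fidelity.

`relax()` integrates at $T = 0$ in windows (default 2000 steps) until
the magnetic energy changes by less than `tol` (default $10^{-24}$ J,
i.e. $\sim 10^{-6}$ of a typical pair energy) over a window.  Energy is
non-increasing between windows at $T=0$; this is a tested invariant.

**Demagnetization.**  For frustrated arrangements a plain relaxation is
trapped by local minima.  The demagnetization protocol exposes the
sample to a sinusoidally oscillating, rotating, amplitude-damped field:
30 carrier oscillations, azimuth winding 7 full turns, polar angle
sweeping $[0,\pi]$ 3 times, amplitude falling linearly 0.05 T → 0 over
$10^{-7}$ s, then a final relaxation.  The counts and bounds are the
protocol's specification; the waveform realizing them (linear envelope,
uniform winding, cosine polar sweep) is this package's reading, since
only the counts are prescribed.  Its justification is behavioural and
tested: over matched seeded ensembles the demagnetized energies have
lower mean *and* smaller spread than plain relaxation.

**Field sweeps.**  `magnetization_curve()` steps the field from
$+B_{max}$ to $-B_{max}$ and back, integrating to an energy plateau at
each value and recording $M/M_s$ projected on the sweep axis — the
projection, not the magnitude, because that is what a magnetometer
measures along the applied field.  A small seeded tilt (0.01 rad,
configurable) is applied before each field step: at $T=0$ a moment
exactly antiparallel to the field sits on an unstable equilibrium of
the LLG flow and would otherwise never switch.  The tilt is the
numerical stand-in for infinitesimal thermal agitation.

## 3. Translational dynamics and the hybrid scheduler

The gel is viscous and the particles are nanometric, so translation is
**overdamped Langevin** motion, $\dot x = F/\zeta + \sqrt{2k_BT/\zeta}\,\xi$,
with Stokes drag $\zeta = 6\pi\eta r$ per particle.  The default
viscosity is 1 Pa·s — a gel-like value, three decades above water;
$\eta$ only rescales time, not the assembled structures.  The default
MD step is chosen so the drift displacement at the typical contact
force stays below $d/100$, and the integrator aborts (advising a
smaller step) if any realized displacement exceeds half a diameter.
The box is reflective: a finite droplet, not a periodic crystal.
Particles default to planar motion (`motion_dim = 2`) with moments free
in 3D, matching quasi-planar samples; full 3D is a flag.

`hybrid_run()` exploits the separation between fast moment dynamics and
slow translation: relax moments at fixed positions, advance positions
for `sd_every` steps at fixed moments, repeat.  Energies, magnetization
and the mean nearest-neighbour distance are recorded at every SD point.
In zero field the dipolar energy falls and the mean nearest-neighbour
distance shrinks as chains and small vortex islands form; both are
acceptance-tested on the scaled 192-particle reference run ($2\times10^5$
MD steps, SD every $10^4$ — the production-scale run of $2\times10^7$
steps is deliberately out of test scope).

## 4. GMR extraction

For granular systems the characteristic curve follows the total
magnetization: $\mathrm{GMR} = A_{GMR}[1 - (M/M_s)^2]$, maximal where
the net magnetization crosses zero and vanishing at saturation.
$A_{GMR}$ defaults to 20 %, the experimentally matched amplitude for
Co/gel systems; it is a pure scale factor.  Computing $A_{GMR}$ from
electronic structure, or resistor-network transport, is out of scope.

## 5. Flow cell and surface binding

The binding half of the package models a protein solution flowing over
a DNA-functionalized sensor floor.  Geometry: 2400 × 500 × 20 µm.  The
aspect ratio (width ≫ height) makes the Stokes flow between the plates
plane Poiseuille, $u(z) = 6\bar u (z/h)(1-z/h)$, which is used
analytically; the 500 µm width enters only the mole bookkeeping.  The
transport problem is therefore 2D (length × height):
$\partial_t c = D\nabla^2 c - u\,\partial_x c$.  (The transport
equation is implemented in this standard dissipative form; the
sign-degenerate variant that sometimes appears in print would make
diffusion anti-dissipative.)

At $D = 10^{-10}$ m²/s (Stokes–Einstein for a 2 nm protein at 20 °C —
the package computes this, and it is one of the acceptance numbers) and
$\bar u = 3.3$ cm/s the channel Péclet number is $\sim 8\times10^5$:
advection must be stabilized and the mass-transfer boundary layer
($\sim$3 µm by the Lévêque estimate) must be resolved.  Numerics:

* first-order upwind advection in $x$ (monotone, no oscillations; its
  numerical diffusion is documented and tested via pulse transport);
* explicit central diffusion in $x$ (negligible constraint at these
  Péclet numbers), with the inlet face acting as a Dirichlet reservoir
  at $c_{in}(t)$ — this is what feeds the cell in the $u=0$ well-mixed
  verification limit.  A `closed` inlet mode seals the box for
  conservation tests;
* implicit (backward-Euler) diffusion in $z$ on a geometrically graded
  mesh (default: 40 cells, ratio 1.15, wall cell ≈ 11 nm, more than ten
  cells in the bottom micron);
* the Robin floor condition
  $D\,\partial_z c|_{wall} = k_a c_w(1 - n/n_A) - k_d n/n_A$ is folded
  *into* the implicit $z$ solve with the coverage $n$ frozen over the
  step, and the surface ODE is then advanced with the **identical
  discrete flux**.  A Strang split with an independent exponential
  surface update was considered and rejected: it double-counts the wall
  flux between fluid and surface and cannot close the mole ledger
  exactly.  The coupled step is first order in the coupling, which at
  the default $\Delta t \approx 4\times10^{-4}$ s against surface rates
  of order 1 s⁻¹ contributes $\sim 10^{-4}$ relative error, while the
  mole ledger (inflow, outflow, stored, bound, all from the scheme's
  own fluxes) closes to $\sim10^{-12}$ — far inside the 0.5 % bound.

The time step defaults to the largest stable value (advective CFL 0.8,
x-diffusion number 0.25, at least ten steps per concentration ramp).
Positivity of $c$ and $0 \le n \le n_A$ hold by construction in valid
runs; the clip counter that would catch violations is asserted to be
zero in the tests.

The **well-mixed verification** (transport made infinitely fast, result
compared with the closed-form Langmuir ODE) runs on a 200 µm cell: with
$D$ raised to $10^{-6}$ m²/s the diffusive mixing time of the full
2400 µm cell is ~6 s — physically not well mixed on the 0.5 s ramp
timescale — whereas the short cell mixes in ~0.04 s.  This is a fixture
geometry choice, not a tolerance adjustment.

## 6. Binding model and inference

The 1:1 Langmuir rate law
$\dot n = k_a c(1-n/n_A) - k_d n/n_A$ keeps the units printed with the
reference system: $k_d$ in mol m⁻² s⁻¹ and $K_D$ in mol m⁻³, so that
$k_a = k_d/K_D$ has velocity units (m/s).  The conventional first-order
off-rate is exposed as the derived $k_{off} = k_d/n_A \approx 0.586$ s⁻¹
at the defaults.  The well-mixed integrator uses the exact exponential
update of the linear-in-$n$ ODE with midpoint-sampled $c$, so
piecewise-constant schedules aligned to the grid integrate without
truncation error.

`fit_dissociation_rate()` fits a line to $\log n(t)$ — the log-linear
reading of the dissociation phase — with the window starting 1 s after
the injection ends (early washout is transport-contaminated while the
channel flushes, ~0.1 s at the reference flow) and ending where the
signal falls below $10^{-3}$ of its peak.  On the full coupled
simulation at reference parameters the recovered slope is within ~2.5 %
of $-k_d/n_A$; the residual bias is genuine rebinding physics (the
transport Damköhler number $k_a \delta/D \approx 0.02$), not solver
error.  `fit_equilibrium_KD()` fits the one-site isotherm
$n = n_{max} c/(c + K_D)$ by `nls` in scaled variables (with
`scaleOffset`, because the textbook relative-offset criterion fails on
the zero-residual synthetic data used in validation), initialized at
$n_{max,0} = \max n$, $K_{D,0} = \mathrm{median}(c)$, with a damped
profile-grid fallback if the refinement stalls.

## 7. The synthetic-data generators and what green tests mean

`random_ensemble()` emulates the as-prepared state: non-overlapping
particles, uniformly random orientations.  Below 30 % area fraction it
is plain rejection sampling.  The dense reference request (192 × 20 nm
in 350 × 350 nm) is a 49 % area fraction — beyond what rejection
sampling can reach (its practical ceiling sits well below the ~55 %
jamming limit) — so dense requests are seeded from a jittered hexagonal
lattice, still seeded-random and overlap-free by construction.  The
generator is monodisperse by default; per-particle diameters are
supported (and exercised via table import) but the measured size
dispersion of real samples is not emulated.

Green tests therefore establish: correctness of the interaction
energies/forces against closed forms and finite differences;
convergence of the relaxation to brute-force ground states on 2–4
particle oracles; the statistical superiority of the demagnetization
protocol; energy descent and densification of scaled assembly runs;
conservation, boundary-layer resolution and limiting behaviour of the
transport solver; and parameter recovery on synthetic sensorgrams.
They do *not* establish quantitative agreement with any laboratory GMR
amplitude (a material/transport property supplied as $A_{GMR}$), nor
rate constants of a real experiment — inference is validated purely on
synthetic data, as no quantitative experimental fit target exists.

## 8. Known limitations

* All-pairs $O(n^2)$ interactions: fine to a few hundred particles, no
  cell lists or Ewald sums (reflective, non-periodic boxes only).
* No hydrodynamic interactions; the gel enters as a scalar drag.
* No buoyancy/sedimentation term in the transport equation.
* The brute-force oracle covers ≤ 4 particles; larger ground states are
  only validated behaviourally.
* Inertial MD exists behind `md_params()` only in the sense that the
  drag is configurable; a velocity-Verlet path is not implemented —
  overdamped dynamics is the regime of every intended application.
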