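# Shared fixtures: everything is built in code at test time.

CO_MS <- 1.446e6          # bulk cobalt saturation magnetization, A/m
D_REF <- 20e-9            # reference particle diameter, m
M_REF <- moment_magnitude(D_REF, CO_MS)
MU0 <- si_constants()$mu0

# closed-form two-dipole ground state (head-to-tail) at distance r
e_head_to_tail <- function(r, m = M_REF) -MU0 * m^2 / (2 * pi * r^3)

# two particles on the x axis at distance r, seeded random moments
pair_ensemble <- function(r = D_REF, seed = 1, moments = NULL) {
  np_ensemble(rbind(c(0, 0, 0), c(r, 0, 0)), D_REF,
              box = np_box(c(4 * r, 4 * r, 4 * r)),
              moments = moments, seed = seed)
}

# fast SD parameter set for relaxation-style tests
fast_sd <- function(seed = 1) sd_params(alpha = 0.5, dt = 1e-12, seed = seed)

# paper-scale binding parameters (PhoB / DNA)
phob_binding <- function() binding_params(kd = 1.5e-8, KD = 21e-3,
                                          nA = 2.56e-8)

NINE_CONC <- c(0.5, 1, 2.5, 5, 7.5, 10, 12.5, 15, 20) * 1e-3  # mol/m^3
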