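test_that("pair dipole energy matches hand-derived configurations", {
  m <- M_REF; r <- 25e-9
  mx <- c(m, 0, 0); mz <- c(0, 0, m)
  # head-to-tail: -mu0 m^2 / (2 pi r^3)
  expect_equal(pair_dipole_energy(mx, mx, c(r, 0, 0)),
               -MU0 * m^2 / (2 * pi * r^3), tolerance = 1e-14)
  # side-by-side parallel: +mu0 m^2 / (4 pi r^3)
  expect_equal(pair_dipole_energy(mz, mz, c(r, 0, 0)),
               MU0 * m^2 / (4 * pi * r^3), tolerance = 1e-14)
  expect_identical(pair_dipole_energy(mx, c(0, 0, 0), c(r, 0, 0)), 0)
  expect_error(pair_dipole_energy(mx, mx, c(0, 0, 0)), "coincident")
})

test_that("pair dipole energy is symmetric under particle exchange", {
  set.seed(11)
  for (k in 1:20) {
    m1 <- rnorm(3) * 1e-18; m2 <- rnorm(3) * 1e-18
    r <- rnorm(3) * 30e-9
    expect_equal(pair_dipole_energy(m1, m2, r),
                 pair_dipole_energy(m2, m1, -r), tolerance = 1e-14)
  }
})

test_that("dipolar field is consistent with the pair energy sum", {
  # two aligned head-to-tail moments: field mu0 m/(2 pi r^3) along moment
  r <- 30e-9
  ens <- pair_ensemble(r, moments = rbind(c(M_REF, 0, 0), c(M_REF, 0, 0)))
  B1 <- dipolar_field(ens, 1)
  expect_equal(B1, c(MU0 * M_REF / (2 * pi * r^3), 0, 0),
               tolerance = 1e-12)
  # single particle: zero field
  single <- np_ensemble(matrix(0, 1, 3), D_REF, seed = 1)
  expect_equal(dipolar_field(single, 1), c(0, 0, 0))
  # -1/2 sum m.B == pairwise sum on a random 10-particle ensemble
  e10 <- random_ensemble(10, c(350e-9, 350e-9), D_REF, seed = 3)
  B <- dipolar_field(e10)
  expect_equal(-0.5 * sum(e10$moments * B), total_energy(e10)$dipolar,
               tolerance = 1e-12)
})

test_that("WCA potential has the exact cutoff structure", {
  eps <- 1e-20; sig <- 20e-9
  expect_equal(wca_energy(2^(1 / 6) * sig, eps, sig), 0)
  expect_equal(wca_energy(10 * sig, eps, sig), 0)
  expect_equal(wca_energy(sig, eps, sig), eps, tolerance = 1e-14)
  expect_error(wca_energy(0, eps, sig), "positive")
  # continuity at the cutoff: approach from below
  rminus <- 2^(1 / 6) * sig * (1 - 1e-8)
  expect_lt(wca_energy(rminus, eps, sig) / eps, 1e-9)
})

test_that("energy breakdown sums exactly and Zeeman term is -m.B", {
  single <- np_ensemble(matrix(0, 1, 3), D_REF,
                        moments = matrix(c(0, 0, M_REF), 1))
  e0 <- total_energy(single)
  expect_identical(e0$total, 0)
  eB <- total_energy(single, B_ext = c(0, 0, 0.05))
  expect_equal(eB$zeeman, -M_REF * 0.05, tolerance = 1e-14)
  expect_identical(eB$total, eB$dipolar + eB$wca + eB$zeeman)
  # two head-to-tail at r beyond cutoff: total is pure dipolar
  r <- 40e-9
  pair <- pair_ensemble(r, moments = rbind(c(M_REF, 0, 0), c(M_REF, 0, 0)))
  expect_equal(total_energy(pair)$total, e_head_to_tail(r),
               tolerance = 1e-12)
})

test_that("analytic forces match finite-difference gradients (oracle)", {
  h <- 1e-12
  for (seed in c(5, 23)) {
    ens <- random_ensemble(8, c(200e-9, 200e-9), D_REF, seed = seed)
    eps <- contact_epsilon(ens)
    F <- pair_forces(ens)
    num <- matrix(0, 8, 3)
    for (i in 1:8) for (k in 1:3) {
      ep <- ens; ep$positions[i, k] <- ep$positions[i, k] + h
      em <- ens; em$positions[i, k] <- em$positions[i, k] - h
      num[i, k] <- -(total_energy(ep, epsilon = eps)$total -
                     total_energy(em, epsilon = eps)$total) / (2 * h)
    }
    expect_lt(max(abs(F - num)) / max(abs(F)), 1e-6)
    # global force balance
    expect_lt(max(abs(colSums(F))) / max(abs(F)), 1e-12)
  }
})

test_that("head-to-tail attraction has the closed-form magnitude", {
  r <- 40e-9  # beyond WCA cutoff
  pair <- pair_ensemble(r, moments = rbind(c(M_REF, 0, 0), c(M_REF, 0, 0)))
  F <- pair_forces(pair)
  expect_equal(F[1, ], -F[2, ], tolerance = 1e-14)
  f_exp <- 3 * MU0 * M_REF^2 / (2 * pi * r^4)
  # particle 1 is pulled toward particle 2 (+x)
  expect_equal(F[1, ], c(f_exp, 0, 0), tolerance = 1e-10)
})

test_that("WCA force vanishes continuously at the cutoff", {
  sig <- D_REF
  ens <- pair_ensemble(sig * 2^(1 / 6) * (1 - 1e-12),
                       moments = rbind(c(0, 0, M_REF), c(0, 0, -M_REF)))
  eps <- contact_epsilon(ens)
  # WCA force is linear in epsilon; differencing two epsilon values
  # isolates it from the (epsilon-independent) dipolar part
  dF <- pair_forces(ens, eps) - pair_forces(ens, eps / 2)
  expect_lt(2 * max(abs(dF)), 1e-9 * eps / sig)
})
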