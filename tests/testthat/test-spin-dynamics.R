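test_that("damped precession aligns a single moment with the field", {
  m0 <- M_REF * c(1, 0, 0)  # 90 degrees from B
  ens <- np_ensemble(matrix(0, 1, 3), D_REF, moments = matrix(m0, 1))
  out <- sd_integrate(ens, field = c(0, 0, 0.05),
                      params = sd_params(alpha = 0.1, dt = 1e-12),
                      n_steps = 20000)
  mm <- out$ensemble$moments
  expect_gt(mm[3] / sqrt(sum(mm^2)), 0.999)
})

test_that("conservative precession conserves energy and |m|", {
  ens <- random_ensemble(5, c(120e-9, 120e-9), D_REF, seed = 3)
  out <- sd_integrate(ens, field = c(0, 0, 0.01),
                      params = sd_params(alpha = 0, dt = 1e-13),
                      n_steps = 1e4, record_every = 500)
  tr <- out$trajectory
  E <- tr$E_dipolar + tr$E_zeeman
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-6)
  mm <- sqrt(rowSums(out$ensemble$moments^2))
  expect_lt(max(abs(mm - M_REF)) / M_REF, 1e-10)
  # |M|/Ms stays in [0, 1] along the trajectory
  expect_true(all(sqrt(tr$Mx^2 + tr$My^2 + tr$Mz^2) <= 1 + 1e-12))
})

test_that("T = 0 damped dynamics never increases magnetic energy", {
  ens <- random_ensemble(12, c(150e-9, 150e-9), D_REF, seed = 8)
  out <- sd_integrate(ens, params = fast_sd(), n_steps = 20000,
                      record_every = 1000)
  E <- out$trajectory$E_dipolar + out$trajectory$E_zeeman
  expect_true(all(diff(E) <= abs(E[-length(E)]) * 1e-9 + 1e-30))
})

test_that("two contact particles relax to the head-to-tail ground state", {
  E0 <- e_head_to_tail(D_REF)
  for (seed in c(2, 9, 17)) {
    ens <- pair_ensemble(D_REF, seed = seed)
    res <- suppressWarnings(relax(ens, params = fast_sd(seed), tol = 1e-26))
    expect_lt(abs(res$energy$dipolar - E0) / abs(E0), 0.01)
    # moments along +-x
    mhat <- res$ensemble$moments / M_REF
    expect_gt(abs(mhat[1, 1]), 0.999)
    expect_gt(mhat[1, 1] * mhat[2, 1], 0)  # parallel, not opposed
  }
})

test_that("relax is a no-op for an isolated particle in zero field", {
  ens <- np_ensemble(matrix(0, 1, 3), D_REF, seed = 4)
  res <- relax(ens, params = fast_sd())
  expect_equal(res$energy$total, 0)
  expect_equal(res$ensemble$moments, ens$moments, tolerance = 1e-9)
})

test_that("relaxed line and square match the brute-force grid oracle", {
  r <- D_REF
  # 3 collinear contact particles -> ferromagnetic chain along the line
  pos3 <- rbind(c(0, 0, 0), c(r, 0, 0), c(2 * r, 0, 0))
  ens3 <- np_ensemble(pos3, D_REF, seed = 1)
  bf3 <- brute_force_ground_state(ens3, step_deg = 2)
  best3 <- Inf
  for (s in 1:5) {
    e <- np_ensemble(pos3, D_REF, seed = 50 + s)
    best3 <- min(best3, suppressWarnings(
      relax(e, params = fast_sd(s), tol = 1e-26))$energy$dipolar)
  }
  expect_lt(abs(best3 - bf3$energy) / abs(bf3$energy), 0.01)
  ang3 <- sort(bf3$angles_deg %% 180)
  expect_true(all(abs(ang3 - ang3[1]) <= 2))  # collinear moments

  # 2x2 contact square -> flux-closure vortex
  pos4 <- rbind(c(0, 0, 0), c(r, 0, 0), c(0, r, 0), c(r, r, 0))
  ens4 <- np_ensemble(pos4, D_REF, seed = 2)
  bf4 <- brute_force_ground_state(ens4, step_deg = 3)
  best4 <- Inf
  for (s in 1:5) {
    e <- np_ensemble(pos4, D_REF, seed = 70 + s)
    best4 <- min(best4, suppressWarnings(
      relax(e, params = fast_sd(s), tol = 1e-26))$energy$dipolar)
  }
  expect_lt(abs(best4 - bf4$energy) / abs(bf4$energy), 0.01)
})

test_that("demagnetization degenerates to relax at B0 = 0", {
  ens <- random_ensemble(8, c(120e-9, 120e-9), D_REF, seed = 6)
  a <- suppressWarnings(demagnetize(ens, demag_protocol(B0 = 0),
                                    params = fast_sd(3)))
  b <- suppressWarnings(relax(ens, params = fast_sd(3)))
  expect_equal(a$energy$total, b$energy$total, tolerance = 1e-10)
  expect_equal(a$ensemble$moments, b$ensemble$moments, tolerance = 1e-10)
})

test_that("the reference demag protocol lowers the energy", {
  ens <- random_ensemble(24, c(150e-9, 150e-9), D_REF, seed = 12)
  E_init <- total_energy(ens)$dipolar
  res <- suppressWarnings(demagnetize(ens, demag_protocol(),
                                      params = fast_sd(1)))
  expect_lte(res$energy$dipolar, E_init)
})

test_that("demag field waveform honors the protocol counts and envelope", {
  p <- demag_protocol(B0 = 0.05, duration = 1e-7)
  f <- nanomagsim:::demag_field_fn(p)
  expect_equal(sqrt(sum(f(0)^2)), 0)          # sin(0) = 0
  expect_equal(sqrt(sum(f(1e-7)^2)), 0)       # fully damped
  # envelope bound: |B(t)| <= B0 (1 - t/T)
  ts <- seq(0, 1e-7, length.out = 400)
  mag <- vapply(ts, function(t) sqrt(sum(f(t)^2)), numeric(1))
  expect_true(all(mag <= 0.05 * (1 - ts / 1e-7) + 1e-15))
  expect_gt(max(mag), 0.03)                   # actually reaches near B0
})

test_that("magnetization curve saturates and has loop shape", {
  ens <- np_ensemble(matrix(0, 1, 3), D_REF, seed = 2)
  sw <- field_sweep(0.05, n_steps = 11)
  mc <- magnetization_curve(ens, sw, fast_sd(3))$curve
  expect_equal(nrow(mc), 21)                  # full loop field sequence
  expect_equal(mc$B[1], 0.05)
  expect_equal(mc$B[11], -0.05)
  expect_equal(mc$m_reduced[1], 1, tolerance = 1e-3)
  expect_equal(mc$m_reduced[11], -1, tolerance = 1e-3)
  expect_true(all(abs(mc$m_reduced) <= 1 + 1e-9))
  # interacting many-particle ensemble: flux closure at remanence
  e12 <- random_ensemble(12, c(120e-9, 120e-9), D_REF, seed = 4)
  rel <- suppressWarnings(relax(e12, params = fast_sd()))
  M <- colSums(rel$ensemble$moments) / (12 * M_REF)
  expect_lt(sqrt(sum(M^2)), 1)
})

test_that("sd_integrate is deterministic given a seed at T > 0", {
  ens <- random_ensemble(6, c(120e-9, 120e-9), D_REF, seed = 5)
  ens$temperature <- 300
  p <- sd_params(alpha = 0.1, dt = 1e-13, seed = 77)
  a <- sd_integrate(ens, params = p, n_steps = 500)
  b <- sd_integrate(ens, params = p, n_steps = 500)
  expect_identical(a$ensemble$moments, b$ensemble$moments)
  p2 <- sd_params(alpha = 0.1, dt = 1e-13, seed = 78)
  c2 <- sd_integrate(ens, params = p2, n_steps = 500)
  expect_false(identical(a$ensemble$moments, c2$ensemble$moments))
})
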