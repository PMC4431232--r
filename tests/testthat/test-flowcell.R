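test_that("geometry builds a wall-refined graded mesh", {
  g <- flow_cell_geometry()
  expect_equal(sum(g$dz), g$height, tolerance = 1e-12)
  expect_lte(g$dz[1], g$height / 200)          # wall cell resolves the BL
  expect_gte(sum(g$zc < 1e-6), 10)             # >= 10 cells in bottom 1 um
  expect_true(all(diff(g$zc) > 0))
  expect_error(flow_cell_geometry(nx = 2), "nx")
})

test_that("Poiseuille profile: no-slip, 1.5x centerline, exact mean", {
  g <- flow_cell_geometry(nz = 200, grading = 1)
  tp <- transport_params(u_mean = 3.3e-2)
  expect_equal(poiseuille_profile(g, tp, 0), 0)
  expect_equal(poiseuille_profile(g, tp, g$height), 0)
  expect_equal(poiseuille_profile(g, tp, g$height / 2), 4.95e-2)
  # depth average over the mesh
  u <- poiseuille_profile(g, tp)
  expect_equal(sum(u * g$dz) / g$height, 3.3e-2, tolerance = 1e-3)
})

test_that("zero injection stays identically empty", {
  g <- flow_cell_geometry(nx = 12, nz = 12)
  sg <- simulate_injection(g, transport_params(), injection_schedule(0),
                           phob_binding(), t_end = 1)
  expect_true(all(sg$n_mean == 0))
  expect_true(all(attr(sg, "fields")$c == 0))
  expect_equal(mass_balance(sg), 0)
})

test_that("closed-box pure diffusion conserves moles and matches erf", {
  H <- 2e-5; D <- 1e-10
  g <- flow_cell_geometry(length = 1e-4, width = 1e-4, height = H,
                          nx = 4, nz = 200, grading = 1)
  off <- binding_params(ka = 0, kd = 0, KD = NULL, nA = 1e-8)
  c0 <- matrix(0, 200, 4); c0[g$zc < H / 2, ] <- 1
  t_end <- 0.04
  sg <- simulate_injection(g, transport_params(D = D, u_mean = 0),
                           injection_schedule(0), off, dt = 2e-5,
                           t_end = t_end, c0 = c0, inlet = "closed")
  m <- attr(sg, "mass")
  expect_lt(abs(m$moles_stored + m$moles_bound - m$moles_initial) /
            m$moles_initial, 1e-6)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  exact <- 0.5 * (1 - erf((g$zc - H / 2) / (2 * sqrt(D * t_end))))
  cfin <- attr(sg, "fields")$c[, 2]
  expect_lt(sqrt(sum((cfin - exact)^2) / sum(exact^2)), 0.01)
})

test_that("upwind advection transports a pulse monotonically", {
  H <- 2e-5
  g <- flow_cell_geometry(length = 2.4e-3, width = 1e-4, height = H,
                          nx = 240, nz = 8, grading = 1)
  tp <- transport_params(D = 1e-14, u_mean = 1e-2)
  off <- binding_params(ka = 0, kd = 0, KD = NULL, nA = 1e-8)
  x <- (seq_len(240) - 0.5) * g$dx
  pulse <- exp(-((x - 4e-4) / 8e-5)^2)
  c0 <- matrix(rep(pulse, each = 8), 8, 240)
  sg <- simulate_injection(g, tp, injection_schedule(0), off,
                           t_end = 0.1, c0 = c0)
  crow <- attr(sg, "fields")$c[4, ]
  u4 <- poiseuille_profile(g, tp)[4]
  expect_equal(x[which.max(crow)], 4e-4 + 0.1 * u4, tolerance = 0.02)
  # monotone scheme: no overshoot, no negative values
  expect_lte(max(crow), max(pulse))
  expect_gte(min(crow), 0)
})

test_that("well-mixed limit of the coupled solver matches the ODE", {
  # short cell + heavy diffusion: mixing time L^2/D ~ 0.04 s << ramps
  p <- phob_binding()
  sch <- injection_schedule(20e-3)
  g <- flow_cell_geometry(length = 2e-4, width = 5e-4, height = 2e-5,
                          nx = 6, nz = 16, grading = 1.1)
  tp <- transport_params(D = 1e-6, u_mean = 0)
  sg <- simulate_injection(g, tp, sch, p, t_end = sch$t_end)
  wm <- wellmixed_sensorgram(sch, p, dt = 0.002, t_end = sch$t_end)
  ref <- approx(wm$t, wm$n_mean, xout = sg$t)$y
  expect_lt(max(abs(sg$n_mean - ref), na.rm = TRUE) / max(wm$n_mean),
            0.02)
})

test_that("paper-parameter injection: conservation, bounds, phases", {
  g <- flow_cell_geometry(nx = 60, nz = 32)   # coarser for unit test speed
  p <- phob_binding()
  sch <- injection_schedule(20e-3)
  sg <- simulate_injection(g, transport_params(), sch, p, t_end = 26)
  expect_lt(mass_balance(sg), 0.005)
  expect_identical(attr(sg, "clip_events"), 0L)
  n <- attr(sg, "fields")$n
  expect_true(all(n >= 0 & n <= p$nA))
  expect_true(all(attr(sg, "fields")$c >= 0))
  # hold phase: non-decreasing once the wall is wetted; washout decreasing
  hold <- sg$t > 2 & sg$t < 20
  expect_true(all(diff(sg$n_mean[hold]) >= -1e-18))
  wash <- sg$t > 22.5
  expect_true(all(diff(sg$n_mean[wash]) <= 1e-18))
  # sensorgram CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensorgram(sg, f)
  back <- read_sensorgram(f)
  expect_equal(back$n_mean, sg$n_mean, tolerance = 1e-12)
})
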