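# Dimensionless equations of motion, characteristic times, frequencies.

test_that("characteristic times match their closed forms and the published cycle ratios", {
  geo <- artery_geometry(R = 3.46e-3, H = 0.68e-3, rho0 = 1160, lam_z0 = 1.53)
  C <- 9892 * 3.46e-3 / 1.16                     # from psR/C = 1.16
  tSk <- characteristic_time(skalak_params(B = C, C = C), geo)
  expect_equal(1 / tSk, 2187, tolerance = 5e-3)  # tcp = 1 s
  a <- 9892 * 3.46e-3 / (4.19 * 0.68e-3)         # from psR/aH = 4.19
  tH <- characteristic_time(hariton_params(a = a, b = 1.5), geo)
  expect_equal(1 / tH, 1143, tolerance = 1e-2)
  # square-root scaling: quadrupling the modulus halves the time
  t1 <- characteristic_time(skalak_params(0, 10), artery_geometry(3e-3, 5e-4))
  t2 <- characteristic_time(skalak_params(0, 40), artery_geometry(3e-3, 5e-4))
  expect_equal(t1 / t2, 2)
  tMR <- characteristic_time(mooney_rivlin_params(40e3, 0),
                             artery_geometry(3e-3, 5e-4, 1160, 1))
  expect_equal(tMR, sqrt(1160 * 9e-6 / 40e3))
})

test_that("Skalak restoring force is exactly its cubic polynomial", {
  expect_equal(skalak_polynomial_coeffs(0, 1), c(c0 = 0, c1 = 1, c2 = 1.5, c3 = 0.5))
  expect_equal(skalak_polynomial_coeffs(1, 1), c(c0 = 0, c1 = 2, c2 = 3, c3 = 1))
  set.seed(13)
  for (case in list(c(0, 1.2), c(0.5, 1.1), c(1, 1.53))) {
    cf <- skalak_polynomial_coeffs(case[1], case[2])
    x <- runif(100, -0.6, 1.5)
    poly <- cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
    expect_equal(restoring_term("skalak", case[1], case[2], x), unname(poly),
                 tolerance = 1e-13)
  }
})

test_that("restoring forces: worked values and collapse guard", {
  expect_equal(restoring_term("skalak", 0, 1.2, 0), (1.2^3 - 1.2) / 2)
  expect_equal(restoring_term("mooney_rivlin", 0, 1.25, 0), 0.369)
  for (law in c("skalak", "hariton", "mooney_rivlin")) {
    expect_equal(restoring_term(law, switch(law, skalak = 0.5, hariton = 5,
                                            mooney_rivlin = 0.1), 1, 0), 0)
    expect_error(restoring_term(law, 0.3, 1, -1.05), "collapsed")
  }
})

test_that("equation of motion: truncation orders and load coupling", {
  g3 <- ring_groups("skalak", 0.5, p_hat_s = 0.2, lam_z0 = 1.2, time_ratio = 2000,
                    order = 3)
  # cubic truncation is the full model
  set.seed(17)
  x <- runif(30, -0.5, 1); v <- runif(30, -1, 1)
  d3 <- ring_deriv(g3, x, v, p_hat = 0.2)
  expect_equal(d3$dv, (1 + x) * 0.2 - restoring_term("skalak", 0.5, 1.2, x))
  expect_equal(d3$dx, v)
  # zero-order: harmonic oscillator with unit stiffness at B/C = 0, lam_z0 = 1
  g0 <- ring_groups("skalak", 0, p_hat_s = 1e-9, lam_z0 = 1, time_ratio = 2000,
                    order = 0)
  d0 <- ring_deriv(g0, x, v, p_hat = 0)
  expect_equal(d0$dv, -x)
})

test_that("Mooney-Rivlin static equilibrium satisfies (1 - p) lam^4 = 1 without pre-stretch", {
  for (p in c(0.2, 0.5, 0.8)) {
    gr <- ring_groups("mooney_rivlin", 0.2, p_hat_s = p, lam_z0 = 1, time_ratio = 1000)
    xeq <- static_equilibrium(gr)
    expect_equal((1 - p) * (1 + xeq)^4, 1, tolerance = 1e-9)
  }
  # and the equilibrium stretch grows without bound as p -> 1
  gr <- ring_groups("mooney_rivlin", 0, p_hat_s = 0.99, lam_z0 = 1, time_ratio = 1000)
  expect_gt(static_equilibrium(gr), (1 - 0.99)^(-1 / 4) - 1 - 1e-6)
  gr1 <- ring_groups("mooney_rivlin", 0, p_hat_s = 1.01, lam_z0 = 1, time_ratio = 1000)
  expect_warning(xna <- static_equilibrium(gr1), "unbounded")
  expect_true(is.na(xna))
})

test_that("zero-order natural frequencies reproduce the published anchors", {
  expect_equal(natural_frequency("skalak", 0, 1, t_char = 5e-4)$omega0, 2000)
  expect_equal(natural_frequency("mooney_rivlin", 0, 1)$omega0_tchar, 2)
  expect_equal(natural_frequency("hariton", 16.7, 1)$omega0, 0)
  # frequency rises with pre-stretch (hardening)
  w <- vapply(c(1, 1.1, 1.2, 1.3),
              function(lz) natural_frequency("skalak", 0, lz)$omega0_tchar, numeric(1))
  expect_true(all(diff(w) > 0))
  # negative linearized stiffness (lam_z0 < 1, C > 24 B) flags non-oscillatory
  nf <- natural_frequency("skalak", 0, 0.5)
  expect_false(nf$oscillatory)
  expect_true(is.na(nf$omega0))
})

test_that("measured small-amplitude period matches the linearized frequency", {
  # free vibration about the static state: period within 0.1% of 2 pi/omega
  cases <- list(
    list(law = "skalak", mr = 0.5, lz = 1),
    list(law = "mooney_rivlin", mr = 0.2, lz = 1),
    list(law = "hariton", mr = 5, lz = 1.3),     # lz = 1 has zero stiffness
    list(law = "skalak", mr = 0, lz = 1.25))
  for (cs in cases) {
    gr <- ring_groups(cs$law, cs$mr, p_hat_s = 1e-12, lam_z0 = cs$lz,
                      time_ratio = 200, pressure_ratio = 1)
    xeq <- static_equilibrium(gr, p_hat = 0)
    tr <- simulate_ring(gr, x0 = xeq + 1e-4,
                        settings = solver_settings(samples_per_cycle = 20000))
    wlin <- sqrt(arteryring:::restoring_slope(cs$law, cs$mr, cs$lz, xeq))
    # period from successive upward zero crossings of v
    v <- tr$v; tau <- tr$tau
    up <- which(v[-length(v)] < 0 & v[-1] >= 0)
    t_up <- tau[up] + (tau[up + 1] - tau[up]) * (-v[up]) / (v[up + 1] - v[up])
    period <- mean(diff(t_up))
    expect_equal(period, 2 * pi / wlin, tolerance = 1e-3)
  }
})
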