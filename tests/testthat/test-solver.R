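# Time integration, peak extraction, dimensionalization, linear closed form.

test_that("a ring at equilibrium stays there", {
  gr <- ring_groups("skalak", 0, p_hat_s = 1e-13, lam_z0 = 1, time_ratio = 2000)
  tr <- simulate_ring(gr)
  expect_lt(max(abs(tr$x)), 1e-9)
  s <- summarise_response(tr)
  expect_lt(abs(s$peak[s$quantity == "W_norm"]), 1e-12)
  # a ring started at its static equilibrium under constant pressure gives a
  # constant trace whose peak is reported at the initial instant
  gr2 <- ring_groups("skalak", 0.5, p_hat_s = 0.16, lam_z0 = 1, time_ratio = 2000,
                     pressure_ratio = 1)
  xeq <- static_equilibrium(gr2)
  tr2 <- simulate_ring(gr2, x0 = xeq)
  expect_lt(diff(range(tr2$x)), 1e-8)
  s2 <- summarise_response(tr2)
  expect_equal(s2$t_peak[s2$quantity == "x"], 0)
  expect_equal(s2$peak[s2$quantity == "x"], xeq, tolerance = 1e-8)
})

test_that("step response of the healthy ring reaches the published 28% displacement", {
  gr <- ring_groups("skalak", 0, p_hat_s = 0.16, lam_z0 = 1, time_ratio = 2000)
  s <- summarise_response(simulate_ring(gr))
  expect_equal(s$peak[s$quantity == "x"], 0.28, tolerance = 0.01)
  # peak energy and first-peak time of the corresponding table entry
  expect_equal(s$peak[s$quantity == "W_norm"], 0.051184, tolerance = 5e-3)
  expect_equal(s$t_peak[s$quantity == "W_norm"], 0.001383, tolerance = 1e-2)
})

test_that("trace columns satisfy the kinematic identities at every sample", {
  gr <- ring_groups("mooney_rivlin", 0.2, p_hat_s = 0.32, lam_z0 = 1.25,
                    time_ratio = 1000)
  tr <- simulate_ring(gr)
  expect_equal(tr$lam_theta, 1 + tr$x, tolerance = 1e-14)
  expect_equal(tr$lam_theta * 1.25 * tr$h_over_H, rep(1, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$W_norm, mr_energy(0.2, tr$lam_theta, 1.25), tolerance = 1e-12)
})

test_that("pre-stretch-dominated rings peak at the initial state", {
  gr <- ring_groups("mooney_rivlin", 0, p_hat_s = 0.32, lam_z0 = 1.25,
                    time_ratio = 1000)
  s <- summarise_response(simulate_ring(gr))
  expect_equal(s$peak[s$quantity == "W_norm"], mr_energy(0, 1, 1.25), tolerance = 1e-10)
  expect_equal(s$t_peak[s$quantity == "W_norm"], 0)
})

test_that("energy is conserved on each constant-pressure segment", {
  fixtures <- list(
    ring_groups("skalak", 0.5, p_hat_s = 0.16, lam_z0 = 1.1, time_ratio = 2000),
    ring_groups("hariton", 15, p_hat_s = 3.2, lam_z0 = 1.1, time_ratio = 1 / 3e-4),
    ring_groups("mooney_rivlin", 0, p_hat_s = 0.32, lam_z0 = 1.05, time_ratio = 1000))
  for (gr in fixtures) {
    drift <- energy_drift(simulate_ring(gr))
    expect_lt(max(drift), 1e-6)
  }
})

test_that("halving the tolerances leaves reported peaks essentially unchanged", {
  fixtures <- list(
    ring_groups("skalak", 0, p_hat_s = 0.16, lam_z0 = 1.25, time_ratio = 2000),
    ring_groups("hariton", 15, p_hat_s = 2.4, lam_z0 = 1.15, time_ratio = 1 / 3e-4),
    ring_groups("mooney_rivlin", 0, p_hat_s = 0.48, lam_z0 = 1.1, time_ratio = 1000))
  for (gr in fixtures) {
    s1 <- summarise_response(simulate_ring(gr))
    s2 <- summarise_response(simulate_ring(
      gr, settings = solver_settings(rtol = 5e-12, atol = 5e-14)))
    rel <- abs(s1$peak - s2$peak) / pmax(abs(s1$peak), 1e-8)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("Mooney-Rivlin response is bounded below the pressure limit and diverges above", {
  bounded <- simulate_ring(
    ring_groups("mooney_rivlin", 0, p_hat_s = 0.8, lam_z0 = 1, time_ratio = 1000))
  expect_false(attr(bounded, "diverged"))
  expect_lt(max(bounded$lam_theta), 20)
  for (p in c(1, 1.2)) {
    diverging <- simulate_ring(
      ring_groups("mooney_rivlin", 0, p_hat_s = p, lam_z0 = 1, time_ratio = 1000))
    expect_true(attr(diverging, "diverged"))
    # monotone growth up to the stretch cap
    sub <- diverging$x
    expect_true(all(diff(sub) > -1e-12))
    expect_gt(max(diverging$lam_theta), 19.9)
  }
})

test_that("Skalak truncation hierarchy converges to the full model as the load shrinks", {
  disc <- vapply(c(0.16, 0.08, 0.04, 0.02), function(p) {
    peaks <- vapply(0:3, function(k) {
      gr <- ring_groups("skalak", 0.5, p_hat_s = p, lam_z0 = 1, time_ratio = 2000,
                        order = k)
      s <- summarise_response(simulate_ring(gr))
      s$peak[s$quantity == "x"]
    }, numeric(1))
    max(abs(peaks[1:3] - peaks[4])) / peaks[4]
  }, numeric(1))
  expect_true(all(diff(disc) < 0))
})

test_that("dimensionalise converts membrane tensions through the current thickness", {
  geo <- artery_geometry(R = 3.46e-3, H = 0.68e-3, rho0 = 1160, lam_z0 = 1.53)
  C <- 9892 * 3.46e-3 / 1.16
  gr <- ring_groups("skalak", 1, p_hat_s = 1.16, lam_z0 = 1.53, time_ratio = 2187,
                    pressure_ratio = 3466 / 9892)
  s <- summarise_response(simulate_ring(gr))
  rep <- dimensionalise(s, skalak_params(B = C, C = C), geo)
  sig <- rep$value[rep$quantity == "sigma_theta"]
  row <- s[s$quantity == "stress_theta_norm", ]
  expect_equal(sig, row$peak * C * row$lam_theta_at_peak * 1.53 / 0.68e-3 / 1000)
  # zero deformation, no pre-stretch: all stresses vanish
  gr0 <- ring_groups("skalak", 0.5, p_hat_s = 1e-13, lam_z0 = 1, time_ratio = 2000)
  s0 <- summarise_response(simulate_ring(gr0))
  rep0 <- dimensionalise(s0, skalak_params(10, 20), artery_geometry(3e-3, 5e-4))
  expect_lt(max(abs(rep0$value[rep0$quantity %in% c("sigma_theta", "sigma_z", "W")])),
            1e-9)
})

test_that("linear closed form: undamped step overshoot and free oscillation", {
  geo <- artery_geometry(R = 3e-3, H = 5e-4, rho0 = 1160, lam_z0 = 1)
  pulse <- pressure_pulse(ps = 12000, pd = 12000, ts = 0.35, tcp = 1)
  Eth <- 400e3
  tr <- linear_closed_form(Eth, geo, pulse, u0 = 0)
  u_static <- 12000 * geo$R^2 / (Eth * geo$H)
  expect_equal(max(tr$u_r), 2 * u_static, tolerance = 1e-6)  # overshoot factor 2
  expect_equal(min(tr$u_r), 0, tolerance = 1e-9)
  # zero pressure, initial displacement u0: oscillation of amplitude u0
  geo2 <- artery_geometry(R = 3e-3, H = 5e-4, rho0 = 1160, lam_z0 = 1.2)
  pulse0 <- pressure_pulse(ps = 1e-12, pd = 0, ts = 0.35, tcp = 1)
  tr0 <- linear_closed_form(Eth, geo2, pulse0)
  expect_equal(max(abs(tr0$u_r)), geo2$R * 0.2, tolerance = 1e-9)
})

test_that("linear closed form agrees with direct numerical integration", {
  geo <- artery_geometry(R = 3e-3, H = 5e-4, rho0 = 1160, lam_z0 = 1.2)
  pulse <- pressure_pulse()
  Eth <- 4e3
  cf <- linear_closed_form(Eth, geo, pulse)
  rhs <- function(t, y, p) {
    list(c(y[2], pressure_at(pulse, t) / (geo$rho0 * geo$H) -
             Eth * y[1] / (geo$rho0 * geo$R^2)))
  }
  # integrate numerically on the closed form's own time grid, restarting at
  # the pressure switch as the package solver does
  y <- c(geo$R * 0.2, 0)
  err <- 0
  for (pp in c(pulse$ps, pulse$pd)) {
    tt <- cf$t[cf$p == pp]
    out <- deSolve::ode(y, tt, rhs, NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
    err <- max(err, max(abs(out[, 2] - cf$u_r[cf$p == pp])))
    y <- unname(out[nrow(out), 2:3])
  }
  expect_lt(err / max(abs(cf$u_r)), 1e-8)
})
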