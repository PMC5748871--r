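# Constitutive layer: strain measures, energies, stresses, tangent moduli.

test_that("strain measures match their defining formulas", {
  expect_equal(unlist(green_strains(1, 1)), c(e_thetatheta = 0, e_zz = 0))
  expect_equal(green_strains(1.2, 1)$e_thetatheta, 0.22)
  expect_equal(green_strains(1, 1.53)$e_zz, 0.67045)

  expect_equal(unlist(skalak_invariants(1, 1)), c(I = 0, II = 0))
  inv <- skalak_invariants(1, 1.2)
  expect_equal(c(inv$I, inv$II), c(0.44, 0.44))   # I = II at lam_theta = 1 only
  inv2 <- skalak_invariants(1.06, 1.53)
  expect_equal(inv2$I, 1.4645, tolerance = 1e-10)
  expect_equal(inv2$II, 1.630236, tolerance = 1e-6)

  expect_equal(unlist(iso_invariants(1, 1)), c(I1 = 3, I2 = 3))
  expect_equal(unlist(iso_invariants(1, 1.25)), c(I1 = 3.2025, I2 = 3.2025))
  expect_equal(iso_invariants(1.42, 1.53)$I1, 4.569156, tolerance = 1e-6)

  expect_error(green_strains(-1, 1), "positive")
  expect_error(iso_invariants(1, 0), "positive")
})

test_that("strain energies vanish at the reference state and match tabulated pre-stretch values", {
  for (r in c(0, 0.3, 1)) expect_identical(skalak_energy(r, 1, 1), 0)
  expect_equal(skalak_energy(0, 1, 1.2), 0.0242, tolerance = 1e-10)
  expect_equal(skalak_energy(0.5, 1, 1.2), 0.0363, tolerance = 1e-10)
  expect_identical(hariton_energy(15, 1, 1), 0)
  expect_equal(hariton_energy(1.5, 1.42, 1.53), 3.559192, tolerance = 1e-5)
  expect_identical(mr_energy(0.2, 1, 1), 0)
  expect_equal(mr_energy(0, 1, 1.25), 0.10125, tolerance = 1e-10)
  expect_equal(mr_energy(-0.5, 1, 1.25), 0.10125, tolerance = 1e-10)  # beta drops out
  expect_equal(mr_energy(0, 1.21, 1), 0.0735567, tolerance = 1e-6)

  # strict positivity away from the reference state
  set.seed(7)
  lams <- runif(40, 0.8, 1.8); lzs <- runif(40, 1, 1.9)
  expect_true(all(skalak_energy(0.5, lams, lzs) > 0))
  expect_true(all(hariton_energy(5, lams, lzs) > 0))
  expect_true(all(mr_energy(0.25, lams, lzs) > 0))

  expect_error(skalak_energy(1.5, 1.1, 1), "0, 1")
  expect_error(mr_energy(0.7, 1.1, 1), "beta")
  expect_error(hariton_energy(30, 3.5, 1.9), "overflow")
})

test_that("Skalak tensions: reference zero, B/C = 0 symmetry, worked value", {
  t0 <- skalak_tensions(0.5, 1, 1)
  expect_equal(c(t0$T_theta_over_C, t0$T_z_over_C), c(0, 0))
  tt <- skalak_tensions(0, 1.2, 1)
  expect_equal(tt$T_theta_over_C, 0.264)
  expect_equal(tt$T_theta_over_C, tt$T_z_over_C, tolerance = 1e-14)
  # equality of the two tensions is exact for B/C = 0 at every state
  set.seed(11)
  for (i in 1:20) {
    lt <- runif(1, 0.8, 1.8); lz <- runif(1, 1, 1.9)
    tn <- skalak_tensions(0, lt, lz)
    expect_equal(tn$T_theta_over_C, tn$T_z_over_C, tolerance = 1e-14)
  }
  expect_equal(skalak_tensions(1, 1.06, 1.53)$T_theta_over_C, 1.364773,
               tolerance = 1e-6)
})

test_that("Mooney-Rivlin circumferential response is beta-independent without pre-stretch", {
  # without pre-stretch I1 = I2, so the energy and the circumferential
  # stress (hence the whole radial dynamics) lose their beta dependence;
  # sigma_zz retains it through the 1/lam_theta^2 vs lam_theta^2 asymmetry
  for (lt in c(0.9, 1.2, 1.5)) {
    a <- mr_stresses(-0.3, lt, 1)
    b <- mr_stresses(0.3, lt, 1)
    expect_equal(a$sigma_theta_over_mu, b$sigma_theta_over_mu, tolerance = 1e-15)
    expect_equal(mr_energy(-0.3, lt, 1), mr_energy(0.3, lt, 1), tolerance = 1e-15)
    expect_equal(restoring_term("mooney_rivlin", -0.3, 1, lt - 1),
                 restoring_term("mooney_rivlin", 0.3, 1, lt - 1), tolerance = 1e-15)
  }
  expect_equal(unlist(mr_stresses(0.1, 1, 1)),
               c(sigma_theta_over_mu = 0, sigma_z_over_mu = 0))
})

test_that("Hariton stresses: reference zero, worked value, sign structure", {
  s0 <- hariton_stresses(1.5, 1, 1)
  expect_equal(c(s0$sigma_theta_over_a, s0$sigma_z_over_a), c(0, 0))
  expect_equal(hariton_stresses(1.5, 1.42, 1.53)$sigma_theta_over_a, 35.89796,
               tolerance = 1e-5)
  set.seed(3)
  for (i in 1:20) {
    lt <- runif(1, 0.8, 1.8); lz <- runif(1, 1, 1.6)
    I1 <- iso_invariants(lt, lz)$I1
    sgn <- sign((lt^2 - 1 / (lt^2 * lz^2)) * (I1 - 3))
    expect_equal(sign(hariton_stresses(2, lt, lz)$sigma_theta_over_a), sgn)
  }
})

test_that("stress equals the energy derivative for all three laws", {
  # sigma_theta = lam_theta dW/dlam_theta (3-D laws, lam_r eliminated by
  # incompressibility); T_theta = (1/lam_z0) dW/dlam_theta (membrane law)
  set.seed(42)
  for (i in 1:20) {
    lt <- runif(1, 0.8, 1.8); lz <- runif(1, 1, 1.9)
    expect_equal(skalak_tensions(0.4, lt, lz)$T_theta_over_C,
                 num_deriv(function(l) skalak_energy(0.4, l, lz), lt) / lz,
                 tolerance = 1e-6)
    expect_equal(hariton_stresses(3, lt, lz)$sigma_theta_over_a,
                 lt * num_deriv(function(l) hariton_energy(3, l, lz), lt),
                 tolerance = 1e-6)
    expect_equal(mr_stresses(0.2, lt, lz)$sigma_theta_over_mu,
                 lt * num_deriv(function(l) mr_energy(0.2, l, lz), lt),
                 tolerance = 1e-6)
  }
})

test_that("thickness ratio follows incompressibility", {
  expect_identical(thickness_ratio(1, 1), 1)
  expect_identical(thickness_ratio(2, 0.5), 1)
  expect_equal(thickness_ratio(1.06, 1.53), 0.6165988, tolerance = 1e-6)
  # product of the three stretches is one to machine precision
  set.seed(5)
  lt <- runif(50, 0.5, 2); lz <- runif(50, 0.8, 1.9)
  expect_equal(lt * lz * thickness_ratio(lt, lz), rep(1, 50), tolerance = 1e-12)
})

test_that("tangent moduli: closed forms and finite-difference agreement", {
  mu <- 30e3
  expect_equal(tangent_modulus(mooney_rivlin_params(mu, 0.3), lam_z0 = 1), 4 * mu)
  expect_equal(tangent_modulus(mooney_rivlin_params(mu, -0.4), lam_z0 = 1), 4 * mu)
  expect_equal(tangent_modulus(hariton_params(44.2e3, 16.7), lam_z0 = 1), 0)
  expect_equal(tangent_modulus(skalak_params(10, 25), H = 5e-4, lam_z0 = 1),
               (10 + 25) / 5e-4)
  expect_error(tangent_modulus(skalak_params(10, 25), lam_z0 = 1), "thickness")

  cases <- list(
    list(p = skalak_params(15, 30), H = 6.8e-4),
    list(p = hariton_params(12e3, 1.5), H = NULL),
    list(p = mooney_rivlin_params(40e3, -0.2), H = NULL))
  for (lz in c(1, 1.25, 1.53, 1.9)) {
    for (cs in cases) {
      fd <- num_deriv(function(l)
        arteryring:::sigma_theta_dimensional(cs$p, l, lz, H = cs$H), 1, h = 1e-5)
      an <- tangent_modulus(cs$p, H = cs$H, lam_z0 = lz)
      if (abs(an) < 1e-6) {
        expect_lt(abs(fd), 1e-3)
      } else {
        expect_equal(an, fd, tolerance = 1e-6)
      }
    }
  }
})

test_that("parameter records enforce their admissibility conditions", {
  expect_error(skalak_params(B = 2, C = 1), "C >= B")
  expect_error(skalak_params(B = -1, C = 1), "C >= B")
  expect_error(hariton_params(a = -1, b = 2), "a > 0")
  expect_error(mooney_rivlin_params(mu = 1, beta = 0.8), "beta")
  expect_warning(artery_geometry(R = 1e-3, H = 2e-3), "thin-wall")
  expect_error(artery_geometry(R = -1, H = 2e-3), "positive")
})
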