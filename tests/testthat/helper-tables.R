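# Published peak normalized strain-energy tables (rows: lam_z0 = 1 to 1.3 in
# steps of 0.05; columns as noted) and shared fixture builders.

lamz_grid <- seq(1, 1.3, by = 0.05)

# Skalak peak W/C, columns B/C = 0, 0.5, 1 (psR/C = 0.16, tcp/tSk = 2000)
table1_published <- matrix(c(
  0.051184, 0.034112, 0.025579,
  0.0321,   0.02378,  0.019512,
  0.017248, 0.017016, 0.017996,
  0.013001, 0.019501, 0.026002,
  0.0242,   0.0363,   0.0484,
  0.041494, 0.060049, 0.079324,
  0.097124, 0.10226,  0.12222), ncol = 3, byrow = TRUE)

# Cells whose printed peaks carry end-of-run energy drift (peak times at or
# after the pressure switch, values above the analytic energy bound of the
# conservative dynamics); these are checked against the bound instead.
table1_drift_cells <- rbind(c(6, 1), c(7, 1), c(7, 2), c(7, 3))

# Hariton peak W/a, columns b = 5, 15, 25 (psR/aH = 3.2, tcp/tH = 1/3e-4)
table2_published <- matrix(c(
  2.6255, 1.9443, 1.6900,
  2.6272, 1.913,  1.6495,
  2.5968, 1.8488, 1.5688,
  2.5317, 1.747,  1.4549,
  2.4317, 1.6072, 1.2991,
  2.2964, 1.4287, 1.0992,
  2.1241, 1.2076, 0.8538), ncol = 3, byrow = TRUE)

# Hariton peak W/a, columns psR/aH = 0.8, 2.4, 4 (b = 15)
table3_published <- matrix(c(
  0.40285, 1.4107,  2.4879,
  0.39027, 1.3863,  2.4441,
  0.36872, 1.3341,  2.374,
  0.33763, 1.2558,  2.2506,
  0.29761, 1.1483,  2.0825,
  0.2494,  1.0106,  1.8603,
  0.19548, 0.84355, 1.5873), ncol = 3, byrow = TRUE)

# Mooney-Rivlin peak W/mu, columns beta = -0.5, 0, 0.5 (psR/muH = 0.32)
table4_published <- matrix(c(
  0.0757, 0.0757, 0.0757,
  0.0558, 0.0606, 0.0662,
  0.0473, 0.0556, 0.0666,
  0.048,  0.0589, 0.0754,
  0.0672, 0.0697, 0.0916,
  0.1013, 0.1013, 0.1145,
  0.1409, 0.1409, 0.1435), ncol = 3, byrow = TRUE)

# (row, col) pairs of Tables 1 and 4 whose printed peak time is exactly 0:
# the pre-stretch reference state is the maximum there.
table1_t0_cells <- as.matrix(expand.grid(row = 4:5, col = 1:3))
table4_t0_cells <- rbind(c(5, 1), c(6, 1), c(6, 2), c(7, 1), c(7, 2))

# per-segment relative energy drift of a trace (against the kinetic-energy
# scale of the motion; exact conservation would give 0)
energy_drift <- function(trace) {
  gr <- attr(trace, "groups")
  fns <- arteryring:::ring_fns(gr)
  segs <- attr(trace, "segments")
  vapply(segs$segment, function(i) {
    sub <- trace[trace$segment == i, ]
    E <- sub$v^2 / 2 + fns$V(sub$x) - fns$work_fun(sub$x, segs$p_hat[segs$segment == i])
    scale <- max(sub$v^2 / 2, 1e-10)
    diff(range(E)) / scale
  }, numeric(1))
}

# numerical central derivative
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
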