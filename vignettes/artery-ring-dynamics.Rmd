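---
title: "Radial dynamics of hyperelastic artery rings: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial dynamics of hyperelastic artery rings: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arteryring)
```

## The model

A short artery segment is idealized as a thin incompressible ring of
reference mid-wall radius $R$, thickness $H$ and density $\rho_0$, held at a
fixed longitudinal pre-stretch $\lambda_z^0$ and loaded by a uniform
time-dependent luminal pressure $p(t)$. The ring deforms radially only
(plane strain), so the kinematics reduce to one degree of freedom, the
circumferential stretch $\lambda_\theta(t) = 1 + u_r(t)/R$;
incompressibility fixes the radial stretch,
$\lambda_\theta \lambda_r \lambda_z^0 = 1$, hence the current thickness
$h/H = 1/(\lambda_\theta \lambda_z^0)$. Radial force balance on a wall
element gives

$$ r\,p(t) - N(t) = \rho_0\, h\, r\, \ddot u_r , $$

where $N = \sigma_{\theta\theta} h$ is the circumferential membrane force.
By incompressibility $h r = H R / \lambda_z^0$ is constant in time, which is
the reading of the inertia term consistent with the characteristic times
below (and the one the package unit-tests against them).

Three hyperelastic laws supply $N$, chosen to span the mechanical states of
the vessel wall:

* **Skalak membrane law** (healthy, convex hardening). A 2-D law with
  moduli $B, C$ in N/m ($C \ge B \ge 0$) in the membrane invariants
  $I = \lambda_\theta^2 + \lambda_z^{0\,2} - 2$,
  $II = \lambda_\theta^2 \lambda_z^{0\,2} - 1$:
  $W = \tfrac{B}{4}\!\left(\tfrac{I^2}{2} + I - II\right) + \tfrac{C}{8} II^2$.
  Tensions follow from
  $T_\theta = (\lambda_\theta/\lambda_z^0)\,\partial W/\partial e_{\theta\theta}$;
  Cauchy stress is recovered through the current thickness,
  $\sigma_{\theta\theta} = T_\theta \lambda_\theta \lambda_z^0 / H$.
* **Hariton/Delfino exponential law** (atherosclerotic, strong hardening).
  $W = \tfrac{a}{b}\left[e^{\frac{b}{2}(I_1 - 3)^2} - 1\right]$ with a
  stress-like $a$ [Pa] and dimensionless $b$, in the isochoric invariant
  $I_1 = \lambda_\theta^2 + \lambda_z^{0\,2} +
  1/(\lambda_\theta^2\lambda_z^{0\,2})$. The quadratic exponent makes the
  wall almost stress-free near the reference state (its initial tangent
  modulus vanishes at $\lambda_z^0 = 1$) and very stiff at large stretch.
* **Mooney–Rivlin law** (aneurysmatic, softening).
  $W = \tfrac{\mu}{2}\left[(\tfrac12+\beta)(I_1-3) +
  (\tfrac12-\beta)(I_2-3)\right]$, $\mu > 0$,
  $\beta \in [-\tfrac12, \tfrac12]$ ($\beta = \tfrac12$ is neo-Hookean).

With the thin-wall, stress-free-outer-surface assumption the hydrostatic
pressure term in the 3-D laws vanishes ($\sigma_{rr} \approx 0$), i.e.
stresses are differences $\sigma_i - \sigma_{rr}$. One consequence worth
stating: without pre-stretch ($I_1 = I_2$) the energy, the circumferential
stress and therefore the whole radial dynamics lose their $\beta$
dependence, but $\sigma_{zz}$ retains it — the $\beta$-independence is a
property of the circumferential response, not of every output.

## Dimensionless formulation

With $x = u_r/R$ and $\tau = t/t_c$ every model becomes

$$ x'' = (1 + x)\,\hat p(\tau) - g(x), $$

where $\hat p$ is the pressure normalized by the law's pressure scale
($p R/C$, $p R/(aH)$, $p R/(\mu H)$) and the characteristic times are
$t_{Sk} = \sqrt{\rho_0 R^2 H/(C\lambda_z^0)}$,
$t_{H} = \sqrt{\rho_0 R^2/(a\lambda_z^0)}$,
$t_{MR} = \sqrt{\rho_0 R^2/(\mu\lambda_z^0)}$. In every law $g$ is the
derivative of the normalized strain energy with respect to $x$, divided by
$\lambda_z^0$ — an identity the package uses heavily (tests, energy audit,
peak extraction).

The Skalak $g$ is an exact cubic $c_0 + c_1 x + c_2 x^2 + c_3 x^3$, which
defines the truncation hierarchy: order 3 is the full model, orders 2 and 1
drop the higher powers, and the zero-order model additionally drops the
$\hat p\,x$ load coupling, leaving a linear constant-coefficient equation
whose free frequency is the radial resonance
$\omega_0 = \sqrt{c_1}/t_c$. For the Mooney–Rivlin law
$\omega_0 t_{MR} = 2$ at $\lambda_z^0 = 1$, the classical incompressible-
rubber-tube result; for the Hariton law $g'(0) = 0$ at $\lambda_z^0 = 1$,
so its zero-order frequency vanishes. A negative linearized stiffness
(possible for Skalak with $\lambda_z^0 < 1$ and $C > 24B$) is returned as a
flagged non-oscillatory result, since it signals a material instability
rather than a numerical failure.

An *equivalent linear model*
$\rho_0 H \ddot u_r = p(t) - E_\theta H u_r / R^2$ built on the initial
tangent modulus $E_\theta = d\sigma_{\theta\theta}/d\lambda_\theta$ at
$\lambda_\theta = 1$ serves as the comparison baseline; its pre-tension
enters through the initial displacement $u_0 = R(\lambda_z^0 - 1)$, and its
piecewise-harmonic solution is available in closed form
(`linear_closed_form()`). The tangent moduli use the closed forms stated in
`tangent_modulus()`; all three are cross-validated against central finite
differences of the dimensional stress to a relative $10^{-6}$.

## Loading

The cardiac cycle is idealized as a rectangular wave: systolic plateau
$p_s$ for $0 \le t \le t_s$, diastolic plateau $p_d$ for the rest of the
cycle $t_{cp}$, repeated periodically (defaults 16 kPa / 10.66 kPa,
$t_s = 0.35$ s, $t_{cp} = 1$ s). The instantaneous rise is deliberately the
most conservative loading: an undamped oscillator under a step overshoots
to twice the static deflection, and the dynamic amplification seen in the
peak-response tables exists only because of the jump. Discontinuity times
are known a priori and are treated as integrator restart points, never
smoothed.

## Numerics

**Integration.** The second-order equation is integrated in state-space
form with `deSolve` (default `lsodar`, with compiled right-hand sides and
root functions; guard roots stop the run cleanly at ring collapse
$1 + x \to 0$, at a stretch cap $1 + x = 20$ that terminates the unbounded
Mooney–Rivlin regime, and before the Hariton exponent can overflow).
Integration is piecewise per pressure plateau, chaining the state across
restarts.

**Peak extraction.** Within a plateau the system is conservative:
$E = v^2/2 + V(x) - \hat p\,(x + x^2/2)$ is invariant (for the uncoupled
zero-order/linear models the work term is linear in $x$), so the orbit
oscillates between exactly two turning displacements — the roots of
$V(x) - U_{load}(x) = E$ adjacent to the entry state. Peak *values* are
therefore solved from this energy level set with a root finder (machine
precision, immune to output-grid aliasing), while peak *times* are read
from the dense output grid at the first occurrence; the $t = 0$ state is
always a candidate, which is why strongly pre-stretched cases correctly
report their maximum strain energy at time zero. All response quantities
are monotone between turning points, so the per-segment extrema are
attained on the candidate set.

**Grid density.** The output grid (default 5000 samples per cycle, floor
1000) is refined automatically to at least six samples per period of the
stiffest linearized frequency inside the orbit, so that turning events
cannot slip between samples even for the fast Hariton oscillations
(thousands of radial periods per cardiac cycle).

**Tolerances.** Defaults are `rtol = 1e-11`, `atol = 1e-13`. These are
deliberately tight: over thousands of oscillation periods a non-symplectic
integrator accumulates energy drift roughly linearly, and at these
tolerances the relative drift per cardiac cycle stays below about
$10^{-7}$ (the test suite enforces $10^{-6}$) at no measurable runtime
cost with the compiled derivatives. Halving the tolerances moves reported
peaks by far less than 0.1 %.

**Initial conditions.** Nonlinear laws start from the pre-stretched ring at
its reference radius and at rest ($x = v = 0$); this choice is validated by
the tabulated cases whose peak occurs at $t = 0$ with exactly the analytic
reference-state energy. The linear model starts at $u_0 = R(\lambda_z^0-1)$.

## Reproduction scope and known discrepancies

The peak-energy tables and response spectra reproduce at the 1 % level
wherever the peak occurs during the first systolic rise or at $t = 0$ —
those peaks are set by the energy balance alone. Quantities realized late
in the cycle are different: after hundreds of oscillation periods the
*phase* at the systole–diastole switch decides how deep the diastolic
rebound swings, and that phase, while fully deterministic here (converged
across `rtol` $10^{-8}$–$10^{-11}$), is exquisitely sensitive to
integrator error. Four published Skalak cells ($\lambda_z^0 \ge 1.25$) and
two Mooney–Rivlin cells print late-cycle peaks that *exceed the analytic
upper bound* of the conservative dynamics (the reference-state energy, for
cases whose motion is inward-only); rerunning this package at loose
tolerance reproduces exactly that signature — spurious strain-energy growth
at the end of the run. The package treats the energy bound, not those
printed values, as the truth, and its table-reproduction tests assert the
bound for those cells. For the same reason the onset of inward-dominated
("reverse-flow") response with increasing pre-stretch is assessed on the
systolic-phase extremum, which flips cleanly between $\lambda_z^0 = 1.1$
and $1.15$ where the pre-stretch restoring force overtakes the systolic
pressure; the full-window extremum already flips slightly below 1.1 due to
the diastolic rebound.

The published worked examples are driven from their printed dimensionless
groups (the printed cycle ratios are normalized with $t_{cp} = 1$ s even
where the example's own cycle is 0.8 s, so the printed groups are taken as
authoritative), and dimensional peaks are recovered with the material
constant implied by the normalized systolic pressure. Skalak strain-energy
density is reported per *current* volume,
$W_{3D} = W_{2D}\lambda_\theta\lambda_z^0/H$, the convention that
reproduces the published kPa values. Residual circumferential stress in the
second example is modeled exactly as published: a constant 50 mmHg
compressive offset subtracted from both pressure levels — no opening-angle
mechanics.

## Pulse-wave helpers

The distension exponent $\alpha$ of the empirical exponential
pressure–area law $p = p_d e^{\alpha(A/A_d - 1)}$ is computed from the
systolic/diastolic circumferential stretches as
$\alpha = \ln(p_s/p_d)\,/\,[(\lambda_\theta^s/\lambda_\theta^d)^2 - 1]$.
`distension_stretches()` derives those stretches from the ring model
itself: the systolic stretch is the *midpoint of the first radial
oscillation* under a suddenly applied systolic load from rest (half the
first dynamic peak, solved from the energy balance — the quasi-static
displacement a measurement would report), and the diastolic stretch scales
that excursion by $p_d/p_s$ (small-signal proportionality). This
construction reproduces the published benchmark stretches to all printed
digits and the benchmark $\alpha$ values (2.37 / 6.59 / 8.49) within 1 %;
static-equilibrium or raw-dynamic-peak definitions do not. The ageing
trend is implemented as $\alpha = 0.42\,(1 + 0.0602\,\mathrm{age})$ — the
printed formula is ambiguous about the bracket, and this reading is the
one that spans the measured 1–8 range over a lifetime. The
axial-to-radial displacement ratio uses the thin-shell estimate
$u_z^s/u_r^s = (\nu\lambda/2\pi R)(1 - c^2/c_p^2)$.

## What the built-in conditions do and do not show

The fixture registry (`builtin_fixture()`) encodes the figure and table
parameter sets: pre-stretch grids 1–1.3, $B/C \in [0,1]$,
$b \in [2, 26]$, $\beta \in [-0.5, 0.5]$, normalized pressures 0.08–4, and
cycle-to-characteristic-time ratios 500–10000; grid resolutions inside
figure ranges are 7–11 evenly spaced points, and the peak-energy tables
carry the figure-caption time ratios (the tables do not restate them —
each fixture records this assumption in `$assumed`). These conditions probe
an idealized wall: a single homogeneous isotropic layer, purely radial
motion, no viscoelastic damping, no fluid–structure interaction or axial
wave propagation, and a square pressure wave. Passing them demonstrates the
nonlinear ring mechanics and its numerics, not the behaviour of a real
artery with layered anisotropy, perivascular tethering and damped smooth
physiological pulses; in vivo responses will be smaller and smoother than
these conservative step-response envelopes.

Problem sizes used by the test suite and the acceptance script are one to
two cardiac cycles per simulation at the default grid (adaptively up to
~$10^5$ samples for the fastest exponential-wall cases), 21-point grids per
table, and 7–15-point grids per spectrum — the full suite runs in about a
minute on one core.

## Limitations

* Viscoelastic damping is outside scope; the undamped model overshoots and
  rings indefinitely, so late-cycle quantities are phase-delicate
  (quantified above).
* The membrane (thin-wall) assumption reports mid-wall averages; published
  inner-surface stresses can differ by several percent (the second worked
  example illustrates this).
* The Mooney–Rivlin law should not be pushed to the large pre-stretches of
  the worked examples; `run_example()` warns accordingly.
* The square wave is a worst-case envelope, not a physiological waveform.
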