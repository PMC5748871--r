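# arteryring

Radial dynamics of short human artery segments modeled as incompressible
hyperelastic rings under pulsatile blood pressure.

When the heart drives a pressure pulse through an artery, each cross-section
behaves locally like a nonlinear ring oscillator: the wall stiffens (healthy
tissue), stiffens exponentially (atherosclerotic tissue) or softens
(aneurysmatic tissue) as it stretches, and the abrupt systolic pressure rise
excites radial vibrations around the quasi-static distension. `arteryring`
implements this lumped cross-section model for laboratory-scale artery
segments — the setting of dynamic cyclic inflation testing — for vascular
biomechanics researchers who need peak deformations, wall stresses,
strain-energy densities (a wall-strength criterion) and radial resonance
frequencies without a full fluid–structure simulation.

## The model

With circumferential stretch λθ = 1 + u_r/R, fixed axial pre-stretch λz0,
and incompressibility λθ·λr·λz0 = 1, radial force balance on the thin ring
gives, in dimensionless time τ = t/t_c,

    x'' = (1 + x)·p̂(τ) − g(x),        x = u_r/R,

where p̂ is the pressure normalized by the constitutive pressure scale and
g(x) is the restoring force derived from one of three strain-energy
functions:

* **Skalak membrane law** (healthy):
  W = (B/4)(I²/2 + I − II) + (C/8)·II², C ≥ B ≥ 0 — g is an exact cubic in
  x, with characteristic time t_Sk = √(ρ₀R²H/(Cλz0));
* **Hariton/Delfino exponential law** (atherosclerotic):
  W = (a/b)·[exp((b/2)(I₁−3)²) − 1], t_H = √(ρ₀R²/(aλz0));
* **Mooney–Rivlin law** (aneurysmatic):
  W = (μ/2)[(½+β)(I₁−3) + (½−β)(I₂−3)], t_MR = √(ρ₀R²/(μλz0)); bounded
  response requires p_s·R/(μH) < 1.

The pulse is a rectangular systole/diastole wave (most conservative
loading), the integrator restarts at each pressure jump, and peak values
are extracted from the exact per-phase energy balance rather than from the
sampling grid. A linearized reference model built on the initial tangent
modulus E_θ, Skalak truncation orders 0–3, response-spectrum sweeps, the
published validation examples, and pulse-wave helpers (distension exponent
α, axial/radial displacement ratio) are included. The methods vignette
(`vignettes/artery-ring-dynamics.Rmd`) derives the formulation and the
numerical choices.

## Worked example

A healthy (Skalak) ring without pre-stretch under the nominal 120/80 mmHg
pulse, normalized systolic pressure p_s·R/C = 0.16, cycle ratio
t_cp/t_Sk = 2000:

```r
library(arteryring)

gr <- ring_groups("skalak", material_ratio = 0, p_hat_s = 0.16,
                  lam_z0 = 1, time_ratio = 2000)
tr <- simulate_ring(gr)
tidy(tr)
#> # A tibble: 6 × 5
#>   quantity            peak tau_peak  t_peak lam_theta_at_peak
#>   <chr>              <dbl>    <dbl>   <dbl>             <dbl>
#> 1 x                 0.281      2.76 0.00138              1.28
#> 2 lam_theta         1.28       2.76 0.00138              1.28
#> 3 h_over_H          0.781      2.76 0.00138              1.28
#> 4 W_norm            0.0512     2.76 0.00138              1.28
#> 5 stress_theta_norm 0.410      2.76 0.00138              1.28
#> 6 stress_z_norm     0.410      2.76 0.00138              1.28
```

The sudden systolic step makes the ring overshoot to a 28 % radial
distension 1.4 ms into systole (about twice the static deflection
`glance(tr)$x_static` = 0.149), thinning the wall to 78 % of its reference
thickness; the peak normalized strain energy W/C = 0.0512 is the
wall-strength metric the response tables catalogue. `autoplot(tr)` draws
the trace; `sweep_response()` and `builtin_fixture()` generate the response
spectra, e.g. `sweep_response(builtin_fixture("table1")$conditions,
builtin_fixture("table1")$base)`.

A published validation case — a dog abdominal aorta (R = 3.46 mm,
H = 0.68 mm, λz0 = 1.53, 74.2/26 mmHg pulse) with the exponential wall
(b = 1.5, p_s·R/aH = 4.19):

```r
run_example("demiray", "hariton")$report
#>      quantity    value unit
#> 1  u_r_over_R   0.4242    -
#> 2         u_r   1.4677   mm
#> 3   lam_theta   1.4242    -
#> 4    h_over_H   0.4589    -
#> 5 sigma_theta 448.5117  kPa
#> 6     sigma_z 525.6362  kPa
#> 7           W  44.0525  kPa
```

i.e. a 42 % peak distension and a 449 kPa peak circumferential Cauchy
stress, within 0.5 % of the published 446.69 kPa for this example.

A thin command-line wrapper ships in `inst/cli/arteryring.R`
(`simulate`, `sweep`, `freq`, `tangent`, `example`, `alpha` subcommands)
over YAML run configurations (`load_run_config()`).

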