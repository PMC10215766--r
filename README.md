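# delamsim

Diffusion-based delamination models for metal–polymer interfaces in active
implantable medical devices (AIMDs).

Silicone-encapsulated implant electronics — cochlear implants are the
archetype — fail most often by fluid infiltration: ions from body fluid
diffuse slowly *through* the silicone bulk and much faster *along* the
metal–polymer interface, where they corrode the contact layer and peel the
encapsulant off (delamination). delamsim implements the transport models of
a benchtop surrogate for this failure mode — copper coated with Sylgard 184
PDMS, probed with potassium polysulfide solution whose colour reaction on
copper makes the arriving ion front visible — for engineers and biomaterials
researchers who want to fit, simulate and stress-test these kinetics outside
a finite-element environment.

## Models

* **Volume diffusion with breakthrough** — Fick's second law
  ∂c/∂t = D ∂²c/∂x² through a slab of thickness L with an infinite-source
  surface (c = c₀) and an inert metal wall; breakthrough when c(L, t)
  reaches the colour-change threshold. Crank–Nicolson on a stretched time
  grid; validated against the erfc and eigenfunction-series closed forms.
* **Stefan-type interface diffusion** — diffusion with immediate
  irreversible immobilization at S sites per unit volume; the saturation
  front obeys S·dX/dt = −Dᵢ·∂c/∂x at x = X and follows X = 2β√(Dᵢt).
  Implemented three independent ways: the exact similarity root β of
  √π·β·e^{β²}·erf(β) = c₀/S, the Goodman heat-balance-integral closure
  (quadratic profile c = a(x−X) + b(x−X)²), and a front-fixing
  finite-difference tracker (supports finite, depleting reservoirs).
* **Mechanical delamination** — anchor points released by a time-shifted
  saturating ramp as the corrosion front X = α√t arrives; the detached gap
  is a line integral over released segments and provably lags the front.
* **Interlayer corrosion transport** — solute fed along a thin interlayer;
  cells are corroded and removed, front-first, on reaching a limiting
  concentration; the detachment front advances with √t kinetics.
* **Calibration & synthetic assays** — Einstein–Smoluchowski estimation
  (D = x²/2t), through-origin least squares for X = α√t (α̂ = ΣX√t / Σt),
  R², and seeded generators emulating both laboratory assays.

The empirical closure is deliberate: the measured front coefficient
α = 0.027 mm·min^−1/2 and interface diffusivity Dᵢ fix β = α_SI/(2√Dᵢ),
and the similarity relation then calibrates the unmeasurable site density
S (and, for the interlayer model, the removal threshold c_limit). After
calibration the models must reproduce the measured kinetics — and do.

## Worked example

```r
library(delamsim)
p <- kps_sylgard_params()          # measured constants of the test system

# 1. How long until ions cross a 10 mm silicone layer?
par <- diffusion_params(p$D_volume, p$c0, p$c_threshold, L = 10e-3)
breakthrough_time(par)
#> Breakthrough at t* = 1.7813e+05 s (49.5 h)

# 2. Calibrate the Stefan model from the measured front law and track it
sp <- stefan_params(p$Di, p$c0, alpha = p$alpha)
sp
#> Moving-boundary interface-diffusion parameters
#>   Di = 1.676e-10 m^2/s, c0 = 159.9 mol/m^3, S = 4359 mol/m^3
#>   loading c0/S = 0.03669, reservoir extent l = infinite
#>   similarity front: X(t) = 2 beta sqrt(Di t), beta = 0.13462
#>   equivalent alpha = 0.027 mm/min^0.5
sol <- track_front(sp, t_end = 400 * 60, out_times = 60 * seq(5, 400, by = 5))
fit_sqrt_law(sol$trace)
#> Square-root-of-time front law fit: X = alpha * sqrt(t)
#>   alpha_hat = 0.027 mm/min^0.5
#>   R^2 = 1.0000 over 82 points

# 3. The interlayer corrosion model, same calibration
tp <- transport_params(p$Di, p$c0, alpha = p$alpha, cell_size = 5e-6)
run_interlayer(tp, length = 15e-3, t_end = 100 * 60, n_steps = 1000)
#> Interlayer corrosion run: X(100 min) = 0.27 mm (54 cells removed)
```

Reading the numbers: a 10 mm silicone layer holds the ions off for about
two days, while the interface route detaches 0.27 mm of a real specimen in
100 minutes — inside the 0.24–0.28 mm band seen experimentally, and the
reason interface transport, not bulk diffusion or mechanics, is the
failure-critical pathway. Fitting the simulated front returns exactly the
coefficient the model was calibrated to, confirming the closure is
self-consistent.

A command-line interface wrapping the same functions is installed at
`inst/cli/delamsim` (subcommands `volume`, `interface-front`,
`interface-transport`, `mechanical`, `fit`, `synth`; flat YAML/JSON
configs, CSV traces — see `inst/extdata/volume_config.yaml`).

## Package layout

* `R/` — solvers and estimators, one file per model family
* `tests/testthat/` — unit, property and end-to-end suites with
  closed-form oracles in `helper-oracles.R`
* `vignettes/diffusion-delamination.Rmd` — the methods vignette: model
  assumptions, numerical choices, calibration logic, limitations
* `scripts/acceptance.R` — headline-quantity reproduction script
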