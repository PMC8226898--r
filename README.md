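# focusurf

Continuous-wave simulation of focused ultrasound from rectangular phased
arrays in layered tissue, and fast machine-learning surrogates trained on
sweeps of those simulations.

Treatment planning for ultrasound ablation or hyperthermia needs three
numbers per candidate sonication: the maximum pressure, the maximum power
deposition, and the maximum steady-state temperature at the focal zone.
`focusurf` computes them from first principles and, because each full
simulation takes minutes, also learns them: a parameter sweep over array
element counts and focus depth produces a tabular dataset from which
regression surrogates predict the same three maxima instantly.

The pipeline:

1. **Source plane** — Rayleigh–Sommerfeld integral of the tiled rectangular
   aperture, p(r) = (iρck/2π) ∫ v_n e^{−ikR}/R dS, evaluated a quarter
   wavelength from the face, with geometric focusing phases
   φ_n = k·d_n mod 2π.
2. **Propagation** — angular-spectrum marching: each plane-wave component
   advances by H = exp(−iΔz·√(k²−kx²−ky²)) with complex k = ω/c − iα
   (power-law attenuation α₀·f^b), crosses tissue interfaces through the
   oblique-incidence transmission coefficient
   T = 2 / (ρ_A c_A cosθ_out / (ρ_B c_B cosθ_in) + 1), with zero padding and
   an angular anti-aliasing taper.
3. **Heating** — intensity I = |p|²/(2ρc), deposition Q = 2αI, and the
   steady Pennes bio-heat equation −∇·(k_t∇T) + W_bC_b(T − T_a) = Q solved
   as a sparse SPD system.
4. **Sweep + surrogates** — the Cartesian design over (X elements,
   Y elements, focus depth) → CSV dataset → 80/20 split, min–max scaling,
   and four models (linear regression, 20-leaf CART, ε-SVR, 1000-tree
   random forest) compared by RMSE, R², AIC and BIC, where both criteria
   share one Gaussian log-likelihood so that BIC − AIC = k(ln N − 2),
   k = 3.

## Worked example

The packaged fast profile (coarse grid, 0.5 MHz, couplant/skin/fat/pancreas
stack) runs one full simulation in about a second:

```r
library(focusurf)

cfg <- load_config(packaged_configs("pancreas_sweep_fast"))
sim <- simulate_scenario(cfg, nx = 32, ny = 16, focus_mm = 50)
print(sim)
#> <fus_sim> target layer: pancreas
#>   max |p| = 4.236e+06 Pa, max Q = 3.464e+07 W/m^3, max T = 368.8 degC
```

(Absolute values scale with the configured source velocity, here the
default v₀ = 1 m/s — far above a therapeutic drive; only ratios and
model comparisons are meaningful without calibration.)

Sweep the packaged 120-combination design and compare the four surrogates:

```r
spec <- sweep_spec(unlist(cfg$sweep$x_elements),
                   unlist(cfg$sweep$y_elements),
                   unlist(cfg$sweep$focus_mm))
ds <- run_sweep(spec, cfg, "fast_sweep.csv")        # ~2 minutes
report <- evaluate_models(ds, seed = 42)
print(report)
#> <fus_report> surrogate comparison (seed 42 )
#>
#>   test set (n = 24 ):
#>          model    rmse     r2     aic     bic
#>         linear 0.05861 0.9403  -62.06  -58.53
#>           cart 0.03153 0.9827  -91.82  -88.29
#>            svr 0.06372 0.9294  -58.05  -54.52
#>  random_forest 0.01313 0.9970 -133.90 -130.30
```

The random forest attains the highest R² and the lowest AIC and BIC, the
ranking the surrogate layer exists to reproduce; RMSE/R² are computed on
min–max-scaled targets. The BIC − AIC spacing is 3(ln 24 − 2) ≈ 3.53 for
every model, by construction of the shared likelihood.

The full study design is `sweep_spec()` with its defaults — 29 × 13 × 51 =
19,227 combinations — and the `pancreas_sweep` config carries the matching
full-volume grid; expect tens of hours on one core.

## Documentation

The methods vignette (`vignettes/focusurf-methods.Rmd`) describes the
propagation model and its conventions, the bio-heat solver and its boundary
conditions, what the packaged scenarios assume (and which of those
assumptions are substitutes for unpublished values), the surrogate
hyperparameters, the exact metric definitions, and the limitations of the
fast test profile.
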