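---
title: "Simulating focused-ultrasound heating in layered tissue and learning fast surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating focused-ultrasound heating in layered tissue and learning fast surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focusurf)
```

## The problem

Therapeutic focused ultrasound (tissue ablation, hyperthermia) needs a
prediction of three quantities at the focal zone before a sonication is
planned: the peak acoustic pressure, the peak volumetric power deposition,
and the peak steady-state temperature. Full-wave simulation of a phased
array through layered tissue delivers these, but at minutes-to-hours per
configuration. `focusurf` implements both halves of a practical answer:

1. a continuous-wave simulator for rectangular phased arrays radiating
   through a stack of tissue layers (couplant, skin, fat, target organ, ...),
   and
2. a surrogate-modelling layer that learns the mapping from array
   configuration to focal maxima from a sweep of such simulations, so that
   subsequent predictions are effectively instantaneous.

## The physics pipeline

### Source plane: Rayleigh–Sommerfeld integral

A planar baffled source with normal velocity $v_n$ radiates

$$p(\mathbf r) = \frac{i \rho c k}{2\pi}\int_S v_n(\mathbf r')\,
\frac{e^{-ik R}}{R}\,dS, \qquad R = |\mathbf r - \mathbf r'|,$$

with the $e^{+i\omega t}$ time factor dropped. Array elements are tiled
exactly across the aperture (element width
$(A_x - (n_x-1)\,\mathrm{kerf})/n_x$) and subdivided into rectangular
sub-sources on a midpoint quadrature with spacing $\le \lambda/4$; the
integral is evaluated by direct summation on one transverse plane a quarter
wavelength from the transducer face, far enough to avoid the surface
singularity yet still in the near field. Each quadrature cell carries a
2 × 2 tensor Gauss–Legendre point set rather than a single midpoint: at
oblique observation angles the kernel's phase turns by up to ~π/2 per
λ/4 cell, where a midpoint rule converges too slowly (halving the cell size
still moved the plane by ~3 %); the Gauss rule reaches the same halving
stability below 0.05 % at 4× the points per cell. Focusing phases are geometric:
$\varphi_n = k_{\mathrm{ref}} d_n \bmod 2\pi$, with $d_n$ the element-to-focus
distance and $k_{\mathrm{ref}}$ evaluated with the couplant sound speed
(straight-ray phasing; no refraction correction, matching common
treatment-planning practice). Excitation is uniform in amplitude — no
apodization.

The same summation evaluated at arbitrary points (`rayleigh_direct()`)
doubles as the independent reference against which the spectral propagator
is tested; quadrature convergence is itself a test (halving the sub-source
spacing moves the plane by < 0.5 %).

### Propagation: angular spectrum with attenuation and transmission

The source plane is advanced plane-by-plane along $z$. Each step applies, in
the 2-D Fourier domain, the transfer function

$$H(k_x,k_y,\Delta z) = \begin{cases}
e^{-i\Delta z\sqrt{k^2-k_x^2-k_y^2}}, & k_x^2+k_y^2 \le \operatorname{Re}(k)^2\\[2pt]
e^{-\Delta z\sqrt{k_x^2+k_y^2-\operatorname{Re}(k)^2}}, & \text{otherwise,}
\end{cases}$$

with the complex wavenumber $k = \omega/c - i\alpha$ carrying the power-law
attenuation $\alpha(f)=\alpha_0 f^b$ (converted from dB/cm to Np/m). On the
propagating branch this reduces to the exact lossless phase factor when
$\alpha = 0$; evanescent components decay on the real branch.

Where a layer interface is crossed, every plane-wave component is multiplied
by the oblique-incidence pressure transmission coefficient

$$T(\theta_{\mathrm{in}}) =
\frac{2}{\dfrac{\rho_A c_A \cos\theta_{\mathrm{out}}}{\rho_B c_B \cos\theta_{\mathrm{in}}} + 1},
\qquad \sin\theta_{\mathrm{out}} = \frac{c_B}{c_A}\sin\theta_{\mathrm{in}},$$

with $\sin\theta_{\mathrm{in}} = \sqrt{k_x^2+k_y^2}/\operatorname{Re}(k_A)$
per component. Totally reflected and evanescent components are set to zero;
reflected waves are discarded entirely (forward-only marching — standing
waves and multiple reflections are out of scope). Interfaces are snapped to
the nearest grid plane (a warning fires if the snap exceeds $\Delta z/2$).

Numerical safeguards:

* **Zero padding** (factor 2 per lateral axis by default) turns the FFT's
  circular convolution into an effectively linear one.
* **Angular taper**: a raised-cosine low-pass in $(k_x,k_y)$ removes
  components whose lateral excursion over the *remaining* propagation
  distance would exceed the padded window's wrap-around allowance
  ($L_{\mathrm{pad}}-L$ per axis; periodic images are $L_{\mathrm{pad}}$
  apart and the stored window is $L$ wide). The cutoff therefore relaxes as
  the march approaches the end of the grid. Roll-off spans the top 15 % of
  the cutoff frequency.
* **Sampling guard**: lateral spacings must satisfy
  $\Delta x, \Delta y \le \lambda/2$ in every layer, otherwise the
  propagator refuses to run.
* Grid planes before the source plane ($z < \lambda/4$) are left at zero and
  excluded from all focal metrics; they lie in the couplant.

With the default padding the field of a 16 × 4-element focused array in
homogeneous water agrees with the Rayleigh reference to ~4 % relative L2 on
a full 64 × 64 transverse plane at 30 mm depth, and doubling the padding
moves the focal region by under 1 % (both are tests). Larger padding buys
accuracy at steep angles; high-gain apertures (F-number well below 1) are
the case where the default is weakest.

### Heating: intensity, deposition, steady Pennes equation

Time-averaged intensity and power deposition follow
$I_A = |p|^2/(2\rho_0 c)$ and $Q = 2\alpha I_A$, with the local layer's
properties per $z$-plane. The steady-state temperature solves the Pennes
bio-heat equation with the time derivative set to zero,

$$-\nabla\!\cdot\!(k_t\nabla T) + W_b C_b\,(T - T_a) = Q,$$

on a 7-point finite-difference stencil, harmonic-mean conductivity at layer
interfaces, and Dirichlet $T = T_a$ on all grid boundaries — the standard
far-field closure for the steady problem, appropriate when the focus sits
at least ~10 mm inside the grid. The system is symmetric positive definite;
small grids (≤ 2·10⁴ unknowns) use a sparse Cholesky factorisation, larger
ones a Jacobi-preconditioned conjugate gradient run to a 1e-10 relative
residual (deterministic; non-convergence raises an error with the residual).
Parameter sweeps assemble the operator once (`bioheat_factor()`) and reuse
it for every right-hand side.

Against the homogeneous-medium Green's function of this operator,
$u(r) = e^{-r/L}/(4\pi k_t r)$ with perfusion length
$L = \sqrt{k_t/(W_b C_b)}$ (7.33 mm for the prostate-like property set), the
solver is accurate to < 2 % relative RMS for radii between 3 grid cells and
$2L$ — inside 3 cells the discrete point source departs from the continuum,
beyond ~$2L$–$3L$ the Dirichlet boundary departs from free space, so the
comparison band is where the analytic reference itself is valid.

The lateral width of a chosen temperature-rise contour (`contour_width()`)
is measured on the axial slice through the hottest voxel: the connected
region above the level containing the peak, edges refined by linear
interpolation between columns, maximum extent over depth. On a synthetic
Gaussian rise this reproduces the closed form
$2\sigma\sqrt{2\ln(\text{peak}/\text{level})}$ to within a grid cell.

## Scenarios and their assumptions

Two scenario families ship as YAML configs (see `packaged_configs()`); all
quantities carry units in their key names and are converted to SI at parse
time, and every run records the config's hash.

* `prostate_validation` — a 2.3 MHz endorectal array focused 40 mm deep
  through water / rectal wall / periprostate / prostate, with the published
  property table for those four media. The reference experiment behind this
  scenario reports a ~6.2 °C peak rise with a ~5.6 mm wide 4 °C contour, but
  neither its source acoustic power nor its layer thicknesses are published
  numerically. The packaged config therefore documents its thicknesses
  (15 / 4 / 5 / 56 mm) and its 45 × 22 tiling of the 990-element aperture as
  assumptions, and `validate_scenario()` is a *calibrated, semi-quantitative*
  check: the peak rise is scaled to a prescribed value (temperature rise is
  linear in $Q \propto v_0^2$), after which the contour width is a
  scale-free shape comparison, not an asserted number.
* `pancreas_sweep` / `pancreas_sweep_fast` — a 50 × 10 mm array radiating
  through couplant / skin / fat into pancreas, the geometry swept by the
  dataset generator. The skin/fat/pancreas property values are
  literature-typical choices made here (the original property table for
  this scenario is not available) and the operating frequency is a config
  key (1.0 MHz full profile, 0.5 MHz fast profile): absolute outputs depend
  on both, but the surrogate comparison is invariant to the overall scale
  because targets are min–max normalised. The full profile spans
  80 × 60 mm laterally and 90 mm in depth so that the whole 25–75 mm focal
  range stays well inside the volume.

The source velocity amplitude defaults to $v_0 = 1$ m/s; no absolute source
power is asserted anywhere. All pressures, depositions and temperatures
scale as $v_0$, $v_0^2$, $v_0^2$.

## The sweep dataset

`sweep_spec()` defaults to the full study design — X elements 16→128 step 4
(29 levels), Y elements 16→64 step 4 (13), focus 25→75 mm step 1 mm (51) —
i.e. 19,227 simulations; `enumerate_sweep()` lists them in row-major order
(focus fastest). `run_sweep()` executes the pipeline per combination,
restricted to a fixed aperture and kerf, and records per row the three
focal-zone maxima, where "focal zone" is interpreted as the entire target
tissue layer (maxima over pancreas voxels, never over skin or couplant).
Rows append incrementally, so interrupted runs resume; reruns are
deterministic and a JSON sidecar stores the config hash and grid.

The packaged *fast profile* exists so the whole pipeline runs at unit-test
scale: coarse grid (1.4 × 1.4 × 2 mm at 0.5 MHz), ~1 s per simulation, and a
120-combination subsample (2 × 2 × 30) of the design. The subsample keeps
the focus distance the densest-sampled dimension, as in the full design —
and deliberately keeps more distinct focus levels (30) than the regression
tree's 20-leaf budget. That inequality is structural in the full design
(51 levels vs 20 leaves) and is what makes a piecewise-constant tree
underfit there; a subsample that dropped below it would let the tree
memorise the focus profile and would misrepresent the study at small scale.

What the fast profile does *not* emulate: absolute magnitudes (coarser
grid, lower frequency, ~100× fewer rows), measurement noise (none — the
simulator is deterministic), and fine diffraction structure. Passing tests
on it demonstrate the pipeline's internal consistency and the qualitative
model ranking, not clinical accuracy.

## Surrogate models and metrics

Three features (X elements, Y elements, focus distance) predict three
targets (max pressure, max power deposition, max temperature). The dataset
is split 80/20 at random (test size $\lceil 0.2N\rceil$, seed recorded);
min–max scaling to $[0,1]$ is fitted **on the training split only** and
applied to features and targets, without clipping out-of-range values.

Four families are fitted with the published hyperparameters:

| model | implementation | settings |
|---|---|---|
| linear | multi-response least squares (`lm`) | — |
| CART | `rpart`, grown with `cp = 0`, cost-complexity-pruned | ≤ 20 leaf nodes |
| ε-SVR | `e1071::svm` (libsvm), RBF kernel, per target | pressure/temperature: C = 5, ε = 0.1, γ = 1/(3·Var(X)); power: C = 100, ε = 0.1, γ = 1/3 |
| random forest | `randomForest`, per target | 1000 trees, bootstrap, all 3 features per split, fixed seed |

`rpart` exposes no direct leaf-node cap, so the tree is grown out and pruned
back along its cost-complexity sequence to the smallest subtree attaining
the best error achievable within the 20-leaf budget — the CART-native
equivalent of best-first growth with a leaf cap (and robust to the
noise-level complexity values of an exactly-fit tree). Trees, SVRs and
forests are fitted once per target and their predictions stacked; the
linear model is genuinely multi-response. `grid_search_cv()` provides 5-fold
cross-validated selection over declared grids (CART leaves {5, 10, 20, 50};
SVR C {1, 5, 10, 100}, ε {0.05, 0.1, 0.2}, γ {variance rule, 1/d}; forest
sizes {100, 500, 1000}), with deterministic folds and ties broken toward
the simpler candidate.

Evaluation pools the three scaled targets: with $N$ rows,

$$\mathrm{MSE} = \frac{1}{3N}\sum_{i,j}(y_{ij}-\hat y_{ij})^2,\quad
\mathrm{RMSE}=\sqrt{\mathrm{MSE}},\quad
R^2 = 1-\frac{\sum (y-\hat y)^2}{\sum (y-\bar y)^2},$$

and the information criteria share one Gaussian log-likelihood built from
the per-row MSE,

$$\ln L = -\frac{N}{2}\left(\ln(2\pi\,\mathrm{MSE})+1\right),\qquad
\mathrm{AIC} = 2k - 2\ln L,\qquad \mathrm{BIC} = k\ln N - 2\ln L,$$

with $k = 3$ (the number of model inputs) for every family. Consequently
$\mathrm{BIC} - \mathrm{AIC} = k(\ln N - 2)$ identically: 18.76 at
$N = 3{,}846$ (the 20 % test split of 19,227) and 0.91 at $N = 10$ — exactly
the spacings the published comparison tables show, which is why this
package deliberately uses $k\ln N$ in the BIC even though the formula is
sometimes misprinted with an extra factor of 2. Metrics are computed on the
*scaled* targets; RMSE magnitudes of a few 0.001–0.1 are only meaningful in
that space.

```{r ic-example}
# BIC from a reported AIC through the shared likelihood, k = 3
bic_from_aic(-82.56, n = 10)      # external set of 10 simulations
bic_from_aic(-44164.63, n = 3846) # 20% test split of 19,227
```

## Numerical choices, in one place

* Phasor convention $e^{+i\omega t}$, forward wave $e^{-ikz}$; principal
  branch of the complex square root in $H$.
* Sub-source quadrature: 2 × 2 Gauss–Legendre per cell, cell size
  $\min(\lambda/4,$ element dimension$)$; coarser cells warn.
* FFT lattice: $k_x = 2\pi \cdot$ FFT frequency; padding centred, so wrap
  margins are symmetric.
* Bio-heat: boundary nodes couple to a ghost layer fixed at $T_a$;
  CG tolerance 1e-10 relative, error on non-convergence; direct solve below
  2·10⁴ unknowns.
* Contour width: 4-connected flood fill from the peak; level above the peak
  returns 0 with a warning; level at the peak collapses to ~0.
* Ties in `grid_search_cv()` go to the earlier (simpler) candidate; fold
  assignment and forest bootstraps derive from explicit seeds; package
  functions save and restore the caller's RNG state.
* `split_table()` uses `ceiling` for the test size: 19,227 rows → 3,846
  test / 15,381 train.

## Problem sizes used by the tests

The suite runs entirely at the fast-profile scale chosen above: 120
simulations on the 56 × 20 × 45 grid (~2 minutes), a 64 × 64 × 44 water
grid for the propagator-vs-Rayleigh comparison, a 41³ grid for the Green's
function check, and a reduced-aperture variant of the validation scenario.
These sizes are the package's own trade-off between resolution and
turnaround for routine verification; the full-volume profiles remain
available for real use.

## Known limitations

* Linear acoustics only: the stored nonlinearity parameter is never used,
  so shocked waveforms and harmonic deposition are absent by design.
* Forward-only marching: no reflections, standing waves, or shear
  conversion; transmission is purely per-plane-wave-component.
* Steady-state thermal only: no sonication-time dynamics, no thermal dose.
* Straight-ray focusing phases (no aberration correction through layers).
* The absolute output scale is arbitrary until the source velocity is
  known; only the calibrated validation workflow ties it to data.
* Frequency-independent sound speed (no dispersion); properties constant in
  temperature.
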