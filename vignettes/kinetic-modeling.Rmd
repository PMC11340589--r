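---
title: "Kinetic modeling of BCAA tracer uptake in adipose tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of BCAA tracer uptake in adipose tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batkinetics)
```

## The model

18F-fluciclovine is a synthetic L-leucine analog: it is transported into
cells by the amino-acid carriers that handle branched-chain amino acids
(BCAAs) but is not metabolized further, so over a 25-minute dynamic PET
acquisition its tissue kinetics are well described by an *irreversible*
two-tissue compartment model. Plasma tracer at concentration $C_p(t)$
exchanges with a free/interstitial compartment $C_f$ and is passed
irreversibly into a contained (intracellular) compartment $C_c$:

$$\frac{dC_f}{dt} = K_1 C_p(t) - (k_2 + k_3)\,C_f, \qquad
  \frac{dC_c}{dt} = k_3\,C_f,$$

with $C_f(0) = C_c(0) = 0$ and $k_4 = 0$ (no efflux from the contained
space). What the scanner measures in a voxel or region is

$$C_T(t) = v_b\,C_b(t) + (1 - v_b)\,\bigl(C_f(t) + C_c(t)\bigr),$$

where $v_b$ is the fractional blood volume and $C_b$ the whole-blood
concentration. The macro-parameter of interest is the net uptake rate

$$K_i = \frac{K_1 k_3}{k_2 + k_3} \quad [\mathrm{mL\,min^{-1}\,cm^{-3}}],$$

the steady-state clearance of tracer from blood into tissue. $K_i$ is the
quantity that ranks depots: supraclavicular adipose tissue (the main human
brown-fat site) above upper-chest and abdominal subcutaneous fat, and
skeletal muscle about 3-fold above supraclavicular fat per unit volume.

Key modeling assumptions, stated explicitly:

* **Input function.** The model is driven by an image-derived
  ascending-aorta curve used directly as the plasma input; by default
  $C_b \equiv C_p$ (no plasma-to-whole-blood correction). A constant
  plasma/whole-blood ratio can be supplied to `plasma_input()` /
  `feng_input()` when such a correction is warranted. No dispersion or
  delay correction is applied; delay fitting was considered and left out
  because the aorta and the depots of interest sit close together in a
  total-body field of view.
* **Decay correction.** All concentrations are assumed decay-corrected to
  injection time (the standard output of PET reconstruction), so the model
  has no physical-decay term.
* **Units.** Time is minutes internally (frame schedules are stored in
  seconds and converted on use); concentration is kBq/mL; $K_1$ and $K_i$
  are mL/min/cm$^3$ with tissue density taken as 1 g/cm$^3$ wherever mass
  units are needed.

## Numerics of the forward model

The system is linear and lower-triangular, so `solve_2tc()` does not use a
generic ODE stepper. On a uniform grid it applies an *exact exponential
update*: over one step the input is interpolated quadratically (sampled at
the step endpoints and midpoint) and the response integrals
$\int e^{-a(h-s)} s^k\,ds$ are evaluated in closed form, with series
expansions guarding the $a h \to 0$ limit against cancellation. The scheme
is unconditionally stable, exact for polynomial inputs up to degree two,
and $O(h^4)$ otherwise. At the default step of 0.5 s (one tenth of the
shortest frame) the solution agrees with a tight-tolerance `lsoda`
integration to about $10^{-9}$ relative — the test suite asserts
$< 10^{-6}$ over 20 random parameter draws.

Frame averaging integrates a cubic-spline interpolant of the fine-grid
curve over each frame (`frame_average()`), so the quadrature error is far
below the solver error even for the 5-second early frames that straddle
the bolus peak. Mid-frame timestamps, $(t_{start}+t_{end})/2$, are the
canonical time axis for all frame-wise data.

The canonical acquisition is 32 frames over 25 min:
12×5 s, 3×10 s, 3×30 s, 6×60 s, 8×120 s (`canonical_frame_schedule()`).

## Fitting

`fit_tac()` estimates $(K_1, k_2, k_3, v_b)$ by bounded nonlinear least
squares (Levenberg–Marquardt via `minpack.lm`, relative tolerance
$10^{-8}$) between measured frame values and the forward model. Choices
that were genuinely open, and how they were settled:

* **Bounds**: $K_1 \in [0,2]$ mL/min/cm$^3$, $k_2 \in [10^{-6},5]$ /min,
  $k_3 \in [0,2]$ /min, $v_b \in [0,0.3]$ — a generous physiologic
  envelope for adipose tissue and muscle; fits at a bound signal an
  unidentifiable parameter rather than a hard failure.
* **Multi-start**: the 4-parameter surface has local minima, so the
  optimizer restarts from 10 Latin-hypercube points inside the bounds
  under a fixed seed; the restart with the lowest weighted residual sum of
  squares wins, ties broken by the lexicographically smallest parameter
  vector. Identical data and options therefore give bit-identical results.
* **Weights**: uniform by default; `duration_over_value`
  ($w_i \propto \Delta t_i / C_i$, a count-statistics variance proxy) is
  available. Uniform was chosen as the default because the frame-noise
  model is itself a modeling choice and uniform weighting makes the
  objective transparent.
* $K_i$ is always reported as $K_1 k_3/(k_2+k_3)$ of the fitted
  parameters, never refit separately. In simulation $K_i$ is markedly
  better identified than $k_2$ or $k_3$ individually (its Monte-Carlo
  coefficient of variation is several-fold smaller), which is why the
  scientific conclusions are phrased in terms of $K_i$.

`patlak_estimate()` provides the independent graphical check: for an
irreversible tracer, $C_T(t)/C_p(t)$ is asymptotically linear in the
stretched time $\int_0^t C_p\,ds / C_p(t)$ with slope $(1-v_b) K_i$ (slope
$K_i$ when $v_b = 0$). The default $t^\ast = 10$ min is well past the
bolus peak within the 25-min acquisition. Patlak retains a small negative
bias (about 1% for depot-realistic parameters at $t^\ast = 10$) because
the free-compartment-to-plasma ratio keeps drifting while the input
decays; this is intrinsic to the graphical method, which is why it serves
as a cross-check rather than the estimator.

## VOI quantification

CT-based masking keeps voxels with radiodensity in the adipose window
$[-190, -30]$ HU, read as a closed interval. PET spill-over exclusion then
removes in-mask voxels above a percentile of the in-mask activity
distribution; the percentile (default 97.5) is configurable because the
underlying clinical criterion is qualitative ("exclude spill-over from
adjacent muscle"). Percentiles interpolate linearly between closest ranks,
stated explicitly for reproducibility. VOIs below 5.0 mL are rejected
unless overridden. SUV normalizes mean activity by injected dose per body
weight, $\mathrm{SUV} = \bar{C}\,[\mathrm{kBq/mL}] \big/
(\mathrm{dose}\,[\mathrm{kBq}]/\mathrm{weight}\,[\mathrm{g}])$, computed
on a single static frame from minute 4 to 14 — late enough to escape the
vascular phase, early enough to avoid the late muscle rise; the window
designation travels with every `voi_stats()` result. Masks live in
voxel-index space: registration and anatomical VOI placement are out of
scope.

## What the synthetic data emulate — and what they do not

`simulate_cohort()` and friends exist so that every pipeline stage can be
exercised against known ground truth:

* **Input function**: a Feng-type tri-exponential bolus
  ($A_1 = 851.1$ kBq/mL/min, $A_2 = 21.9$, $A_3 = 20.8$ kBq/mL,
  $\lambda = -4.13, -0.12, -0.01$ /min), zero at injection and peaking
  within the first minute, consistent with a 12×5 s early-frame design.
* **Depot priors**: independent log-normals per parameter with medians
  chosen so median $K_i$ is $\approx 0.012$ (SCV, the published anchor),
  $0.008$ (UCH), $0.005$ (ABD) and $0.036$ (muscle, the 3-fold anchor);
  spreads (log-SD 0.25–0.30) let the distributions overlap the way real
  depot data do while keeping the median ordering stable at cohort size.
  Only the two anchors are published; the rest is synthetic calibration,
  not a reproduction of patient tables.
* **Covariate structure**: BMI uniform on 20–38 (normal through obese), a
  T2D flag, and a log-linear BMI effect (default $-0.03$ per BMI unit)
  plus a multiplicative T2D effect (default 0.7) applied to the
  supraclavicular $K_1$, so $K_i$ inherits the designed negative BMI
  correlation and T2D reduction.
* **Noise**: zero-mean Gaussian per frame with
  $\mathrm{SD} = \eta \sqrt{C_i/\Delta t_i}$, variance inversely
  proportional to frame duration — a count-statistics proxy for
  frame-averaged PET concentrations; $\eta = 0.05$ is the default
  "moderate" level. Values are clipped at zero.
* **Phantoms**: rectangular tissue blocks (adipose near $-100$ HU, muscle
  near $+45$ HU, a hot blood pool) on the 2.344 mm isotropic grid with
  known per-region voxel counts.
* **qPCR**: reference-gene Ct plus gene offsets, with group fold-changes
  entering as $-\log_2(\mathrm{FC})$ cycles, so $2^{-\Delta Ct}$ carries
  the designed effects; expression is quantified relative to RPLP0 with no
  calibrator sample ($2^{-\Delta Ct}$, not $\Delta\Delta Ct$).

What passing on these data does **not** show: robustness to scanner
physics (scatter, randoms, PSF, reconstruction artifacts), to input-function
delay/dispersion, to misregistration between PET and CT, to partial-volume
effects at depot boundaries, or to non-Gaussian noise. The generators are
deterministic given a seed and always retain the generating parameters.

## Statistics

The comparison functions reproduce the analysis conventions of the
clinical study design: paired depot comparisons route by Shapiro–Wilk at
$\alpha = 0.05$ (the normality test itself was an open choice) into either
repeated-measures ANOVA with Tukey-corrected contrasts or the Friedman
test with Dunn's correction; independent groups into Welch's t /
Mann–Whitney U (two groups) or one-way ANOVA + Tukey / Kruskal–Wallis +
Dunn (three or more). Mann–Whitney p values are exact for combined
$n \le 20$ without ties. Correlations use Spearman's rho with midranks.
All tests are two-sided at $\alpha = 0.05$. Degenerate inputs (identical
depot columns) are reported as the null result rather than NaN. BMI
categories use the WHO cutoffs 25/30; BAT-volume grouping splits at 20 mL
(HBAT $\ge$ 20 mL). Whole-depot clearance scales $K_i$ by tissue volume:
100 cm$^3$ of BAT at 0.012 mL/min/cm$^3$ clears 1.2 mL plasma/min.

## Problem sizes

The shipped checks use sizes a laptop handles comfortably: 20 random
parameter draws for the ODE cross-check, a 4×4×4 truth grid for noiseless
recovery, 200 Monte-Carlo replicates at the default noise level, a
50-subject simulated cohort (200 TAC fits), and $40^3$ phantoms. These are
the package's reference conditions; all of them regenerate from seeds in
code.

## A worked example

```{r example, eval = FALSE}
input <- feng_input()
truth <- kinetic_params(K1 = 0.04, k2 = 0.35, k3 = 0.15, vb = 0.05)
y <- simulate_tac(truth, input, canonical_frame_schedule(),
                  noise_level = 0.05, seed = 7)
fit <- fit_tac(y, input)
fit$ki                       # close to macro_ki(truth) = 0.012
patlak_estimate(y, input)$slope / (1 - fit$params$vb)   # graphical check
clearance_estimate(100, fit$ki)   # whole-depot clearance, mL/min
```

## Known limitations

Reversible ($k_4 > 0$) models, spectral analysis and voxel-wise parametric
imaging are out of scope, as are image reconstruction, registration and
automatic anatomical VOI placement. The depot priors are anchored to two
published medians only; everything else about their shape is a synthetic
design choice and should not be quoted as tissue physiology.
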