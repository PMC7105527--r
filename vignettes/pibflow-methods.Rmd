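---
title: "Models and methods behind pibflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pibflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pibflow)
```

# Overview

`pibflow` quantifies four signals from a simultaneous amyloid PET/MRI
session: early-phase perfusion (PET-CBF) from dynamic [11C]PiB data,
late-phase amyloid load (SUV/SUVr), resting-state fALFF, and regional
and voxelwise group statistics. Every stage is validated against a
digital phantom with known ground truth. This vignette explains the
models, the tunable parameters and why their defaults are what they
are, the numerical choices, and what the synthetic validation does and
does not demonstrate.

# Early-phase kinetics

## Model and assumptions

During the first minutes after injection, PiB delivery is
flow-limited, so tissue activity follows the one-tissue compartment
model

$$\frac{dC}{dt} = K_1\,C_p(t) - k_2\,C(t), \qquad
C(t) = K_1 \int_0^t C_p(s)\,e^{-k_2 (t-s)}\,ds,$$

with influx $K_1$ (min^-1^), efflux $k_2$ (min^-1^) and plasma input
$C_p$ (kBq/mL). Flow follows from $K_1 = E \cdot \mathrm{CBF}/100$
with a fixed extraction fraction $E = 0.65$ and tissue density
1 g/mL, giving CBF in mL/min/100 g. The model deliberately omits a
blood-volume term and any specific amyloid binding; late-phase binding
is handled separately through SUVr. In regions with substantial
amyloid, early binding can bias $K_1$ upward — a known limitation of
one-tissue analysis of this tracer.

Assumptions worth keeping in mind:

- activity is decay-corrected to scan start (the phantom emits
  decay-corrected data directly, so no physical decay appears anywhere);
- no tracer-arrival delay between the input-function site and the
  brain, because the input is read from the same dynamic volume at the
  skull base;
- the unmetabolized (plasma-available) fraction of whole-blood
  activity is a single multiplicative constant, 0.95, over the fit
  window. It is applied as one factor; whether it represents a
  plasma-to-whole-blood ratio, a metabolite correction, or their
  product does not change the algebra at this time scale.

## Image-derived input function

The 10–40 s duration-weighted average image localizes the bolus in the
intracranial arteries; the 30 most intense voxels inside the supplied
arterial search region form the IDIF mask. Ties at the selection
cutoff are broken by ascending voxel index so the mask is
deterministic under any storage order. The mask's per-frame mean,
sampled at frame mid-times and truncated to 0–180 s, is the measured
whole-blood curve.

Peripheral measurement smears the true curve; this is modelled as
convolution with $(1/\tau)e^{-t/\tau}$, $\tau = 4$ s. The correction
inverts it to first order,
$C_\text{true}(t) = C_d(t) + \tau\,dC_d/dt$, with central differences
in the interior, one-sided differences at the endpoints, and negative
values floored at zero. On a 1 s grid the forward-then-inverse round
trip of a smooth bolus errs by well under 1% of the peak; the error is
$O(\tau\,\Delta t^2 |C'''|)$ and vanishes as the grid refines.

## The three-weighted-integral estimator

With weights $w_1 = 1$, $w_2 = t$, $w_3 = t^2$ on the fit window, the
frame-domain integrals $I_j = \sum_f w_j(t_f)\,C_f\,\Delta t_f$ have a
useful structure: $C$ is linear in $K_1$, so $I_2/I_1$ depends on
$k_2$ alone. The package tabulates that ratio over a 200-point
log-spaced $k_2$ grid (0.001–1.0 min^-1^), asserts strict
monotonicity, and inverts a measured ratio by monotone cubic
(`monoH.FC`) interpolation; $K_1$ then follows as $I_1/D_1(k_2)$ from
the unit-$K_1$ integral. The polynomial weight family is the package's
choice among several used with weighted-integral methods; the third
integral is retained purely as a consistency diagnostic (relative
deviation of the observed $I_3$ from its model prediction), not as a
third estimating equation.

Numerical conventions, chosen so the estimator is exactly consistent
with the forward model:

- the exponential convolution uses the exact one-step solution for a
  piecewise-linear input (no quadrature error beyond the interpolant);
  a piecewise-constant mode exists for step-like inputs, where the
  discrete operator is exact;
- frame averages integrate the dense curve with trapezoids and exact
  frame-boundary interpolation; the weighted integrals then use the
  mid-time rectangle rule on those frame values, and the lookup is
  built with the identical quadrature, so noise-free recovery is exact
  up to interpolation error;
- a sampled input that starts after $t = 0$ is extended with a zero
  sample at $t = 0$ (pre-arrival blood is empty);
- degenerate voxels: an all-zero series yields $K_1 = 0$ without a
  flag; a ratio outside the lookup range clamps to the grid edge and
  flags the voxel; a negative $K_1$ floors to zero and flags.

A bounded Levenberg–Marquardt least-squares fit of the same model
(`fit_nlls`) serves as the reference estimator: on noise-free curves
the two agree within 1% in $K_1$ across
$K_1 \in [0.1, 0.5]$, $k_2 \in [0.05, 0.3]$ min^-1^.

# Late-phase uptake

SUV divides late-frame activity (kBq/mL) by injected dose per body
weight (MBq/kg = kBq/g), so SUV is unitless at unit tissue density.
SUVr divides the SUV map by the cerebellar-cortex mean, making the
reference region exactly 1 and cancelling dose and weight. The
cortical SUVr mean is the unweighted mean over the eight lobar regions
(four per hemisphere); the averaging set is a configurable argument
because no single convention dominates. The GM/WM ratio divides that
cortical mean by white-matter SUVr; white matter carries a
myelin-driven signal that does not separate groups, so the ratio
sharpens the cortical contrast. Visual scores are stored as integers
0–3 (negative, slight, moderate, severe) and only enter statistics;
scoring itself is a human task.

# fALFF

After discarding the first 10 volumes, removing the per-voxel linear
trend, and optionally residualizing against user-supplied nuisance
regressors (ordinary least squares with an intercept; rank-deficient
designs are rejected), the amplitude spectrum of each voxel is the
modulus of its DFT over positive-frequency bins — a windowless,
untapered periodogram square root, the common ALFF convention. ALFF
sums amplitudes over bins with $0.01 \le f \le 0.08$ Hz (inclusive
edges, fixed for determinism); fALFF divides by the sum over all
positive bins, so it lies in [0, 1], is invariant to amplitude
scaling, and for white noise approaches the band's share of bins.
"Sum of amplitudes" rather than the band mean is used; the choice
affects the ALFF scale only, not fALFF. Zero-variance voxels get
fALFF 0 and a flag. Subject-level z-maps standardize within a mask;
slice timing, realignment, spatial normalization and motion models are
out of scope — the nuisance-regressor hook is the interface for
externally estimated confounds.

# Group statistics

Regional summaries are unweighted voxel means per parcellation label.
Atrophy-style scores use the control-referenced convention
$z = (\bar x_\text{ctl} - x)/s_\text{ctl}$, positive when the
individual lies below controls. Group tests are Welch two-sample
t-tests (variance homogeneity is not assumed; with groups of unequal
size and spread this keeps the type-I rate close to nominal), flagged
at $P < 0.05$, with a one-way ANOVA across regions per group as a
heterogeneity summary.

Voxelwise inference thresholds the Welch t-map at uncorrected
$p < 0.005$ (one-sided by default, since the contrasts of interest are
directional decreases), labels suprathreshold components under
18-connectivity (faces + edges, the convention of standard
neuroimaging cluster software), and removes components below 50
voxels. Cluster-level p-values, when requested, come from permutation
of group labels against the null distribution of the maximum cluster
size — a distribution-free replacement for random-field theory, which
would need smoothness estimates the pipeline does not compute. The
Welch-Satterthwaite p-values are exactly calibrated only
asymptotically; at 16 subjects per group the empirical suprathreshold
fraction sits within the binomial confidence band of 0.005 (verified
in the suite), while very small groups run slightly conservative.

# The phantom, and what passing tests mean

The phantom emulates the signal structure the pipeline must invert,
not brain anatomy: a block parcellation (four lobes × two hemispheres,
cerebellum, central white matter, a bright artery blob disjoint from
tissue), a gamma-variate whole-blood bolus (peak 25 s, 100 kBq/mL)
with its dispersed counterpart in the artery voxels, 1TCM tissue
curves at the control-group regional CBF operating points (right
frontal 41.6 mL/min/100 g, etc.; white matter set to 22, a typical
deep white-matter flow), efflux rates 0.06–0.12 min^-1^ within the
plausible early-phase range, SUVr seeds per group (cerebellum 1, white
matter 1.6 in both groups), and frame noise with SD
$\sigma \propto \sqrt{C/\Delta t_f}$ — the standard
reconstruction-noise approximation in which variance scales with
activity and inversely with frame duration. BOLD-like series are sums
of in-band sinusoids (snapped to the series' DFT grid so the emitted
ground truth is leakage-free) plus white noise and an optional trend,
with the per-voxel target fALFF recorded exactly in the two limiting
cases. Cohorts draw per-subject regional values from the stored group
means and SDs, with MMSE coupled negatively to cortical amyloid
(controls ≈ 29 ± 1, patients ≈ 24 ± 3) and visual scores derived by
thresholding the implied cortical SUVr.

What the phantom does **not** contain: anatomy and partial-volume
structure, scanner point-spread and attenuation effects, head motion,
physiological noise with realistic spectra, spill-over into the IDIF
mask, or specific binding in the early phase. Passing tests therefore
demonstrate that the estimators invert their own generative models at
the published operating points and tolerances — correctness of the
numerics and plumbing — not that the pipeline is robust to every
artefact of real acquisitions.

# Reproducibility and problem sizes

All randomness flows from one integer seed per phantom/config; the
end-to-end study writes a manifest with an md5 checksum of every
output, and a rerun with the same configuration reproduces every
checksum (NIfTI outputs are written uncompressed so files are
byte-stable). The test suite runs the full study at a reduced scale —
an 18×18×12 grid with 4+4 subjects and 10 permutations — and the
acceptance-style checks use the default 24×24×12 grid, cohorts of 5+5
with 25 permutations, null simulations of 10 000 voxels × 50
replicates at 16 subjects per group, and 100 random (K1, k2) draws for
the estimator-agreement property; these sizes were chosen to exercise
every code path at desk scale while keeping the suite fast.

# Known limitations

- One-tissue kinetics ignore early specific binding; in high-amyloid
  regions K1 (hence CBF) can be biased.
- The extraction fraction is fixed at 0.65; no flow-dependent
  (Renkin–Crone) extraction is modelled.
- The IDIF is taken at face value: no partial-volume or spill-over
  correction.
- The 0.95 plasma factor is constant over the fit window.
- fALFF preprocessing covers discard/detrend/regression only;
  registration and motion estimation live upstream.
- Permutation cluster inference exchanges group labels, assuming
  exchangeability under the null.
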