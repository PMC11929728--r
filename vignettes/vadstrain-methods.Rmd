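---
title: "From sonomicrometry distances to brain strain: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sonomicrometry distances to brain strain: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vadstrain)
```

## The measurement problem

In a vacuum-assisted delivery (VAD) phantom experiment, a suction cup
sealed to a fetal-head phantom applies a traction force while a
sonomicrometry system measures, at about 200.3 Hz, the distances between
three *fixed* piezoelectric crystals (F1–F3, mounted in the rigid skull
phantom) and three *brain* crystals (B1–B3, cast inside the brain
phantom). The traction force is recorded separately: by a hand-held gage
at 10 Hz in the manual setup, or by a testing machine at 1000 Hz in the
automatic setup. The quantity of interest is the one-dimensional
engineering strain of the brain material along the traction direction,
and how its peak relates to the peak force.

`vadstrain` implements the full processing chain:

1. spike removal on the raw distance traces;
2. per-pair calibration against CT-derived reference distances;
3. three-sphere trilateration to 3D brain-crystal positions over time;
4. trajectory-direction estimation and construction of a traction-force
   reference frame;
5. displacement projection, crystal-pair selection, strain computation;
6. peak detection and alignment, Pearson force–strain correlation, and
   repeatability summaries.

Because no raw recordings are publicly available, the package also ships
a synthetic-experiment generator with exact ground truth; every stage is
validated against it.

## The synthetic phantom

`generate_layout()` places three non-collinear fixed crystals at the
skull base and three brain-crystal clusters (cortical region under the
cup, ventricular, sensorimotor) whose within-region separations span
roughly 3–22 mm, the range observed in the physical phantom, plus a small
seeded placement jitter (SD 0.4 mm) emulating imprecision of casting
crystals into a mold.

`deformation_model()` drives brain crystal $b$ as

$$\mathbf{p}_b(t) = \mathbf{p}_b(0) + \big(c_\text{rigid} + c_b\big)\,F(t)\,\hat{\mathbf{d}},$$

a quasi-static affine response along a single unit direction
$\hat{\mathbf{d}}$. The shared term $c_\text{rigid}$ (default
0.012 mm/N) translates the whole brain rigidly and must produce zero
strain; differences between the per-crystal compliances $c_b$ (defaults
0.0060/0.0072/0.0048 mm/N) generate strain with the closed form

$$\varepsilon_{ij}(t) = \frac{(c_i - c_j)\,F(t)}{D_0}, \qquad
D_0 = (\mathbf{p}_i(0)-\mathbf{p}_j(0))\cdot\hat{\mathbf{d}} > 0 .$$

These defaults give peak displacements of about 1–2 mm and peak strain
magnitudes of about 1–4 % at 70–110 N, the scale observed on the physical
phantom. The load–displacement relation of the real phantom was never
measured; linearity is a deliberate modelling choice that keeps a
closed-form recovery target, not an empirical claim. No shear, rotation,
contact mechanics or fluid dynamics are modelled — consistent with the
observation that all brain crystals move essentially along the traction
direction — so passing recovery tests demonstrates correctness of the
*processing*, not realism of phantom mechanics.

The force waveform is the automatic setup's trapezoid: 0 N for 0.5 s, a
ramp at 30 N/s to the predefined peak, a plateau, a symmetric down-ramp
and a final 0.5 s at 0 N, over 10 s in total. Manual mode perturbs the
ramp rate (relative SD 10 %) and the attained peak (relative SD 2 %, the
level consistent with a force-peak relative SD below 3.5 % over repeats)
and adds a smooth low-frequency profile wobble, clipped at 0 N.

The measurement channel applies, per fixed–brain pair, a multiplicative
scale bias drawn once from (0.95, 1.05) — this is what the calibration
stage must absorb — plus Gaussian noise (SD 0.01 mm) and sporadic
additive outliers (rate 0.005 per sample, SD 5 mm). Noise defaults are
small relative to the 0.2–4 mm displacements of interest yet large
enough to exercise every filtering stage. Outliers are injected only
into measurements, never into the ground truth, and every injection is
logged so tests can count them.

## Signal conditioning

Three filters, all mask-based (no interpolation, time base preserved):

* **`mad_filter()`** removes samples more than $k$ (default 3) scaled
  median absolute deviations from the median. The scaling constant is
  the Gaussian-consistency value 1.4826, so the scaled MAD estimates the
  SD for normal data. If the scaled MAD is zero (majority of ties) only
  samples equal to the median are kept, with a warning.
* **`gaussian_smooth()`**: Gaussian-weighted moving average over a
  0.26 s window (52 samples at 200.3 Hz). The kernel SD is window/5 so
  the window covers ±2.5σ; the window length is the only documented
  constant, the σ choice is ours and is configurable.
* **`block_smooth()`**: moving average with a rectangular kernel of
  1.04 s.

Both smoothers renormalize their weights over the valid samples actually
present in each window. This avoids attenuating the trace near its ends
and across masked gaps — important because peak detection feeds on the
smoothed series, and zero-padded edges would bias peaks downward.

**Spike removal on trending traces.** Applying the global MAD rule to a
whole quasi-static trace is degenerate whenever one force level dominates
the sample distribution: for a 10 s trapezoid at 70–90 N the plateau
holds the median, the MAD collapses, and the entire rest phase —
including the calibration window — is classified as outlying. On real
recordings the MAD is inflated by noise and hand-applied force wobble,
which masks the problem; on clean synthetic data it is fatal. The
pipeline therefore applies the 3×scaled-MAD rule to residuals from a
moving-median baseline (window 0.26 s) — `despike()` — which removes
isolated spikes at the same threshold while never classifying slow
motion as outlying. `mad_filter()` remains available and tested as the
global variant for stationary series.

## Calibration and trilateration

Each pair's calibration factor is
$f = D_\text{CT} / \bar{D}_\text{sono}(t_0)$, the ratio of the
CT-derived reference distance to the measured distance averaged over the
initial rest window $t_0 = (0, 0.25)$ s; the raw trace is multiplied by
$f$. The window reducer is the mean by default (the window is documented,
the reducer is not; the median is available via configuration and is
robust to outliers that slip into the window). A per-pair
*multiplicative* channel error is absorbed exactly by this construction;
the tests assert exactly that case.

Trilateration intersects three spheres centred on the fixed crystals
(held constant throughout, as their mounting assumes) with radii equal to
the calibrated distances. In the canonical frame (centre 1 at the
origin, centre 2 on the first axis, centre 3 in the first plane) the
in-plane coordinates follow from the two-circle reduction and the
out-of-plane coordinate is $z = \pm\sqrt{h}$, $h = r_1^2 - x^2 - y^2$.
Three numerical regimes:

* $h \ge 0$: exact intersection, two mirror solutions;
* $-\text{tol}_h \le h < 0$ (default $\text{tol}_h = (3\times0.01)^2$
  mm², three noise SDs squared): spheres barely miss, $h$ clamped to 0;
* $h < -\text{tol}_h$: gross inconsistency; fall back to a BFGS
  least-squares minimization of $\sum_i (\lVert p-c_i\rVert - r_i)^2$,
  and mark the sample invalid if the RMS residual exceeds 1 mm.

The mirror ambiguity — never mentioned in typical descriptions of the
method, but unavoidable — is resolved by choosing the solution nearest
the previous valid position; the first sample uses a hemisphere rule
(by default the side of the fixed-crystal plane on which the reference
position of that crystal lies). Each recovered coordinate series is then
despiked. On noiseless synthetic data the reconstruction is exact to
better than $10^{-6}$ mm, consistent with the near-zero rest-position
errors reported for the physical experiments; under default noise the
RMS position error stays below three distance-noise SDs.

## Trajectories, force frame, projection

Per crystal and Cartesian plane, the trajectory direction is the total
least-squares line through the projected 2D scatter — the principal axis
of the centred scatter — reported as the angle to the plane's horizontal
axis (X for XY and XZ, Y for YZ), mapped to (−90°, 90°]. An
eigen-decomposition of the 2×2 scatter matrix serves as the independent
oracle in the tests.

Reconstructing a single 3D direction from three per-plane 2D angles is
overdetermined and sign-ambiguous, so the package estimates the traction
direction directly: per crystal and experiment, the 3D principal axis of
the position scatter, sign-aligned so that displacement at peak
excursion is positive along it, then averaged over crystals and
experiments and normalized. The per-plane angles are still computed and
reported for comparison with the published per-plane tables. The
averaging order (crystals within experiment vs experiments within
crystal) is not distinguishable from the published summaries; averaging
over all crystal–experiment axes jointly was chosen.

`build_force_frame()` completes the direction into a right-handed
orthonormal frame (Z′ = traction direction; X′ = initial X minus its
component along the direction, falling back to initial Y near
parallelism). Displacement is the dot product of the position change
(relative to the rest-window mean position) with the direction, then
Gaussian-smoothed.

## Pair selection and strain

Within a region, strain is computed for one crystal pair: the one whose
rest separation is best aligned with the traction direction. The default
score is the cosine alignment $|d_\text{force}| / d_\text{total}$, ties
broken by larger force-direction component, then lexicographic pair id;
pairs with a total separation under 1 mm are excluded (a baseline that
small makes engineering strain meaningless at these displacement
scales). On the published component tables this rule reproduces three of
the four documented pair choices; the ventricular region is genuinely
ambiguous in the source material (the components table and the peak
table disagree about which pair was used), so the rule is configurable
and an explicit per-region override is supported rather than guessing.

The projected separation
$D(t) = (\mathbf{p}_i(t) - \mathbf{p}_j(t))\cdot\hat{\mathbf{d}}$
(ordered so that the rest value is positive) is despiked and
Gaussian-smoothed; the rest length $D_0$ is its mean over the rest
window; the strain is

$$\varepsilon(t) = \frac{D(t) - D_0}{D_0},$$

finally smoothed with the 1.04 s block filter. Defining $D_0$ from the
*filtered* series makes the mean strain over the rest window exactly
zero by construction. Rigid translations of the whole crystal set cancel
in the difference and produce strain below $10^{-12}$; this is asserted
as an invariant.

Peaks are global extrema of the smoothed series (ties → earliest;
boundary peaks flagged with a warning — a peak at the trace edge usually
means the strain signal is noise-dominated). Alignment shifts each
series so its peak time matches the force-peak time; series are not
resampled, so the 10 Hz force gage and the 200.3 Hz sonomicrometry clock
never need a common grid. Correlation of peak force vs peak strain is
Pearson's r with the two-sided p-value from the t-distribution on n − 2
degrees of freedom (`stats::cor.test`), with a least-squares line for
plotting. Repeatability over aligned repeats reports pointwise mean/SD
profiles on the overlap region and the relative SD (SD/mean) at the
peak.

## Problem sizes and what the tests show

The test suite and the analysis scripts run entirely on synthetic data:
10 s experiments at 200.3 Hz (about 2000 samples × 9 pairs each), force
grids of 30–110 N in 20 N steps, four repeats for repeatability, 1000
random geometries for the trilateration oracle check, and a 3×3
compliance–force grid for strain recovery. These sizes were chosen so
the whole suite completes in about a minute while every property has
enough data to be meaningful.

Passing them shows that the *pipeline implementation* is correct: exact
recovery without noise, graceful degradation with it, and agreement with
published worked examples wherever the source tables print both inputs
and outputs (pair-component norms, all-sets angle aggregation, pair
selection). It does not validate phantom mechanics: the generator is
affine, uniaxial and stationary, while real brain phantoms creep, have
heterogeneous moduli, and deform triaxially. The published strain-peak
repeatability (relative SDs of 26–61 %) is far worse than the synthetic
one, indicating real-world variability sources (cup–skull interaction,
material memory, 1D projection of 3D motion) that the generator
deliberately does not emulate.

## Known limitations

* 1D engineering strain along one direction only; no strain tensor, no
  large-deformation formulation. Ventricular-style geometries, where
  displacements approach 30 % of the inter-crystal baseline, sit at the
  edge of small-strain validity — the minimum-separation guard and the
  pair override exist for exactly that case, and the synthetic
  ventricular cluster indeed produces a compressive projected strain.
* Fixed crystals are assumed perfectly static; skull deformation would
  bias all positions.
* The force and distance streams are synchronized only by peak
  alignment, mirroring the original acquisition, so sub-second timing
  offsets between force and strain are not resolvable.
* The least-squares trilateration fallback returns a point estimate
  without uncertainty; samples are either valid or masked.
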