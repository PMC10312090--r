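---
title: "Three-pool T2 relaxometry with cswater: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-pool T2 relaxometry with cswater}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cswater)
```

## The measurement model

Water in healthy brain tissue relaxes with three distinguishable T2
populations: water trapped in myelin sheaths (T2 around 10 ms), axonal and
interstitial ("intra/extra-cellular") water (around 70 ms), and free or
quasi-free CSF-like water (around 2 s). A multi-echo acquisition that
samples the decay — here a six-point schedule at nominal preparation times
0, 7.5, 17.5, 67.5, 147.5 and 307.5 ms (`defaultEchoTimes()`), with the
first point acquired with the T2 preparation off and treated as exactly
TE = 0 — supports a three-pool decomposition per voxel:

$$S(TE) = A_{MW} e^{-TE/T2_{MW}} + A_{IEW} e^{-TE/T2_{IEW}}
        + A_{CSF} e^{-TE/T2_{CSF}}.$$

Water exchange between compartments and compartmental T1 weighting are
deliberately not modelled, following standard practice in multi-exponential
brain T2 mapping. The water fractions MWF, IEWF and CSFF are the amplitude
ratios against the total `A_MW + A_IEW + A_CSF`; they sum to 1 by
construction, so only relative water content is measured.

With six echoes and six free parameters the fit is exactly determined.
Identifiability therefore rests on the box constraints — T2 bounds
[5, 20], [20, 200] and [200, 2000] ms per pool — and on a deterministic,
physiologically informed initialization: T2 starts at (10 ms, log-linear
estimate, 2000 ms), where the middle pool's start is an ordinary
least-squares fit of log-signal against TE over the first four echoes
(clamped to [20, 200] ms; a flat signal clamps to the upper bound as a
formally infinite T2, while rising or nonpositive signals take a 70 ms
fallback); amplitudes start at 10% and 90% of the first-echo signal and
the last-echo signal. Per-voxel residual norms are returned in a quality
map precisely so that non-uniqueness or poor fits are visible downstream.

## Numerical choices in the fit

The bounded least-squares problem is solved by L-BFGS-B with an analytic
gradient. T2 values are optimized in log space, which conditions the
problem across three decades of relaxation times; amplitudes carry a plain
nonnegativity bound. Convergence tolerances are `factr = 1e2`,
`pgtol = 1e-10`, at most 500 iterations; a line search that stalls once
the objective reaches the numerical floor (below `1e-12` times the signal
energy) is counted as converged. There are no random restarts: by default
each voxel is fit from the standard initialization plus two fixed
alternates (`nStarts = 3` in `fitConfig()`), and the lowest final
objective wins with ties resolved in initialization order, keeping the
whole fit a pure function of its inputs. On noiseless synthetic voxels
with well-separated pools this recovers water fractions within 0.02 in
well over 95% of cases.

### Spatial regularization

`fitVolume()` optionally couples voxels through a discrete-Laplacian
penalty on the parameter maps (all six by default), computed on the
6-neighborhood with weights $1/h^2$ from the physical voxel spacing, on
the optimizer's own scale (amplitudes normalized by the volume's mean
first-echo signal, T2s in log ms) so that the weight `lambda` is
dimensionless. Minimization is by Gauss-Seidel sweeps that refit each
voxel with its neighbors frozen — a desk-scale stand-in for a joint
multi-voxel solve that reproduces its smoothing behavior. On a
piecewise-constant phantom with moderate noise, `lambda = 0.5` with one
sweep reduces the CSFF map error (it roughly halves the voxelwise sd);
the package default is `lambda = 0`, the independent per-voxel fit, which
is also the reference configuration for every oracle test.

Two caveats are worth stating plainly. First, the penalty is invariant to
constant shifts of a parameter map, so smoothing reduces variance but
cannot correct any spatially uniform bias. Second, the calibrated weight
is an L-curve-style compromise on the default phantom; real data with
different SNR or structure may want a different value, and `lambda = 0`
is always a valid fallback.

## Magnitude noise: model, estimation, correction

Sum-of-squares combination of $n$ receive channels turns complex Gaussian
channel noise into non-central chi magnitude noise with $2n$ degrees of
freedom. The simulator places the full true signal on one channel's real
part — any split with the same noncentrality is equivalent in
distribution, which the moment tests pin down — and draws
$M = \sigma\sqrt{X}$ with $X \sim \chi^2_{2n}(A^2/\sigma^2)$.

The noise sd is estimated from background air on the two edge slices of
the last echo (where anatomical signal is weakest), through the central
chi mean $E[M \mid A{=}0] = \sigma\sqrt{2}\,\Gamma(n+\tfrac12)/\Gamma(n)$.
Bias correction inverts the exact first moment: a strictly increasing
lookup table of $m = E[M \mid A]$ on 2000 grid points over
$A/\sigma \in [0, 50]$, evaluated by a truncated Poisson-mixture series
(numerically exact where naive quadrature underflows), inverted by
monotone piecewise-cubic interpolation. Measured magnitudes at or below
the noise floor $m(0)$ map to zero — amplitudes are physically
nonnegative — and values beyond the table use the asymptote
$A = \sqrt{m^2 - (2n-1)\sigma^2}$.

A single scalar sigma is used for the whole volume, matching the single
background estimate; no spatially varying noise maps are attempted.

What this correction can and cannot do: applied to the *expected*
magnitude it is exact at every SNR by construction, and applied pointwise
it strictly reduces the mean bias at every tested SNR and coil count. But
with many coils the noise floor itself sits at several sigma (about
$8\sigma$ at 32 coils), and for true amplitudes below or near that floor
a pointwise monotone nonnegative map cannot make the mean of corrected
draws unbiased — Jensen curvature and the clamp at zero leave a residual
relative bias of several percent at $A \approx 3{-}5\sigma$ that no
implementation of this correction class removes. The same mechanism,
propagated through the nonlinear fit, leaves a small positive CSFF offset
(about +0.02 at first-echo SNR 100 with 32 coils on the default phantom)
that spatial smoothing reduces in variance but, being a DC effect, not in
mean. Users comparing groups at matched acquisition settings are
unaffected; absolute CSFF levels at low SNR should be read with this in
mind.

## ROI erosion and the distance criterion

Partial-volume mixing with ventricular and subarachnoid CSF inflates
regional CSFF estimates near tissue-CSF interfaces. The analysis ROIs
(cerebral WM, cortex, deep GM — the latter defined as cerebral GM minus
cortex) are therefore eroded in two stages: a 1 mm isotropic erosion of
each ROI, then removal of every voxel whose distance to any CSF-labelled
voxel fails the anisotropic criterion of at least 1 mm in-plane and 5 mm
through-plane, combined as the ellipsoidal norm
$(d_x/1)^2 + (d_y/1)^2 + (d_z/5)^2 > 1$ (values chosen to match the
1.3 x 1.3 x 5 mm acquisition voxel).

"Distance" is not self-defining on a voxel grid, so the semantics are
explicit and test-pinned: distances are physical (mm), computed
center-to-center by default through an exact separable lower-envelope
distance transform (verified voxel-for-voxel against brute force); a
boundary-to-boundary mode (subtracting half-voxel extents, brute-force) is
available. The stage-1 erosion removes voxels whose center lies within
1 mm of the ROI's boundary surface, which with 1.3 mm in-plane voxels
removes exactly the in-plane boundary layer and no additional
through-plane layers. A voxel whose center sits exactly at the limit
(e.g. one 5 mm slice from a ventricle voxel) is removed, since its
*boundary* distance is necessarily smaller. The progressive-erosion sweep
(`erosionSweep()`, through-plane minima 1/3/5/7 mm) is meaningful on the
1 mm isotropic segmentation grid that ROI masks live on; on the coarse
5 mm acquisition grid several of those levels coincide.

An optional lesion mask can exclude WM hyperintensities from the WM ROI;
it defaults to off, as the exclusion has negligible effect on regional
means in practice.

## The synthetic cohort and what passing tests mean

The phantom generator builds a concentric six-label geometry (background,
WM shell, cortical ribbon, deep GM, central ventricles, outer
subarachnoid rim) with seed-controlled boundary jitter, anisotropic
1.3 x 1.3 x 5 mm voxels by default, and per-tissue three-pool ground
truth (`defaultTissueTruth()`: e.g. WM 11% / 84% / 5% at T2 = 10 / 60 /
2000 ms; pure CSF in the ventricles and subarachnoid space).

The cohort simulator emulates the statistical structure the analysis is
designed to detect, on the fraction scale: per-(ROI, outcome) age trends
(inverted-U MWF in all ROIs peaking near age 45; IEWF declining about
0.7 percentage points over the adult range in WM and 1.6 in cortex; CSFF
rising linearly in WM and deep GM and following a U-shaped quadratic in
cortex around a 4% level), a small additive sex effect, ROI volumes
declining with age, Gaussian residuals of about 1 percentage point, and
ages uniform on 22-80 years with n = 60 — magnitudes chosen once to match
the levels, trend sizes and scatter the analysis context reports, and
kept fixed. Rows are clipped to [0, 1] (warning if more than 1% of rows
clip) and renormalized to exact unit sum.

What the simulator does *not* emulate: spiral k-space acquisition and
Gibbs ringing (inputs are assumed pre-corrected; the pipeline records
that assumption), B1/flip-angle effects, T1 weighting, exchange,
within-ROI heterogeneity beyond the optional smooth modulation field, and
any registration error (labels arrive aligned). Passing tests therefore
demonstrate correctness of the estimators under the stated noise and
decay model — not robustness to acquisition artifacts absent from the
model.

## Statistics

For each of the nine (ROI x water fraction) outcomes, two nested OLS
models are fit: linear, `WF = b0 + b1 Age + b2 Sex + b3 Volume`, and
quadratic with an added `Age^2` term. The quadratic model is kept only if
the nested-model ANOVA F-test rejects at alpha = 0.05; under a true
linear model this selects the quadratic in 5% of replicates (calibration
verified by simulation at n = 60 over 2000 replicates), and under the
default cortical-CSFF curvature it selects the quadratic in well over 80%.
If both models interpolate the data exactly (zero residuals), parsimony
keeps the linear model; if only the quadratic is exact, F is formally
infinite and the quadratic is selected.

The "age p-value" entering the FDR family is the ANOVA p of the Age-squared
term when the quadratic model is selected and the Wald p of the age
coefficient otherwise; since the choice among the three candidate
quadratic-model p-values (Age Wald, Age-squared Wald, ANOVA) is a
convention, all are reported side by side in `ageAssociationReport()`.
The FDR family is exactly the nine selected p-values, adjusted by
Benjamini-Hochberg. Sex is coded 0/1 with female reference, affecting
only intercept interpretation. ROI volume enters as the uneroded,
skull-normalized volume, accepted as an external input
(`normalizeVolume()` is a guarded product; the normalization factor's
provenance is out of scope). Repeatability uses Bland-Altman bias and
1.96-sd limits of agreement; the ventricle-volume/CSFF association uses
Spearman correlation implemented as Pearson on average ranks with a
two-sided t approximation. Fractions are reported at the 1-decimal
percent convention in formatted output only; all internal computation is
full precision.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: phantoms of 16^3 to 32^3 voxels, single-voxel fits in
the hundreds, Monte-Carlo noise checks at 1e5 draws per condition, and
2000-replicate selection calibrations — sizes at which every oracle
(brute-force distance transforms, closed-form moments, normal-equation
solves) can be evaluated exactly alongside the implementation.

## Known limitations

- Absolute water content is not measured; all fractions are relative, so
  a change in one compartment moves the others through the denominator
  (see `compartmentShift()` for the arithmetic).
- The last echo near 300 ms gives limited leverage on the CSF T2 itself;
  CSFF is robust, the fitted T2_CSF value much less so.
- Low-SNR amplitude estimation retains a small positive CSFF bias after
  magnitude correction (quantified above); comparisons should hold
  acquisition settings fixed.
- The Gauss-Seidel spatial solver approximates, not implements, a joint
  multi-voxel optimization.
- No continuous-T2-spectrum (regularized NNLS) variant is provided; the
  three-pool decomposition is the model, not an approximation of a
  spectrum fit.
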