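# cswater

Multi-compartment T2 relaxometry of the brain for R: from multi-echo
magnitude MRI volumes to voxelwise water-fraction maps, eroded-ROI regional
summaries, and age-association statistics — together with a digital phantom
and cohort simulator so that every stage of the analysis can be verified
end-to-end without any scanner data.

The package is aimed at quantitative-MRI researchers studying brain water
compartments across the adult lifespan: the parenchymal cerebrospinal-fluid
fraction (CSFF) is a candidate marker of microscopic perivascular/CSF space
dilation, the myelin water fraction (MWF) of myelin integrity, and the
intra/extra-cellular water fraction (IEWF) of the tissue water bulk.

## The model

Each voxel's multi-echo magnitude signal is modelled as a three-pool
exponential decay

    S(TE) = A_MW  exp(-TE / T2_MW)
          + A_IEW exp(-TE / T2_IEW)
          + A_CSF exp(-TE / T2_CSF)

with amplitudes `A_i >= 0` and pool T2 values box-constrained to
[5, 20] ms (myelin water), [20, 200] ms (intra/extra-cellular water) and
[200, 2000] ms (CSF). The fit is a bounded non-linear least-squares
solution per voxel (L-BFGS-B, T2s optimized in log space, deterministic
initialization: T2 = 10 / log-linear estimate / 2000 ms, amplitudes = 10% /
90% of the first-echo signal / last-echo signal), optionally coupled across
voxels by a discrete-Laplacian smoothness penalty on the parameter maps.
Water fractions are the amplitude ratios `WF_i = A_i / (A_MW + A_IEW +
A_CSF)`, so MWF + IEWF + CSFF = 1.

Before fitting, the non-central chi noise bias of sum-of-squares
coil-combined magnitudes is removed: the per-channel noise sd is estimated
from background air on the edge slices of the last echo via the central-chi
mean identity, and measured magnitudes are mapped through an invertible
lookup table of the exact nc-chi first moment `m = E[M | A, sigma, n]`.

Regional means are taken over conservatively eroded ROIs (cerebral WM,
cortex, deep GM): a 1 mm isotropic erosion followed by removal of voxels
closer than 1 mm in-plane or 5 mm through-plane to ventricular or
subarachnoid CSF, combined as the ellipsoidal criterion
`(dx/1)^2 + (dy/1)^2 + (dz/5)^2 > 1` on an exact anisotropic distance
transform. Age associations use nested OLS models per (ROI, water
fraction) outcome — linear `WF = b0 + b1 Age + b2 Sex + b3 Volume` versus
quadratic with an added `Age^2` term — selected by the ANOVA F-test and
FDR-adjusted (Benjamini-Hochberg) across the nine outcomes.

## Worked example

A complete phantom run — simulate, corrupt with 32-coil nc-chi noise at
SNR 100, re-estimate the noise, correct, fit, erode, summarize:

```r
library(cswater)

labels <- buildLabelVolume(c(32, 32, 16), voxelSize = c(1.3, 1.3, 5), seed = 7)
truth  <- defaultTissueTruth(s0 = 1000)
clean  <- forwardSignal(truth, labels)
noisy  <- addNcChiNoise(clean, NoiseModel(sigma = 10, nCoils = 32), seed = 7)

bg    <- array(labelData(labels) == 0, dim(labelData(labels)))
noise <- estimateSigma(noisy, bg, nCoils = 32)
noise
#> NoiseModel: sigma = 9.974836 , nCoils = 32

corrected <- correctMagnitude(noisy, buildCorrectionTable(noise))
tissue    <- array(labelData(labels) %in% 1:3, dim(labelData(labels)))
fit       <- fitVolume(corrected, tissue)
rois      <- erodeRois(labels, erosionSpec())
regionalMeans(fit$wf, rois)
#>      roi n_voxels        mwf      iewf       csff
#> 1     wm      920 0.12033103 0.8059288 0.07374022
#> 2 cortex       39 0.03902419 0.8910292 0.06994665
#> 3 deepgm      135 0.04907710 0.8551681 0.09575482
```

The estimated sigma recovers the simulated value (10) within 0.3%. The
regional means sit close to the generated tissue composition (WM truth:
MWF 0.11, IEWF 0.84, CSFF 0.05); the residual upward CSFF offset at this
noise level is the small-amplitude estimation bias discussed in the
methods vignette, and shrinks as SNR rises or vanishes for noiseless
input.

The interpretation helpers reproduce standard compartment arithmetic: a
cortical CSFF of 4.0% in tissue of 0.83 g/mL water content corresponds to
a CSF volume fraction of

```r
csffToVcsf(0.040, 0.83, percent = TRUE)
#> [1] 3.3
```

and a loss of intra/extra-cellular water from 0.90 to 0.76 g/mL in a
(0.05, 0.90, 0.05) g/mL voxel shifts the fractions by

```r
compartmentShift(c(0.05, 0.90, 0.05), 0.76)
#>   deltaMwf deltaIewf deltaCsff
#>  0.8139535 -1.6279070 0.8139535
```

percentage points. A one-command version of the whole chain (plus cohort
statistics) is `runPipeline(pipelineConfig(seed = 1, outDir = "out"))`, or
from a shell: `Rscript inst/scripts/cswater.R run --seed 1 --out out`.

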