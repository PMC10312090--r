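## Digital phantom and cohort simulator: the ground-truth generator every
## downstream stage is verified against.

#' Build a concentric six-label head phantom
#'
#' Deterministically generates a 3D label volume with a central ventricle
#' region (label 4) surrounded by deep GM (3), a WM shell (1), a cortical
#' ribbon (2), an outer subarachnoid CSF rim (5) and background (0). The
#' shells follow an ellipsoidal radius normalized to the grid half-extents,
#' with a small seed-controlled angular jitter of the shell boundaries so
#' that repeated builds with different seeds give different (but valid)
#' geometries.
#'
#' @param shape integer(3) grid size, at least (16, 16, 8).
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @param seed integer seed controlling the boundary jitter.
#' @return a \linkS4class{LabelVolume} containing every label at least once.
#' @examples
#' lv <- buildLabelVolume(c(32, 32, 16), c(1.3, 1.3, 5), seed = 7)
#' table(labelData(lv))
#' @export
buildLabelVolume <- function(shape = c(32L, 32L, 16L),
                             voxelSize = defaultVoxelSize(),
                             seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(16L, 16L, 8L)))
    stop("shape must be >= (16, 16, 8): too small to host all six labels")
  if (length(voxelSize) != 3L || any(voxelSize <= 0))
    stop("voxelSize must be 3 strictly positive values")

  half <- (shape - 1) / 2
  i <- (seq_len(shape[1L]) - 1 - half[1L]) / half[1L]
  j <- (seq_len(shape[2L]) - 1 - half[2L]) / half[2L]
  k <- (seq_len(shape[3L]) - 1 - half[3L]) / half[3L]
  gi <- array(i, shape)
  gj <- array(rep(j, each = shape[1L]), shape)
  gk <- array(rep(k, each = shape[1L] * shape[2L]), shape)
  r <- sqrt(gi^2 + gj^2 + gk^2)

  ## Angular jitter: low-order spherical harmonics with seed-drawn phases,
  ## amplitude kept small so shell ordering (and 4/5 non-adjacency) is safe.
  ph <- withSeed(seed, runif(3L, 0, 2 * pi))
  theta <- atan2(gj, gi)
  jit <- 0.015 * (sin(2 * theta + ph[1L]) + sin(3 * theta + ph[2L]) +
                  gk * sin(theta + ph[3L]))
  r <- r + jit

  lab <- array(0L, shape)
  lab[r < 0.95] <- .LABELS[["subarachnoid"]]
  lab[r < 0.85] <- .LABELS[["cortex"]]
  lab[r < 0.70] <- .LABELS[["wm"]]
  lab[r < 0.45] <- .LABELS[["deepgm"]]
  lab[r < 0.25] <- .LABELS[["ventricles"]]

  missing <- setdiff(.LABELS, unique(as.vector(lab)))
  if (length(missing))
    stop("shape too small to host all six labels (missing: ",
         paste(missing, collapse = ", "), ")")
  LabelVolume(lab, voxelSize)
}

#' Default per-tissue three-pool ground truth
#'
#' Nominal pool amplitudes and T2 values per tissue label. T2 values follow
#' the three-pool convention (myelin water ~10 ms, intra/extra-cellular
#' water ~70 ms, CSF ~2 s); amplitudes are fractions of \code{s0} chosen to
#' give WM/cortex/deep GM water-fraction compositions typical of healthy
#' adult brain, and pure CSF in the ventricles and subarachnoid space.
#'
#' @param s0 total signal amplitude at TE = 0 in tissue voxels.
#' @return a \linkS4class{TissueTruth}.
#' @export
defaultTissueTruth <- function(s0 = 1000) {
  pools <- data.frame(
    label = c(1L, 2L, 3L, 4L, 5L),
    aMW   = s0 * c(0.11, 0.035, 0.045, 0,    0),
    aIEW  = s0 * c(0.84, 0.925, 0.905, 0,    0),
    aCSF  = s0 * c(0.05, 0.040, 0.050, 1,    1),
    t2MW  =      c(10,   10,    10,    10,   10),
    t2IEW =      c(60,   80,    75,    70,   70),
    t2CSF =      c(2000, 2000,  2000,  2000, 2000))
  new("TissueTruth", pools = pools, modulation = NULL)
}

#' Construct a TissueTruth from a pools table
#'
#' @param pools data.frame with columns label, aMW, aIEW, aCSF, t2MW,
#'   t2IEW, t2CSF.
#' @param modulation optional positive 3D array multiplying all amplitudes.
#' @return a \linkS4class{TissueTruth}.
#' @export
TissueTruth <- function(pools, modulation = NULL) {
  new("TissueTruth", pools = pools, modulation = modulation)
}

#' Noiseless three-pool forward signal
#'
#' Evaluates S(TE) = A_MW exp(-TE/T2_MW) + A_IEW exp(-TE/T2_IEW) +
#' A_CSF exp(-TE/T2_CSF) for every voxel of a label volume, using the
#' per-label ground truth. Background voxels are 0; S(0) equals the
#' amplitude sum. Water exchange and compartmental T1 weighting are not
#' modelled.
#'
#' @param truth a \linkS4class{TissueTruth}.
#' @param labels a \linkS4class{LabelVolume}.
#' @param teMs echo schedule in ms, ascending, first >= 0.
#' @return a noiseless \linkS4class{EchoVolume}.
#' @export
forwardSignal <- function(truth, labels, teMs = defaultEchoTimes()) {
  stopifnot(is(truth, "TissueTruth"), is(labels, "LabelVolume"))
  validObject(truth)
  teMs <- as.numeric(teMs)
  if (teMs[1L] < 0 || any(diff(teMs) <= 0))
    stop("teMs must be ascending with first entry >= 0")
  p <- truth@pools
  if (any(p[, c("aMW", "aIEW", "aCSF")] < 0))
    stop("negative amplitude in truth")
  if (any(p[, c("t2MW", "t2IEW", "t2CSF")] <= 0))
    stop("nonpositive T2 in truth")

  lab <- labels@labels
  d <- dim(lab)
  out <- array(0, c(d, length(teMs)))
  for (row in seq_len(nrow(p))) {
    sel <- lab == p$label[row]
    if (!any(sel)) next
    decay <- p$aMW[row]  * exp(-teMs / p$t2MW[row]) +
             p$aIEW[row] * exp(-teMs / p$t2IEW[row]) +
             p$aCSF[row] * exp(-teMs / p$t2CSF[row])
    for (e in seq_along(teMs)) {
      slab <- out[, , , e, drop = FALSE]
      slab[sel] <- decay[e]
      out[, , , e] <- slab
    }
  }
  if (!is.null(truth@modulation)) {
    if (!identical(dim(truth@modulation), d))
      stop("modulation field dimensions must match the label volume")
    out <- out * as.vector(truth@modulation)
  }
  EchoVolume(out, labels@voxelSize, teMs)
}

#' Add non-central chi magnitude noise
#'
#' Emulates sum-of-squares combination of \code{nCoils} receive channels:
#' each voxel/echo magnitude A is replaced by
#' sqrt(sum_k (x_k^2 + y_k^2)) with all 2*nCoils Gaussian components having
#' sd sigma and the full true signal placed on one channel's real part
#' (equivalent in distribution to any split with the same noncentrality).
#' Draws are sigma * sqrt(X) with X ~ noncentral chi-square(2 nCoils,
#' (A/sigma)^2). sigma = 0 returns the input unchanged.
#'
#' @param clean an \linkS4class{EchoVolume} of true amplitudes.
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed integer seed; the draw is a pure function of (clean, noise,
#'   seed).
#' @return a noisy \linkS4class{EchoVolume}.
#' @export
addNcChiNoise <- function(clean, noise, seed = 1L) {
  stopifnot(is(clean, "EchoVolume"), is(noise, "NoiseModel"))
  validObject(noise)
  if (noise@sigma == 0) return(clean)
  a <- clean@data
  ncp <- (as.vector(a) / noise@sigma)^2
  draws <- withSeed(seed,
    noise@sigma * sqrt(stats::rchisq(length(ncp), df = 2 * noise@nCoils,
                                     ncp = ncp)))
  EchoVolume(array(draws, dim(a)), clean@voxelSize, clean@teMs)
}

#' Cohort specification for the regional-table simulator
#'
#' Describes a synthetic cross-sectional cohort: per-(ROI, water fraction)
#' age trends (raw polynomial coefficients b0 + b1*age + b2*age^2 on the
#' fraction scale), residual sds, an additive sex effect, and a per-ROI
#' normalized-volume model. Defaults emulate the age patterns the analysis
#' is designed to detect: an inverted-U MWF trend in all ROIs, linearly
#' declining IEWF, linearly rising CSFF in WM and deep GM and a U-shaped
#' (quadratic) CSFF trend in the cortex.
#'
#' @param nSubjects number of subjects (>= 4).
#' @param ageRange numeric(2) in years (default 22-80).
#' @param trends data.frame with columns roi, wf, b0, b1, b2.
#' @param residualSd data.frame with columns roi, wf, sd (>= 0).
#' @param sexEffect additive shift (fraction units) for sex == 1, applied to
#'   every outcome.
#' @param volumeCoef coefficient of the (centered) normalized ROI volume in
#'   each outcome.
#' @param volumeModel data.frame with columns roi, v0, v1, v2, sd giving the
#'   normalized-volume age polynomial and its residual sd.
#' @param seed integer seed.
#' @return a list of class \code{cohortSpec}.
#' @export
cohortSpec <- function(nSubjects = 60L,
                       ageRange = c(22, 80),
                       trends = defaultCohortTrends(),
                       residualSd = defaultResidualSd(),
                       sexEffect = 0.002,
                       volumeCoef = 0,
                       volumeModel = defaultVolumeModel(),
                       seed = 1L) {
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 4L) stop("nSubjects must be >= 4")
  if (any(residualSd$sd < 0)) stop("residual sds must be >= 0")
  if (ageRange[1L] < 18 || ageRange[2L] > 100 || diff(ageRange) <= 0)
    stop("ageRange must be an increasing interval within adulthood")
  structure(list(nSubjects = nSubjects, ageRange = as.numeric(ageRange),
                 trends = trends, residualSd = residualSd,
                 sexEffect = sexEffect, volumeCoef = volumeCoef,
                 volumeModel = volumeModel, seed = as.integer(seed)),
            class = "cohortSpec")
}

## Trend defaults are written in vertex form c + q*(age - v)^2 (or slope
## form) and expanded to raw polynomial coefficients.
.vertexQuad <- function(c0, q, v) c(b0 = c0 + q * v^2, b1 = -2 * q * v, b2 = q)
.linTrend  <- function(c0, s, v) c(b0 = c0 - s * v, b1 = s, b2 = 0)

#' Default age trends for the nine regional water-fraction outcomes
#'
#' @return data.frame with columns roi, wf, b0, b1, b2 (fraction units,
#'   age in years).
#' @export
defaultCohortTrends <- function() {
  rows <- list(
    c(list(roi = "wm",     wf = "mwf"),  as.list(.vertexQuad(0.112, -1.2e-5, 45))),
    c(list(roi = "wm",     wf = "iewf"), as.list(.linTrend(0.845, -1.2e-4, 50))),
    c(list(roi = "wm",     wf = "csff"), as.list(.linTrend(0.050,  1.2e-4, 40))),
    c(list(roi = "cortex", wf = "mwf"),  as.list(.vertexQuad(0.036, -8e-6, 45))),
    c(list(roi = "cortex", wf = "iewf"), as.list(.linTrend(0.920, -2.7e-4, 50))),
    c(list(roi = "cortex", wf = "csff"), as.list(.vertexQuad(0.040,  2.0e-5, 45))),
    c(list(roi = "deepgm", wf = "mwf"),  as.list(.vertexQuad(0.046, -8e-6, 45))),
    c(list(roi = "deepgm", wf = "iewf"), as.list(.vertexQuad(0.905, -1.5e-5, 40))),
    c(list(roi = "deepgm", wf = "csff"), as.list(.linTrend(0.050,  1.3e-4, 50))))
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Default residual standard deviations per outcome
#'
#' Cross-subject scatter around the age trend, on the fraction scale.
#'
#' @return data.frame with columns roi, wf, sd.
#' @export
defaultResidualSd <- function() {
  g <- expand.grid(roi = .TISSUE_ROIS, wf = .WF_NAMES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$sd <- ifelse(g$wf == "mwf", 0.008, 0.010)
  g
}

#' Default normalized-volume age model per ROI
#'
#' Normalized (skull-scaled) ROI volumes in mL: gently declining WM/deep GM
#' and cortex volumes with age, with subject-level scatter.
#'
#' @return data.frame with columns roi, v0, v1, v2, sd.
#' @export
defaultVolumeModel <- function() {
  data.frame(roi = .TISSUE_ROIS,
             v0 = c(620, 640, 62),
             v1 = c(0.8, 0.2, 0.05),
             v2 = c(-0.018, -0.006, -0.0012),
             sd = c(35, 30, 4))
}

#' Simulate a cross-sectional regional water-fraction cohort
#'
#' Draws ages uniformly over the age range, sex as Bernoulli(0.5) and
#' normalized ROI volumes from the volume model, then generates the nine
#' (ROI x water fraction) outcomes as trend(age) + sex effect +
#' volume effect + Gaussian noise. Each ROI row's three fractions are
#' clipped to [0, 1] (with a warning if clipping touches more than 1\% of
#' rows) and renormalized to sum to exactly 1.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return a long-format data.frame (the regional table) with columns
#'   subject_id, age_years, sex, roi, normalized_volume, mwf, iewf, csff.
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  n <- spec$nSubjects
  withSeed(spec$seed, {
    age <- stats::runif(n, spec$ageRange[1L], spec$ageRange[2L])
    sex <- stats::rbinom(n, 1L, 0.5)
    out <- vector("list", length(.TISSUE_ROIS))
    for (ri in seq_along(.TISSUE_ROIS)) {
      roi <- .TISSUE_ROIS[ri]
      vm <- spec$volumeModel[spec$volumeModel$roi == roi, ]
      vol <- vm$v0 + vm$v1 * age + vm$v2 * age^2 + stats::rnorm(n, 0, vm$sd)
      volC <- vol - mean(vol)
      wf <- matrix(NA_real_, n, 3L, dimnames = list(NULL, .WF_NAMES))
      for (w in .WF_NAMES) {
        tr <- spec$trends[spec$trends$roi == roi & spec$trends$wf == w, ]
        sd <- spec$residualSd$sd[spec$residualSd$roi == roi &
                                 spec$residualSd$wf == w]
        wf[, w] <- tr$b0 + tr$b1 * age + tr$b2 * age^2 +
          spec$sexEffect * sex + spec$volumeCoef * volC +
          stats::rnorm(n, 0, sd)
      }
      out[[ri]] <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                              age_years = age, sex = sex, roi = roi,
                              normalized_volume = vol,
                              mwf = wf[, "mwf"], iewf = wf[, "iewf"],
                              csff = wf[, "csff"])
    }
    tab <- do.call(rbind, out)
    clipped <- tab$mwf < 0 | tab$mwf > 1 | tab$iewf < 0 | tab$iewf > 1 |
      tab$csff < 0 | tab$csff > 1
    if (mean(clipped) > 0.01)
      warning(sprintf("fraction clipping affected %.1f%% of rows",
                      100 * mean(clipped)))
    for (w in .WF_NAMES) tab[[w]] <- pmin(pmax(tab[[w]], 0), 1)
    tot <- tab$mwf + tab$iewf + tab$csff
    for (w in .WF_NAMES) tab[[w]] <- tab[[w]] / tot
    rownames(tab) <- NULL
    tab
  })
}
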