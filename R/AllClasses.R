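#' @import methods
NULL

## Label codes shared across the package. 0 = background, 1 = cerebral WM,
## 2 = cortex, 3 = deep GM, 4 = lateral ventricles, 5 = subarachnoid CSF.
.LABELS <- c(background = 0L, wm = 1L, cortex = 2L, deepgm = 3L,
             ventricles = 4L, subarachnoid = 5L)
.CSF_LABELS <- c(4L, 5L)
.TISSUE_ROIS <- c("wm", "cortex", "deepgm")
.WF_NAMES <- c("mwf", "iewf", "csff")

#' EchoVolume: multi-echo magnitude image data
#'
#' A 4D magnitude volume (x, y, z, echo) together with its physical voxel
#' size in mm and the echo-time schedule in ms (for T2prep-based sequences
#' the nominal preparation time plays the role of the echo time).
#'
#' @slot data 4D numeric array, dimensions (nx, ny, nz, nTE).
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot teMs numeric(nTE), ascending echo times in ms, first >= 0.
#' @exportClass EchoVolume
setClass("EchoVolume",
  representation(data = "array", voxelSize = "numeric", teMs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a 4D array (x, y, z, echo)")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 strictly positive values (mm)")
    if (length(dim(object@data)) == 4L &&
        dim(object@data)[4L] != length(object@teMs))
      msg <- c(msg, "length(teMs) must equal the 4th data dimension")
    if (length(object@teMs) && (object@teMs[1L] < 0 ||
        any(diff(object@teMs) <= 0)))
      msg <- c(msg, "teMs must be ascending with first entry >= 0")
    if (length(msg)) msg else TRUE
  })

#' LabelVolume: integer tissue segmentation
#'
#' 3D integer labels: 0 background, 1 cerebral WM, 2 cortex, 3 deep GM,
#' 4 lateral ventricles, 5 subarachnoid CSF.
#'
#' @slot labels 3D integer array.
#' @slot voxelSize numeric(3), mm.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (!all(object@labels %in% .LABELS))
      msg <- c(msg, "labels limited to {0,1,2,3,4,5}")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 strictly positive values (mm)")
    if (length(msg)) msg else TRUE
  })

#' TissueTruth: per-label three-pool ground truth
#'
#' Ground-truth pool amplitudes (arbitrary signal units) and T2 values (ms)
#' for each tissue label of a phantom, with an optional smooth multiplicative
#' modulation field applied to the amplitudes.
#'
#' @slot pools data.frame with columns label, aMW, aIEW, aCSF, t2MW, t2IEW,
#'   t2CSF (one row per tissue label present in the phantom).
#' @slot modulation either NULL or a 3D array of positive multipliers.
#' @exportClass TissueTruth
setClass("TissueTruth",
  representation(pools = "data.frame", modulation = "ANY"),
  validity = function(object) {
    p <- object@pools
    need <- c("label", "aMW", "aIEW", "aCSF", "t2MW", "t2IEW", "t2CSF")
    if (!all(need %in% names(p)))
      return(paste("pools must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (any(p[, c("aMW", "aIEW", "aCSF")] < 0))
      msg <- c(msg, "amplitudes must be nonnegative")
    b <- poolBounds()
    if (any(p$t2MW < b[1, 1] | p$t2MW > b[1, 2]) ||
        any(p$t2IEW < b[2, 1] | p$t2IEW > b[2, 2]) ||
        any(p$t2CSF < b[3, 1] | p$t2CSF > b[3, 2]))
      msg <- c(msg, "every T2 must lie inside its pool's bounds")
    csf <- p$label %in% .CSF_LABELS
    if (any(p$aMW[csf] != 0) || any(p$aIEW[csf] != 0))
      msg <- c(msg, "pure-CSF labels (4, 5) must have aMW = aIEW = 0")
    if (!is.null(object@modulation) &&
        (!is.array(object@modulation) || any(object@modulation <= 0)))
      msg <- c(msg, "modulation must be NULL or a positive array")
    if (length(msg)) msg else TRUE
  })

#' NoiseModel: non-central chi magnitude noise
#'
#' @slot sigma per-channel Gaussian noise sd in signal units (>= 0).
#' @slot nCoils number of active coil elements (integer >= 1).
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(sigma = "numeric", nCoils = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma < 0)
      msg <- c(msg, "sigma must be a single finite value >= 0")
    if (length(object@nCoils) != 1L || is.na(object@nCoils) ||
        object@nCoils < 1L)
      msg <- c(msg, "nCoils must be a single integer >= 1")
    if (length(msg)) msg else TRUE
  })

#' CorrectionTable: invertible magnitude-bias lookup
#'
#' Tabulates the expected sum-of-squares magnitude m = E[M | A, sigma,
#' nCoils] on a grid of true amplitudes A, so that measured magnitudes can be
#' mapped back to bias-corrected amplitudes by monotone interpolation.
#'
#' @slot amplitude ascending grid of true amplitudes, starting at 0.
#' @slot meanMag expected measured magnitude at each grid amplitude
#'   (strictly increasing; first entry is the central-chi mean, the noise
#'   floor).
#' @slot noise the \linkS4class{NoiseModel} the table was built for.
#' @exportClass CorrectionTable
setClass("CorrectionTable",
  representation(amplitude = "numeric", meanMag = "numeric",
                 noise = "NoiseModel"),
  validity = function(object) {
    msg <- character()
    if (length(object@amplitude) != length(object@meanMag))
      msg <- c(msg, "amplitude and meanMag must have equal length")
    if (length(object@amplitude) < 2L)
      msg <- c(msg, "table needs at least 2 rows")
    if (any(diff(object@amplitude) <= 0) || any(diff(object@meanMag) <= 0))
      msg <- c(msg, "both columns must be strictly increasing")
    if (length(object@amplitude) && object@amplitude[1L] != 0)
      msg <- c(msg, "amplitude grid must start at 0")
    if (length(msg)) msg else TRUE
  })

#' WFMaps: voxelwise water-fraction maps
#'
#' Myelin water fraction (MWF), intra/extra-cellular water fraction (IEWF)
#' and CSF fraction (CSFF) per voxel. Voxels where the fit was not defined
#' (zero total amplitude, outside the mask, unfittable) are flagged in
#' \code{defined} and carry NA in the maps, never a silent 0.
#'
#' @slot mwf,iewf,csff 3D numeric arrays in [0,1] (NA where undefined).
#' @slot defined 3D logical array.
#' @slot voxelSize numeric(3), mm.
#' @exportClass WFMaps
setClass("WFMaps",
  representation(mwf = "array", iewf = "array", csff = "array",
                 defined = "array", voxelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@mwf)
    msg <- character()
    if (!identical(d, dim(object@iewf)) || !identical(d, dim(object@csff)) ||
        !identical(d, dim(object@defined)))
      msg <- c(msg, "all maps must share the same 3D dimensions")
    if (length(d) != 3L) msg <- c(msg, "maps must be 3D")
    def <- object@defined
    s <- object@mwf[def] + object@iewf[def] + object@csff[def]
    if (length(s) && (anyNA(s) || max(abs(s - 1)) > 1e-9))
      msg <- c(msg, "fractions must sum to 1 (1e-9) on defined voxels")
    if (any(!is.na(object@mwf[!def])))
      msg <- c(msg, "undefined voxels must carry NA")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 strictly positive values (mm)")
    if (length(msg)) msg else TRUE
  })

#' RoiMaskSet: eroded analysis regions
#'
#' Binary masks for the cerebral WM, cortex and deep GM analysis regions,
#' together with the erosion specification that produced them.
#'
#' @slot masks named list of 3D logical arrays (wm, cortex, deepgm).
#' @slot spec list recording the erosion parameters used (provenance).
#' @slot voxelSize numeric(3), mm.
#' @exportClass RoiMaskSet
setClass("RoiMaskSet",
  representation(masks = "list", spec = "list", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(sort(names(object@masks)), sort(.TISSUE_ROIS)))
      msg <- c(msg, "masks must be named wm, cortex, deepgm")
    else {
      m <- object@masks
      if (any(m$wm & m$cortex) || any(m$wm & m$deepgm) ||
          any(m$cortex & m$deepgm))
        msg <- c(msg, "ROI masks must be pairwise disjoint")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "EchoVolume", function(object) {
  d <- dim(object@data)
  cat("EchoVolume:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "echoes\n")
  cat("  voxel size (mm):", paste(object@voxelSize, collapse = " x "), "\n")
  cat("  TE (ms):", paste(object@teMs, collapse = ", "), "\n")
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume:", paste(dim(object@labels), collapse = " x "),
      "voxels\n  voxel size (mm):",
      paste(object@voxelSize, collapse = " x "), "\n")
  tab <- table(factor(object@labels, levels = .LABELS,
                      labels = names(.LABELS)))
  cat("  counts:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel: sigma =", format(object@sigma), ", nCoils =",
      object@nCoils, "\n")
})

setMethod("show", "CorrectionTable", function(object) {
  cat("CorrectionTable:", length(object@amplitude), "rows, A/sigma up to",
      format(max(object@amplitude) / max(object@noise@sigma, .Machine$double.eps)),
      "\n  noise floor E[M|A=0] =", format(object@meanMag[1L]), "\n")
})

setMethod("show", "WFMaps", function(object) {
  cat("WFMaps:", paste(dim(object@mwf), collapse = " x "), "voxels,",
      sum(object@defined), "defined\n")
  if (any(object@defined))
    cat("  mean MWF/IEWF/CSFF:",
        paste(signif(c(mean(object@mwf[object@defined]),
                       mean(object@iewf[object@defined]),
                       mean(object@csff[object@defined])), 4),
              collapse = " / "), "\n")
})

setMethod("show", "RoiMaskSet", function(object) {
  cat("RoiMaskSet:",
      paste(names(object@masks), vapply(object@masks, sum, 0L),
            sep = "=", collapse = " "), "voxels\n")
})
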