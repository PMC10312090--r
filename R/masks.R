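## Analysis-ROI construction: two-stage anisotropic erosion keeping tissue
## voxels away from CSF-filled spaces, and regional summaries.

#' Erosion specification
#'
#' Stage 1 is an isotropic morphological erosion of each ROI by
#' \code{stage1Mm} (physical distance to the ROI's own boundary surface).
#' Stage 2 removes voxels closer to any CSF-labelled voxel (ventricles or
#' subarachnoid space) than \code{inPlaneMm} in-plane or
#' \code{throughPlaneMm} through-plane, combined as the ellipsoidal
#' criterion (dx/inPlane)^2 + (dy/inPlane)^2 + (dz/throughPlane)^2 > 1.
#' Distances are center-to-center by default; \code{distanceMode =
#' "boundary"} measures to the CSF voxel boundary instead (subtracting the
#' half-voxel extent per axis; brute-force, intended for modest volumes).
#'
#' @param stage1Mm isotropic erosion radius, mm (default 1).
#' @param inPlaneMm minimum in-plane distance to CSF, mm (default 1).
#' @param throughPlaneMm minimum through-plane distance to CSF, mm
#'   (default 5).
#' @param distanceMode "center" (default) or "boundary".
#' @return a list of class \code{erosionSpec}.
#' @export
erosionSpec <- function(stage1Mm = 1, inPlaneMm = 1, throughPlaneMm = 5,
                        distanceMode = c("center", "boundary")) {
  if (any(c(stage1Mm, inPlaneMm, throughPlaneMm) < 0))
    stop("all erosion distances must be >= 0")
  structure(list(stage1Mm = stage1Mm, inPlaneMm = inPlaneMm,
                 throughPlaneMm = throughPlaneMm,
                 distanceMode = match.arg(distanceMode)),
            class = "erosionSpec")
}

## Structuring element for the stage-1 erosion: all integer offsets whose
## center-to-voxel-cube distance is below the radius, so with 1.3 x 1.3 x
## 5 mm voxels a 1 mm erosion removes exactly the in-plane boundary layer.
.stage1Offsets <- function(voxelSize, radiusMm) {
  if (radiusMm <= 0) return(matrix(0L, 1L, 3L))
  reach <- pmax(ceiling(radiusMm / voxelSize + 0.5), 1L)
  g <- as.matrix(expand.grid(i = -reach[1L]:reach[1L],
                             j = -reach[2L]:reach[2L],
                             k = -reach[3L]:reach[3L]))
  comp <- sweep(pmax(abs(g) - 0.5, 0), 2L, voxelSize, `*`)
  g[sqrt(rowSums(comp^2)) < radiusMm, , drop = FALSE]
}

.erodeBinary <- function(mask, voxelSize, radiusMm) {
  offs <- .stage1Offsets(voxelSize, radiusMm)
  d <- dim(mask)
  out <- mask
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    if (all(o == 0L)) next
    shifted <- array(FALSE, d)
    src <- lapply(1:3, function(ax) {
      ix <- seq_len(d[ax]) + o[ax]
      ix[ix >= 1L & ix <= d[ax]]
    })
    dst <- lapply(1:3, function(ax) {
      ix <- seq_len(d[ax])
      ix[ix + o[ax] >= 1L & ix + o[ax] <= d[ax]]
    })
    shifted[dst[[1L]], dst[[2L]], dst[[3L]]] <-
      mask[src[[1L]], src[[2L]], src[[3L]]]
    out <- out & shifted
  }
  out
}

## Stage-2 keep criterion against the CSF set. Center mode uses the exact
## scaled distance transform; boundary mode subtracts the half-voxel extent
## per axis (brute force over CSF voxels).
.csfKeep <- function(csf, voxelSize, inPlaneMm, throughPlaneMm, mode) {
  radii <- c(inPlaneMm, inPlaneMm, throughPlaneMm)
  if (all(radii == 0)) return(array(TRUE, dim(csf)))
  radii[radii == 0] <- Inf   # a 0 mm minimum constrains nothing on that axis
  if (mode == "center") {
    dsq <- scaledSquaredDistance(csf, voxelSize, radii)
    return(dsq > 1 + 1e-12)
  }
  d <- dim(csf)
  idx <- which(csf, arr.ind = TRUE)
  dsq <- array(Inf, d)
  ax <- lapply(1:3, function(a) seq_len(d[a]))
  coords <- cbind(rep(ax[[1L]], times = d[2L] * d[3L]),
                  rep(rep(ax[[2L]], each = d[1L]), times = d[3L]),
                  rep(ax[[3L]], each = d[1L] * d[2L]))
  for (r in seq_len(nrow(idx))) {
    delta <- abs(sweep(coords, 2L, idx[r, ], `-`))
    comp <- sweep(sweep(delta, 2L, voxelSize, `*`) -
                  matrix(voxelSize / 2, nrow(delta), 3L, byrow = TRUE),
                  1:2, 0, pmax)
    dsq <- pmin(dsq, array(rowSums(sweep(comp, 2L, radii, `/`)^2), d))
  }
  dsq > 1 + 1e-12
}

#' Erode tissue ROIs away from their boundaries and from CSF
#'
#' Applies the two-stage erosion of \code{\link{erosionSpec}} to the
#' cerebral WM, cortex and deep GM label regions. Each output mask is a
#' subset of its source label region; an erosion that empties a mask emits
#' a warning, never a silent empty result.
#'
#' @param labels a \linkS4class{LabelVolume} (CSF labels 4 and 5 must be
#'   present).
#' @param spec an \code{\link{erosionSpec}}.
#' @return a \linkS4class{RoiMaskSet}.
#' @export
erodeRois <- function(labels, spec = erosionSpec()) {
  stopifnot(is(labels, "LabelVolume"), inherits(spec, "erosionSpec"))
  lab <- labels@labels
  h <- labels@voxelSize
  csf <- array(lab %in% .CSF_LABELS, dim(lab))
  if (!any(csf))
    stop("no CSF labels (4, 5) present; cannot apply the CSF-distance ",
         "erosion")
  keep <- .csfKeep(csf, h, spec$inPlaneMm, spec$throughPlaneMm,
                   spec$distanceMode)
  masks <- lapply(stats::setNames(.TISSUE_ROIS, .TISSUE_ROIS), function(rn) {
    roi <- array(lab == .LABELS[[rn]], dim(lab))
    m <- .erodeBinary(roi, h, spec$stage1Mm) & keep
    if (!any(m))
      warning(sprintf("erosion left the %s mask empty", rn))
    m
  })
  new("RoiMaskSet", masks = masks, spec = unclass(spec), voxelSize = h)
}

#' Progressive-erosion sweep of the cortical CSFF
#'
#' Reproduces the CSF-contamination experiment: starting from the uneroded
#' cortical mask, the CSF-distance criterion is applied at 1 mm in-plane
#' and a sweep of through-plane minima, and the mean cortical CSFF is
#' tabulated per erosion level. Voxel counts are non-increasing along the
#' sweep by construction (the criteria are nested).
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param wfMaps a \linkS4class{WFMaps}.
#' @param throughPlaneMm sweep of through-plane minima, mm (default
#'   c(1, 3, 5, 7)).
#' @param inPlaneMm in-plane minimum, mm (default 1).
#' @param distanceMode "center" or "boundary".
#' @return data.frame with columns level, through_plane_mm, n_voxels,
#'   mean_csff.
#' @export
erosionSweep <- function(labels, wfMaps, throughPlaneMm = c(1, 3, 5, 7),
                         inPlaneMm = 1,
                         distanceMode = c("center", "boundary")) {
  stopifnot(is(labels, "LabelVolume"), is(wfMaps, "WFMaps"))
  distanceMode <- match.arg(distanceMode)
  lab <- labels@labels
  h <- labels@voxelSize
  cortex <- array(lab == .LABELS[["cortex"]], dim(lab))
  csf <- array(lab %in% .CSF_LABELS, dim(lab))
  csffMap <- wfMaps@csff
  ok <- wfMaps@defined

  summarize <- function(m, level, tp) {
    sel <- m & ok
    if (!any(sel)) {
      warning(sprintf("erosion level '%s' left no defined cortical voxels",
                      level))
      return(data.frame(level = level, through_plane_mm = tp,
                        n_voxels = sum(m), mean_csff = NA_real_))
    }
    data.frame(level = level, through_plane_mm = tp, n_voxels = sum(m),
               mean_csff = mean(csffMap[sel]))
  }
  rows <- list(summarize(cortex, "uneroded", 0))
  for (tp in throughPlaneMm) {
    keep <- .csfKeep(csf, h, inPlaneMm, tp, distanceMode)
    rows <- c(rows, list(summarize(cortex & keep,
                                   sprintf("%g-%g", inPlaneMm, tp), tp)))
  }
  do.call(rbind, rows)
}

#' Regional mean water fractions
#'
#' Arithmetic mean of each water-fraction map over the defined voxels of
#' each ROI mask, with voxel counts. An ROI with no defined voxels yields a
#' missing-value row and a warning.
#'
#' @param wfMaps a \linkS4class{WFMaps}.
#' @param rois a \linkS4class{RoiMaskSet}.
#' @return data.frame with columns roi, n_voxels, mwf, iewf, csff.
#' @export
regionalMeans <- function(wfMaps, rois) {
  stopifnot(is(wfMaps, "WFMaps"), is(rois, "RoiMaskSet"))
  ok <- wfMaps@defined
  rows <- lapply(.TISSUE_ROIS, function(rn) {
    sel <- rois@masks[[rn]] & ok
    if (!any(sel)) {
      warning(sprintf("ROI %s has no defined voxels", rn))
      return(data.frame(roi = rn, n_voxels = 0L, mwf = NA_real_,
                        iewf = NA_real_, csff = NA_real_))
    }
    data.frame(roi = rn, n_voxels = sum(sel),
               mwf = mean(wfMaps@mwf[sel]),
               iewf = mean(wfMaps@iewf[sel]),
               csff = mean(wfMaps@csff[sel]))
  })
  do.call(rbind, rows)
}

#' Skull-size volume normalization
#'
#' Multiplies a raw ROI volume by an externally supplied skull-derived
#' scaling factor (head-size normalization; the factor is accepted as
#' input).
#'
#' @param rawVolumeMm3 raw volume(s), mm^3.
#' @param scalingFactor positive scaling factor(s).
#' @return normalized volume(s).
#' @export
normalizeVolume <- function(rawVolumeMm3, scalingFactor) {
  if (any(scalingFactor <= 0)) stop("scalingFactor must be > 0")
  rawVolumeMm3 * scalingFactor
}
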