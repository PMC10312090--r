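## NIfTI-1 and sidecar IO. Echo volumes are written with the echo index as
## the 4th dimension and the echo schedule as a JSON sidecar
## {"te_ms": [...]}; label volumes and masks as integer volumes.

.withPixdim <- function(arr, voxelSize) {
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  img$pixdim <- c(-1, voxelSize, rep(1, 4 - length(voxelSize)),
                  rep(1, 3))[seq_len(8)]
  img
}

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an EchoVolume as NIfTI plus JSON sidecar
#'
#' @param volume an \linkS4class{EchoVolume}.
#' @param path output NIfTI path (.nii or .nii.gz); the echo schedule goes
#'   to the matching .json sidecar.
#' @return invisibly, the sidecar path.
#' @export
writeEchoVolume <- function(volume, path) {
  stopifnot(is(volume, "EchoVolume"))
  RNifti::writeNifti(.withPixdim(volume@data, volume@voxelSize), path)
  sc <- .sidecarPath(path)
  jsonlite::write_json(list(te_ms = volume@teMs), sc, auto_unbox = FALSE,
                       digits = NA)
  invisible(sc)
}

#' Read an EchoVolume from NIfTI plus JSON sidecar
#'
#' @param path NIfTI path; the echo schedule is read from the matching
#'   .json sidecar unless \code{teMs} is given.
#' @param teMs optional echo schedule override (ms).
#' @return an \linkS4class{EchoVolume}.
#' @export
readEchoVolume <- function(path, teMs = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(teMs)) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc))
      stop("no echo schedule: sidecar ", sc, " not found and teMs not given")
    teMs <- as.numeric(jsonlite::read_json(sc, simplifyVector = TRUE)$te_ms)
  }
  EchoVolume(array(as.vector(img), dim(img)), RNifti::pixdim(img)[1:3],
             teMs)
}

#' Write a LabelVolume as NIfTI
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param path output NIfTI path.
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  RNifti::writeNifti(.withPixdim(labels@labels, labels@voxelSize), path,
                     datatype = "int16")
  invisible(path)
}

#' Read a LabelVolume from NIfTI
#'
#' @param path NIfTI path of an integer label volume.
#' @return a \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  LabelVolume(array(as.integer(round(as.array(img))), dim(img)),
              RNifti::pixdim(img)[1:3])
}

#' Write water-fraction maps as NIfTI
#'
#' Three 3D volumes (mwf/iewf/csff) plus an integer defined-mask volume,
#' under a common prefix.
#'
#' @param wfMaps a \linkS4class{WFMaps}.
#' @param prefix output path prefix; files are <prefix>_mwf.nii.gz etc.
#' @return invisibly, the written paths.
#' @export
writeWFMaps <- function(wfMaps, prefix) {
  stopifnot(is(wfMaps, "WFMaps"))
  paths <- character()
  for (w in .WF_NAMES) {
    m <- slot(wfMaps, w)
    m[is.na(m)] <- 0      # NIfTI has no NA; the defined mask disambiguates
    p <- paste0(prefix, "_", w, ".nii.gz")
    RNifti::writeNifti(.withPixdim(m, wfMaps@voxelSize), p)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_defined.nii.gz")
  RNifti::writeNifti(.withPixdim(array(as.integer(wfMaps@defined),
                                       dim(wfMaps@defined)),
                                 wfMaps@voxelSize), p, datatype = "int16")
  invisible(c(paths, p))
}
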