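#' Accessors for cswater data classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a cswater S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))
#' @rdname accessors
#' @export
setGeneric("echoData", function(x) standardGeneric("echoData"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))
#' @rdname accessors
#' @export
setGeneric("coilCount", function(x) standardGeneric("coilCount"))
#' @rdname accessors
#' @export
setGeneric("wfMap", function(x, which) standardGeneric("wfMap"))
#' @rdname accessors
#' @export
setGeneric("definedMask", function(x) standardGeneric("definedMask"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x, which) standardGeneric("roiMask"))

#' @rdname accessors
#' @export
setMethod("voxelSize", "EchoVolume", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "WFMaps", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("echoTimes", "EchoVolume", function(x) x@teMs)
#' @rdname accessors
#' @export
setMethod("echoData", "EchoVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("labelData", "LabelVolume", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("noiseSigma", "NoiseModel", function(x) x@sigma)
#' @rdname accessors
#' @export
setMethod("noiseSigma", "CorrectionTable", function(x) x@noise@sigma)
#' @rdname accessors
#' @export
setMethod("coilCount", "NoiseModel", function(x) x@nCoils)
#' @rdname accessors
#' @export
setMethod("coilCount", "CorrectionTable", function(x) x@noise@nCoils)

#' @rdname accessors
#' @param which map or mask name: one of "mwf", "iewf", "csff" for
#'   \code{wfMap}; one of "wm", "cortex", "deepgm" for \code{roiMask}.
#' @export
setMethod("wfMap", "WFMaps", function(x, which = c("mwf", "iewf", "csff")) {
  which <- match.arg(which)
  slot(x, which)
})
#' @rdname accessors
#' @export
setMethod("definedMask", "WFMaps", function(x) x@defined)
#' @rdname accessors
#' @export
setMethod("roiMask", "RoiMaskSet",
          function(x, which = c("wm", "cortex", "deepgm")) {
  which <- match.arg(which)
  x@masks[[which]]
})
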