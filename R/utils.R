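## Internal helpers shared across modules.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Constructor helpers -------------------------------------------------------

#' Construct an EchoVolume
#'
#' @param data 4D numeric array (x, y, z, echo).
#' @param voxelSize numeric(3), mm.
#' @param teMs echo times in ms, ascending, first >= 0.
#' @return an \linkS4class{EchoVolume}.
#' @export
EchoVolume <- function(data, voxelSize, teMs) {
  new("EchoVolume", data = data, voxelSize = as.numeric(voxelSize),
      teMs = as.numeric(teMs))
}

#' Construct a LabelVolume
#'
#' @param labels 3D integer array with values in {0,...,5}.
#' @param voxelSize numeric(3), mm.
#' @return a \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, voxelSize) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, voxelSize = as.numeric(voxelSize))
}

#' Construct a NoiseModel
#'
#' @param sigma per-channel noise sd (signal units), >= 0.
#' @param nCoils active coil element count, integer >= 1.
#' @return a \linkS4class{NoiseModel}.
#' @export
NoiseModel <- function(sigma, nCoils) {
  new("NoiseModel", sigma = as.numeric(sigma), nCoils = as.integer(nCoils))
}

## The default six-echo T2prep schedule (ms): preparation off for the first
## acquisition, then logarithmically spread preparation times.
#' Default echo-time schedule
#'
#' Nominal T2prep times (ms) of the six-echo acquisition the package
#' emulates: 0 (preparation off), 7.5, 17.5, 67.5, 147.5, 307.5.
#'
#' @return numeric(6) of echo times in ms.
#' @export
defaultEchoTimes <- function() c(0, 7.5, 17.5, 67.5, 147.5, 307.5)

#' Default anisotropic voxel size
#'
#' @return numeric(3): 1.3 x 1.3 x 5 mm.
#' @export
defaultVoxelSize <- function() c(1.3, 1.3, 5.0)
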