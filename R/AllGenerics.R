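#' @import methods
#' @importFrom stats fft quantile rnorm runif sd setNames
NULL

#' Extract the voxel data array of a volume
#'
#' @param x an \linkS4class{ImageVolume} or \linkS4class{MaskVolume}
#' @return the 3D numeric array of voxel values
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' Voxel spacing of a volume in millimetres
#'
#' @param x an \linkS4class{ImageVolume}
#' @return numeric(3), per-axis voxel size in mm
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Physical origin of a volume in millimetres
#'
#' @param x an \linkS4class{ImageVolume}
#' @return numeric(3) physical offset of voxel (0, 0, 0)
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))

#' Compartment label of a mask
#'
#' @param x a \linkS4class{MaskVolume}
#' @return character(1) label
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))
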