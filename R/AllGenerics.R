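#' @include AllClasses.R
NULL

#' Extract the voxel value array
#' @param x an object with a voxel value array
#' @return a numeric (or complex) array
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' Extract the grid geometry
#' @param x an object carrying a [VolumeGrid-class]
#' @return a [VolumeGrid-class]
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' Grid shape in voxels
#' @param x a [VolumeGrid-class] or object carrying one
#' @return integer(3)
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' Voxel size in mm
#' @param x a [VolumeGrid-class] or object carrying one
#' @return numeric(3)
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Unit vector of the main field B0
#' @param x a [VolumeGrid-class] or object carrying one
#' @return numeric(3), unit norm
#' @export
setGeneric("b0Direction", function(x) standardGeneric("b0Direction"))

#' Units tag of a scalar volume
#' @param x a [ScalarVolume-class]
#' @return character scalar
#' @export
setGeneric("volumeUnits", function(x) standardGeneric("volumeUnits"))

#' Echo times in seconds
#' @param x a [ComplexEchoSeries-class] or [PhantomSpec-class]
#' @return numeric vector
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' Field strength in Tesla
#' @param x a [ComplexEchoSeries-class] or [PhantomSpec-class]
#' @return numeric scalar
#' @export
setGeneric("fieldStrength", function(x) standardGeneric("fieldStrength"))

#' Field map kind
#' @param x a [FieldMap-class]
#' @return one of "total", "background", "local"
#' @export
setGeneric("fieldKind", function(x) standardGeneric("fieldKind"))
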