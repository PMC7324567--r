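#' @include AllClasses.R AllGenerics.R
NULL

# ---- constructors -----------------------------------------------------------

#' Create a volume grid
#'
#' @param shape integer(3) array dimensions (voxels).
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @param b0Direction 3-vector giving the B0 direction in the array frame;
#'   normalized internally.
#' @return a [VolumeGrid-class]
#' @examples
#' g <- volumeGrid(c(32, 32, 32))
#' gridShape(g)
#' @export
volumeGrid <- function(shape, voxelSize = c(1, 1, 1), b0Direction = c(0, 0, 1)) {
  b0 <- as.numeric(b0Direction)
  nb <- sqrt(sum(b0^2))
  if (!is.finite(nb) || nb == 0) stop("b0Direction must be a nonzero vector")
  new("VolumeGrid", shape = as.integer(shape),
      voxelSize = as.numeric(voxelSize), b0Direction = b0 / nb)
}

#' Create a scalar volume
#'
#' @param values 3D numeric array.
#' @param grid a [VolumeGrid-class]; defaults to isotropic 1 mm voxels.
#' @param units units tag.
#' @return a [ScalarVolume-class]
#' @export
scalarVolume <- function(values, grid = NULL, units = "arbitrary") {
  if (is.null(grid)) grid <- volumeGrid(dim(values))
  new("ScalarVolume", grid = grid, values = values, units = units)
}

#' Create a field map
#'
#' @inheritParams scalarVolume
#' @param kind one of `"total"`, `"background"`, `"local"`.
#' @return a [FieldMap-class] in ppm
#' @export
fieldMap <- function(values, grid = NULL, kind = "total") {
  if (is.null(grid)) grid <- volumeGrid(dim(values))
  new("FieldMap", grid = grid, values = values, units = "ppm", kind = kind)
}

#' Create a susceptibility map
#'
#' @inheritParams scalarVolume
#' @return a [SusceptibilityMap-class] in ppm
#' @export
susceptibilityMap <- function(values, grid = NULL) {
  if (is.null(grid)) grid <- volumeGrid(dim(values))
  new("SusceptibilityMap", grid = grid, values = values, units = "ppm")
}

#' Create a binary mask volume
#'
#' @param values 3D array; coerced to 0/1 via `!= 0`.
#' @param grid a [VolumeGrid-class].
#' @return a [MaskVolume-class]
#' @export
maskVolume <- function(values, grid = NULL) {
  if (is.null(grid)) grid <- volumeGrid(dim(values))
  v <- array(as.numeric(values != 0), dim = dim(values))
  new("MaskVolume", grid = grid, values = v)
}

#' Create a complex echo series
#'
#' @param echoes list of complex 3D arrays (one per echo).
#' @param tes echo times in seconds.
#' @param b0 field strength in Tesla.
#' @param grid a [VolumeGrid-class].
#' @return a [ComplexEchoSeries-class]
#' @export
complexEchoSeries <- function(echoes, tes, b0 = 3, grid = NULL) {
  if (is.null(grid)) grid <- volumeGrid(dim(echoes[[1]]))
  new("ComplexEchoSeries", grid = grid, echoes = echoes,
      tes = as.numeric(tes), b0 = as.numeric(b0))
}

#' Proton gyromagnetic ratio (gamma-bar), Hz per Tesla
#'
#' @return 42.576e6 Hz/T
#' @export
gyromagneticRatio <- function() 42.576e6

# ---- accessors --------------------------------------------------------------

#' @describeIn voxelValues value array of a scalar volume
#' @export
setMethod("voxelValues", "ScalarVolume", function(x) x@values)

#' @describeIn voxelValues kernel samples on the Fourier lattice
#' @export
setMethod("voxelValues", "KernelVolume", function(x) x@values)

#' @describeIn voxelValues 0/1 mask array
#' @export
setMethod("voxelValues", "MaskVolume", function(x) x@values)

#' @describeIn voxelValues 4D per-direction edge-penalty array
#' @export
setMethod("voxelValues", "EdgeMask", function(x) x@values)

#' @describeIn gridGeometry grid of a grid (identity)
#' @export
setMethod("gridGeometry", "VolumeGrid", function(x) x)
#' @describeIn gridGeometry grid of a scalar volume
#' @export
setMethod("gridGeometry", "ScalarVolume", function(x) x@grid)
#' @describeIn gridGeometry grid of a kernel volume
#' @export
setMethod("gridGeometry", "KernelVolume", function(x) x@grid)
#' @describeIn gridGeometry grid of a mask
#' @export
setMethod("gridGeometry", "MaskVolume", function(x) x@grid)
#' @describeIn gridGeometry grid of an edge mask
#' @export
setMethod("gridGeometry", "EdgeMask", function(x) x@grid)
#' @describeIn gridGeometry grid of an echo series
#' @export
setMethod("gridGeometry", "ComplexEchoSeries", function(x) x@grid)
#' @describeIn gridGeometry grid of a phantom spec
#' @export
setMethod("gridGeometry", "PhantomSpec", function(x) x@grid)

#' @describeIn gridShape shape of a grid
#' @export
setMethod("gridShape", "VolumeGrid", function(x) x@shape)
#' @describeIn gridShape shape via the carried grid
#' @export
setMethod("gridShape", "ANY", function(x) gridGeometry(x)@shape)

#' @describeIn voxelSize voxel size of a grid
#' @export
setMethod("voxelSize", "VolumeGrid", function(x) x@voxelSize)
#' @describeIn voxelSize voxel size via the carried grid
#' @export
setMethod("voxelSize", "ANY", function(x) gridGeometry(x)@voxelSize)

#' @describeIn b0Direction B0 direction of a grid
#' @export
setMethod("b0Direction", "VolumeGrid", function(x) x@b0Direction)
#' @describeIn b0Direction B0 direction via the carried grid
#' @export
setMethod("b0Direction", "ANY", function(x) gridGeometry(x)@b0Direction)

#' @describeIn volumeUnits units tag of a scalar volume
#' @export
setMethod("volumeUnits", "ScalarVolume", function(x) x@units)

#' @describeIn echoTimes echo times of a series
#' @export
setMethod("echoTimes", "ComplexEchoSeries", function(x) x@tes)
#' @describeIn echoTimes echo times of a phantom spec
#' @export
setMethod("echoTimes", "PhantomSpec", function(x) x@tes)

#' @describeIn fieldStrength field strength of a series
#' @export
setMethod("fieldStrength", "ComplexEchoSeries", function(x) x@b0)
#' @describeIn fieldStrength field strength of a phantom spec
#' @export
setMethod("fieldStrength", "PhantomSpec", function(x) x@b0)

#' @describeIn fieldKind kind flag of a field map
#' @export
setMethod("fieldKind", "FieldMap", function(x) x@kind)

# ---- show methods -----------------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@shape, collapse = " x "), "voxels,",
      paste(format(object@voxelSize, digits = 3), collapse = " x "), "mm;",
      "B0 = (", paste(format(object@b0Direction, digits = 3), collapse = ", "), ")\n")
})

setMethod("show", "ScalarVolume", function(object) {
  v <- object@values
  cat(class(object), ":", paste(dim(v), collapse = " x "),
      sprintf("[%s]; range %.4g .. %.4g\n", object@units,
              min(v), max(v)))
})

setMethod("show", "FieldMap", function(object) {
  cat("FieldMap (", object@kind, "): ",
      paste(dim(object@values), collapse = " x "),
      sprintf(" [ppm]; range %.4g .. %.4g\n",
              min(object@values), max(object@values)), sep = "")
})

setMethod("show", "MaskVolume", function(object) {
  cat("MaskVolume:", paste(dim(object@values), collapse = " x "),
      "-", sum(object@values), "voxels in mask\n")
})

setMethod("show", "ComplexEchoSeries", function(object) {
  cat("ComplexEchoSeries:", length(object@echoes), "echoes,",
      paste(dim(object@echoes[[1]]), collapse = " x "), "voxels; TEs (ms):",
      paste(format(object@tes * 1e3, digits = 4), collapse = ", "),
      "; B0 =", object@b0, "T\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@grid@shape, collapse = " x "),
      "grid; chi remote/infarct =", object@chiRemote, "/", object@chiInfarct,
      "ppm; T2* remote/infarct =", object@t2sRemote, "/", object@t2sInfarct,
      "ms; SNR =", object@snr, "; seed =", object@seed, "\n")
})

setMethod("show", "InversionResult", function(object) {
  cat("InversionResult:", length(object@objectiveTrace), "outer iterations;",
      "objective", format(utils::tail(object@objectiveTrace, 1), digits = 6),
      if (object@converged) "(converged)" else "(not converged)", "\n")
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.4f, Youden J = %.4f at threshold %.4g (sens %.3f, spec %.3f)\n",
              object@auc, object@youdenJ, object@optimalThreshold,
              object@sensOpt, object@specOpt))
})
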