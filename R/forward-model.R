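#' @include AllClasses.R accessors.R utils-internal.R
NULL

#' Fourier-domain dipole kernel
#'
#' Samples the unit dipole kernel D = 1/3 - kz^2/k^2 on the discrete Fourier
#' frequency lattice of a grid.  Frequencies are computed in physical units
#' (cycles/mm) from the grid shape and voxel size, so anisotropic voxels are
#' handled correctly; kz is the projection of the frequency vector onto the
#' B0 direction, so oblique B0 (as in short-axis cardiac acquisitions) is
#' supported.  The zero-frequency sample is set to 0: a spatially uniform
#' field offset is unobservable and susceptibility maps are referenced post
#' hoc against remote myocardium.
#'
#' @param grid a [VolumeGrid-class].
#' @return a [KernelVolume-class] with values in [-2/3, 1/3].
#' @examples
#' D <- dipoleKernel(volumeGrid(c(16, 16, 16)))
#' range(voxelValues(D))
#' @export
dipoleKernel <- function(grid) {
  stopifnot(is(grid, "VolumeGrid"))
  validObject(grid)
  shp <- grid@shape
  if (any(shp < 2L)) stop("grid too small for a dipole kernel: every dimension must be >= 2")
  fx <- .fftFreq(shp[1], grid@voxelSize[1])
  fy <- .fftFreq(shp[2], grid@voxelSize[2])
  fz <- .fftFreq(shp[3], grid@voxelSize[3])
  KX <- array(fx, dim = shp)
  KY <- array(rep(fy, each = shp[1]), dim = shp)
  KZ <- array(rep(fz, each = shp[1] * shp[2]), dim = shp)
  b <- grid@b0Direction
  kpar2 <- (KX * b[1] + KY * b[2] + KZ * b[3])^2
  k2 <- KX^2 + KY^2 + KZ^2
  D <- 1 / 3 - kpar2 / k2
  D[k2 == 0] <- 0
  new("KernelVolume", grid = grid, values = D)
}

# Apply the dipole convolution F^-1 D F to a plain array; kernel reused if
# supplied.
.dipoleApply <- function(values, kernel) {
  Re(.ifftn(voxelValues(kernel) * .fftn(values)))
}

#' Simulate the field induced by a susceptibility distribution
#'
#' Forward model: the normalized field perturbation (ppm) induced by a
#' susceptibility map (ppm) is Phi = F^-1 (D . F chi), with D the Fourier
#' dipole kernel.  The convolution is circular; callers should keep sources
#' away from the volume boundary (the phantom generator keeps geometry at
#' least 25% of the grid extent from the faces).  The output has zero spatial
#' mean because D(0) = 0.
#'
#' @param chi a [SusceptibilityMap-class] (or 3D array in ppm).
#' @param kernel optional precomputed [KernelVolume-class] matching the grid.
#' @param grid grid to use when `chi` is a plain array.
#' @return a [FieldMap-class], kind `"total"`, in ppm.
#' @examples
#' chi <- array(0, c(16, 16, 16)); chi[8, 8, 8] <- 1
#' phi <- simulateField(susceptibilityMap(chi))
#' abs(mean(voxelValues(phi))) < 1e-12
#' @export
simulateField <- function(chi, kernel = NULL, grid = NULL) {
  if (is(chi, "ScalarVolume")) {
    grid <- chi@grid
    vals <- chi@values
  } else {
    vals <- chi
    if (is.null(grid)) grid <- volumeGrid(dim(vals))
  }
  if (any(!is.finite(vals))) stop("susceptibility values must be finite")
  if (is.null(kernel)) kernel <- dipoleKernel(grid)
  .checkSameGrid(grid, kernel)
  fieldMap(.dipoleApply(vals, kernel), grid = grid, kind = "total")
}

#' Apply the (self-adjoint) dipole forward operator
#'
#' Computes F^-1 (D . F v).  Because D is real and even, the operator is
#' self-adjoint: `<Av, w> == <v, Aw>`.  Used by the conjugate-gradient
#' solvers in background removal and dipole inversion.
#'
#' @param v a [ScalarVolume-class] or 3D array.
#' @param kernel optional precomputed [KernelVolume-class].
#' @param grid grid when `v` is a plain array.
#' @return object of the same flavor as `v` (volume in, volume out).
#' @export
applyForwardAdjoint <- function(v, kernel = NULL, grid = NULL) {
  isVol <- is(v, "ScalarVolume")
  if (isVol) { grid <- v@grid; vals <- v@values }
  else { vals <- v; if (is.null(grid)) grid <- volumeGrid(dim(vals)) }
  if (is.null(kernel)) kernel <- dipoleKernel(grid)
  .checkSameGrid(grid, kernel)
  out <- .dipoleApply(vals, kernel)
  if (isVol) scalarVolume(out, grid = grid, units = v@units) else out
}
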