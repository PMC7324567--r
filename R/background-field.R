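#' @include AllClasses.R accessors.R forward-model.R utils-internal.R
NULL

#' Erode a binary mask
#'
#' Morphological erosion with the 6-connected cross structuring element,
#' applied `voxels` times; erosion by 0 is the identity.  Voxels on the
#' volume boundary erode (outside the grid counts as background).
#'
#' @param mask a [MaskVolume-class].
#' @param voxels non-negative integer erosion radius.
#' @return a [MaskVolume-class]
#' @export
erodeMask <- function(mask, voxels = 1L) {
  stopifnot(is(mask, "MaskVolume"))
  voxels <- as.integer(voxels)
  if (voxels < 0L) stop("erosion radius must be >= 0")
  if (voxels == 0L) return(mask)
  m <- .erodeTimes(voxelValues(mask) != 0, voxels)
  if (!any(m)) stop("erosion emptied the mask")
  maskVolume(array(as.numeric(m), dim = dim(m)), grid = mask@grid)
}

#' Background field removal by projection onto dipole fields (PDF)
#'
#' Fits a susceptibility distribution supported strictly outside the tissue
#' mask to the measured total field, by solving the weighted least-squares
#' problem `min || W (F^-1 D F chi_ext - Phi_total) ||_2^2` with conjugate
#' gradients on the normal equations, and subtracts the fitted exterior
#' (background) dipole field inside the mask.  Exterior support is the
#' complement of the mask eroded by `boundaryErode` voxels, so the unreliable
#' boundary shell is assigned to the exterior.
#'
#' @param total a [FieldMap-class] of kind `"total"` (ppm).
#' @param mask a [MaskVolume-class].
#' @param weight a [WeightVolume-class] (SNR weights, zero outside the mask).
#' @param cgTol conjugate-gradient relative residual tolerance.
#' @param cgMaxiter maximum CG iterations.
#' @param boundaryErode voxels of mask erosion defining the interior kept out
#'   of the exterior-source support.
#' @param kernel optional precomputed [KernelVolume-class].
#' @return list with `localField` (a [FieldMap-class], kind `"local"`, zero
#'   outside the mask), `backgroundField` (kind `"background"`),
#'   `chiExterior` (fitted exterior sources, zero inside the mask),
#'   `iterations`, `relres`, and `converged`; non-convergence returns the
#'   partial result with a warning.
#' @export
removeBackgroundPDF <- function(total, mask, weight, cgTol = 1e-6,
                                cgMaxiter = 100L, boundaryErode = 1L,
                                kernel = NULL) {
  stopifnot(is(total, "FieldMap"), is(mask, "MaskVolume"),
            is(weight, "WeightVolume"))
  if (total@kind != "total")
    stop("removeBackgroundPDF expects a field map of kind 'total'")
  .checkSameGrid(total, mask, weight)
  grid <- total@grid
  m <- voxelValues(mask) != 0
  if (!any(m)) stop("mask is empty")
  if (all(m)) stop("mask covers the whole volume: no exterior to project onto")
  interior <- .erodeTimes(m, as.integer(boundaryErode))
  ext <- !interior
  if (is.null(kernel)) kernel <- dipoleKernel(grid)
  W2 <- voxelValues(weight)^2
  phi <- voxelValues(total)
  extN <- array(as.numeric(ext), dim = dim(phi))
  applyA <- function(x) {
    fx <- .dipoleApply(x * extN, kernel)
    .dipoleApply(W2 * fx, kernel) * extN
  }
  b <- .dipoleApply(W2 * phi, kernel) * extN
  sol <- .conjugateGradient(applyA, b, tol = cgTol, maxiter = as.integer(cgMaxiter))
  if (!sol$converged)
    warning(sprintf("PDF conjugate gradient stopped at %d iterations with relative residual %.3g",
                    sol$iterations, sol$relres))
  chiExt <- sol$x * extN
  bg <- .dipoleApply(chiExt, kernel)
  localVals <- (phi - bg) * as.numeric(m)
  list(localField = fieldMap(localVals, grid = grid, kind = "local"),
       backgroundField = fieldMap(bg, grid = grid, kind = "background"),
       chiExterior = scalarVolume(chiExt, grid = grid, units = "ppm"),
       iterations = sol$iterations, relres = sol$relres,
       converged = sol$converged)
}
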