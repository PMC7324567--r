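#' @include AllClasses.R accessors.R
NULL

#' Write a volume to NIfTI-1
#'
#' Voxel size is recorded in the header (RAS+ convention, 0-based voxel
#' indexing); the units tag travels in the YAML/JSON sidecars written by the
#' pipeline, not in the NIfTI header.
#'
#' @param vol a [ScalarVolume-class], [MaskVolume-class] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSize voxel size (mm) when `vol` is a plain array.
#' @return the path, invisibly
#' @export
writeVolume <- function(vol, path, voxelSize = c(1, 1, 1)) {
  if (is(vol, "ScalarVolume") || is(vol, "MaskVolume")) {
    voxelSize <- gridGeometry(vol)@voxelSize
    vol <- voxelValues(vol)
  }
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param units units tag for the returned volume.
#' @param b0Direction B0 direction for the constructed grid.
#' @return a [ScalarVolume-class]
#' @export
readVolume <- function(path, units = "arbitrary", b0Direction = c(0, 0, 1)) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  scalarVolume(vals, grid = volumeGrid(dim(vals), vs, b0Direction), units = units)
}

#' Write an echo series as magnitude/phase NIfTI pairs plus a YAML sidecar
#'
#' Magnitude and phase (radians, in (-pi, pi]) are written per echo, the
#' acquisition metadata (echo times in seconds, field strength, B0 direction,
#' voxel size) to `<prefix>.yaml`.
#'
#' @param series a [ComplexEchoSeries-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; files are
#'   `<prefix>_mag_e<j>.nii.gz`, `<prefix>_phase_e<j>.nii.gz`.
#' @return named list of written paths, invisibly
#' @export
writeEchoSeries <- function(series, dir, prefix = "echo") {
  stopifnot(is(series, "ComplexEchoSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- series@grid@voxelSize
  magPaths <- phasePaths <- character(length(series@echoes))
  for (j in seq_along(series@echoes)) {
    magPaths[j] <- file.path(dir, sprintf("%s_mag_e%d.nii.gz", prefix, j))
    phasePaths[j] <- file.path(dir, sprintf("%s_phase_e%d.nii.gz", prefix, j))
    writeVolume(Mod(series@echoes[[j]]), magPaths[j], voxelSize = vs)
    writeVolume(Arg(series@echoes[[j]]), phasePaths[j], voxelSize = vs)
  }
  sidecar <- file.path(dir, paste0(prefix, ".yaml"))
  yaml::write_yaml(list(tes = as.numeric(series@tes), b0 = series@b0,
                        b0Direction = as.numeric(series@grid@b0Direction),
                        voxelSize = as.numeric(vs),
                        shape = as.integer(series@grid@shape)),
                   sidecar)
  invisible(list(magnitude = magPaths, phase = phasePaths, sidecar = sidecar))
}

#' Read an echo series from magnitude/phase NIfTI pairs
#'
#' Phase volumes must be in radians in (-pi, pi]; values outside that range
#' (e.g. degrees or scanner integer scaling) are rejected.  All echoes must
#' share one shape and voxel geometry.
#'
#' @param magPaths,phasePaths equal-length vectors of NIfTI paths, one per
#'   echo.
#' @param sidecar optional YAML sidecar path supplying `tes`, `b0` and
#'   `b0Direction`; explicit arguments override it.
#' @param tes echo times in seconds.
#' @param b0 field strength in Tesla.
#' @param b0Direction B0 direction in the array frame.
#' @return a [ComplexEchoSeries-class]
#' @export
readEchoSeries <- function(magPaths, phasePaths, sidecar = NULL,
                           tes = NULL, b0 = NULL, b0Direction = NULL) {
  if (length(magPaths) != length(phasePaths))
    stop("equal numbers of magnitude and phase volumes are required")
  if (!is.null(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (is.null(tes)) tes <- meta$tes
    if (is.null(b0)) b0 <- meta$b0
    if (is.null(b0Direction)) b0Direction <- meta$b0Direction
  }
  if (is.null(tes)) stop("echo times are required (sidecar or `tes`)")
  if (is.null(b0)) stop("field strength is required (sidecar or `b0`)")
  if (is.null(b0Direction)) b0Direction <- c(0, 0, 1)
  echoes <- vector("list", length(magPaths))
  grid <- NULL
  for (j in seq_along(magPaths)) {
    mag <- RNifti::readNifti(magPaths[j])
    ph <- RNifti::readNifti(phasePaths[j])
    if (!identical(dim(mag), dim(ph)))
      stop(sprintf("echo %d: magnitude and phase shapes differ", j))
    if (max(abs(as.numeric(ph))) > pi + 0.01)
      stop(sprintf("echo %d: phase values exceed pi in magnitude; phase must be radians in (-pi, pi]", j))
    vs <- RNifti::pixdim(mag)[1:3]
    g <- volumeGrid(dim(mag), vs, b0Direction)
    if (is.null(grid)) grid <- g
    else if (!identical(g@shape, grid@shape) ||
             max(abs(g@voxelSize - grid@voxelSize)) > 1e-6)
      stop(sprintf("echo %d: shape or voxel geometry mismatch across echoes", j))
    echoes[[j]] <- array(complex(modulus = as.numeric(mag),
                                 argument = as.numeric(ph)), dim = dim(mag))
  }
  complexEchoSeries(echoes, tes = tes, b0 = b0, grid = grid)
}

#' Write phantom truth volumes
#'
#' Writes the true susceptibility map, T2* map and label volume as NIfTI
#' next to the synthesized echoes.
#'
#' @param truth a [PhantomTruth-class].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return named list of paths, invisibly
#' @export
writePhantomTruth <- function(truth, dir, prefix = "truth") {
  stopifnot(is(truth, "PhantomTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(chi = file.path(dir, paste0(prefix, "_chi.nii.gz")),
            t2s = file.path(dir, paste0(prefix, "_t2s.nii.gz")),
            labels = file.path(dir, paste0(prefix, "_labels.nii.gz")))
  writeVolume(truth@chiMap, p$chi)
  writeVolume(truth@t2sMap, p$t2s)
  writeVolume(array(as.numeric(truth@labels), dim = dim(truth@labels)),
              p$labels, voxelSize = truth@chiMap@grid@voxelSize)
  invisible(p)
}
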