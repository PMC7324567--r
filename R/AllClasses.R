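#' @import methods
NULL

#' Acquisition grid geometry
#'
#' A `VolumeGrid` records the voxel lattice of a 3D acquisition: the array
#' shape in voxels, the voxel edge lengths in mm, and the unit vector of the
#' main magnetic field B0 expressed in the array coordinate frame.  Cardiac
#' short-axis acquisitions are oblique, so B0 need not be axis-aligned.
#'
#' @slot shape integer(3), array dimensions in voxels.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (all > 0).
#' @slot b0Direction numeric(3), unit vector of B0 in the array frame.
#' @export
setClass("VolumeGrid",
  representation(shape = "integer", voxelSize = "numeric", b0Direction = "numeric"))

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 2L))
    msg <- c(msg, "shape must be 3 integers, each >= 2")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (length(object@b0Direction) != 3L ||
      abs(sqrt(sum(object@b0Direction^2)) - 1) > 1e-12)
    msg <- c(msg, "b0Direction must be a unit 3-vector (within 1e-12)")
  if (length(msg)) msg else TRUE
})

#' Scalar volume on a grid
#'
#' A real-valued voxelwise map with a units tag.  Units are one of
#' `"ppm"`, `"Hz"`, `"radians"`, `"ms"`, `"1/ms"`, `"arbitrary"`.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot values 3D numeric array matching `gridShape(grid)`.
#' @slot units character scalar units tag.
#' @export
setClass("ScalarVolume",
  representation(grid = "VolumeGrid", values = "array", units = "character"))

.volUnits <- c("ppm", "Hz", "radians", "ms", "1/ms", "arbitrary")

setValidity("ScalarVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values dimensions must equal grid shape")
  if (length(object@units) != 1L || !(object@units %in% .volUnits))
    msg <- c(msg, paste("units must be one of:", paste(.volUnits, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Fourier-domain dipole kernel
#'
#' The real, even Fourier multiplier D = 1/3 - kz^2/k^2 sampled on the
#' discrete frequency lattice of a grid, with D(k = 0) = 0 by convention
#' (the uniform field offset is unobservable).
#'
#' @slot grid a [VolumeGrid-class].
#' @slot values 3D numeric array of kernel samples in [-2/3, 1/3].
#' @export
setClass("KernelVolume",
  representation(grid = "VolumeGrid", values = "array"))

setValidity("KernelVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values dimensions must equal grid shape")
  rng <- range(object@values)
  if (rng[1] < -2 / 3 - 1e-12 || rng[2] > 1 / 3 + 1e-12)
    msg <- c(msg, "kernel values must lie in [-2/3, 1/3]")
  if (abs(object@values[1, 1, 1]) > 0)
    msg <- c(msg, "kernel value at zero frequency must be 0")
  if (length(msg)) msg else TRUE
})

#' Susceptibility map (ppm)
#'
#' Voxelwise magnetic susceptibility difference from water, in parts per
#' million.  After inversion the map is zero outside the tissue mask and is
#' referenced post hoc (see [referenceSusceptibility()]).
#' @export
setClass("SusceptibilityMap", contains = "ScalarVolume")

setValidity("SusceptibilityMap", function(object) {
  if (!identical(object@units, "ppm")) return("SusceptibilityMap units must be ppm")
  if (any(!is.finite(object@values))) return("susceptibility values must be finite")
  TRUE
})

#' Field map (ppm)
#'
#' Normalized field perturbation delta-B/B0 in ppm, flagged as the total
#' field, the background field, or the local tissue field.
#'
#' @slot kind character, one of `"total"`, `"background"`, `"local"`.
#' @export
setClass("FieldMap", contains = "ScalarVolume",
  representation(kind = "character"))

setValidity("FieldMap", function(object) {
  msg <- character()
  if (!identical(object@units, "ppm")) msg <- c(msg, "FieldMap units must be ppm")
  if (length(object@kind) != 1L || !(object@kind %in% c("total", "background", "local")))
    msg <- c(msg, "kind must be one of total, background, local")
  if (length(msg)) msg else TRUE
})

#' Binary tissue mask
#'
#' @slot grid a [VolumeGrid-class].
#' @slot values 3D array with values in \{0, 1\}.
#' @export
setClass("MaskVolume",
  representation(grid = "VolumeGrid", values = "array"))

setValidity("MaskVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values dimensions must equal grid shape")
  if (!all(object@values %in% c(0, 1)))
    msg <- c(msg, "mask values must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' SNR weight volume
#'
#' Non-negative per-voxel weight W estimated from the echo magnitudes
#' (root-sum-of-squares), zero outside the mask and normalized to mean 1
#' over the mask.
#' @export
setClass("WeightVolume", contains = "ScalarVolume")

setValidity("WeightVolume", function(object) {
  if (any(object@values < 0)) return("weights must be non-negative")
  TRUE
})

#' Gradient-edge mask for morphology-enabled inversion
#'
#' Per-direction binary penalty mask M: 1 where susceptibility gradients are
#' penalized, 0 at magnitude-image edges (the top `edgeFraction` of in-mask
#' gradient magnitudes, per direction).
#'
#' @slot grid a [VolumeGrid-class].
#' @slot values 4D array `c(shape, 3)`, values in \{0, 1\}; the 4th axis is
#'   the gradient direction.
#' @slot edgeFraction fraction of in-mask voxels left unpenalized per direction.
#' @export
setClass("EdgeMask",
  representation(grid = "VolumeGrid", values = "array", edgeFraction = "numeric"))

setValidity("EdgeMask", function(object) {
  msg <- character()
  if (!identical(dim(object@values), c(as.integer(object@grid@shape), 3L)))
    msg <- c(msg, "values must have dimensions c(grid shape, 3)")
  if (!all(object@values %in% c(0, 1)))
    msg <- c(msg, "edge mask values must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Multi-echo complex gradient-echo series
#'
#' Per-echo complex volumes with echo times (seconds) and field strength
#' (Tesla).  The proton gyromagnetic ratio gamma-bar = 42.576e6 Hz/T converts
#' between ppm field offsets and Hz.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot echoes list of complex 3D arrays, one per echo.
#' @slot tes numeric vector of echo times in seconds, strictly increasing.
#' @slot b0 field strength in Tesla.
#' @export
setClass("ComplexEchoSeries",
  representation(grid = "VolumeGrid", echoes = "list", tes = "numeric", b0 = "numeric"))

setValidity("ComplexEchoSeries", function(object) {
  msg <- character()
  if (length(object@echoes) < 1L) msg <- c(msg, "at least one echo required")
  if (length(object@tes) != length(object@echoes))
    msg <- c(msg, "one echo time per echo required")
  if (length(object@tes) && (any(object@tes <= 0) || any(diff(object@tes) <= 0)))
    msg <- c(msg, "echo times must be positive and strictly increasing")
  shp <- as.integer(object@grid@shape)
  ok <- vapply(object@echoes, function(e) identical(dim(e), shp), logical(1))
  if (!all(ok)) msg <- c(msg, "all echo volumes must share the grid shape")
  if (length(object@b0) != 1L || object@b0 <= 0)
    msg <- c(msg, "b0 must be a positive scalar (Tesla)")
  if (length(msg)) msg else TRUE
})

#' Cardiac phantom parameterization
#'
#' Full specification of the synthetic cardiac phantom: an ellipsoidal
#' myocardial shell containing an angular infarct wedge, region
#' susceptibilities and T2* values, signal amplitudes, SNR, field strength,
#' echo times and RNG seed.  `cardiacPhantomSpec()` builds the default
#' ex-vivo-like profile.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot outerSemiAxes numeric(3), outer semi-axes of the shell (mm).
#' @slot wallThickness shell wall thickness (mm).
#' @slot center numeric(3), shell center in mm from the volume center.
#' @slot infarctCenterAngle center angle of the infarct wedge (degrees).
#' @slot infarctExtent angular extent of the wedge (degrees).
#' @slot transmurality fraction (0, 1] of wall depth infarcted, from the
#'   endocardial surface outward.
#' @slot chiRemote,chiInfarct,chiBackground,chiAir susceptibility (ppm).
#' @slot t2sRemote,t2sInfarct,t2sBlood T2* per region (ms).
#' @slot s0Remote,s0Infarct,s0Blood,s0Background signal amplitude at TE = 0.
#' @slot airRadius radius of a spherical air inclusion (mm); 0 disables it.
#' @slot phi0 receiver phase offset (radians).
#' @slot snr amplitude SNR: s0Remote / noise SD; `Inf` disables noise.
#' @slot b0 field strength (Tesla).
#' @slot tes echo times (seconds).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(grid = "VolumeGrid",
    outerSemiAxes = "numeric", wallThickness = "numeric", center = "numeric",
    infarctCenterAngle = "numeric", infarctExtent = "numeric",
    transmurality = "numeric",
    chiRemote = "numeric", chiInfarct = "numeric", chiBackground = "numeric",
    chiAir = "numeric",
    t2sRemote = "numeric", t2sInfarct = "numeric", t2sBlood = "numeric",
    s0Remote = "numeric", s0Infarct = "numeric", s0Blood = "numeric",
    s0Background = "numeric", airRadius = "numeric",
    phi0 = "numeric", snr = "numeric", b0 = "numeric", tes = "numeric",
    seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@transmurality <= 0 || object@transmurality > 1)
    msg <- c(msg, "transmurality must be in (0, 1]")
  t2s <- c(object@t2sRemote, object@t2sInfarct, object@t2sBlood)
  if (any(t2s < 1) || any(t2s > 200))
    msg <- c(msg, "T2* values must lie in [1, 200] ms")
  if (any(object@tes <= 0) || (length(object@tes) > 1 && any(diff(object@tes) <= 0)))
    msg <- c(msg, "echo times must be positive and strictly increasing")
  if (object@snr <= 0) msg <- c(msg, "snr must be positive")
  if (object@infarctExtent <= 0) msg <- c(msg, "infarct wedge extent must be positive")
  if (object@wallThickness <= 0) msg <- c(msg, "wall thickness must be positive")
  if (length(msg)) msg else TRUE
})

#' Phantom ground truth
#'
#' Label volume and voxelwise true susceptibility, T2* and amplitude maps.
#' Labels: 0 background, 1 remote myocardium, 2 infarct, 3 blood pool, 4 air.
#'
#' @slot chiMap a [SusceptibilityMap-class] of true susceptibility (ppm).
#' @slot t2sMap a [ScalarVolume-class] of true T2* (ms).
#' @slot s0Map a [ScalarVolume-class] of true amplitude.
#' @slot labels 3D integer array of region labels.
#' @export
setClass("PhantomTruth",
  representation(chiMap = "SusceptibilityMap", t2sMap = "ScalarVolume",
    s0Map = "ScalarVolume", labels = "array"))

#' Multi-echo field fit result
#'
#' @slot totalField a [FieldMap-class], kind `"total"`, in ppm.
#' @slot phi0Map a [ScalarVolume-class], receiver phase offset (radians).
#' @slot residualMap a [ScalarVolume-class], weighted RMS fit residual (radians).
#' @export
setClass("FieldFitResult",
  representation(totalField = "FieldMap", phi0Map = "ScalarVolume",
    residualMap = "ScalarVolume"))

#' Dipole inversion configuration
#'
#' Tunables of the morphology-enabled TV-regularized inversion.
#'
#' @slot lambda Lagrangian weight balancing the TV penalty against data
#'   fidelity (fields in ppm, gradients per mm).
#' @slot edgeFraction fraction of in-mask gradient voxels left unpenalized.
#' @slot irlsEpsilon smoothing constant of the IRLS majorizer (ppm/mm).
#' @slot outerIterations maximum outer IRLS iterations.
#' @slot cgTol,cgMaxiter inner conjugate-gradient controls.
#' @slot isotropic logical; isotropic rather than per-axis TV.
#' @export
setClass("InversionConfig",
  representation(lambda = "numeric", edgeFraction = "numeric",
    irlsEpsilon = "numeric", outerIterations = "integer",
    cgTol = "numeric", cgMaxiter = "integer", isotropic = "logical"))

setValidity("InversionConfig", function(object) {
  msg <- character()
  if (object@lambda <= 0) msg <- c(msg, "lambda must be positive")
  if (object@edgeFraction <= 0 || object@edgeFraction >= 1)
    msg <- c(msg, "edgeFraction must be in (0, 1)")
  if (object@irlsEpsilon <= 0) msg <- c(msg, "irlsEpsilon must be positive")
  if (object@outerIterations < 1L) msg <- c(msg, "outerIterations must be >= 1")
  if (object@cgTol <= 0 || object@cgMaxiter < 1L)
    msg <- c(msg, "cgTol must be positive and cgMaxiter >= 1")
  if (length(msg)) msg else TRUE
})

#' Dipole inversion result
#'
#' @slot chi recovered [SusceptibilityMap-class] (ppm), zero outside the mask.
#' @slot objectiveTrace objective value after each outer IRLS iteration.
#' @slot converged logical convergence flag.
#' @slot dataFidelity,regularizer objective terms at exit.
#' @export
setClass("InversionResult",
  representation(chi = "SusceptibilityMap", objectiveTrace = "numeric",
    converged = "logical", dataFidelity = "numeric", regularizer = "numeric"))

#' T2* relaxometry fit result
#'
#' Voxelwise two-parameter monoexponential fit S(TE) = A exp(-TE/T2*), with
#' R2* = 1/T2* and a relative RMS residual error map.
#'
#' @slot aMap amplitude A at TE = 0 (signal units).
#' @slot t2sMap T2* (ms), clamped to [1, 200].
#' @slot r2sMap R2* = 1/T2* (1/ms).
#' @slot errorMap relative RMS residual (dimensionless).
#' @slot clampedMask 3D array flagging voxels that hit the clamp bounds.
#' @slot nClamped number of clamped voxels.
#' @export
setClass("T2StarFitResult",
  representation(aMap = "ScalarVolume", t2sMap = "ScalarVolume",
    r2sMap = "ScalarVolume", errorMap = "ScalarVolume",
    clampedMask = "array", nClamped = "integer"))

#' Region set for ROI analysis
#'
#' Masks for isointense remote myocardium and hyper-/hypointense infarct
#' regions, on one grid; `infarct = hyper | hypo`.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot remote,hyper,hypo,infarct,reference 3D arrays with values in \{0, 1\}.
#' @export
setClass("RegionSet",
  representation(grid = "VolumeGrid", remote = "array", hyper = "array",
    hypo = "array", infarct = "array", reference = "array"))

setValidity("RegionSet", function(object) {
  if (any(object@remote * object@infarct > 0))
    return("remote and infarct regions must be disjoint")
  TRUE
})

#' ROC analysis result
#'
#' ROC curve for infarct (1) vs remote (0) classification with "greater is
#' positive" polarity, AUC by trapezoidal integration (equal to the pairwise
#' concordance probability with ties counted 1/2), and the Youden-optimal
#' operating point.
#'
#' @slot thresholds sorted candidate thresholds (ascending).
#' @slot sensitivity,specificity arrays aligned with `thresholds`.
#' @slot auc area under the curve, in [0, 1].
#' @slot youdenJ max(sensitivity + specificity - 1).
#' @slot optimalThreshold threshold attaining the Youden maximum (lowest on ties).
#' @slot sensOpt,specOpt sensitivity and specificity at the optimum.
#' @export
setClass("RocResult",
  representation(thresholds = "numeric", sensitivity = "numeric",
    specificity = "numeric", auc = "numeric", youdenJ = "numeric",
    optimalThreshold = "numeric", sensOpt = "numeric", specOpt = "numeric"))

setValidity("RocResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
  TRUE
})
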