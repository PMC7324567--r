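#' @include AllClasses.R accessors.R utils-internal.R
NULL

.wrapToPi <- function(x) ((x + pi) %% (2 * pi)) - pi

# Quality-guided spatial unwrap of one phase volume within a mask, by
# region growing from the highest-magnitude voxel: each voxel entering the
# region is shifted by the multiple of 2*pi that best matches the neighbor
# it was reached from.  Exact for smooth phase; used only for the first echo
# and only when wrap-sized jumps are present.
.spatialUnwrap <- function(phase, magnitude, mask) {
  d <- dim(phase)
  nb <- .neighborOffsets(d)
  u <- phase
  inMask <- mask != 0
  if (!any(inMask)) return(u)
  seed <- which(inMask)[which.max(magnitude[inMask])]
  visited <- !inMask
  visited[seed] <- TRUE
  frontier <- as.integer(seed)
  twopi <- 2 * pi
  while (length(frontier)) {
    nxt <- integer(0)
    for (k in 1:6) {
      ok <- nb$valid[[k]](frontier)
      src <- frontier[ok]
      cand <- src + nb$offsets[k]
      keep <- !visited[cand]
      cand <- cand[keep]; src <- src[keep]
      if (length(cand)) {
        u[cand] <- phase[cand] + twopi * round((u[src] - phase[cand]) / twopi)
        visited[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    if (length(nxt)) {
      first <- !duplicated(nxt)
      frontier <- nxt[first]
    } else frontier <- integer(0)
  }
  u
}

# TRUE if any in-mask 6-neighbor phase jump exceeds pi (a wrap signature).
.hasWrapJumps <- function(phase, mask) {
  d <- dim(mask)
  m <- mask != 0
  for (axis in 1:3) {
    n <- d[axis]
    if (axis == 1) {
      dj <- abs(phase[2:n, , , drop = FALSE] - phase[1:(n - 1), , , drop = FALSE])
      mm <- m[2:n, , , drop = FALSE] & m[1:(n - 1), , , drop = FALSE]
    } else if (axis == 2) {
      dj <- abs(phase[, 2:n, , drop = FALSE] - phase[, 1:(n - 1), , drop = FALSE])
      mm <- m[, 2:n, , drop = FALSE] & m[, 1:(n - 1), , drop = FALSE]
    } else {
      dj <- abs(phase[, , 2:n, drop = FALSE] - phase[, , 1:(n - 1), drop = FALSE])
      mm <- m[, , 2:n, drop = FALSE] & m[, , 1:(n - 1), drop = FALSE]
    }
    if (any(dj[mm] > pi)) return(TRUE)
  }
  FALSE
}

#' Unwrap multi-echo phase
#'
#' Temporal unwrapping of a multi-echo series: the per-voxel frequency is
#' estimated from wrapped inter-echo phase differences (valid when the echo
#' spacing keeps successive differences below pi in magnitude), the phase at
#' each echo is predicted from the first-echo phase plus the accrual implied
#' by that frequency, and each wrapped phase is shifted by the integer
#' multiple of 2*pi closest to its prediction.  The first echo itself gets a
#' quality-guided spatial unwrap when wrap-sized spatial jumps are detected
#' inside the mask.  Output phases are congruent to the inputs modulo 2*pi
#' at every voxel by construction.
#'
#' This replaces graph-cut unwrapping with chemical-shift removal used on
#' scanner data: the phantom is water-only, so no chemical-shift term exists,
#' and the contract (integer wrap residuals, correct field recovery) is
#' algorithm-independent.
#'
#' @param series a [ComplexEchoSeries-class] with at least 2 echoes.
#' @param mask a [MaskVolume-class].
#' @return list of unwrapped phase [ScalarVolume-class]s (radians), one per
#'   echo.
#' @export
unwrapPhase <- function(series, mask) {
  stopifnot(is(series, "ComplexEchoSeries"), is(mask, "MaskVolume"))
  .checkSameGrid(series, mask)
  if (length(series@echoes) < 2L)
    stop("at least 2 echoes are required for temporal unwrapping")
  m <- voxelValues(mask) != 0
  if (!any(m)) stop("mask is empty")
  mags <- lapply(series@echoes, Mod)
  if (all(mags[[1]][m] == 0))
    stop("all-zero magnitude inside the mask: no phase information")
  phases <- lapply(series@echoes, Arg)
  tes <- series@tes
  twopi <- 2 * pi
  # frequency from inter-echo differences, magnitude-weighted
  num <- array(0, dim = dim(m)); den <- array(0, dim = dim(m))
  for (j in seq_len(length(phases) - 1)) {
    dphi <- Arg(series@echoes[[j + 1]] * Conj(series@echoes[[j]]))
    w <- mags[[j]] * mags[[j + 1]]
    num <- num + w * dphi / (tes[j + 1] - tes[j])
    den <- den + w
  }
  omega <- num / pmax(den, .Machine$double.eps)   # rad/s
  u1 <- phases[[1]]
  if (.hasWrapJumps(phases[[1]], voxelValues(mask)))
    u1 <- .spatialUnwrap(phases[[1]], mags[[1]], voxelValues(mask))
  out <- vector("list", length(phases))
  out[[1]] <- u1
  for (j in seq_along(phases)[-1]) {
    pred <- u1 + omega * (tes[j] - tes[1])
    out[[j]] <- phases[[j]] + twopi * round((pred - phases[[j]]) / twopi)
  }
  lapply(out, scalarVolume, grid = series@grid, units = "radians")
}

#' Fit the total field from unwrapped multi-echo phase
#'
#' Per-voxel weighted linear least squares of `phi(TE) = phi0 + 2 pi f TE`,
#' with weights equal to the squared echo magnitudes (the maximum-likelihood
#' weighting for complex Gaussian noise).  The slope `f` (Hz) is converted to
#' a normalized field in ppm via `f / (gamma_bar * B0) * 1e6`.
#'
#' @param unwrapped list of unwrapped phase volumes from [unwrapPhase()].
#' @param series the originating [ComplexEchoSeries-class] (for magnitudes,
#'   echo times and B0).
#' @param mask a [MaskVolume-class]; results are zeroed outside.
#' @return a [FieldFitResult-class] with total field (ppm), phi0 map
#'   (radians) and weighted-RMS residual map (radians).
#' @export
fitTotalField <- function(unwrapped, series, mask) {
  stopifnot(is(series, "ComplexEchoSeries"), is(mask, "MaskVolume"))
  .checkSameGrid(series, mask)
  nEcho <- length(series@echoes)
  if (nEcho < 2L)
    stop("field fitting needs >= 2 echoes: slope and intercept are not jointly identifiable from one echo")
  if (length(unwrapped) != nEcho) stop("one unwrapped phase volume per echo required")
  shp <- series@grid@shape
  m <- voxelValues(mask)
  tes <- series@tes
  ph <- lapply(unwrapped, function(u) if (is(u, "ScalarVolume")) u@values else u)
  w <- lapply(series@echoes, function(e) Mod(e)^2)
  # weighted normal equations, vectorized across voxels
  Sw <- Swt <- Swt2 <- Swy <- Swty <- array(0, dim = shp)
  for (j in seq_len(nEcho)) {
    Sw <- Sw + w[[j]]
    Swt <- Swt + w[[j]] * tes[j]
    Swt2 <- Swt2 + w[[j]] * tes[j]^2
    Swy <- Swy + w[[j]] * ph[[j]]
    Swty <- Swty + w[[j]] * ph[[j]] * tes[j]
  }
  det <- Sw * Swt2 - Swt^2
  det[det == 0] <- NA
  slope <- (Sw * Swty - Swt * Swy) / det          # rad/s
  phi0 <- (Swt2 * Swy - Swt * Swty) / det
  fHz <- slope / (2 * pi)
  ppm <- fHz / (gyromagneticRatio() * series@b0) * 1e6
  res2 <- array(0, dim = shp)
  for (j in seq_len(nEcho)) {
    r <- ph[[j]] - (phi0 + slope * tes[j])
    res2 <- res2 + w[[j]] * r^2
  }
  resid <- sqrt(res2 / pmax(Sw, .Machine$double.eps))
  ppm[is.na(ppm)] <- 0; phi0[is.na(phi0)] <- 0; resid[is.na(resid)] <- 0
  ppm <- ppm * m; phi0 <- phi0 * m; resid <- resid * m
  new("FieldFitResult",
      totalField = fieldMap(ppm, grid = series@grid, kind = "total"),
      phi0Map = scalarVolume(phi0, grid = series@grid, units = "radians"),
      residualMap = scalarVolume(resid, grid = series@grid, units = "radians"))
}

#' Threshold-based tissue mask from echo magnitudes
#'
#' The mask is generated by thresholding the first-echo magnitude image:
#' voxels above `relThreshold` times the 99th percentile of the magnitude are
#' kept, the largest 6-connected component is retained, and the result is
#' eroded by one voxel to drop unreliable boundary phase.
#'
#' @param series a [ComplexEchoSeries-class].
#' @param relThreshold relative threshold in (0, 1); default 0.15.
#' @return a [MaskVolume-class]
#' @export
makeMask <- function(series, relThreshold = 0.15) {
  stopifnot(is(series, "ComplexEchoSeries"))
  if (relThreshold <= 0 || relThreshold >= 1)
    stop("relThreshold must be in (0, 1)")
  mag <- Mod(series@echoes[[1]])
  ref <- stats::quantile(mag, 0.99, names = FALSE)
  thr <- relThreshold * ref
  keep <- mag > thr
  if (!any(keep))
    stop(sprintf("empty mask: no voxels above threshold %.4g (99th percentile %.4g)",
                 thr, ref))
  keep <- .largestComponent(keep)
  er <- .erodeOnce(keep)
  if (!any(er))
    stop(sprintf("mask vanished after 1-voxel erosion (threshold %.4g); lower relThreshold", thr))
  maskVolume(array(as.numeric(er), dim = dim(er)), grid = series@grid)
}

#' Per-voxel SNR weight from echo magnitudes
#'
#' W is the root-sum-of-squares of the echo magnitudes, zeroed outside the
#' mask and normalized to mean 1 over the mask.  It weights the data-fidelity
#' terms of background removal and dipole inversion.
#'
#' @param series a [ComplexEchoSeries-class].
#' @param mask a [MaskVolume-class].
#' @return a [WeightVolume-class]
#' @export
computeNoiseWeight <- function(series, mask) {
  stopifnot(is(series, "ComplexEchoSeries"), is(mask, "MaskVolume"))
  .checkSameGrid(series, mask)
  m <- voxelValues(mask)
  if (!any(m != 0)) stop("mask is empty")
  ss <- Reduce(`+`, lapply(series@echoes, function(e) Mod(e)^2))
  w <- sqrt(ss) * m
  w <- w / mean(w[m != 0])
  new("WeightVolume", grid = series@grid, values = w, units = "arbitrary")
}
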