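#' @include AllClasses.R accessors.R utils-internal.R
NULL

#' Classify iso/hyper/hypo regions on a T2*-weighted image
#'
#' Deterministic replacement for interactive active-contour segmentation:
#' intensity statistics (mu, sigma) are taken from a seed region known a
#' priori to be remote myocardium; in-mask voxels below `mu - kSd * sigma`
#' are hypointense, above `mu + kSd * sigma` hyperintense, the remainder
#' isointense (remote).  Infarct = hyper + hypo.  Externally drawn masks can
#' be substituted for any component downstream.
#'
#' @param t2sw a [ScalarVolume-class] (T2*-weighted magnitude).
#' @param tissueMask a [MaskVolume-class] restricting the classification.
#' @param remoteSeedMask a [MaskVolume-class]; nonempty seed of known remote
#'   tissue (in the phantom, drawn from truth labels).
#' @param kSd threshold in remote SDs; default 2.
#' @return a [RegionSet-class]
#' @export
classifyT2swRegions <- function(t2sw, tissueMask, remoteSeedMask, kSd = 2) {
  stopifnot(is(t2sw, "ScalarVolume"), is(tissueMask, "MaskVolume"),
            is(remoteSeedMask, "MaskVolume"))
  .checkSameGrid(t2sw, tissueMask, remoteSeedMask)
  v <- voxelValues(t2sw)
  m <- voxelValues(tissueMask) != 0
  seed <- voxelValues(remoteSeedMask) != 0
  if (!any(seed)) stop("remote seed mask is empty")
  mu <- mean(v[seed])
  sigma <- stats::sd(v[seed])
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate remote reference: zero intensity variance in the seed region")
  shp <- dim(v)
  hypo <- array(as.numeric(m & v < mu - kSd * sigma), dim = shp)
  hyper <- array(as.numeric(m & v > mu + kSd * sigma), dim = shp)
  infarct <- array(as.numeric(hypo + hyper > 0), dim = shp)
  remote <- array(as.numeric(m & infarct == 0), dim = shp)
  new("RegionSet", grid = t2sw@grid, remote = remote, hyper = hyper,
      hypo = hypo, infarct = infarct, reference = remote)
}

#' Reference a susceptibility map to a region
#'
#' Subtracts the mean susceptibility over a reference region (typically
#' remote myocardium) from the whole map.  The absolute susceptibility
#' offset is unobservable (the dipole kernel has D(0) = 0), so reported
#' values are always differences against the reference; referencing is
#' idempotent and preserves all pairwise contrasts.
#'
#' @param chi a [SusceptibilityMap-class].
#' @param referenceMask a [MaskVolume-class] or 0/1 array.
#' @return a [SusceptibilityMap-class] with zero mean over the reference.
#' @export
referenceSusceptibility <- function(chi, referenceMask) {
  stopifnot(is(chi, "SusceptibilityMap"))
  ref <- if (is(referenceMask, "MaskVolume")) voxelValues(referenceMask) else referenceMask
  ref <- ref != 0
  if (!any(ref)) stop("reference mask is empty")
  susceptibilityMap(chi@values - mean(chi@values[ref]), grid = chi@grid)
}

#' Full-width-at-half-maximum infarct mask
#'
#' Threshold rule for infarct sizing on enhancement-like images: with remote
#' mean `r` and myocardial maximum `M`, keep myocardial voxels at or above
#' `r + 0.5 (M - r)` (variant `"half_max"`: at or above `0.5 M`).  Anchoring
#' the half-maximum to the remote mean makes the rule invariant to affine
#' intensity rescaling.
#'
#' @param lgeLike a [ScalarVolume-class] with infarct-bright contrast.
#' @param myocardiumMask a [MaskVolume-class] of the myocardium.
#' @param remoteMask a [MaskVolume-class] of remote myocardium.
#' @param variant `"remote_anchored"` (default) or `"half_max"`.
#' @return a [MaskVolume-class]; empty with a warning when there is no
#'   enhancement above the remote mean.
#' @export
fwhmInfarctMask <- function(lgeLike, myocardiumMask, remoteMask,
                            variant = c("remote_anchored", "half_max")) {
  variant <- match.arg(variant)
  stopifnot(is(lgeLike, "ScalarVolume"), is(myocardiumMask, "MaskVolume"),
            is(remoteMask, "MaskVolume"))
  .checkSameGrid(lgeLike, myocardiumMask, remoteMask)
  v <- voxelValues(lgeLike)
  myo <- voxelValues(myocardiumMask) != 0
  rem <- voxelValues(remoteMask) != 0
  if (!any(myo) || !any(rem)) stop("myocardium and remote masks must be nonempty")
  remoteMean <- mean(v[rem])
  peak <- max(v[myo])
  thr <- if (variant == "remote_anchored") remoteMean + 0.5 * (peak - remoteMean)
         else 0.5 * peak
  if (peak <= remoteMean) {
    warning("no enhancement above the remote mean; returning an empty infarct mask")
    return(maskVolume(array(0, dim = dim(v)), grid = lgeLike@grid))
  }
  maskVolume(array(as.numeric(myo & v >= thr), dim = dim(v)),
             grid = lgeLike@grid)
}

#' ROC curve, AUC and Youden-optimal operating point
#'
#' Computes the ROC curve for classifying infarct (label 1) versus remote
#' (label 0) voxels or ROIs from a scalar predictor, with "greater is
#' positive" polarity.  Thresholds sweep the unique predictor values
#' (prediction: positive when value >= threshold).  AUC is obtained by
#' trapezoidal integration of sensitivity against 1 - specificity with tied
#' values grouped, which equals the pairwise concordance probability with
#' ties counted 1/2 (the Mann-Whitney statistic).  The optimal operating
#' point maximizes Youden's J = sensitivity + specificity - 1; at ties the
#' lowest threshold is reported.
#'
#' @param values numeric predictor (e.g. susceptibility in ppm).
#' @param labels binary labels, 1 = infarct, 0 = remote.
#' @return a [RocResult-class]
#' @examples
#' rocCurve(c(1, 3, 2, 4), c(0, 0, 1, 1))@auc  # 0.75
#' @export
rocCurve <- function(values, labels) {
  values <- as.numeric(values)
  labels <- as.integer(labels != 0)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes (infarct = 1, remote = 0) must be present")
  o <- order(values)
  vSorted <- values[o]; lSorted <- labels[o]
  newGrp <- !duplicated(vSorted)
  grp <- cumsum(newGrp)
  thr <- vSorted[newGrp]
  nGrp <- length(thr)
  # counts of each class at each unique value
  posAt <- tabulate(grp[lSorted == 1L], nbins = nGrp)
  negAt <- tabulate(grp[lSorted == 0L], nbins = nGrp)
  # predict positive when value >= threshold
  tp <- rev(cumsum(rev(posAt)))
  fp <- rev(cumsum(rev(negAt)))
  sens <- tp / nPos
  spec <- 1 - fp / nNeg
  # trapezoid over the full curve from (0,0) [threshold above max] to (1,1)
  fpr <- c(0, rev(fp) / nNeg, 1)
  tpr <- c(0, rev(tp) / nPos, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[1]  # thresholds ascending: lowest threshold on ties
  new("RocResult", thresholds = thr, sensitivity = sens, specificity = spec,
      auc = auc, youdenJ = j[best], optimalThreshold = thr[best],
      sensOpt = sens[best], specOpt = spec[best])
}

#' Per-region summary statistics
#'
#' Exact n, mean, sample SD (n - 1 denominator) and median of a map over
#' each region of a [RegionSet-class], as a tidy table ready for downstream
#' group statistics.  Empty regions are reported with n = 0 and missing
#' statistics.
#'
#' @param map a [ScalarVolume-class] (chi in ppm, T2* in ms, ...).
#' @param regions a [RegionSet-class], or a named list of masks/0-1 arrays.
#' @return data.frame with columns region, n, mean, sd, median, units.
#' @export
regionStats <- function(map, regions) {
  stopifnot(is(map, "ScalarVolume"))
  v <- voxelValues(map)
  if (is(regions, "RegionSet"))
    regions <- list(remote = regions@remote, hyper = regions@hyper,
                    hypo = regions@hypo, infarct = regions@infarct)
  rows <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    if (is(r, "MaskVolume")) r <- voxelValues(r)
    sel <- v[r != 0]
    sel <- sel[!is.na(sel)]
    if (length(sel) == 0)
      data.frame(region = nm, n = 0L, mean = NA_real_, sd = NA_real_,
                 median = NA_real_)
    else
      data.frame(region = nm, n = length(sel), mean = mean(sel),
                 sd = if (length(sel) > 1) stats::sd(sel) else 0,
                 median = stats::median(sel))
  })
  out <- do.call(rbind, rows)
  out$units <- map@units
  out
}
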