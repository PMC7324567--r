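#' @include AllClasses.R accessors.R utils-internal.R
NULL

#' Voxelwise two-parameter T2* fit
#'
#' Fits the monoexponential decay `S(TE) = A exp(-TE/T2*)` to the echo
#' magnitudes of every in-mask voxel.  Initialization is a weighted
#' log-linear regression of `ln S` on TE with weights `S^2` (which undoes the
#' log-transform variance distortion), followed by vectorized Gauss-Newton
#' refinement of the nonlinear least-squares problem on the magnitude data.
#' T2* is clamped to [1, 200] ms with clamped voxels flagged and counted;
#' R2* = 1/T2*; the error map is the RMS fit residual divided by the fitted
#' amplitude A (relative RMS residual).
#'
#' @param series a [ComplexEchoSeries-class] (magnitudes are used).
#' @param mask a [MaskVolume-class]; voxels outside get NA results.
#' @param clampMs numeric(2) clamp range for T2* in ms; default `c(1, 200)`.
#' @param maxIter Gauss-Newton iterations; default 25.
#' @return a [T2StarFitResult-class]
#' @examples
#' tes <- c(3.3, 6.5, 9.7, 12.9, 16.1) * 1e-3
#' sig <- lapply(tes, function(te) array(100 * exp(-te / 0.020) + 0i, c(4, 4, 4)))
#' fit <- fitT2Star(complexEchoSeries(sig, tes), maskVolume(array(1, c(4, 4, 4))))
#' voxelValues(fit@t2sMap)[1, 1, 1]  # 20 ms
#' @export
fitT2Star <- function(series, mask, clampMs = c(1, 200), maxIter = 25L) {
  stopifnot(is(series, "ComplexEchoSeries"), is(mask, "MaskVolume"))
  .checkSameGrid(series, mask)
  nEcho <- length(series@echoes)
  if (nEcho < 2L) stop("T2* fitting needs >= 2 echoes")
  if (any(diff(series@tes) <= 0)) stop("echo times must be strictly increasing")
  shp <- series@grid@shape
  m <- voxelValues(mask) != 0
  idx <- which(m)
  tesMs <- series@tes * 1e3
  S <- vapply(series@echoes, function(e) Mod(e)[idx], numeric(length(idx)))
  if (!is.matrix(S)) S <- matrix(S, nrow = length(idx))
  dead <- rowSums(S) == 0
  # weighted log-linear initialization: ln S = ln A - TE/T2*, weights S^2
  eps <- .Machine$double.xmin
  L <- log(pmax(S, eps))
  W <- S^2
  sw <- rowSums(W)
  swt <- rowSums(sweep(W, 2, tesMs, `*`))
  swt2 <- rowSums(sweep(W, 2, tesMs^2, `*`))
  swl <- rowSums(W * L)
  swtl <- rowSums(W * sweep(L, 2, tesMs, `*`))
  det <- sw * swt2 - swt^2
  det[det == 0] <- NA
  slope <- (sw * swtl - swt * swl) / det      # = -1/T2* (1/ms)
  interc <- (swt2 * swl - swt * swtl) / det   # = ln A
  r <- pmin(pmax(-slope, 1 / clampMs[2]), 1 / clampMs[1])  # decay rate 1/ms
  a <- pmin(pmax(interc, log(eps)), 700)                   # log amplitude
  # Gauss-Newton on S = exp(a - r * TE)
  for (it in seq_len(maxIter)) {
    Fhat <- exp(outer(a, rep(1, nEcho)) - outer(r, tesMs))
    R <- S - Fhat
    # Jacobian columns: dS/da = Fhat, dS/dr = -TE * Fhat
    Jaa <- rowSums(Fhat^2)
    Jar <- -rowSums(sweep(Fhat^2, 2, tesMs, `*`))
    Jrr <- rowSums(sweep(Fhat^2, 2, tesMs^2, `*`))
    ga <- rowSums(Fhat * R)
    gr <- -rowSums(sweep(Fhat * R, 2, tesMs, `*`))
    det2 <- Jaa * Jrr - Jar^2
    ok <- is.finite(det2) & det2 > eps
    da <- ifelse(ok, (Jrr * ga - Jar * gr) / det2, 0)
    dr <- ifelse(ok, (Jaa * gr - Jar * ga) / det2, 0)
    # damped step to keep the exponential well-behaved
    da <- pmin(pmax(da, -2), 2)
    dr <- pmin(pmax(dr, -0.5), 0.5)
    a <- a + da
    r <- pmin(pmax(r + dr, 1 / clampMs[2]), 1 / clampMs[1])
    if (max(abs(da), abs(dr)) < 1e-12) break
  }
  t2s <- 1 / r
  clamped <- (t2s <= clampMs[1] + 1e-9) | (t2s >= clampMs[2] - 1e-9)
  A <- exp(a)
  Fhat <- exp(outer(a, rep(1, nEcho)) - outer(r, tesMs))
  rmse <- sqrt(rowMeans((S - Fhat)^2))
  errRel <- rmse / pmax(A, eps)
  t2s[dead] <- NA_real_; A[dead] <- NA_real_; errRel[dead] <- NA_real_
  clamped[dead] <- FALSE
  put <- function(x, fill = NA_real_) {
    out <- array(fill, dim = shp); out[idx] <- x; out
  }
  t2sArr <- put(t2s)
  new("T2StarFitResult",
      aMap = scalarVolume(put(A), grid = series@grid, units = "arbitrary"),
      t2sMap = scalarVolume(t2sArr, grid = series@grid, units = "ms"),
      r2sMap = scalarVolume(put(1 / t2s), grid = series@grid, units = "1/ms"),
      errorMap = scalarVolume(put(errRel), grid = series@grid, units = "arbitrary"),
      clampedMask = put(as.numeric(clamped), fill = 0),
      nClamped = as.integer(sum(clamped, na.rm = TRUE)))
}

#' T2*-weighted image at a chosen echo
#'
#' The magnitude image of the selected echo; regions with short T2* (iron,
#' hemorrhage) appear hypointense at late echoes, which is the contrast used
#' to delineate infarct sub-regions.
#'
#' @param series a [ComplexEchoSeries-class].
#' @param echoIndex 1-based echo index; defaults to the last echo.
#' @return a [ScalarVolume-class] (arbitrary units)
#' @export
t2swImage <- function(series, echoIndex = length(series@echoes)) {
  stopifnot(is(series, "ComplexEchoSeries"))
  if (echoIndex < 1L || echoIndex > length(series@echoes))
    stop(sprintf("echoIndex %d out of range 1..%d", echoIndex, length(series@echoes)))
  scalarVolume(Mod(series@echoes[[echoIndex]]), grid = series@grid,
               units = "arbitrary")
}
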