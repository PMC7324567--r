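#' @include AllClasses.R
NULL

# DFT frequency samples in cycles/mm for axis length n, spacing d (mm),
# in FFT storage order (0, positive, negative).
.fftFreq <- function(n, d) {
  i <- 0:(n - 1)
  i[i > (n - 1) %/% 2] <- i[i > (n - 1) %/% 2] - n
  i / (n * d)
}

.fftn <- function(x) stats::fft(x)
.ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Preconditioner-free conjugate gradient for SPD operators on arrays.
# applyA: function(array) -> array.  Returns list(x, iterations, relres,
# converged).
.conjugateGradient <- function(applyA, b, x0 = NULL, tol = 1e-6, maxiter = 100L) {
  x <- if (is.null(x0)) array(0, dim = dim(b)) else x0
  r <- b - applyA(x)
  p <- r
  rs <- sum(r * r)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) bnorm <- 1
  it <- 0L
  while (it < maxiter && sqrt(rs) / bnorm > tol) {
    Ap <- applyA(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) break  # numerical loss of positive-definiteness
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  relres <- sqrt(rs) / bnorm
  list(x = x, iterations = it, relres = relres, converged = relres <= tol)
}

# 6-connectivity binary erosion of a logical array, one step; voxels touching
# the volume boundary are eroded (outside counts as background).
.erodeOnce <- function(m) {
  d <- dim(m)
  r <- m
  pad <- function(arr, axis, dir) {
    # neighbor value along axis in direction dir, FALSE beyond the boundary
    out <- array(FALSE, dim = d)
    if (axis == 1) {
      if (dir > 0) out[1:(d[1] - 1), , ] <- arr[2:d[1], , ]
      else out[2:d[1], , ] <- arr[1:(d[1] - 1), , ]
    } else if (axis == 2) {
      if (dir > 0) out[, 1:(d[2] - 1), ] <- arr[, 2:d[2], ]
      else out[, 2:d[2], ] <- arr[, 1:(d[2] - 1), ]
    } else {
      if (dir > 0) out[, , 1:(d[3] - 1)] <- arr[, , 2:d[3]]
      else out[, , 2:d[3]] <- arr[, , 1:(d[3] - 1)]
    }
    out
  }
  for (axis in 1:3) for (dir in c(-1, 1)) r <- r & pad(m, axis, dir)
  r
}

.erodeTimes <- function(m, times) {
  for (i in seq_len(times)) m <- .erodeOnce(m)
  m
}

# Linear-index offsets of the 6-neighborhood, with a validity predicate that
# rejects neighbors wrapping across array faces.
.neighborOffsets <- function(d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  list(
    offsets = c(-1L, 1L, -nx, nx, -nx * ny, nx * ny),
    valid = list(
      function(i) ((i - 1L) %% nx) != 0L,         # -x: not at x = 1
      function(i) ((i - 1L) %% nx) != (nx - 1L),  # +x: not at x = nx
      function(i) (((i - 1L) %/% nx) %% ny) != 0L,
      function(i) (((i - 1L) %/% nx) %% ny) != (ny - 1L),
      function(i) ((i - 1L) %/% (nx * ny)) != 0L,
      function(i) ((i - 1L) %/% (nx * ny)) != (nz - 1L)
    ))
}

# Flood fill (6-connectivity) from seed over TRUE voxels of `m`; returns a
# logical array of the reached component.  Frontier expansion is vectorized.
.floodFill <- function(m, seed) {
  d <- dim(m)
  nb <- .neighborOffsets(d)
  visited <- array(FALSE, dim = d)
  visited[seed] <- TRUE
  frontier <- as.integer(seed)
  while (length(frontier)) {
    nxt <- integer(0)
    for (k in 1:6) {
      ok <- nb$valid[[k]](frontier)
      cand <- frontier[ok] + nb$offsets[k]
      cand <- cand[m[cand] & !visited[cand]]
      if (length(cand)) {
        visited[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
  }
  visited
}

# Largest 6-connected component of a logical array.
.largestComponent <- function(m) {
  remaining <- m
  best <- NULL
  bestn <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- .floodFill(remaining, seed)
    n <- sum(comp)
    if (n > bestn) { best <- comp; bestn <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) m else best
}

.checkSameGrid <- function(...) {
  grids <- lapply(list(...), gridGeometry)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(g@shape, ref@shape) ||
        max(abs(g@voxelSize - ref@voxelSize)) > 1e-9 ||
        max(abs(g@b0Direction - ref@b0Direction)) > 1e-9)
      stop("inputs must share one VolumeGrid (shape, voxel size, B0 direction)")
  }
  invisible(ref)
}
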