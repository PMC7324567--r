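# Shared fixtures: small, fast phantoms and independent oracles.

# Desk-scale ex vivo phantom: 48^3 at 1.8 mm keeps the published heart
# geometry (86.4 mm extent) while every stage runs in seconds.
smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(shape = c(48, 48, 48), voxelSizeMm = 1.8)
  do.call(cardiacPhantomSpec, utils::modifyList(defaults, args))
}

smallPhantom <- function(...) {
  spec <- smallSpec(...)
  truth <- buildPhantom(spec)
  list(spec = spec, truth = truth, series = synthesizeEchoes(truth, spec))
}

# Brute-force AUC oracle: pairwise concordance with ties counted 1/2.
aucByConcordance <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force per-voxel weighted least-squares line fit (normal equations
# assembled longhand), the oracle for fitTotalField.
wlsSlopeOracle <- function(phis, tes, wts) {
  A <- cbind(1, tes)
  W <- diag(wts)
  beta <- solve(t(A) %*% W %*% A, t(A) %*% W %*% phis)
  list(phi0 = beta[1], slope = beta[2])
}

# Elementwise objective evaluation, independent of the package's FFT
# plumbing except for the dipole convolution itself being re-derived here
# from first principles (explicit DFT on a tiny grid).
objectiveBruteForce <- function(chi, phi, w, M, lambda, voxelSize) {
  d <- dim(chi)
  n <- prod(d)
  # explicit DFT dipole convolution
  f1 <- function(nn, dd) {
    i <- 0:(nn - 1); i[i > (nn - 1) %/% 2] <- i[i > (nn - 1) %/% 2] - nn
    i / (nn * dd)
  }
  kx <- f1(d[1], voxelSize[1]); ky <- f1(d[2], voxelSize[2]); kz <- f1(d[3], voxelSize[3])
  KX <- array(kx, d); KY <- array(rep(ky, each = d[1]), d)
  KZ <- array(rep(kz, each = d[1] * d[2]), d)
  k2 <- KX^2 + KY^2 + KZ^2
  D <- 1 / 3 - KZ^2 / k2
  D[k2 == 0] <- 0
  field <- Re(fft(D * fft(chi), inverse = TRUE)) / n
  fid <- sum((w * (field - phi))^2)
  reg <- 0
  for (axis in 1:3) {
    g <- array(0, d)
    nn <- d[axis]
    if (axis == 1) g[1:(nn - 1), , ] <- chi[2:nn, , ] - chi[1:(nn - 1), , ]
    if (axis == 2) g[, 1:(nn - 1), ] <- chi[, 2:nn, ] - chi[, 1:(nn - 1), ]
    if (axis == 3) g[, , 1:(nn - 1)] <- chi[, , 2:nn] - chi[, , 1:(nn - 1)]
    reg <- reg + sum(abs(M[, , , axis] * g / voxelSize[axis]))
  }
  lambda * reg + fid
}

# Random smooth susceptibility texture supported on a mask (for PDF and
# inversion property tests).
smoothTexture <- function(n, corrK = 0.2, sdPpm = 0.1, mask = NULL, seed = 11) {
  set.seed(seed)
  tex <- array(stats::rnorm(n^3), c(n, n, n))
  f1 <- function(nn) { i <- 0:(nn - 1); i[i > (nn - 1) %/% 2] <- i[i > (nn - 1) %/% 2] - nn; i / nn }
  fx <- f1(n)
  FX <- array(fx, c(n, n, n)); FY <- array(rep(fx, each = n), c(n, n, n))
  FZ <- array(rep(fx, each = n^2), c(n, n, n))
  lp <- exp(-(FX^2 + FY^2 + FZ^2) / (2 * corrK^2))
  sm <- Re(stats::fft(stats::fft(tex) * lp, inverse = TRUE)) / n^3
  if (is.null(mask)) mask <- array(TRUE, c(n, n, n))
  sm <- sm / stats::sd(sm[mask]) * sdPpm
  sm * as.numeric(mask)
}

# Spherical mask + unit weight on an isotropic grid.
sphericalMaskFixture <- function(n, radius) {
  g <- volumeGrid(c(n, n, n))
  co <- (1:n) - (n / 2 + 0.5)
  X <- array(co, c(n, n, n)); Y <- array(rep(co, each = n), c(n, n, n))
  Z <- array(rep(co, each = n^2), c(n, n, n))
  r <- sqrt(X^2 + Y^2 + Z^2)
  m <- r <= radius
  mask <- maskVolume(array(as.numeric(m), c(n, n, n)), grid = g)
  w <- new("WeightVolume", grid = g,
           values = array(as.numeric(m), c(n, n, n)), units = "arbitrary")
  list(grid = g, mask = mask, weight = w, r = r, inMask = m)
}
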