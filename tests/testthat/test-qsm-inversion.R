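test_that("spatial gradient and its adjoint are exact companions", {
  set.seed(13)
  vs <- c(0.9, 1.1, 1.4)
  v <- array(rnorm(10 * 12 * 14), c(10, 12, 14))
  w <- lapply(1:3, function(i) array(rnorm(10 * 12 * 14), c(10, 12, 14)))
  g <- spatialGradient(v, vs)
  gt <- spatialGradientAdjoint(w, vs)
  lhs <- sum(g[[1]] * w[[1]]) + sum(g[[2]] * w[[2]]) + sum(g[[3]] * w[[3]])
  rhs <- sum(v * gt)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  # constant volume: zero gradients
  gc <- spatialGradient(array(5, c(6, 6, 6)), c(1, 1, 1))
  expect_identical(max(abs(gc[[1]])), 0)
  # linear ramp a*x: x-gradient constant a (interior), others 0
  n <- 8
  ramp <- array(rep(2.5 * (1:n)), c(n, n, n))
  gr <- spatialGradient(ramp, c(1, 1, 1))
  expect_true(all(abs(gr[[1]][1:(n - 1), , ] - 2.5) < 1e-12))
  expect_identical(max(abs(gr[[2]])), 0)
  expect_identical(max(abs(gr[[3]])), 0)
})

test_that("edge mask marks magnitude edges and honors the requested fraction", {
  n <- 24
  g <- volumeGrid(c(n, n, n))
  mask <- maskVolume(array(1, c(n, n, n)), grid = g)
  # uniform magnitude: no structure, full penalization
  su <- complexEchoSeries(list(array(7 + 0i, c(n, n, n))), 1e-3, grid = g)
  Mu <- voxelValues(computeEdgeMask(su, mask, 0.3))
  expect_identical(min(Mu), 1)
  # two-compartment step: x-direction edge exactly on the interface
  stepMag <- array(1, c(n, n, n)); stepMag[13:n, , ] <- 2
  ss <- complexEchoSeries(list(stepMag + 0i), 1e-3, grid = g)
  Ms <- voxelValues(computeEdgeMask(ss, mask, 0.04))
  expect_true(all(Ms[12, , , 1] == 0))       # forward difference at the step
  expect_true(all(Ms[c(1:11, 13:n), , , 1] == 1))
  # fraction contract on a continuous image
  set.seed(3)
  randMag <- array(abs(rnorm(n^3)) + 1, c(n, n, n))
  sr <- complexEchoSeries(list(randMag + 0i), 1e-3, grid = g)
  Mr <- voxelValues(computeEdgeMask(sr, mask, 0.3))
  for (axis in 1:3)
    expect_equal(mean(Mr[, , , axis] == 0), 0.3, tolerance = 0.07)
  expect_error(computeEdgeMask(sr, mask, 1.2), "edgeFraction")
})

test_that("objective evaluation matches an independent brute-force computation", {
  n <- 8
  g <- volumeGrid(c(n, n, n), voxelSize = c(1.1, 0.9, 1.3))
  set.seed(5)
  for (rep in 1:3) {
    chi <- array(rnorm(n^3, sd = 0.1), c(n, n, n))
    phi <- array(rnorm(n^3, sd = 0.05), c(n, n, n))
    wArr <- array(abs(rnorm(n^3)) + 0.5, c(n, n, n))
    Marr <- array(sample(c(0, 1), n^3 * 3, replace = TRUE), c(n, n, n, 3))
    w <- new("WeightVolume", grid = g, values = wArr, units = "arbitrary")
    M <- new("EdgeMask", grid = g, values = Marr, edgeFraction = 0.5)
    lambda <- 0.002
    got <- evaluateObjective(chi, fieldMap(phi, grid = g, kind = "local"),
                             w, M, lambda)
    want <- objectiveBruteForce(chi, phi, wArr, Marr, lambda, c(1.1, 0.9, 1.3))
    expect_lt(abs(got$objective - want) / want, 1e-10)
  }
  # closed-form corners
  z <- array(0, c(n, n, n))
  wu <- new("WeightVolume", grid = g, values = array(1, c(n, n, n)), units = "arbitrary")
  Mu <- new("EdgeMask", grid = g, values = array(1, c(n, n, n, 3)), edgeFraction = 0.5)
  expect_identical(evaluateObjective(z, fieldMap(z, grid = g, kind = "local"),
                                     wu, Mu, 1)$objective, 0)
  phi <- array(rnorm(n^3), c(n, n, n))
  expect_equal(evaluateObjective(z, fieldMap(phi, grid = g, kind = "local"),
                                 wu, Mu, 1)$objective, sum(phi^2))
})

test_that("a zero field inverts to a zero susceptibility map", {
  fx <- sphericalMaskFixture(24, 8)
  loc <- fieldMap(array(0, c(24, 24, 24)), grid = fx$grid, kind = "local")
  M <- new("EdgeMask", grid = fx$grid, values = array(1, c(24, 24, 24, 3)),
           edgeFraction = 0.3)
  res <- mediInvert(loc, fx$weight, M, fx$mask, inversionConfig())
  expect_identical(max(abs(voxelValues(res@chi))), 0)
})

test_that("the IRLS objective trace is non-increasing and chi vanishes outside the mask", {
  spec <- smallSpec(snr = 40, seed = 23)
  truth <- buildPhantom(spec)
  series <- synthesizeEchoes(truth, spec)
  mask <- makeMask(series, 0.15)
  fit <- fitTotalField(unwrapPhase(series, mask), series, mask)
  w <- computeNoiseWeight(series, mask)
  edge <- computeEdgeMask(series, mask, 0.3)
  loc <- fieldMap(voxelValues(fit@totalField) * voxelValues(mask),
                  grid = series@grid, kind = "local")
  res <- suppressWarnings(mediInvert(loc, w, edge, mask,
    inversionConfig(outerIterations = 6, cgMaxiter = 25)))
  tr <- res@objectiveTrace
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) <= 1e-10 * abs(tr[-length(tr)])))
  expect_identical(max(abs(voxelValues(res@chi)[voxelValues(mask) == 0])), 0)
})

test_that("a sphere inverts back to its susceptibility at small lambda", {
  n <- 48
  g <- volumeGrid(c(n, n, n))
  k <- dipoleKernel(g)
  chi <- sphereSusceptibility(g, 6, 1, center = c(0.5, 0.5, 0.5))
  phi <- simulateField(chi, kernel = k)
  co <- (1:n) - (n / 2 + 0.5) - 0.5
  X <- array(co, c(n, n, n)); Y <- array(rep(co, each = n), c(n, n, n))
  Z <- array(rep(co, each = n^2), c(n, n, n))
  r <- sqrt(X^2 + Y^2 + Z^2)
  mask <- maskVolume(array(as.numeric(r <= 14), c(n, n, n)), grid = g)
  w <- new("WeightVolume", grid = g,
           values = array(as.numeric(r <= 14), c(n, n, n)), units = "arbitrary")
  M <- new("EdgeMask", grid = g, values = array(1, c(n, n, n, 3)),
           edgeFraction = 0.3)
  loc <- fieldMap(voxelValues(phi) * voxelValues(mask), grid = g, kind = "local")
  res <- suppressWarnings(mediInvert(loc, w, M, mask,
    inversionConfig(lambda = 1e-6, outerIterations = 4, cgMaxiter = 200), kernel = k))
  inner <- r <= 4
  expect_gt(mean(voxelValues(res@chi)[inner]), 0.9)
  expect_lt(mean(voxelValues(res@chi)[inner]), 1.1)
})

test_that("the unregularized normal equations scale linearly with the field", {
  fx <- sphericalMaskFixture(24, 8)
  k <- dipoleKernel(fx$grid)
  chi <- smoothTexture(24, 0.25, 0.1, mask = fx$inMask, seed = 8)
  phi <- voxelValues(simulateField(susceptibilityMap(chi, grid = fx$grid), kernel = k))
  M <- new("EdgeMask", grid = fx$grid, values = array(1, c(24, 24, 24, 3)),
           edgeFraction = 0.3)
  run <- function(phiv) voxelValues(suppressWarnings(mediInvert(
    fieldMap(phiv * as.numeric(fx$inMask), grid = fx$grid, kind = "local"),
    fx$weight, M, fx$mask,
    inversionConfig(lambda = 1e-14, outerIterations = 1, cgMaxiter = 200),
    kernel = k))@chi)
  x1 <- run(phi)
  x2 <- run(2 * phi)
  expect_lt(max(abs(x2 - 2 * x1)) / max(abs(x2)), 1e-4)
})

test_that("very strong regularization flattens the map", {
  spec <- smallSpec(snr = 40, seed = 2)
  truth <- buildPhantom(spec)
  series <- synthesizeEchoes(truth, spec)
  mask <- makeMask(series, 0.15)
  fit <- fitTotalField(unwrapPhase(series, mask), series, mask)
  w <- computeNoiseWeight(series, mask)
  edge <- computeEdgeMask(series, mask, 0.3)
  loc <- fieldMap(voxelValues(fit@totalField) * voxelValues(mask),
                  grid = series@grid, kind = "local")
  lo <- suppressWarnings(mediInvert(loc, w, edge, mask,
    inversionConfig(lambda = 1e-12, outerIterations = 3, cgMaxiter = 30)))
  hi <- suppressWarnings(mediInvert(loc, w, edge, mask,
    inversionConfig(lambda = 10, outerIterations = 3, cgMaxiter = 30)))
  expect_lt(hi@regularizer, 0.01 * lo@regularizer)
})

test_that("band-limited susceptibility away from the kernel zero cone is recovered", {
  n <- 32
  g <- volumeGrid(c(n, n, n))
  k <- dipoleKernel(g)
  D <- voxelValues(k)
  set.seed(17)
  raw <- array(rnorm(n^3), c(n, n, n))
  keep <- abs(D) > 0.12  # spectral mask excluding the zero cone
  # also low-pass so the field is smooth
  f1 <- function(nn) { i <- 0:(nn - 1); i[i > (nn - 1) %/% 2] <- i[i > (nn - 1) %/% 2] - nn; i / nn }
  fx <- f1(n)
  FX <- array(fx, c(n, n, n)); FY <- array(rep(fx, each = n), c(n, n, n))
  FZ <- array(rep(fx, each = n^2), c(n, n, n))
  lp <- exp(-(FX^2 + FY^2 + FZ^2) / (2 * 0.15^2))
  chi <- Re(fft(fft(raw) * lp * keep, inverse = TRUE)) / n^3
  chi <- chi / max(abs(chi))
  phi <- voxelValues(simulateField(susceptibilityMap(chi, grid = g), kernel = k))
  full <- maskVolume(array(1, c(n, n, n)), grid = g)
  wfull <- new("WeightVolume", grid = g, values = array(1, c(n, n, n)),
               units = "arbitrary")
  M <- new("EdgeMask", grid = g, values = array(1, c(n, n, n, 3)),
           edgeFraction = 0.3)
  res <- suppressWarnings(mediInvert(
    fieldMap(phi, grid = g, kind = "local"), wfull, M, full,
    inversionConfig(lambda = 1e-14, outerIterations = 1, cgMaxiter = 400,
                    cgTol = 1e-10), kernel = k))
  err <- voxelValues(res@chi) - chi
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(chi^2)), 0.01)
})

test_that("NaN inputs are rejected", {
  fx <- sphericalMaskFixture(12, 4)
  bad <- array(0, c(12, 12, 12)); bad[2] <- NaN
  M <- new("EdgeMask", grid = fx$grid, values = array(1, c(12, 12, 12, 3)),
           edgeFraction = 0.3)
  expect_error(mediInvert(fieldMap(bad, grid = fx$grid, kind = "local"),
                          fx$weight, M, fx$mask, inversionConfig()),
               "finite")
})
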