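test_that("region classification reproduces the seeded-statistics rule", {
  n <- 20
  g <- volumeGrid(c(n, n, n))
  set.seed(8)
  img <- array(rnorm(n^3, 100, 5), c(n, n, n))
  img[1:5, , ] <- 40    # hypointense block
  img[16:20, , ] <- 160 # hyperintense block
  tissue <- maskVolume(array(1, c(n, n, n)), grid = g)
  seedArr <- array(0, c(n, n, n)); seedArr[8:12, , ] <- 1
  seed <- maskVolume(seedArr, grid = g)
  rs <- classifyT2swRegions(scalarVolume(img, grid = g), tissue, seed, kSd = 2)
  expect_true(all(rs@hypo[1:5, , ] == 1))
  expect_true(all(rs@hyper[16:20, , ] == 1))
  expect_true(all(rs@infarct == ((rs@hypo + rs@hyper) > 0)))
  expect_identical(max(rs@remote * rs@infarct), 0)
  # enormous k: everything isointense
  rsBig <- classifyT2swRegions(scalarVolume(img, grid = g), tissue, seed, kSd = 1e6)
  expect_identical(sum(rsBig@infarct), 0)
  # degenerate reference
  flat <- scalarVolume(array(1, c(n, n, n)), grid = g)
  expect_error(classifyT2swRegions(flat, tissue, seed), "variance")
})

test_that("a uniform image yields no hyper or hypo regions", {
  n <- 10
  g <- volumeGrid(c(n, n, n))
  img <- array(50, c(n, n, n)); img[1, 1, 1] <- 50.001  # avoid zero variance
  tissue <- maskVolume(array(1, c(n, n, n)), grid = g)
  rs <- classifyT2swRegions(scalarVolume(img, grid = g), tissue,
                            maskVolume(array(1, c(n, n, n)), grid = g), kSd = 2)
  expect_lt(sum(rs@infarct), 2)
})

test_that("short-T2* infarct cores are caught as hypointense at SNR 40", {
  ph <- smallPhantom(snr = 40, seed = 6)
  mask <- makeMask(ph$series, 0.15)
  lab <- ph$truth@labels
  m <- voxelValues(mask) != 0
  seed <- maskVolume(array(as.numeric(lab == 1L & m), dim(lab)),
                     grid = ph$series@grid)
  rs <- classifyT2swRegions(t2swImage(ph$series), mask, seed, kSd = 2)
  recall <- sum(rs@hypo[lab == 2L & m]) / sum(lab == 2L & m)
  expect_gte(recall, 0.8)
})

test_that("susceptibility referencing zeroes the reference mean and is idempotent", {
  n <- 12
  g <- volumeGrid(c(n, n, n))
  set.seed(2)
  chi <- susceptibilityMap(array(rnorm(n^3, 0.3, 0.1), c(n, n, n)), grid = g)
  refArr <- array(0, c(n, n, n)); refArr[3:6, 3:6, 3:6] <- 1
  ref <- maskVolume(refArr, grid = g)
  out <- referenceSusceptibility(chi, ref)
  expect_lt(abs(mean(voxelValues(out)[refArr == 1])), 1e-10)
  again <- referenceSusceptibility(out, ref)
  expect_equal(voxelValues(again), voxelValues(out), tolerance = 1e-12)
  # pairwise differences preserved (shift invariance)
  d0 <- voxelValues(chi)[1, 1, 1] - voxelValues(chi)[5, 5, 5]
  d1 <- voxelValues(out)[1, 1, 1] - voxelValues(out)[5, 5, 5]
  expect_equal(d1, d0, tolerance = 1e-12)
  # constant map references to zero
  cst <- susceptibilityMap(array(0.42, c(n, n, n)), grid = g)
  expect_lt(max(abs(voxelValues(referenceSusceptibility(cst, ref)))), 1e-12)
  expect_error(referenceSusceptibility(chi, maskVolume(array(0, c(n, n, n)), grid = g)),
               "empty")
})

test_that("referencing phantom truth reproduces the specified infarct shift", {
  truth <- buildPhantom(smallSpec(chiInfarct = 0.07, chiRemote = 0))
  lab <- truth@labels
  ref <- maskVolume(array(as.numeric(lab == 1L), dim(lab)),
                    grid = truth@chiMap@grid)
  out <- referenceSusceptibility(truth@chiMap, ref)
  expect_equal(mean(voxelValues(out)[lab == 2L]), 0.07, tolerance = 1e-12)
})

test_that("the FWHM threshold rule matches a hand-worked example", {
  # 5-voxel strip {100, 150, 210, 290, 120}; remote mean 100, max 290 over the
  # strip would give threshold 195; anchor the hand example with max 300
  shp <- c(5, 2, 2)
  g <- volumeGrid(shp)
  img <- array(0, shp)
  img[, 1, 1] <- c(100, 150, 210, 290, 120)
  img[1, 2, 1] <- 300                      # myocardial maximum
  myo <- array(0, shp); myo[, 1, 1] <- 1; myo[1, 2, 1] <- 1
  rem <- array(0, shp); rem[1, 1, 1] <- 1  # remote mean 100
  fw <- fwhmInfarctMask(scalarVolume(img, grid = g),
                        maskVolume(myo, grid = g), maskVolume(rem, grid = g))
  # threshold = 100 + 0.5 * (300 - 100) = 200: strip selects {210, 290}
  expect_identical(sum(voxelValues(fw)[, 1, 1]), 2)
  # doubling every intensity leaves the selection unchanged
  fw2 <- fwhmInfarctMask(scalarVolume(2 * img, grid = g),
                         maskVolume(myo, grid = g), maskVolume(rem, grid = g))
  expect_identical(voxelValues(fw2), voxelValues(fw))
  # no enhancement: empty mask with a warning
  flat <- scalarVolume(array(7, shp), grid = g)
  expect_warning(fw0 <- fwhmInfarctMask(flat, maskVolume(myo, grid = g),
                                        maskVolume(rem, grid = g)),
                 "enhancement")
  expect_identical(sum(voxelValues(fw0)), 0)
})

test_that("the half-max FWHM variant uses 0.5 * max alone", {
  shp <- c(5, 2, 2)
  g <- volumeGrid(shp)
  img <- array(0, shp); img[, 1, 1] <- c(10, 140, 160, 290, 120); img[1, 2, 1] <- 300
  myo <- array(0, shp); myo[, 1, 1] <- 1; myo[1, 2, 1] <- 1
  rem <- array(0, shp); rem[1, 1, 1] <- 1
  fw <- fwhmInfarctMask(scalarVolume(img, grid = g), maskVolume(myo, grid = g),
                        maskVolume(rem, grid = g), variant = "half_max")
  # threshold 150: selects {160, 290} from the strip
  expect_identical(sum(voxelValues(fw)[, 1, 1]), 2)
})

test_that("ROC analysis matches hand-worked and brute-force references", {
  r1 <- rocCurve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_identical(r1@auc, 1)
  expect_identical(r1@youdenJ, 1)
  r2 <- rocCurve(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_identical(r2@auc, 0.75)
  # perfectly separated with ties inside classes
  r3 <- rocCurve(c(0, 0, 5, 5), c(0, 0, 1, 1))
  expect_identical(r3@auc, 1)
  # all ties across classes: chance
  r4 <- rocCurve(c(2, 2, 2, 2), c(0, 1, 0, 1))
  expect_identical(r4@auc, 0.5)
  expect_error(rocCurve(c(1, 2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance on random instances", {
  set.seed(55)
  for (rep in 1:8) {
    nv <- sample(20:300, 1)
    vals <- sample(round(rnorm(nv), sample(0:2, 1)))  # induces ties
    labs <- rbinom(nv, 1, 0.4)
    if (sum(labs) == 0 || sum(labs) == nv) next
    r <- rocCurve(vals, labs)
    expect_equal(r@auc, aucByConcordance(vals, labs), tolerance = 1e-12)
    expect_equal(r@youdenJ, max(r@sensitivity + r@specificity - 1),
                 tolerance = 1e-12)
    # sensitivity non-increasing with the threshold
    expect_true(all(diff(r@sensitivity) <= 1e-12))
  }
})

test_that("ROC agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  set.seed(77)
  vals <- rnorm(400)
  labs <- rbinom(400, 1, 0.5)
  r <- rocCurve(vals, labs)
  ref <- pROC::roc(labs, vals, quiet = TRUE, direction = "<")
  expect_equal(r@auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("label-independent predictors give chance AUC", {
  set.seed(123)
  vals <- rnorm(1e4)
  labs <- rbinom(1e4, 1, 0.5)
  expect_equal(rocCurve(vals, labs)@auc, 0.5, tolerance = 0.04)
})

test_that("region statistics are exact and conserve voxel counts", {
  n <- 10
  g <- volumeGrid(c(n, n, n))
  v <- array(0, c(n, n, n)); v[1, 1, 1] <- 5; v[1:3, 2, 1] <- c(1, 2, 3)
  mapv <- scalarVolume(v, grid = g, units = "ppm")
  single <- array(0, c(n, n, n)); single[1, 1, 1] <- 1
  trio <- array(0, c(n, n, n)); trio[1:3, 2, 1] <- 1
  empty <- array(0, c(n, n, n))
  st <- regionStats(mapv, list(single = single, trio = trio, none = empty))
  expect_identical(st$n, c(1L, 3L, 0L))
  expect_identical(st$mean[1], 5)
  expect_identical(st$sd[1], 0)
  expect_identical(st$mean[2], 2)
  expect_identical(st$sd[2], 1)        # sample SD of {1,2,3}
  expect_identical(st$median[2], 2)
  expect_true(is.na(st$mean[3]))
  expect_identical(unique(st$units), "ppm")
  # disjoint regions partition the mask: counts conserve
  a <- array(0, c(n, n, n)); a[1:5, , ] <- 1
  b <- array(0, c(n, n, n)); b[6:10, , ] <- 1
  st2 <- regionStats(mapv, list(a = a, b = b))
  expect_identical(sum(st2$n), as.integer(n^3))
})
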