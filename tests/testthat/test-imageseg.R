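test_that("fast marching tracks Euclidean distance under uniform speed", {
  d <- c(41, 41, 41)
  vol <- imageVolume(array(0, d), c(1, 1, 1))
  am <- fastMarching(vol, c(20, 20, 20), speed = array(1, d))
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  dist <- sqrt(rowSums((t(t(idx) - c(21, 21, 21)))^2))
  sel <- dist <= 20 & dist > 0
  expect_lt(max(abs(am@arrival[sel] - dist[sel]) / dist[sel]), 0.10)
  expect_true(am@monotone)
  # determinism
  am2 <- fastMarching(vol, c(20, 20, 20), speed = array(1, d))
  expect_identical(am@arrival, am2@arrival)
})

test_that("zero-speed regions stay unreached", {
  d <- c(21, 21, 41)
  sp <- array(0, d); sp[8:14, 8:14, ] <- 1   # a square duct
  vol <- imageVolume(array(0, d), c(1, 1, 1))
  am <- fastMarching(vol, c(10, 10, 5), speed = sp)
  expect_true(all(!is.finite(am@arrival[sp == 0])))
  expect_true(all(is.finite(am@arrival[8:14, 8:14, ])))
})

test_that("colliding fronts recover the tube connecting two seeds", {
  tp <- tubePhantom(2, 40)
  vx <- voxelizeTree(tp, spacing = 0.5, noiseSd = 40, psfSigma = 0.4,
                     seed = 7, ventricle = FALSE)
  img <- vx$image
  i0 <- ctFFR:::worldToIndex(img, c(0, 0, 2))
  i1 <- ctFFR:::worldToIndex(img, c(0, 0, 38))
  cf <- collidingFronts(img, i0, i1)
  expect_gte(diceCoefficient(cf, vx$lumenTruth), 0.80)
  # degenerate: both seeds identical still contains the seed voxel
  cf0 <- collidingFronts(img, i0, i0)
  expect_true(cf0[i0[1] + 1, i0[2] + 1, i0[3] + 1])
  # disconnected components (zero speed between two blobs)
  v <- array(0, c(12, 12, 12))
  v[2:4, 2:4, 2:4] <- 400; v[9:11, 9:11, 9:11] <- 400
  img2 <- imageVolume(v, c(1, 1, 1))
  expect_error(collidingFronts(img2, c(2, 2, 2), c(9, 9, 9),
                               speed = (v > 0) * 1.0),
               "disconnected")
})

test_that("colliding fronts exclude the other daughter of a Y tree", {
  tr <- generateTree(depth = 1, rootRadius = 1.8, seed = 3)
  vx <- voxelizeTree(tr, spacing = 0.5, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  sv <- ctFFR:::treeSeedVoxels(tr, vx$image)
  cf <- collidingFronts(vx$image, sv$root, sv$leaves[1, ])
  # voxels unambiguously in the *other* daughter (distal half)
  s <- tr@segments
  other <- s[s$id == 3, ]
  mid <- c((other$x0 + other$x1), (other$y0 + other$y1),
           (other$z0 + other$z1)) / 2
  p1 <- c(other$x1, other$y1, other$z1)
  idx <- which(vx$lumenTruth, arr.ind = TRUE)
  w <- t(t(idx - 1) * spacing(vx$image) + origin(vx$image))
  inOther <- rowSums((w - matrix(mid, nrow(w), 3, byrow = TRUE))^2) <
    sum((p1 - mid)^2)
  inOther <- inOther & w[, 3] > mid[3] - 2
  excl <- !cf[idx[inOther, , drop = FALSE]]
  expect_gt(mean(excl), 0.90)
})

test_that("level-set refinement improves Dice on a noisy tube", {
  tp <- tubePhantom(2, 40)
  vx <- voxelizeTree(tp, spacing = 0.5, noiseSd = 40, psfSigma = 0.4,
                     seed = 7, ventricle = FALSE)  # noise = 10% of contrast
  img <- vx$image
  i0 <- ctFFR:::worldToIndex(img, c(0, 0, 2))
  i1 <- ctFFR:::worldToIndex(img, c(0, 0, 38))
  cf <- collidingFronts(img, i0, i1)
  d0 <- diceCoefficient(cf, vx$lumenTruth)
  ls <- levelSetRefine(img, cf, iterations = 60)
  d1 <- diceCoefficient(ls@phi < 0, vx$lumenTruth)
  expect_gte(d1, 0.90)
  expect_gte(d1, d0)
})

test_that("zero level-set iterations return the initialization boundary", {
  tp <- tubePhantom(1.5, 20)
  vx <- voxelizeTree(tp, spacing = 0.5, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  ls <- levelSetRefine(vx$image, vx$lumenTruth, iterations = 0)
  expect_identical(ls@phi < 0, vx$lumenTruth)
  expect_identical(ls@iterations, 0L)
})

test_that("curvature weight shrinks the surface area of a noisy sphere", {
  sf <- sphereField(r = 6, sp = 0.5)
  set.seed(1)
  mask <- sf$phi + array(rnorm(length(sf$phi), 0, 0.3), dim(sf$phi)) < 0
  img <- imageVolume(400 * mask, sf$spacing, sf$origin)
  a0 <- surfaceArea(extractSurface(mask, spacing = sf$spacing,
                                   origin = sf$origin))
  ls <- levelSetRefine(img, mask, iterations = 30, curvature = 0.5)
  a1 <- surfaceArea(extractSurface(ls))
  expect_lt(a1, a0)
})

test_that("surface extraction matches the analytic sphere", {
  sf <- sphereField(r = 10, sp = 0.5)
  surf <- extractSurface(sf$phi, 0, spacing = sf$spacing, origin = sf$origin)
  expect_lt(abs(surfaceArea(surf) - 4 * pi * 100) / (4 * pi * 100), 0.02)
  expect_identical(eulerCharacteristic(surf), 2L)
  expect_true(isWatertight(surf))
  # enclosed volume against the analytic ball
  expect_lt(abs(enclosedVolume(surf) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)
  expect_error(extractSurface(sf$phi, 99, spacing = sf$spacing), "outside")
})

test_that("mask surfaces are watertight and recover the mask volume", {
  tp <- tubePhantom(2, 30)
  vx <- voxelizeTree(tp, spacing = 0.5, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  surf <- extractSurface(vx$lumenTruth, spacing = spacing(vx$image),
                         origin = origin(vx$image))
  expect_true(isWatertight(surf))
  vVox <- sum(vx$lumenTruth) * 0.5^3
  expect_lt(abs(enclosedVolume(surf) - vVox) / vVox, 0.05)
})

test_that("myocardial mass is the calibrated volume integral", {
  # ellipsoid semi-axes 30/30/45 mm at 0.5 mm spacing, density 1.05
  sp <- 0.5
  ax <- seq(-32, 32, by = sp); az <- seq(-47, 47, by = sp)
  X <- array(ax, c(length(ax), length(ax), length(az)))
  Y <- aperm(array(ax, c(length(ax), length(ax), length(az))), c(2, 1, 3))
  Z <- aperm(array(az, c(length(az), length(ax), length(ax))), c(2, 3, 1))
  mask <- (X / 30)^2 + (Y / 30)^2 + (Z / 45)^2 <= 1
  m <- myocardialMass(mask, rep(sp, 3), density = 1.05)
  mTheory <- 1.05 * 4 / 3 * pi * 30 * 30 * 45 / 1000
  expect_lt(abs(m - mTheory) / mTheory, 0.02)
  # unit conversion and linearity
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(myocardialMass(one, c(1, 1, 1), density = 1.0), 0.001)
  expect_equal(myocardialMass(mask, rep(sp, 3), density = 2.1), 2 * m)
  expect_error(myocardialMass(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
})

test_that("segmentation pipeline reaches Dice 0.9 across seeded phantoms", {
  dices <- vapply(1:10, function(s) {
    tr <- generateTree(depth = 1, rootRadius = 1.8, severities = 0.5, seed = s)
    vx <- voxelizeTree(tr, spacing = 0.5, noiseSd = 40, psfSigma = 0.4,
                       seed = s, ventricle = FALSE)
    sv <- ctFFR:::treeSeedVoxels(tr, vx$image)
    cf <- collidingFronts(vx$image, sv$root, sv$leaves[1, ]) |
      collidingFronts(vx$image, sv$root, sv$leaves[2, ])
    ls <- levelSetRefine(vx$image, cf, iterations = 60)
    diceCoefficient(ls@phi < 0, vx$lumenTruth)
  }, 0)
  expect_gte(median(dices), 0.90)
  expect_gte(min(dices), 0.85)
})
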