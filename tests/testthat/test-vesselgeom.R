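test_that("centerline of a straight tube recovers length and radius", {
  tp <- tubePhantom(2, 40)
  vx <- voxelizeTree(tp, spacing = 0.5, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  img <- vx$image
  root <- ctFFR:::worldToIndex(img, c(0, 0, 0.5))
  ep <- ctFFR:::worldToIndex(img, c(0, 0, 39.5))
  ct <- extractCenterline(vx$lumenTruth, root, ep, spacing(img), origin(img))
  expect_identical(length(branches(ct)), 1L)
  b <- branches(ct)[[1]]
  expect_lt(abs(max(b$arclen) - 39) / 40, 0.05)   # seeded 0.5 mm from ends
  expect_lt(abs(median(b$radius) - 2), 0.25)
  # containment: every centerline point lies strictly inside the mask
  ijk <- cbind(round((b$x - origin(img)[1]) / 0.5),
               round((b$y - origin(img)[2]) / 0.5),
               round((b$z - origin(img)[3]) / 0.5)) + 1
  expect_true(all(vx$lumenTruth[ijk]))
  expect_true(all(diff(b$arclen) > 0))
})

test_that("Y phantom yields three branches and unreachable endpoints fail", {
  tr <- generateTree(depth = 1, rootRadius = 1.8, seed = 3)
  vx <- voxelizeTree(tr, spacing = 0.5, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  sv <- ctFFR:::treeSeedVoxels(tr, vx$image)
  ct <- extractCenterline(vx$lumenTruth, sv$root, sv$leaves,
                          spacing(vx$image), origin(vx$image))
  expect_identical(length(branches(ct)), 3L)
  topo <- topology(ct)
  expect_identical(sum(is.na(topo$parent)), 1L)
  # endpoint outside the mask is rejected by name
  bad <- sv$leaves
  bad[1, ] <- c(0, 0, 0)
  expect_error(extractCenterline(vx$lumenTruth, sv$root, bad,
                                 spacing(vx$image), origin(vx$image)),
               "endpoint 1")
})

test_that("stenosis quantification recovers the phantom severity", {
  tp <- tubePhantom(2, 40, severity = 0.8)
  vx <- voxelizeTree(tp, spacing = 0.25, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  img <- vx$image
  root <- ctFFR:::worldToIndex(img, c(0, 0, 0.5))
  ep <- ctFFR:::worldToIndex(img, c(0, 0, 39.5))
  ct <- extractCenterline(vx$lumenTruth, root, ep, spacing(img), origin(img))
  les <- quantifyStenosis(ct)
  expect_identical(nrow(les), 1L)
  expect_gte(les$ds_percent, 75)
  expect_lte(les$ds_percent, 85)
  expect_true(les$ccta_positive)
  # radius dip is unimodal within the lesion
  b <- branches(ct)[[1]]
  inLes <- b$arclen >= les$start & b$arclen <= les$end
  r <- b$radius[inLes]
  dmin <- which.min(r)
  expect_true(all(diff(r[1:dmin]) <= 1e-9) || dmin <= 2)
  expect_true(all(diff(r[dmin:length(r)]) >= -1e-9) || dmin >= length(r) - 1)
})

test_that("a 55% phantom is CCTA-positive and a uniform tube has no lesions", {
  tp <- tubePhantom(2, 40, severity = 0.55)
  vx <- voxelizeTree(tp, spacing = 0.25, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  img <- vx$image
  ct <- extractCenterline(vx$lumenTruth,
                          ctFFR:::worldToIndex(img, c(0, 0, 0.5)),
                          ctFFR:::worldToIndex(img, c(0, 0, 39.5)),
                          spacing(img), origin(img))
  les <- quantifyStenosis(ct)
  expect_identical(nrow(les), 1L)
  expect_true(les$ccta_positive)   # >= 50% threshold

  prof <- stenosisProfile(0)       # exact uniform profile
  les0 <- quantifyStenosis(profileTree(prof))
  expect_identical(nrow(les0), 0L)
})

test_that("axisymmetric mesh honours the size cap and geometry", {
  prof <- stenosisProfile(0.6, R = 2, L = 40)
  mesh <- buildAxiMesh(profile = prof, hMax = 0.3)
  expect_lte(max(diff(mesh@zFaces)), 0.3)
  expect_lte(max(diff(mesh@rFaces)), 0.3)
  # refinement scaling ~ 4x per halving
  mesh2 <- buildAxiMesh(profile = prof, hMax = 0.15)
  ratio <- cellCount(mesh2) / cellCount(mesh)
  expect_gte(ratio, 3.5); expect_lte(ratio, 4.5)
  # wall fidelity: mesh minimum equals profile minimum within a cell
  expect_lt(abs(min(mesh@wall) - min(prof$radius)), max(diff(mesh@rFaces)))
  # meridional area matches the trapezoidal profile integral within 1%
  trap <- sum(diff(prof$arclen) *
                (head(prof$radius, -1) + tail(prof$radius, -1)) / 2)
  expect_lt(abs(meshMeridionalArea(mesh) - trap) / trap, 0.01)
  expect_error(buildAxiMesh(profile = prof, hMax = 0), "hMax")
})

test_that("1-D network construction counts elements and outlets", {
  prof <- data.frame(arclen = c(0, 40), radius = c(2, 2))
  net <- buildNetwork(profileTree(prof), dx = 1)
  expect_identical(nrow(net@elements), 40L)
  expect_identical(nrow(net@outlets), 1L)
  expect_true(all(net@elements$length <= 1 + 1e-9))
  # radius samples stay within the data range
  expect_true(all(net@elements$r0 >= 2 - 1e-12 & net@elements$r0 <= 2 + 1e-12))

  tr <- generateTree(depth = 2, seed = 11)
  vx <- voxelizeTree(tr, spacing = 0.5, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  sv <- ctFFR:::treeSeedVoxels(tr, vx$image)
  ct <- extractCenterline(vx$lumenTruth, sv$root, sv$leaves,
                          spacing(vx$image), origin(vx$image))
  netY <- buildNetwork(ct, dx = 1)
  nLeaves <- nrow(sv$leaves)
  expect_identical(nrow(netY@outlets), nLeaves)
})
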