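test_that("tree generation is seed-reproducible and Murray-consistent", {
  t1 <- generateTree(depth = 2, seed = 42)
  t2 <- generateTree(depth = 2, seed = 42)
  expect_identical(t1@segments, t2@segments)
  expect_identical(t1@stenoses, t2@stenoses)

  s <- t1@segments
  for (p in unique(s$parent[!is.na(s$parent)])) {
    kids <- s[!is.na(s$parent) & s$parent == p, ]
    if (nrow(kids) != 2) next
    d0 <- 2 * s$r1[s$id == p]
    expect_lt(abs(d0^3 - sum((2 * kids$r0)^3)) / d0^3, 1e-9)
  }
  expect_true(all(s$r0 > 0 & s$r1 > 0))
  expect_identical(sum(is.na(s$parent)), 1L)
})

test_that("occlusions are rejected and zero severity is the identity", {
  expect_error(generateTree(severities = 1.0), "occlusions excluded")
  expect_error(tubePhantom(severity = 1), "occlusions excluded")
  tp <- generateTree(depth = 1, severities = 0, seed = 1)
  expect_identical(nrow(tp@stenoses), 0L)
  # zero-severity radius profile is constant along the segment
  tp0 <- tubePhantom(2, 40, severity = 0)
  r <- ctFFR:::segmentRadius(tp0@segments[1, ], tp0@stenoses,
                             seq(0, 40, by = 0.5), 40)
  expect_true(all(r == 2))
})

test_that("voxelization reproduces the analytic cylinder volume", {
  tp <- tubePhantom(radius = 2, length = 40)
  vx <- voxelizeTree(tp, spacing = 0.5, noiseSd = 0, psfSigma = 0,
                     ventricle = FALSE)
  vol <- sum(vx$lumenTruth) * 0.5^3
  expect_lt(abs(vol - pi * 4 * 40) / (pi * 4 * 40), 0.05)
  # interior voxels carry the exact foreground intensity without noise
  expect_true(all(voxels(vx$image)[vx$lumenTruth] == 400))
  # volume error strictly decreases with refinement
  vx2 <- voxelizeTree(tp, spacing = 0.25, noiseSd = 0, psfSigma = 0,
                      ventricle = FALSE)
  e1 <- abs(vol - pi * 4 * 40)
  e2 <- abs(sum(vx2$lumenTruth) * 0.25^3 - pi * 4 * 40)
  expect_lt(e2, e1)
})

test_that("voxelization is seed-reproducible with noise and checks extent", {
  tp <- tubePhantom(1.5, 20)
  a <- voxelizeTree(tp, noiseSd = 30, seed = 9, ventricle = FALSE)
  b <- voxelizeTree(tp, noiseSd = 30, seed = 9, ventricle = FALSE)
  expect_identical(voxels(a$image), voxels(b$image))
  expect_error(
    voxelizeTree(tp, ventricle = FALSE,
                 extent = list(lower = c(-5, -5, 0), upper = c(5, 5, 10))),
    "segment 1")
})

test_that("cohort generator hits the configured prevalence and noise model", {
  co <- generateCohort(1000, seed = 3, prevalence = 0.3)
  v <- co[co$level == "vessel", ]
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(mean(v$reference_ffr <= 0.80) - 0.3), 3 * se)
  expect_true(all(v$reference_ffr > 0 & v$reference_ffr <= 1))
  expect_true(all(v$index_ffr > 0 & v$index_ffr <= 1))

  # noiseless identity: index equals reference, perfect classification
  co0 <- generateCohort(200, seed = 4, bias = 0, sd = 0)
  v0 <- co0[co0$level == "vessel", ]
  expect_equal(v0$index_ffr, v0$reference_ffr)
  cts <- confusionCounts(co0, "vessel")
  expect_identical(unname(counts(cts)[c("fp", "fn")]), c(0L, 0L))
  expect_equal(auc(rocAuc(v0$index_ffr, v0$reference_ffr <= 0.8)), 1.0)

  # cardinality and per-patient minimum rule
  co78 <- generateCohort(78, seed = 5)
  expect_identical(sum(co78$level == "vessel"), 78L)
  v78 <- co78[co78$level == "vessel", ]
  p78 <- co78[co78$level == "patient", ]
  agg <- tapply(v78$reference_ffr, v78$patient, min)
  expect_equal(unname(p78$reference_ffr), as.numeric(agg[order(as.integer(names(agg)))]))
})

test_that("single-class cohorts are flagged degenerate", {
  expect_warning(co <- generateCohort(30, seed = 1, prevalence = 0),
                 "single-class")
  expect_true(attr(co, "degenerate"))
  v <- co[co$level == "vessel", ]
  expect_error(rocAuc(v$index_ffr, v$reference_ffr <= 0.8), "both classes")
})
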