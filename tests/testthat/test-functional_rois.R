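## small helper: a z volume from an array
zVol <- function(a) brainVolume(a, voxelSize = c(1, 1, 1))

test_that("cluster extraction honours threshold, extent and connectivity", {
  a <- array(0, c(8, 8, 8))
  a[2:3, 2:3, 2:3] <- 5            # 8-voxel blob
  a[6, 6, 6] <- 5                  # singleton
  cl <- extractClusters(zVol(a), clusterConfig(minExtent = 5))
  expect_length(cl, 1)
  expect_equal(maskSize(cl[[1]]), 8)
  ## extent filter: a 3-voxel blob under min_extent 5 yields nothing
  b <- array(0, c(8, 8, 8)); b[2:4, 2, 2] <- 5
  expect_length(extractClusters(zVol(b), clusterConfig(minExtent = 5)), 0)
  ## corner-touching blobs: separate at connectivity 6, merged at 26
  d <- array(0, c(6, 6, 6))
  d[2, 2, 2] <- 4; d[3, 3, 3] <- 4
  expect_length(extractClusters(zVol(d),
                                clusterConfig(minExtent = 0,
                                              connectivity = 6)), 2)
  expect_length(extractClusters(zVol(d),
                                clusterConfig(minExtent = 0,
                                              connectivity = 26)), 1)
})

test_that("cluster extraction agrees with a brute-force component oracle", {
  set.seed(21)
  for (conn in c(6, 18, 26)) {
    for (i in 1:100) {
      a <- array(ifelse(runif(6^3) < 0.25, 3, 0), c(6, 6, 6))
      got <- extractClusters(zVol(a), clusterConfig(zThreshold = 2.3,
                                                    minExtent = 0,
                                                    connectivity = conn))
      want <- oracleComponents(a > 2.3, conn)
      gotSets <- lapply(got, maskIndices)
      expect_equal(length(gotSets), length(want))
      ## same partition regardless of ordering
      expect_setequal(vapply(gotSets, paste, collapse = ",", ""),
                      vapply(want, paste, collapse = ",", ""))
    }
  }
})

test_that("permutation-calibrated extents suppress chance-sized clusters", {
  set.seed(3)
  a <- array(rnorm(16^3), c(16, 16, 16))
  a[4:8, 4:8, 4:8] <- a[4:8, 4:8, 4:8] + 6    # a real 125-voxel effect
  cl <- extractClusters(zVol(a), clusterConfig(minExtent = "permutation",
                                               nPerm = 200, seed = 1,
                                               connectivity = 26))
  expect_gte(attr(cl, "minExtent"), 1)
  expect_length(cl, 1)
  expect_gte(maskSize(cl[[1]]), 100)
})

test_that("hMT+ selection is by anchor proximity, not size", {
  a <- array(0, c(20, 8, 8))
  a[2:5, 2:5, 2:5] <- 4            # big cluster near x ~ 3
  a[16:17, 4:5, 4:5] <- 5          # small cluster near x ~ 16
  v <- zVol(a)
  cfg <- clusterConfig(minExtent = 2)
  big <- defineHMT(v, cfg, anchor = c(3, 3, 3))
  small <- defineHMT(v, cfg, anchor = c(16, 4, 4))
  expect_equal(maskSize(big), 64)
  expect_equal(maskSize(small), 8)
  expect_error(defineHMT(zVol(array(0, c(8, 8, 8))), cfg, c(1, 1, 1)),
               class = "corticomap_no_clusters")
})

test_that("MST takes intersecting ipsilateral clusters in full", {
  base <- array(0, c(30, 4, 4))
  hmtArr <- base; hmtArr[1:20, 2, 2] <- 5
  hmt <- extractClusters(zVol(hmtArr), clusterConfig(minExtent = 0))[[1]]
  ## ipsi cluster overlapping hMT+ {15..25} is kept in full
  ipsi <- base; ipsi[15:25, 2, 2] <- 4
  mst <- defineMST(hmt, zVol(ipsi), clusterConfig(minExtent = 0))
  want <- which(ipsi > 2.3)
  expect_identical(maskIndices(mst), sort(want))
  ## disjoint ipsi cluster contributes nothing
  ipsi2 <- base; ipsi2[25:28, 2, 2] <- 4
  expect_equal(maskSize(defineMST(hmt, zVol(ipsi2),
                                  clusterConfig(minExtent = 0))), 0)
  ## two ipsi clusters, only the intersecting one kept (in full)
  ipsi3 <- base; ipsi3[18:22, 2, 2] <- 4; ipsi3[27:29, 2, 2] <- 4
  mst3 <- defineMST(hmt, zVol(ipsi3), clusterConfig(minExtent = 0))
  first <- base; first[18:22, 2, 2] <- 1
  expect_identical(maskIndices(mst3), sort(which(first == 1)))
})

test_that("V5/MT is coherent retinotopic hMT+ minus MST", {
  vol <- zVol(array(0, c(50, 2, 2)))
  hmt <- voxelMask(10:30, vol)
  mst <- voxelMask(25:35, vol)
  coh <- array(0, c(50, 2, 2)); coh[10:30] <- 0.9
  retino <- new("RetinotopyResult", phase = coh * 0, amplitude = coh,
                coherence = coh, stimulusFrequency = 1 / 64,
                nFrames = 256L, frameInterval = 2,
                gridRef = parentFingerprint(vol))
  v5 <- defineV5MT(retino, 0.25, hmt, mst)
  expect_identical(maskIndices(v5), 10:24)
  ## V5/MT and MST are disjoint by construction
  expect_length(intersect(maskIndices(v5), maskIndices(mst)), 0)
  ## all-subthreshold coherence yields the empty set
  retino0 <- retino; retino0@coherence <- coh * 0.1
  expect_equal(maskSize(defineV5MT(retino0, 0.25, hmt, mst)), 0)
  ## empty MST keeps all coherent hMT+ voxels
  v5all <- defineV5MT(retino, 0.25, hmt, voxelMask(integer(0), vol))
  expect_identical(maskIndices(v5all), 10:30)
})

## build a small time-series volume from a voxel x time matrix
tsVol <- function(X, dt = 1) {
  brainTimeSeries(array(X, c(nrow(X), 1, 1, ncol(X))), frameInterval = dt)
}

test_that("Fourier retinotopy recovers phase, amplitude and coherence", {
  nt <- 64; tt <- 0:(nt - 1)
  per <- 16
  x <- cos(2 * pi * tt / per - 1.0)
  r <- fourierRetinotopy(tsVol(matrix(x, 1), dt = 1), stimulusPeriod = per)
  expect_equal(as.numeric(r@phase[1, 1, 1]), 1.0, tolerance = 1e-6)
  expect_equal(as.numeric(r@amplitude[1, 1, 1]), 1, tolerance = 1e-9)
  expect_equal(as.numeric(r@coherence[1, 1, 1]), 1, tolerance = 1e-9)
  ## a quarter-period shift appears as phase pi/2
  x2 <- cos(2 * pi * (tt - per / 4) / per)
  r2 <- fourierRetinotopy(tsVol(matrix(x2, 1)), per)
  expect_equal(as.numeric(r2@phase[1, 1, 1]), pi / 2, tolerance = 1e-6)
  ## off-bin periods are refused with guidance
  expect_error(fourierRetinotopy(tsVol(matrix(x, 1)), 13),
               class = "corticomap_period_off_bin")
})

test_that("pure-noise coherence matches a Monte-Carlo null oracle", {
  nt <- 64; per <- 16; nv <- 10000
  set.seed(31)
  X <- matrix(rnorm(nv * nt), nv, nt)
  r <- fourierRetinotopy(brainTimeSeries(array(X, c(100, 100, 1, nt))), per)
  fracPkg <- mean(r@coherence > 0.25)
  ## independent oracle: direct DFT of fresh noise draws
  set.seed(32)
  kbin <- nt / per + 1
  half <- 2:(nt / 2 + 1)
  fracMC <- mean(replicate(1000, {
    y <- rnorm(nt)
    y <- stats::residuals(stats::lm(y ~ seq_len(nt)))
    sp <- Mod(stats::fft(y))
    sp[kbin] / sqrt(sum(sp[half]^2)) > 0.25
  }))
  expect_lt(abs(fracPkg - fracMC), 0.02)
})

test_that("complex averaging over repeats improves coherence in signal voxels", {
  ## signal voxels at the amplitude/noise-sd = 2 regime used throughout
  nt <- 64; per <- 16; nv <- 200
  tt <- 0:(nt - 1)
  set.seed(40)
  phase <- runif(nv, 0, 2 * pi)
  sig <- t(sapply(phase, function(p) 2 * cos(2 * pi * tt / per - p)))
  set.seed(41)
  mk <- function() brainTimeSeries(
    array(sig + matrix(rnorm(nv * nt, 0, 1), nv, nt), c(nv, 1, 1, nt)))
  r1run <- fourierRetinotopy(mk(), per)
  r2run <- fourierRetinotopy(list(mk(), mk()), per)
  expect_gte(mean(r2run@coherence >= r1run@coherence), 0.95)
  ## and phase recovery stays accurate: mean abs circular error < 0.1 rad
  ## at amplitude/noise = 2
  set.seed(42)
  s2 <- brainTimeSeries(array(sig + matrix(rnorm(nv * nt), nv, nt),
                              c(nv, 1, 1, nt)))
  rs <- fourierRetinotopy(s2, per)
  err <- abs((as.vector(rs@phase)[1:100] - phase[1:100] + pi) %% (2 * pi) - pi)
  expect_lt(mean(err), 0.1)
})

test_that("group masks apply the at-least-fraction rule at the boundary", {
  surf <- flatSheetSurface(4, 4)
  masks <- lapply(1:8, function(i) vertexMask(
    c(if (i <= 4) 1L else NULL, if (i <= 3) 2L else NULL, 3L), surf))
  ## vertex 1 in 4 of 8 masks: included at minFraction 0.5
  g <- groupMask(masks, 0.5)
  expect_true(1L %in% maskIndices(g))
  ## vertex 2 in 3 of 8: excluded
  expect_false(2L %in% maskIndices(g))
  ## minFraction 1 is the intersection
  expect_identical(maskIndices(groupMask(masks, 1)), 3L)
  ## monotone: raising the fraction never adds vertices
  prev <- NULL
  for (f in c(0.25, 0.5, 0.75, 1)) {
    cur <- maskIndices(groupMask(masks, f))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})
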