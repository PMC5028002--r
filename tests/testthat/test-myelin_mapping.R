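test_that("ratio map averages repeats before dividing and guards zeros", {
  mk <- function(val) brainVolume(array(val, c(3, 3, 3)))
  expect_equal(unique(as.vector(imageData(ratioMap(mk(2), mk(1))))), 2)
  ## two T1w repeats of 1 and 3 over T2w == 2: mean first, then divide
  r <- ratioMap(list(mk(1), mk(3)), mk(2))
  expect_equal(unique(as.vector(imageData(r))), 1)
  ## zero denominator invalidates just that voxel
  t2 <- array(1, c(3, 3, 3)); t2[2, 2, 2] <- 0
  r2 <- ratioMap(mk(4), brainVolume(t2))
  expect_false(validMask(r2)[2, 2, 2])
  expect_equal(sum(!validMask(r2)), 1)
  expect_equal(imageData(r2)[1, 1, 1], 4)
  ## grids must match
  expect_error(ratioMap(mk(1), brainVolume(array(1, c(4, 3, 3)))),
               class = "corticomap_grid_mismatch")
})

## a volume whose value equals the world z coordinate, over a flat sheet
zFieldVolume <- function(n = 12, vs = 0.5, z0 = -2) {
  zvals <- z0 + (seq_len(n) - 1) * vs
  tr <- diag(c(vs, vs, vs, 1)); tr[1:3, 4] <- c(-1, -1, z0)
  brainVolume(array(rep(zvals, each = n * n), c(n, n, n)),
              voxelSize = rep(vs, 3), transform = tr)
}

test_that("depth sampling is linear in depth on an analytic z field", {
  vol <- zFieldVolume()
  surf <- flatSheetSurface(nx = 5, ny = 5, h = 0.8, thickness = 1, z0 = 0)
  vals <- sapply(seq(0, 1, 0.25), function(f)
    mean(mapValues(sampleToSurface(vol, surf, f))))
  ## sampled value = white z + f * thickness = -0.5 + f
  expect_equal(vals, -0.5 + seq(0, 1, 0.25), tolerance = 1e-9)
  ## depth 0 vs 1 differ by the cortical thickness
  m0 <- sampleToSurface(vol, surf, 0); m1 <- sampleToSurface(vol, surf, 1)
  expect_equal(mapValues(m1) - mapValues(m0), rep(1, 25), tolerance = 1e-9)
  ## constant volume: identical map at every depth
  cv <- brainVolume(array(7, c(12, 12, 12)), voxelSize = rep(0.5, 3),
                    transform = vol@transform)
  expect_equal(mapValues(sampleToSurface(cv, surf, 0.3)),
               mapValues(sampleToSurface(cv, surf, 0.9)))
  ## sampling outside the volume is an error
  far <- flatSheetSurface(nx = 3, ny = 3, h = 1, thickness = 1, z0 = 50)
  expect_error(sampleToSurface(vol, far, 0.5),
               class = "corticomap_sample_out_of_bounds")
})

test_that("optimal depth fraction maximizes mean intensity with ties to 0", {
  surf <- flatSheetSurface(nx = 9, ny = 9, h = 0.5, thickness = 1, z0 = 0)
  ## volume whose value peaks at a chosen depth: value = -(z - zpeak)^2;
  ## 0.1 mm voxels so the peak sits on a voxel centre (exhaustive over the
  ## 11-step grid)
  mkPeak <- function(zpeak, n = 60, vs = 0.1, z0 = -2) {
    zv <- z0 + (seq_len(n) - 1) * vs
    tr <- diag(c(vs, vs, vs, 1)); tr[1:3, 4] <- c(-0.5, -0.5, z0)
    brainVolume(array(rep(-(zv - zpeak)^2, each = n * n), c(n, n, n)),
                voxelSize = rep(vs, 3), transform = tr)
  }
  ## peak at z = 0.1 => depth fraction (0.1 + 0.5)/1 = 0.6
  expect_equal(as.numeric(optimalDepthFraction(mkPeak(0.1), surf)), 0.6)
  ## peak at z = -0.3 => depth fraction 0.2
  expect_equal(as.numeric(optimalDepthFraction(mkPeak(-0.3), surf)), 0.2)
  ## uniform volume: exact tie, resolved toward the smaller fraction
  cv <- brainVolume(array(1, c(60, 60, 60)), voxelSize = rep(0.1, 3),
                    transform = mkPeak(0)@transform)
  expect_equal(as.numeric(optimalDepthFraction(cv, surf)), 0)
})

test_that("threshold rules reproduce hand-computed masks", {
  surf <- flatSheetSurface(nx = 3, ny = 3)
  m <- vertexMap(1:9, surf)
  top <- thresholdMap(m, topFraction(1 / 3), surf)
  expect_identical(maskIndices(top), 7:9)

  surf5 <- flatSheetSurface(nx = 5, ny = 1)
  ## values [0,0,0,0,4]: mean 0.8, sd 1.789, sem 0.8 -> cut 1.6 -> only the 4
  m5 <- vertexMap(c(0, 0, 0, 0, 4), surf5)
  sem1 <- thresholdMap(m5, meanPlusKSEM(1), surf5)
  expect_identical(maskIndices(sem1), 5L)
  expect_equal(attr(sem1, "threshold"), 1.6, tolerance = 1e-12)

  ## mean + 0 SEM on symmetric values keeps about half
  surfBig <- flatSheetSurface(nx = 100, ny = 100)
  set.seed(7)
  mBig <- vertexMap(rnorm(1e4), surfBig)
  frac <- maskSize(thresholdMap(mBig, meanPlusKSEM(0), surfBig)) / 1e4
  expect_lt(abs(frac - 0.5), 0.02)

  ## the intensity-range reading of "top third"
  mR <- vertexMap(c(0, 30, 59, 61, 90), flatSheetSurface(5, 1))
  topR <- thresholdMap(mR, topFraction(1 / 3, reading = "intensity_range"),
                       flatSheetSurface(5, 1))
  expect_identical(maskIndices(topR), 4:5)   # cut at 0 + 2/3 * 90 = 60
})

test_that("exclusion masks leave the reference statistics untouched", {
  surf <- flatSheetSurface(nx = 3, ny = 2)
  m <- vertexMap(c(1, 2, 3, 4, 5, 100), surf)
  excl <- vertexMask(6, surf)
  ## without exclusion, 100 dominates mean + sem; with exclusion the
  ## reference population is 1..5
  withx <- thresholdMap(m, meanPlusKSEM(1), surf, exclusionMask = excl)
  expect_false(6L %in% maskIndices(withx))
  ## reference population 1..5: mean 3, sem 0.7071 -> cut 3.707 -> {4, 5}
  expect_identical(maskIndices(withx), 4:5)
  expect_error(thresholdMap(vertexMap(1:6, surf), topFraction(0.5), surf,
                            exclusionMask = vertexMask(1:5, surf)),
               class = "corticomap_empty_after_exclusion")
})

test_that("threshold masks are monotone, exclusion-consistent and scale-free", {
  surf <- flatSheetSurface(nx = 20, ny = 20)
  set.seed(11)
  m <- vertexMap(rnorm(400), surf)
  ## monotone in k and in f
  prev <- NULL
  for (k in c(0, 0.5, 1, 1.5, 2)) {
    cur <- maskIndices(thresholdMap(m, meanPlusKSEM(k), surf))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (f in c(0.5, 0.3, 0.2, 0.1)) {
    cur <- maskIndices(thresholdMap(m, topFraction(f), surf))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  ## exclusions never appear in the output, and the reference statistics
  ## are recomputed over the surviving population only
  set.seed(12)
  for (i in 1:20) {
    excl <- vertexMask(sample(400, sample(1:100, 1)), surf)
    cur <- thresholdMap(m, meanPlusKSEM(1), surf, exclusionMask = excl)
    expect_length(intersect(maskIndices(cur), maskIndices(excl)), 0)
    keep <- setdiff(seq_len(400), maskIndices(excl))
    v <- mapValues(m)[keep]
    expect_equal(attr(cur, "threshold"),
                 mean(v) + sd(v) / sqrt(length(v)))
  }
  ## scaling all values by c > 0 changes neither rule's mask
  m2 <- vertexMap(mapValues(m) * 37.5, surf)
  expect_identical(maskIndices(thresholdMap(m2, topFraction(0.25), surf)),
                   maskIndices(thresholdMap(m, topFraction(0.25), surf)))
  expect_identical(maskIndices(thresholdMap(m2, meanPlusKSEM(1), surf)),
                   maskIndices(thresholdMap(m, meanPlusKSEM(1), surf)))
})

test_that("contiguous region area follows the mask component of the seed", {
  surf <- flatSheetSurface(nx = 6, ny = 6)
  areas <- vertexAreas(surf)
  ## a single marked vertex contributes its own per-vertex area
  single <- vertexMask(8, surf)
  expect_equal(as.numeric(contiguousRegionArea(single, surf, 8)), areas[8])
  ## two disjoint blobs: only the seeded one counts
  blob1 <- c(1, 2, 7, 8)          # corner block (nx = 6)
  blob2 <- c(29, 30, 35, 36)      # opposite corner
  both <- vertexMask(c(blob1, blob2), surf)
  a1 <- contiguousRegionArea(both, surf, 1)
  expect_equal(sort(attr(a1, "vertices")), sort(as.integer(blob1)))
  expect_equal(as.numeric(a1), sum(areas[blob1]))
  expect_error(contiguousRegionArea(both, surf, 15),
               class = "corticomap_seed_not_in_mask")
})

test_that("display clipping plateaus the extremes and nothing else", {
  surf <- flatSheetSurface(nx = 101, ny = 1)
  m <- vertexMap(0:100, surf)
  clipped <- displayClip(m, 4, 96)
  expect_equal(range(mapValues(clipped)), c(4, 96))
  ## interior values untouched
  expect_equal(mapValues(clipped)[20], 19)
  ## identity and constant-map edge cases
  expect_equal(mapValues(displayClip(m, 0, 100)), mapValues(m))
  const <- vertexMap(rep(3, 101), surf)
  expect_equal(mapValues(displayClip(const)), rep(3, 101))
})

test_that("noisy phantoms recover the patch area within tolerance", {
  ## a focused version of the recovery property: one noisy, biased phantom
  spec <- testSpec(noiseSD = 0.06, biasAmplitude = 0.1, seed = 5L)
  ph <- makePhantom(spec)
  st <- renderStructural(ph$surface, ph$truth, spec)
  map <- sampleToSurface(ratioMap(st$t1w, st$t2w), ph$surface, 0.6)
  fTrue <- ph$truth@patchArea / sum(vertexAreas(ph$surface))
  mask <- thresholdMap(map, topFraction(fTrue), ph$surface)
  a <- contiguousRegionArea(mask, ph$surface, patchSeedVertex(ph))
  expect_lt(abs(a - ph$truth@patchArea) / ph$truth@patchArea, 0.15)
})
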