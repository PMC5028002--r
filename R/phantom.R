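## Synthetic cortical phantom: a single sheet of cortex (flat or folded in
## one direction, hence developable and geodesically flat) carrying a
## depth-dependent myelin field with an embedded high-myelin disc patch (the
## V5/MT-MST analogue). Ground truth is computed from geometry alone and is
## independent of every rendering setting.
##
## Geometry. The midthickness is the graph z = A sin(2*pi*x/lambda). White
## and pial surfaces are vertical offsets of +-h(x) with
## h(x) = (t/2) * sqrt(1 + f'(x)^2), chosen so that the normal distance
## between them equals the cortical thickness t everywhere. The sheet's
## intrinsic (arc-length) coordinates are (s(x), y) with
## s(x) = integral of sqrt(1 + f'(u)^2); geodesic discs in these coordinates
## are exact, so a patch of radius r has true area pi*r^2 wherever it fits.

#' Construct a phantom specification
#'
#' Defaults describe the stated world: a 30 x 30 mm sheet sampled at 0.3 mm
#' (10201 vertices), 2 mm cortical thickness, myelin peaking at depth
#' fraction 0.6, a 5 mm-radius patch with 1.5x myelin contrast (area
#' pi*25 ~ 78.5 mm^2, the scale of the V5/MT-MST complex), 0.5 mm rendering
#' voxels, 5% structural noise, 10% bias fields, a functional cluster offset
#' 2 mm from the patch, and an 8-cycle phase-encoded run (256 frames, TR 2 s,
#' 64 s period).
#'
#' @param ... named overrides of \linkS4class{PhantomSpec} slots.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  defaults <- list(
    sheetExtent = c(30, 30), vertexSpacing = 0.3,
    foldAmplitude = 0, foldWavelength = 15, sheetTilt = 0.15, thickness = 2,
    profilePeakDepth = 0.6, profileWidth = 0.2, profileFloor = 0.5,
    patchCenter = c(15, 15), patchRadius = 5, patchContrast = 1.5,
    voxelSize = 0.5, noiseSD = 0.05, biasAmplitude = 0.1,
    clusterOffset = c(2, 0), clusterRadius = 4, clusterPeakZ = 6,
    ipsiRadius = 2, ipsiShift = 3, ipsiPeakZ = 5,
    retinoPeriod = 64, retinoFrames = 256L, retinoInterval = 2,
    retinoAmplitude = 1, retinoNoiseSD = 0.5,
    seed = 1L)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad))
    stop(corticomapError("bad_spec_field",
      paste("unknown PhantomSpec field(s):", paste(bad, collapse = ", "))))
  vals <- utils::modifyList(defaults, args)
  vals$retinoFrames <- as.integer(vals$retinoFrames)
  vals$seed <- as.integer(vals$seed)
  do.call(new, c(list(Class = "PhantomSpec"), vals))
}

## evaluate expr under a given seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

foldDeriv <- function(spec, x) {
  out <- rep(spec@sheetTilt, length(x))
  if (spec@foldAmplitude != 0)
    out <- out + spec@foldAmplitude * (2 * pi / spec@foldWavelength) *
      cos(2 * pi * x / spec@foldWavelength)
  out
}

foldHeight <- function(spec, x) {
  out <- spec@sheetTilt * x
  if (spec@foldAmplitude != 0)
    out <- out + spec@foldAmplitude * sin(2 * pi * x / spec@foldWavelength)
  out
}

## arc-length s(x) along the fold, via fine trapezoid integration
arcLengthFun <- function(spec) {
  if (spec@foldAmplitude == 0) {
    sc <- sqrt(1 + spec@sheetTilt^2)
    return(function(x) x * sc)
  }
  xs <- seq(0, spec@sheetExtent[1], by = min(0.01, spec@vertexSpacing / 8))
  g <- sqrt(1 + foldDeriv(spec, xs)^2)
  s <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * diff(xs)))
  function(x) stats::approx(xs, s, xout = x, rule = 2)$y
}

## z range of the midthickness over the sheet
midZRange <- function(spec) {
  range(foldHeight(spec, seq(0, spec@sheetExtent[1], length.out = 512)))
}

#' Generate a phantom surface and its ground truth
#'
#' Builds the folded-sheet cortical surface (white/pial pairs on a shared
#' regular triangulation) and records geometry-only truth: the patch vertex
#' set (geodesic disc in intrinsic coordinates), its true surface area
#' (summed per-vertex midthickness areas), and the depth fraction of peak
#' myelin. Deterministic: no random numbers are consumed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{surface} (\linkS4class{CorticalSurface})
#'   and \code{truth} (\linkS4class{PhantomTruth}).
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  ext <- spec@sheetExtent
  xs <- seq(0, ext[1], by = spec@vertexSpacing)
  ys <- seq(0, ext[2], by = spec@vertexSpacing)
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(x = xs, y = ys)
  fp <- foldDeriv(spec, g$x)
  hv <- (spec@thickness / 2) * sqrt(1 + fp^2)
  zmid <- foldHeight(spec, g$x)
  white <- cbind(g$x, g$y, zmid - hv)
  pial <- cbind(g$x, g$y, zmid + hv)
  ## regular grid triangulation (two triangles per cell)
  idx <- matrix(seq_len(nx * ny), nrow = nx)
  v00 <- as.vector(idx[-nx, -ny]); v10 <- as.vector(idx[-1, -ny])
  v01 <- as.vector(idx[-nx, -1]);  v11 <- as.vector(idx[-1, -1])
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  surface <- corticalSurface(white, pial, faces, hemisphere = "left")
  sfun <- arcLengthFun(spec)
  sheet <- cbind(sfun(g$x), g$y)
  sc <- c(sfun(spec@patchCenter[1]), spec@patchCenter[2])
  sMax <- sfun(ext[1])
  r <- spec@patchRadius
  if (sc[1] - r < 0 || sc[1] + r > sMax || sc[2] - r < 0 || sc[2] + r > ext[2])
    stop(corticomapError("patch_too_large",
      "patch disc does not fit inside the sheet extent"))
  d2 <- (sheet[, 1] - sc[1])^2 + (sheet[, 2] - sc[2])^2
  patch <- which(d2 <= r^2)
  areas <- vertexAreas(surface)
  truth <- new("PhantomTruth",
               patchVertices = as.integer(patch),
               patchArea = sum(areas[patch]),
               peakDepth = spec@profilePeakDepth,
               sheetCoords = sheet,
               surfaceRef = parentFingerprint(surface))
  list(surface = surface, truth = truth)
}

## myelin depth profile, peak value 1
myelinProfile <- function(spec, depth) {
  spec@profileFloor + (1 - spec@profileFloor) *
    exp(-(depth - spec@profilePeakDepth)^2 / (2 * spec@profileWidth^2))
}

## the rendering grid and per-voxel geometry shared by all renders
phantomGrid <- function(spec, margin = 2) {
  ext <- spec@sheetExtent
  vs <- spec@voxelSize
  zr <- midZRange(spec)
  zmin <- zr[1] - spec@thickness - margin
  zmax <- zr[2] + spec@thickness + margin
  x0 <- -margin; y0 <- -margin
  nxv <- ceiling((ext[1] + 2 * margin) / vs)
  nyv <- ceiling((ext[2] + 2 * margin) / vs)
  nzv <- ceiling((zmax - zmin) / vs)
  transform <- diag(c(vs, vs, vs, 1))
  transform[1:3, 4] <- c(x0, y0, zmin)
  ii <- seq_len(nxv) - 1L; jj <- seq_len(nyv) - 1L; kk <- seq_len(nzv) - 1L
  wx <- x0 + ii * vs; wy <- y0 + jj * vs; wz <- zmin + kk * vs
  dims <- c(nxv, nyv, nzv)
  ## per-voxel geometry, vectorized over the full grid
  X <- array(rep(wx, times = nyv * nzv), dims)
  Z <- array(rep(wz, each = nxv * nyv), dims)
  fp <- foldDeriv(spec, wx)
  hvx <- (spec@thickness / 2) * sqrt(1 + fp^2)
  zm <- foldHeight(spec, wx)
  Hv <- array(rep(hvx, times = nyv * nzv), dims)
  Zm <- array(rep(zm, times = nyv * nzv), dims)
  depth <- (Z - (Zm - Hv)) / (2 * Hv)
  inSheetX <- wx >= 0 & wx <= ext[1]
  inSheetY <- wy >= 0 & wy <= ext[2]
  inSheet <- array(rep(inSheetX, times = nyv * nzv), dims) &
    array(rep(rep(inSheetY, each = nxv), times = nzv), dims)
  inRibbon <- inSheet & depth >= 0 & depth <= 1
  sfun <- arcLengthFun(spec)
  sx <- sfun(wx)
  S <- array(rep(sx, times = nyv * nzv), dims)
  Y <- array(rep(rep(wy, each = nxv), times = nzv), dims)
  list(dims = dims, transform = transform, voxelSize = rep(vs, 3),
       depth = depth, inRibbon = inRibbon, S = S, Y = Y, X = X, Z = Z,
       sfun = sfun)
}

## sheet-coordinate distance^2 from a centre, over the grid
sheetDist2 <- function(grid, center) {
  (grid$S - center[1])^2 + (grid$Y - center[2])^2
}

## smooth low-order polynomial bias field with max |deviation| = amplitude
biasField <- function(grid, amplitude) {
  if (amplitude == 0) return(1)
  d <- grid$dims
  u <- (grid$X - mean(range(grid$X))) / diff(range(grid$X))
  v <- (grid$Y - mean(range(grid$Y))) / diff(range(grid$Y))
  w <- (grid$Z - mean(range(grid$Z))) / diff(range(grid$Z))
  cf <- stats::runif(9, -1, 1)
  p <- cf[1] * u + cf[2] * v + cf[3] * w + cf[4] * u * v + cf[5] * u * w +
    cf[6] * v * w + cf[7] * u^2 + cf[8] * v^2 + cf[9] * w^2
  1 + amplitude * p / max(abs(p))
}

## noiseless myelin field over the grid (truth map; NA outside the ribbon)
phantomMyelinField <- function(spec, grid, truth) {
  sc <- c(grid$sfun(spec@patchCenter[1]), spec@patchCenter[2])
  inPatch <- sheetDist2(grid, sc) <= spec@patchRadius^2
  M <- myelinProfile(spec, grid$depth) *
    (1 + (spec@patchContrast - 1) * inPatch)
  M[!grid$inRibbon] <- NA_real_
  M
}

#' Render the structural (T1w, T2w) volumes of a phantom
#'
#' Within the ribbon, T1w intensity increases and T2w decreases with the
#' local myelin value, so the T1w/T2w ratio is strictly increasing in true
#' myelin when noise and bias are off. Each volume is multiplied by an
#' independent smooth polynomial bias field (amplitude per spec) and receives
#' additive Gaussian noise. Outside the ribbon, voxels take CSF/white-matter
#' analogue levels.
#'
#' @param surface phantom surface from \code{\link{makePhantom}}.
#' @param truth matching \linkS4class{PhantomTruth}.
#' @param spec the \linkS4class{PhantomSpec}.
#' @return list with \code{t1w}, \code{t2w} (\linkS4class{BrainVolume}),
#'   \code{myelin} (noiseless truth \linkS4class{BrainVolume}, invalid
#'   outside the ribbon) and \code{grid} metadata.
#' @export
renderStructural <- function(surface, truth, spec) {
  grid <- phantomGrid(spec)
  M <- phantomMyelinField(spec, grid, truth)
  gm <- grid$inRibbon
  csf <- grid$depth > 1 | is.na(grid$depth)
  wm <- !gm & !csf
  ## background classes: CSF dark in T1w, bright in T2w; the white-matter
  ## analogue sits just below peak cortical ratio (dense deep-layer myelin
  ## approaches white matter intensity), so depth profiles are dominated by
  ## intracortical contrast rather than boundary partial volume
  t1 <- array(0.35, grid$dims); t2 <- array(1.6, grid$dims)
  t1[wm] <- 1.4; t2[wm] <- 0.75
  t1[gm] <- 0.9 + 0.6 * M[gm]
  t2[gm] <- 1.3 - 0.6 * M[gm]
  withSeed(spec@seed, {
    b1 <- biasField(grid, spec@biasAmplitude)
    b2 <- biasField(grid, spec@biasAmplitude)
    n <- prod(grid$dims)
    t1 <- t1 * b1 + stats::rnorm(n, 0, spec@noiseSD)
    t2 <- t2 * b2 + stats::rnorm(n, 0, spec@noiseSD)
  })
  mk <- function(a) brainVolume(a, voxelSize = grid$voxelSize,
                                transform = grid$transform,
                                spaceTag = "phantom")
  myel <- M
  list(t1w = mk(t1), t2w = mk(t2), myelin = mk(myel), grid = grid)
}

#' Render a functional z-statistic volume of a phantom
#'
#' A smooth Gaussian-profile cluster of configurable peak z is placed at the
#' configured sheet-coordinate offset from the patch centre, within the
#' ribbon, on an N(0,1) noise background. The ipsilateral contrast adds a
#' smaller anterior (+x) subcluster, the MST analogue. The truth voxel set
#' is the noiseless suprathreshold (z > 2.3) set.
#'
#' @param surface phantom surface.
#' @param truth matching \linkS4class{PhantomTruth}.
#' @param spec the \linkS4class{PhantomSpec}.
#' @param contrast "full_field" or "ipsilateral".
#' @return list with \code{zmap} (\linkS4class{BrainVolume}),
#'   \code{clusterVoxels} (truth \linkS4class{IndexMask}) and
#'   \code{deterministic} (the noiseless z volume).
#' @export
renderFunctional <- function(surface, truth, spec,
                             contrast = c("full_field", "ipsilateral")) {
  contrast <- match.arg(contrast)
  grid <- phantomGrid(spec)
  sc <- c(grid$sfun(spec@patchCenter[1]), spec@patchCenter[2])
  center <- sc + spec@clusterOffset
  if (contrast == "full_field") {
    sigma <- spec@clusterRadius / 2
    zdet <- spec@clusterPeakZ * exp(-sheetDist2(grid, center) / (2 * sigma^2))
  } else {
    ic <- center + c(spec@ipsiShift, 0)
    sigma <- spec@ipsiRadius / 2
    zdet <- spec@ipsiPeakZ * exp(-sheetDist2(grid, ic) / (2 * sigma^2))
  }
  zdet[!grid$inRibbon] <- 0
  seedOff <- if (contrast == "full_field") 101L else 102L
  z <- withSeed(spec@seed + seedOff,
                zdet + stats::rnorm(prod(grid$dims)))
  zmap <- brainVolume(array(z, grid$dims), voxelSize = grid$voxelSize,
                      transform = grid$transform, spaceTag = "phantom")
  det <- brainVolume(zdet, voxelSize = grid$voxelSize,
                     transform = grid$transform, spaceTag = "phantom")
  mask <- voxelMask(which(zdet > 2.3), zmap)
  list(zmap = zmap, clusterVoxels = mask, deterministic = det, grid = grid)
}

#' Render a phase-encoded retinotopy time series of a phantom
#'
#' In-cluster voxels (the truth full-field cluster set) respond with
#' amplitude * cos(2*pi*f*t - phase), where the true phase is the polar
#' angle of the voxel around the cluster centre in sheet coordinates
#' (wrapped to [0, 2*pi)); all voxels receive independent Gaussian noise.
#'
#' @param surface phantom surface.
#' @param truth matching \linkS4class{PhantomTruth}.
#' @param spec the \linkS4class{PhantomSpec}; the run must span at least 2
#'   stimulus cycles.
#' @return list with \code{series} (\linkS4class{BrainTimeSeries}),
#'   \code{truePhase} (3D array, NA outside the cluster) and
#'   \code{clusterVoxels}.
#' @export
renderRetinotopy <- function(surface, truth, spec) {
  nCycles <- spec@retinoFrames * spec@retinoInterval / spec@retinoPeriod
  if (nCycles < 2)
    stop(corticomapError("too_few_cycles",
      "the run must span at least 2 stimulus cycles"))
  ff <- renderFunctional(surface, truth, spec, "full_field")
  grid <- ff$grid
  idx <- maskIndices(ff$clusterVoxels)
  sc <- c(grid$sfun(spec@patchCenter[1]), spec@patchCenter[2])
  center <- sc + spec@clusterOffset
  phase <- array(NA_real_, grid$dims)
  phase[idx] <- (atan2(grid$Y[idx] - center[2], grid$S[idx] - center[1])) %%
    (2 * pi)
  tgrid <- (seq_len(spec@retinoFrames) - 1L) * spec@retinoInterval
  f <- 1 / spec@retinoPeriod
  nvox <- prod(grid$dims)
  data <- withSeed(spec@seed + 103L, {
    arr <- array(stats::rnorm(nvox * spec@retinoFrames, 0,
                              spec@retinoNoiseSD),
                 c(grid$dims, spec@retinoFrames))
    if (length(idx) && spec@retinoAmplitude != 0) {
      sig <- spec@retinoAmplitude *
        cos(outer(rep(1, length(idx)), 2 * pi * f * tgrid) -
              outer(phase[idx], rep(1, spec@retinoFrames)))
      for (t in seq_len(spec@retinoFrames)) {
        frame <- arr[, , , t]
        frame[idx] <- frame[idx] + sig[, t]
        arr[, , , t] <- frame
      }
    }
    arr
  })
  series <- brainTimeSeries(data, voxelSize = grid$voxelSize,
                            transform = grid$transform,
                            spaceTag = "phantom",
                            frameInterval = spec@retinoInterval)
  list(series = series, truePhase = phase, clusterVoxels = ff$clusterVoxels)
}

#' Midpoint stain threshold for a phantom's histology renders
#'
#' The grayscale value halfway between the non-patch and patch stain
#' intensities at the depth where \code{\link{sectionMyelinLength}} samples
#' (fraction \code{deepFraction} of the pial-to-white distance), computed
#' analytically from the spec's stain model (tissue value
#' 220 - 130 * myelin).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param deepFraction sampling depth, fraction of pial-to-white distance.
#' @return grayscale threshold.
#' @export
stainThresholdFor <- function(spec, deepFraction = 0.7) {
  d <- 1 - deepFraction              # depth fraction from the white surface
  base <- myelinProfile(spec, d)
  (2 * 220 - 130 * base * (1 + spec@patchContrast)) / 2
}

#' Render a Gallyas-like histology section series of a phantom
#'
#' Sections are cut perpendicular to the sheet's y axis (the mediolateral
#' analogue) at the given spacing; each section is a grayscale raster in the
#' (x, z) plane where stain darkness increases with local myelin (dense
#' myelin is dark). The per-section true myelinated length along the pial
#' surface is recorded: for a disc patch it is the chord
#' 2*sqrt(r^2 - dy^2) in intrinsic coordinates.
#'
#' @param surface phantom surface.
#' @param truth matching \linkS4class{PhantomTruth}.
#' @param spec the \linkS4class{PhantomSpec}.
#' @param spacing mm between retained sections.
#' @param thickness section thickness in micrometres (metadata).
#' @param pixelSize mm per raster pixel.
#' @param noiseSD grayscale noise sd (default 0: noiseless stain).
#' @param margin extra sheet length covered beyond the patch, mm.
#' @return list with \code{series} (\linkS4class{SectionSeries}),
#'   \code{trueLengths} (mm per section), \code{positions} (section y, mm)
#'   and per-section \code{pialTrace}/\code{whiteTrace} polylines in image
#'   mm coordinates.
#' @export
renderHistology <- function(surface, truth, spec, spacing = 0.5,
                            thickness = 50, pixelSize = 0.05,
                            noiseSD = 0, margin = 2) {
  yc <- spec@patchCenter[2]; r <- spec@patchRadius
  positions <- seq(yc - r - margin, yc + r + margin, by = spacing)
  positions <- positions[positions >= 0 & positions <= spec@sheetExtent[2]]
  if (!length(positions))
    stop(corticomapError("empty_intersection",
      "section positions do not intersect the ribbon"))
  ext <- spec@sheetExtent
  zr <- midZRange(spec)
  zmin <- zr[1] - spec@thickness - 0.5
  zmax <- zr[2] + spec@thickness + 0.5
  xs <- seq(pixelSize / 2, ext[1] - pixelSize / 2, by = pixelSize)
  zs <- seq(zmin + pixelSize / 2, zmax - pixelSize / 2, by = pixelSize)
  sfun <- arcLengthFun(spec)
  sxs <- sfun(xs)
  sc <- c(sfun(spec@patchCenter[1]), yc)
  fp <- foldDeriv(spec, xs)
  hv <- (spec@thickness / 2) * sqrt(1 + fp^2)
  zm <- foldHeight(spec, xs)
  images <- vector("list", length(positions))
  pialTrace <- vector("list", length(positions))
  whiteTrace <- vector("list", length(positions))
  trueLengths <- numeric(length(positions))
  withSeed(spec@seed + 104L, {
    for (k in seq_along(positions)) {
      yk <- positions[k]
      dy2 <- (yk - sc[2])^2
      inPatchX <- (sxs - sc[1])^2 + dy2 <= r^2
      depth <- outer(zm - hv, rep(1, length(zs)))
      depth <- (outer(rep(1, length(xs)), zs) - depth) /
        outer(2 * hv, rep(1, length(zs)))
      M <- myelinProfile(spec, depth) *
        (1 + (spec@patchContrast - 1) * outer(inPatchX, rep(TRUE, length(zs))))
      img <- matrix(230, length(xs), length(zs))
      tissue <- depth >= 0 & depth <= 1
      img[tissue] <- 220 - 130 * M[tissue]
      if (noiseSD > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, noiseSD),
                            nrow(img), ncol(img))
      images[[k]] <- img
      pialTrace[[k]] <- cbind(xs, zm + hv - zmin)
      whiteTrace[[k]] <- cbind(xs, zm - hv - zmin)
      trueLengths[k] <- if (dy2 < r^2) 2 * sqrt(r^2 - dy2) else 0
    }
  })
  series <- new("SectionSeries", images = images, pixelSize = pixelSize,
                spacing = spacing, thickness = thickness,
                positions = positions, orientation = "parasagittal")
  list(series = series, trueLengths = trueLengths, positions = positions,
       pialTrace = pialTrace, whiteTrace = whiteTrace)
}
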