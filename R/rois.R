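## Functional ROI definition: z-map cluster extraction with a
## permutation-calibrated extent criterion, the hMT+/MST/V5-MT assignment
## rules, Fourier analysis of phase-encoded retinotopy, and group masks.

#' Cluster-forming configuration
#'
#' Voxels above \code{zThreshold} are grouped into connected components
#' under the given connectivity; components survive if their extent exceeds
#' the extent criterion. Gaussian-random-field cluster p-values are out of
#' scope: with \code{minExtent = "permutation"} the criterion is calibrated
#' by sign-flip surrogates of the z-map (null distribution of the largest
#' suprathreshold cluster; extent taken at the 1 - clusterAlpha quantile);
#' an integer \code{minExtent} overrides this with a fixed voxel count.
#'
#' @param zThreshold cluster-forming threshold (default 2.3).
#' @param clusterAlpha cluster-level alpha (default 0.05).
#' @param minExtent "permutation" or a fixed voxel count.
#' @param connectivity 6, 18 or 26.
#' @param nPerm surrogates used when \code{minExtent = "permutation"}.
#' @param seed RNG seed for the surrogates.
#' @return a cluster-config object.
#' @export
clusterConfig <- function(zThreshold = 2.3, clusterAlpha = 0.05,
                          minExtent = "permutation", connectivity = 26,
                          nPerm = 1000L, seed = 0L) {
  stopifnot(clusterAlpha > 0, clusterAlpha < 1,
            connectivity %in% c(6, 18, 26))
  structure(list(zThreshold = zThreshold, clusterAlpha = clusterAlpha,
                 minExtent = minExtent, connectivity = connectivity,
                 nPerm = as.integer(nPerm), seed = as.integer(seed)),
            class = "corticomap_cluster_config")
}

connectivityOffsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  off <- off[nz > 0, , drop = FALSE]
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 `6` = nz == 1, `18` = nz <= 2, `26` = nz <= 3)
  off <- off[keep, , drop = FALSE]
  ## half neighbourhood: lexicographically positive offsets only
  pos <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off[pos, , drop = FALSE]
}

## connected components of TRUE voxels in a 3D logical array;
## returns a list of 1-based linear index vectors
componentIndexSets <- function(mask3d, connectivity) {
  d <- dim(mask3d)
  cand <- which(mask3d)
  if (!length(cand)) return(list())
  idmap <- integer(prod(d)); idmap[cand] <- seq_along(cand)
  pos <- arrayInd(cand, d)
  offs <- connectivityOffsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
    hit <- idmap[lin] > 0L
    edges[[length(edges) + 1L]] <-
      cbind(idmap[cand[ok]][hit], idmap[lin][hit])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(cand), directed = FALSE)
  if (!is.null(e) && nrow(e)) g <- igraph::add_edges(g, t(e))
  memb <- igraph::components(g)$membership
  split(cand, memb)
}

## null distribution of the largest suprathreshold cluster under sign flips
permutationExtent <- function(zmap, cfg) {
  d <- dim(zmap@data)
  cand <- which(abs(zmap@data) > cfg$zThreshold & zmap@valid)
  if (!length(cand)) return(0)
  ## adjacency among candidate voxels, computed once
  idmap <- integer(prod(d)); idmap[cand] <- seq_along(cand)
  pos <- arrayInd(cand, d)
  offs <- connectivityOffsets(cfg$connectivity)
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
    hit <- idmap[lin] > 0L
    efrom <- c(efrom, idmap[cand[ok]][hit])
    eto <- c(eto, idmap[lin][hit])
  }
  nulls <- withSeed(cfg$seed, vapply(seq_len(cfg$nPerm), function(i) {
    act <- stats::runif(length(cand)) < 0.5
    if (!any(act)) return(0)
    keep <- act[efrom] & act[eto]
    g <- igraph::make_empty_graph(n = length(cand), directed = FALSE)
    if (any(keep))
      g <- igraph::add_edges(g, rbind(efrom[keep], eto[keep]))
    memb <- igraph::components(g)$membership
    max(tabulate(memb[act]))
  }, numeric(1)))
  stats::quantile(nulls, 1 - cfg$clusterAlpha, names = FALSE, type = 1)
}

#' Extract suprathreshold clusters from a z-statistic map
#'
#' Connected components of \{z > zThreshold\} under the configured
#' connectivity, retaining those whose voxel extent exceeds the extent
#' criterion; the surviving clusters are returned sorted by decreasing peak
#' z. The extent criterion used is attached as the "minExtent" attribute.
#'
#' @param zmap a \linkS4class{BrainVolume} of z statistics.
#' @param cfg a \code{\link{clusterConfig}}.
#' @return list of voxel \linkS4class{IndexMask} objects (possibly empty).
#' @export
extractClusters <- function(zmap, cfg = clusterConfig()) {
  supra <- zmap@data > cfg$zThreshold & zmap@valid
  comps <- componentIndexSets(supra, cfg$connectivity)
  minExtent <- if (identical(cfg$minExtent, "permutation"))
    permutationExtent(zmap, cfg) else cfg$minExtent
  comps <- Filter(function(ix) length(ix) > minExtent, comps)
  if (length(comps)) {
    peaks <- vapply(comps, function(ix) max(zmap@data[ix]), numeric(1))
    comps <- comps[order(-peaks)]
  }
  out <- lapply(comps, voxelMask, volume = zmap)
  attr(out, "minExtent") <- minExtent
  out
}

voxelWorldCoords <- function(volume, indices) {
  ijk <- arrayInd(indices, dim(volume@data)) - 1L
  (cbind(ijk, 1) %*% t(volume@transform))[, 1:3, drop = FALSE]
}

#' Define the hMT+ complex from a full-field motion z-map
#'
#' Among the surviving clusters, returns the one whose peak voxel lies
#' nearest (in world coordinates) to the anchor — the user-supplied putative
#' anatomical location of the complex. Proximity beats size; exact distance
#' ties break toward the higher-peak (lower-index) cluster, with a message.
#'
#' @param fullFieldZmap a \linkS4class{BrainVolume}.
#' @param cfg a \code{\link{clusterConfig}}.
#' @param anchor numeric(3) world coordinate, mm.
#' @return a voxel \linkS4class{IndexMask}.
#' @export
defineHMT <- function(fullFieldZmap, cfg, anchor) {
  clusters <- extractClusters(fullFieldZmap, cfg)
  if (!length(clusters))
    stop(corticomapError("no_clusters", "no surviving clusters"))
  dist <- vapply(clusters, function(m) {
    ix <- maskIndices(m)
    peak <- ix[which.max(fullFieldZmap@data[ix])]
    sqrt(sum((voxelWorldCoords(fullFieldZmap, peak) - anchor)^2))
  }, numeric(1))
  best <- which(dist == min(dist))
  if (length(best) > 1L)
    message("defineHMT: anchor equidistant from ", length(best),
            " clusters; keeping the highest-peak one")
  clusters[[best[1]]]
}

#' Define MST from the ipsilateral-motion z-map
#'
#' The union of ipsilateral clusters that intersect hMT+, each included in
#' full — including any voxels extending outside hMT+ (when ipsilateral
#' activation forms a single cluster extending beyond the complex, the
#' entire cluster is kept).
#'
#' @param hmt the hMT+ voxel \linkS4class{IndexMask}.
#' @param ipsiZmap a \linkS4class{BrainVolume}.
#' @param cfg a \code{\link{clusterConfig}}.
#' @return a voxel \linkS4class{IndexMask} (possibly empty).
#' @export
defineMST <- function(hmt, ipsiZmap, cfg) {
  if (!identical(hmt@parentRef, parentFingerprint(ipsiZmap)))
    stop(corticomapError("grid_mismatch",
      "hMT+ mask and ipsilateral z-map are on different grids"))
  clusters <- extractClusters(ipsiZmap, cfg)
  keep <- integer(0)
  for (cl in clusters)
    if (length(intersect(maskIndices(cl), maskIndices(hmt))))
      keep <- union(keep, maskIndices(cl))
  voxelMask(keep, ipsiZmap)
}

#' Fourier analysis of phase-encoded retinotopy runs
#'
#' Per run, each voxel's time course is (optionally) linearly detrended and
#' discrete-Fourier transformed; the complex components are averaged across
#' repeat runs (vector averaging, before phase extraction). Phase (radians
#' in [0, 2*pi), under the cos(2*pi*f*t - phase) convention), amplitude and
#' coherence are taken at the stimulus-frequency bin. Coherence is the
#' stimulus-bin amplitude divided by the root-sum-square amplitude over all
#' positive non-DC frequency bins of the averaged spectrum.
#'
#' The trend is estimated jointly with the stimulus sine/cosine pair and
#' only the intercept and slope are removed: over a finite run a linear ramp
#' is not exactly orthogonal to the stimulus frequency, and removing a
#' naively fitted trend would leak a pure tone into neighbouring bins and
#' bias its phase.
#'
#' @param runs a \linkS4class{BrainTimeSeries} or list of repeat runs on a
#'   common grid with equal frame counts.
#' @param stimulusPeriod stimulus period, seconds; must land on a DFT bin
#'   (nFrames * frameInterval must be an integer multiple >= 2 of it).
#' @param detrend remove a per-voxel linear trend first (default TRUE).
#' @return A \linkS4class{RetinotopyResult}.
#' @export
fourierRetinotopy <- function(runs, stimulusPeriod, detrend = TRUE) {
  if (is(runs, "BrainTimeSeries")) runs <- list(runs)
  ref <- runs[[1]]
  for (r in runs) checkSameGrid(ref, r)
  nt <- dim(ref@data)[4]
  dt <- ref@frameInterval
  kbin <- nt * dt / stimulusPeriod
  if (abs(kbin - round(kbin)) > 1e-8 || round(kbin) < 2)
    stop(corticomapError("period_off_bin", paste0(
      "stimulus period must divide the run length into >= 2 whole cycles; ",
      "run length ", nt * dt, " s / period ", stimulusPeriod,
      " s = ", signif(kbin, 6), " cycles. Choose nFrames*frameInterval as an",
      " integer multiple of the period.")))
  kbin <- as.integer(round(kbin))
  d3 <- dim(ref@data)[1:3]
  nvox <- prod(d3)
  tt <- seq_len(nt) - 1
  w <- 2 * pi * kbin * tt / nt
  D <- if (detrend) cbind(1, tt - mean(tt), cos(w), sin(w))
       else cbind(rep(1, nt), cos(w), sin(w))
  DtDinv <- solve(crossprod(D))
  acc <- matrix(0 + 0i, nt, nvox)
  for (r in runs) {
    X <- t(matrix(r@data, nvox, nt))   # time x voxel
    coef <- DtDinv %*% crossprod(D, X)
    nuis <- if (detrend) 1:2 else 1
    X <- X - D[, nuis, drop = FALSE] %*% coef[nuis, , drop = FALSE]
    acc <- acc + stats::mvfft(X)
  }
  acc <- acc / length(runs)
  half <- 2:(floor(nt / 2) + 1L)     # positive non-DC bins
  stim <- acc[kbin + 1L, ]
  amp <- 2 * Mod(stim) / nt
  denom <- sqrt(colSums(Mod(acc[half, , drop = FALSE])^2))
  coh <- ifelse(denom > 0, Mod(stim) / denom, 0)
  phase <- (-Arg(stim)) %% (2 * pi)
  new("RetinotopyResult",
      phase = array(phase, d3), amplitude = array(amp, d3),
      coherence = array(coh, d3),
      stimulusFrequency = 1 / stimulusPeriod, nFrames = as.integer(nt),
      frameInterval = dt, gridRef = parentFingerprint(ref))
}

#' Define V5/MT from retinotopy within hMT+
#'
#' Voxels of hMT+ whose retinotopic coherence exceeds the threshold,
#' excluding MST (ipsilaterally driven activity inside the retinotopic
#' region belongs to MST, not V5/MT).
#'
#' @param retino a \linkS4class{RetinotopyResult} on the same grid.
#' @param coherenceThreshold coherence criterion (conventionally 0.25).
#' @param hmt hMT+ voxel \linkS4class{IndexMask}.
#' @param mst MST voxel \linkS4class{IndexMask} (may be empty).
#' @return a voxel \linkS4class{IndexMask}.
#' @export
defineV5MT <- function(retino, coherenceThreshold, hmt, mst) {
  if (!identical(retino@gridRef, hmt@parentRef))
    stop(corticomapError("grid_mismatch",
      "retinotopy and hMT+ mask are on different grids"))
  checkSameParent(hmt, mst)
  keep <- maskIndices(hmt)[retino@coherence[maskIndices(hmt)] >
                             coherenceThreshold]
  newMaskLike(hmt, setdiff(keep, maskIndices(mst)))
}

#' Group mask from individual masks in a common space
#'
#' Binarizes each mask, sums them, and keeps locations present in at least
#' \code{minFraction} of the masks (e.g. 0.5 for the ">= 50% of individuals"
#' rule; a vertex in exactly half the masks is included).
#'
#' @param masks list of \linkS4class{IndexMask} objects sharing a parent.
#' @param minFraction required fraction in (0, 1].
#' @return an \linkS4class{IndexMask}.
#' @export
groupMask <- function(masks, minFraction) {
  stopifnot(length(masks) >= 1, minFraction > 0, minFraction <= 1)
  for (m in masks[-1]) checkSameParent(masks[[1]], m)
  counts <- integer(masks[[1]]@parentSize)
  for (m in masks) counts[m@indices] <- counts[m@indices] + 1L
  newMaskLike(masks[[1]], which(counts / length(masks) >= minFraction))
}
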