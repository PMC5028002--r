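#' @import methods
NULL

#' BrainVolume: a 3D scalar image on a regular grid
#'
#' Container for structural intensities, z-statistics or label volumes. The
#' grid-to-world mapping follows the NIfTI convention: world = transform %*%
#' c(i, j, k, 1) with zero-based voxel indices (i, j, k). Non-finite voxels
#' are never carried silently: they are zeroed in \code{data} and flagged
#' \code{FALSE} in the \code{valid} mask, and all statistics in this package
#' skip them.
#'
#' @slot data 3D numeric array (arbitrary units).
#' @slot voxelSize numeric(3), mm per axis.
#' @slot transform 4x4 grid-to-world affine (mm).
#' @slot spaceTag free-text label of the coordinate space.
#' @slot valid logical array, same dimensions as \code{data}.
#' @export
setClass("BrainVolume",
  representation(data = "array", voxelSize = "numeric",
                 transform = "matrix", spaceTag = "character",
                 valid = "array"))

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive finite numbers")
  if (!identical(dim(object@transform), c(4L, 4L)))
    msg <- c(msg, "transform must be a 4x4 matrix")
  if (!identical(dim(object@valid), dim(object@data)))
    msg <- c(msg, "valid mask must match data dimensions")
  if (any(!is.finite(object@data[object@valid])))
    msg <- c(msg, "data contains non-finite values not flagged in the validity mask")
  if (length(msg)) msg else TRUE
})

#' BrainTimeSeries: a 4D image (space x time)
#'
#' Same grid conventions as \linkS4class{BrainVolume}; \code{frameInterval}
#' is the repetition time in seconds. The validity mask is per-voxel (3D): a
#' voxel is invalid if any frame is non-finite.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot voxelSize numeric(3), mm.
#' @slot transform 4x4 grid-to-world affine.
#' @slot spaceTag character label.
#' @slot valid 3D logical array.
#' @slot frameInterval seconds between frames.
#' @export
setClass("BrainTimeSeries",
  representation(data = "array", voxelSize = "numeric",
                 transform = "matrix", spaceTag = "character",
                 valid = "array", frameInterval = "numeric"))

setValidity("BrainTimeSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array")
  if (!identical(dim(object@valid), dim(object@data)[1:3]))
    msg <- c(msg, "valid mask must match the spatial dimensions")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' CorticalSurface: a triangulated mesh with paired white/pial coordinates
#'
#' White and pial coordinate arrays share one triangulation, enabling
#' cortical-depth sampling at any thickness fraction and per-vertex area
#' measurement on the midthickness surface. Face indices are stored 1-based
#' (R convention); GIFTI I/O converts to/from 0-based.
#'
#' @slot verticesWhite N x 3 matrix, mm.
#' @slot verticesPial N x 3 matrix, mm.
#' @slot faces M x 3 integer matrix of 1-based vertex indices.
#' @slot hemisphere "left" or "right".
#' @export
setClass("CorticalSurface",
  representation(verticesWhite = "matrix", verticesPial = "matrix",
                 faces = "matrix", hemisphere = "character"))

setValidity("CorticalSurface", function(object) {
  msg <- character()
  nw <- nrow(object@verticesWhite); np <- nrow(object@verticesPial)
  if (ncol(object@verticesWhite) != 3L || ncol(object@verticesPial) != 3L)
    msg <- c(msg, "vertex arrays must have 3 columns")
  if (nw != np)
    msg <- c(msg, "white and pial surfaces must have the same vertex count")
  if (ncol(object@faces) != 3L)
    msg <- c(msg, "faces must have 3 columns")
  if (nrow(object@faces) > 0L) {
    if (min(object@faces) < 1L || max(object@faces) > nw)
      msg <- c(msg, "face index out of range")
  }
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' VertexMap: a per-vertex scalar map on one hemisphere's surface
#'
#' @slot values numeric vector, one value per surface vertex.
#' @slot valid logical vector flagging vertices with usable values.
#' @slot depthFraction cortical thickness fraction in [0,1] at which the map
#'   was sampled (0 = white surface, 1 = pial), or NA if not applicable.
#' @slot surfaceRef fingerprint of the parent surface (see
#'   \code{\link{parentFingerprint}}).
#' @export
setClass("VertexMap",
  representation(values = "numeric", valid = "logical",
                 depthFraction = "numeric", surfaceRef = "character"))

setValidity("VertexMap", function(object) {
  msg <- character()
  if (length(object@values) != length(object@valid))
    msg <- c(msg, "values and valid must have equal length")
  if (!is.na(object@depthFraction) &&
      (object@depthFraction < 0 || object@depthFraction > 1))
    msg <- c(msg, "depthFraction must lie in [0,1]")
  if (any(!is.finite(object@values[object@valid])))
    msg <- c(msg, "non-finite values must be flagged invalid")
  if (length(msg)) msg else TRUE
})

#' IndexMask: a set of vertex or voxel indices tied to a parent object
#'
#' Indices are stored 1-based, sorted and unique; voxel masks index the
#' flattened 3D array in R's column-major order. Text export
#' (\code{\link{writeMask}}) writes 0-based indices, one per line.
#'
#' @slot indices sorted unique 1-based integer indices.
#' @slot parentRef fingerprint of the parent surface or volume.
#' @slot parentSize number of vertices/voxels of the parent.
#' @slot kind "vertex" or "voxel".
#' @export
setClass("IndexMask",
  representation(indices = "integer", parentRef = "character",
                 parentSize = "integer", kind = "character"))

setValidity("IndexMask", function(object) {
  msg <- character()
  idx <- object@indices
  if (anyDuplicated(idx)) msg <- c(msg, "mask indices must be unique")
  if (is.unsorted(idx)) msg <- c(msg, "mask indices must be sorted")
  if (length(idx) && (min(idx) < 1L || max(idx) > object@parentSize))
    msg <- c(msg, "mask index out of parent bounds")
  if (!object@kind %in% c("vertex", "voxel"))
    msg <- c(msg, "kind must be 'vertex' or 'voxel'")
  if (length(msg)) msg else TRUE
})

#' SectionSeries: an ordered series of 2D histology rasters
#'
#' Grayscale sections cut at regular physical intervals, as in a 1-in-k
#' series of silver (Gallyas) stained sections. Higher pixel values are
#' lighter; dense myelin stains dark.
#'
#' @slot images list of numeric matrices (rows = first in-plane axis).
#' @slot pixelSize mm per pixel (isotropic in-plane).
#' @slot spacing mm between consecutive retained sections.
#' @slot thickness section thickness in micrometres (metadata; not used by
#'   the trapezoid area rule by default).
#' @slot positions mm position of each section along the cutting axis.
#' @slot orientation free-text tag (e.g. "parasagittal").
#' @export
setClass("SectionSeries",
  representation(images = "list", pixelSize = "numeric", spacing = "numeric",
                 thickness = "numeric", positions = "numeric",
                 orientation = "character"))

setValidity("SectionSeries", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
  if (object@thickness <= 0) msg <- c(msg, "thickness must be positive")
  if (length(object@positions) != length(object@images))
    msg <- c(msg, "positions must match the number of sections")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "section positions must be strictly increasing")
  if (!all(vapply(object@images, is.matrix, logical(1))))
    msg <- c(msg, "images must be matrices")
  if (length(msg)) msg else TRUE
})

#' IntensityProfile: stain or image intensity versus cortical depth
#'
#' Mean and standard deviation of image intensity sampled at regular steps
#' along a pial-to-white path, with lateral replicates at each step.
#'
#' @slot positions micrometres from the pial surface, strictly increasing.
#' @slot mean mean intensity per position.
#' @slot sd standard deviation per position.
#' @slot n number of lateral samples per position.
#' @export
setClass("IntensityProfile",
  representation(positions = "numeric", mean = "numeric",
                 sd = "numeric", n = "integer"))

setValidity("IntensityProfile", function(object) {
  msg <- character()
  k <- length(object@positions)
  if (length(object@mean) != k || length(object@sd) != k ||
      length(object@n) != k)
    msg <- c(msg, "positions, mean, sd and n must have equal length")
  if (k > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (k && any(object@n < 1L))
    msg <- c(msg, "n must be >= 1 at every position")
  if (length(msg)) msg else TRUE
})

#' RetinotopyResult: per-voxel phase, amplitude and coherence
#'
#' Output of the Fourier analysis of phase-encoded runs. Coherence is the
#' amplitude at the stimulus frequency divided by the root-sum-square
#' amplitude over all non-DC frequencies (detrended), bounded in [0,1].
#' Phase is reported in radians in [0, 2*pi) and is meaningful only where
#' coherence is appreciable.
#'
#' @slot phase 3D array, radians.
#' @slot amplitude 3D array.
#' @slot coherence 3D array in [0,1].
#' @slot stimulusFrequency Hz.
#' @slot nFrames frames per run.
#' @slot frameInterval seconds.
#' @slot gridRef fingerprint of the source grid.
#' @export
setClass("RetinotopyResult",
  representation(phase = "array", amplitude = "array", coherence = "array",
                 stimulusFrequency = "numeric", nFrames = "integer",
                 frameInterval = "numeric", gridRef = "character"))

#' CorrespondenceResult: an areal overlap percentage with its exact counts
#'
#' @slot percent overlap percentage in [0,100].
#' @slot nOverlap integer overlap count.
#' @slot denominator integer denominator count.
#' @slot context "whole_cortex", "roi" or "percent_roi".
#' @export
setClass("CorrespondenceResult",
  representation(percent = "numeric", nOverlap = "integer",
                 denominator = "integer", context = "character"))

setValidity("CorrespondenceResult", function(object) {
  msg <- character()
  if (object@percent < 0 || object@percent > 100)
    msg <- c(msg, "percent must lie in [0,100]")
  if (object@denominator > 0 &&
      abs(object@percent - 100 * object@nOverlap / object@denominator) > 1e-9)
    msg <- c(msg, "percent must equal 100*nOverlap/denominator exactly")
  if (length(msg)) msg else TRUE
})

#' PermutationNull: a permutation null distribution and its p-value
#'
#' The p-value uses the add-one convention
#' p = (1 + #\{null >= observed\}) / (nPerm + 1), which never returns zero.
#'
#' @slot nPerm number of permutations.
#' @slot nullPercents null statistic values.
#' @slot observed observed statistic.
#' @slot pValue permutation p-value.
#' @export
setClass("PermutationNull",
  representation(nPerm = "integer", nullPercents = "numeric",
                 observed = "numeric", pValue = "numeric"))

setValidity("PermutationNull", function(object) {
  p <- (1 + sum(object@nullPercents >= object@observed)) / (object@nPerm + 1)
  if (abs(p - object@pValue) > 1e-12)
    "pValue must equal (1 + #{null >= observed})/(nPerm + 1)" else TRUE
})

#' PhantomSpec: parameters of the synthetic cortical phantom
#'
#' A single sheet of cortex (flat slab or sinusoidally folded in x) with a
#' depth-dependent myelin field, a circular high-myelin patch (the V5/MT-MST
#' analogue), a functional activation cluster at a configurable offset from
#' the patch, phase-encoded retinotopy responses and Gallyas-like sections.
#' All physical units are mm and seconds unless stated. Fixing \code{seed}
#' makes every render byte-identical.
#'
#' @slot sheetExtent numeric(2), sheet size in mm (x, y).
#' @slot vertexSpacing mm between surface grid vertices.
#' @slot foldAmplitude mm; 0 gives a flat slab.
#' @slot foldWavelength mm of the sinusoidal fold along x.
#' @slot sheetTilt slope of the sheet against the rendering grid (rise in z
#'   per mm of x); keeps the ribbon from being pathologically aligned with
#'   voxel planes, as real cortex never is.
#' @slot thickness cortical thickness, mm.
#' @slot profilePeakDepth depth fraction (0 = white, 1 = pial) of peak myelin.
#' @slot profileWidth Gaussian width of the depth profile (depth-fraction units).
#' @slot profileFloor myelin value far from the peak (peak value is 1).
#' @slot patchCenter numeric(2), sheet coordinates (mm) of the patch centre.
#' @slot patchRadius geodesic radius, mm.
#' @slot patchContrast multiplicative myelin contrast inside the patch.
#' @slot voxelSize mm, isotropic rendering grid.
#' @slot noiseSD additive Gaussian noise sd on structural images
#'   (fraction of the gray-matter base level).
#' @slot biasAmplitude peak fractional amplitude of the smooth bias fields
#'   (<= 0.2); 0 disables them.
#' @slot clusterOffset numeric(2), mm offset (sheet coordinates) of the
#'   functional cluster centre from the patch centre.
#' @slot clusterRadius mm.
#' @slot clusterPeakZ peak z of the full-field cluster before noise.
#' @slot ipsiRadius mm radius of the ipsilateral (MST-analogue) subcluster.
#' @slot ipsiShift mm anterior (+x) shift of the ipsilateral subcluster.
#' @slot ipsiPeakZ peak z of the ipsilateral subcluster.
#' @slot retinoPeriod stimulus period, s.
#' @slot retinoFrames number of frames.
#' @slot retinoInterval frame interval (TR), s.
#' @slot retinoAmplitude response amplitude.
#' @slot retinoNoiseSD time-course noise sd.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(sheetExtent = "numeric", vertexSpacing = "numeric",
                 foldAmplitude = "numeric", foldWavelength = "numeric",
                 sheetTilt = "numeric", thickness = "numeric",
                 profilePeakDepth = "numeric", profileWidth = "numeric",
                 profileFloor = "numeric",
                 patchCenter = "numeric", patchRadius = "numeric",
                 patchContrast = "numeric",
                 voxelSize = "numeric", noiseSD = "numeric",
                 biasAmplitude = "numeric",
                 clusterOffset = "numeric", clusterRadius = "numeric",
                 clusterPeakZ = "numeric",
                 ipsiRadius = "numeric", ipsiShift = "numeric",
                 ipsiPeakZ = "numeric",
                 retinoPeriod = "numeric", retinoFrames = "integer",
                 retinoInterval = "numeric", retinoAmplitude = "numeric",
                 retinoNoiseSD = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@thickness <= 0) msg <- c(msg, "thickness must be > 0")
  if (object@patchRadius <= 0) msg <- c(msg, "patchRadius must be > 0")
  if (object@clusterRadius <= 0) msg <- c(msg, "clusterRadius must be > 0")
  if (object@vertexSpacing <= 0) msg <- c(msg, "vertexSpacing must be > 0")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude > 0.2)
    msg <- c(msg, "biasAmplitude must lie in [0, 0.2]")
  if (object@profilePeakDepth < 0 || object@profilePeakDepth > 1)
    msg <- c(msg, "profilePeakDepth must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth of a synthetic phantom
#'
#' Recorded from geometry alone; independent of noise, bias and all other
#' rendering settings.
#'
#' @slot patchVertices 1-based indices of patch vertices.
#' @slot patchArea true patch surface area, mm^2 (summed per-vertex
#'   midthickness areas).
#' @slot peakDepth depth fraction of peak myelin.
#' @slot sheetCoords N x 2 developable (arc-length) coordinates of vertices.
#' @slot surfaceRef fingerprint of the generated surface.
#' @export
setClass("PhantomTruth",
  representation(patchVertices = "integer", patchArea = "numeric",
                 peakDepth = "numeric", sheetCoords = "matrix",
                 surfaceRef = "character"))
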