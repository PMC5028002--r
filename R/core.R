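## Constructors, accessors and shared plumbing for the core containers.

#' Create a BrainVolume
#'
#' Non-finite voxels are zeroed and flagged in the validity mask rather than
#' silently kept; they are excluded from all downstream statistics.
#'
#' @param data 3D numeric array.
#' @param voxelSize numeric(3), mm per axis.
#' @param transform optional 4x4 grid-to-world affine; defaults to a scaling
#'   by \code{voxelSize} with zero origin.
#' @param spaceTag free-text coordinate-space label.
#' @return A \linkS4class{BrainVolume}.
#' @export
brainVolume <- function(data, voxelSize = c(1, 1, 1), transform = NULL,
                        spaceTag = "native") {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (is.null(transform)) {
    transform <- diag(c(voxelSize, 1))
  }
  valid <- is.finite(data)
  data[!valid] <- 0
  new("BrainVolume", data = data, voxelSize = as.numeric(voxelSize),
      transform = transform, spaceTag = spaceTag, valid = valid)
}

#' Create a BrainTimeSeries
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxelSize numeric(3), mm.
#' @param transform optional 4x4 affine.
#' @param spaceTag coordinate-space label.
#' @param frameInterval seconds between frames.
#' @return A \linkS4class{BrainTimeSeries}.
#' @export
brainTimeSeries <- function(data, voxelSize = c(1, 1, 1), transform = NULL,
                            spaceTag = "native", frameInterval = 1) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (is.null(transform)) transform <- diag(c(voxelSize, 1))
  valid <- apply(is.finite(data), c(1, 2, 3), all)
  data[!is.finite(data)] <- 0
  new("BrainTimeSeries", data = data, voxelSize = as.numeric(voxelSize),
      transform = transform, spaceTag = spaceTag, valid = valid,
      frameInterval = frameInterval)
}

#' Create a CorticalSurface
#'
#' @param verticesWhite,verticesPial N x 3 coordinate matrices, mm.
#' @param faces M x 3 matrix of 1-based vertex indices.
#' @param hemisphere "left" or "right".
#' @return A \linkS4class{CorticalSurface}.
#' @export
corticalSurface <- function(verticesWhite, verticesPial, faces,
                            hemisphere = "left") {
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(verticesWhite) != nrow(verticesPial))
    stop(corticomapError("surface_vertex_mismatch",
      "white and pial surfaces must have the same vertex count"))
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(verticesWhite)))
    stop(corticomapError("surface_face_out_of_range",
      "face index out of range"))
  new("CorticalSurface",
      verticesWhite = as.matrix(verticesWhite),
      verticesPial = as.matrix(verticesPial),
      faces = faces, hemisphere = hemisphere)
}

#' Create a VertexMap
#'
#' @param values numeric vector, one per vertex of \code{surface}.
#' @param surface the parent \linkS4class{CorticalSurface}.
#' @param depthFraction cortical thickness fraction, or NA.
#' @param valid optional logical vector; non-finite values are always
#'   flagged invalid.
#' @return A \linkS4class{VertexMap}.
#' @export
vertexMap <- function(values, surface, depthFraction = NA_real_,
                      valid = NULL) {
  if (length(values) != nVertices(surface))
    stop(corticomapError("map_length_mismatch",
      "map length must match surface vertex count"))
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  valid <- valid & is.finite(values)
  values[!valid] <- 0
  new("VertexMap", values = as.numeric(values), valid = valid,
      depthFraction = as.numeric(depthFraction),
      surfaceRef = parentFingerprint(surface))
}

#' Create a vertex mask
#'
#' @param indices 1-based vertex indices (any order; duplicates dropped).
#' @param surface the parent \linkS4class{CorticalSurface}.
#' @return An \linkS4class{IndexMask} of kind "vertex".
#' @export
vertexMask <- function(indices, surface) {
  new("IndexMask", indices = sort(unique(as.integer(indices))),
      parentRef = parentFingerprint(surface),
      parentSize = nVertices(surface), kind = "vertex")
}

#' Create a voxel mask
#'
#' Indices address the flattened 3D array in column-major order (1-based).
#'
#' @param indices 1-based linear voxel indices.
#' @param volume the parent \linkS4class{BrainVolume} (or
#'   \linkS4class{BrainTimeSeries}).
#' @return An \linkS4class{IndexMask} of kind "voxel".
#' @export
voxelMask <- function(indices, volume) {
  new("IndexMask", indices = sort(unique(as.integer(indices))),
      parentRef = parentFingerprint(volume),
      parentSize = as.integer(prod(dim(volume@data)[1:3])), kind = "voxel")
}

## ---- generics -------------------------------------------------------------

#' Number of vertices
#' @param x a surface-like object.
#' @return integer count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname nVertices
#' @export
setMethod("nVertices", "CorticalSurface",
          function(x) nrow(x@verticesWhite))

#' Number of faces
#' @param x a surface-like object.
#' @return integer count.
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname nFaces
#' @export
setMethod("nFaces", "CorticalSurface", function(x) nrow(x@faces))

#' Voxel size in mm
#' @param x a volume-like object.
#' @return numeric(3).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "BrainVolume", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "BrainTimeSeries", function(x) x@voxelSize)

#' Image data array
#' @param x a volume-like object.
#' @return the numeric array.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname imageData
#' @export
setMethod("imageData", "BrainVolume", function(x) x@data)

#' @rdname imageData
#' @export
setMethod("imageData", "BrainTimeSeries", function(x) x@data)

#' Validity mask of an image or map
#' @param x a volume, time series or vertex map.
#' @return logical array/vector.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname validMask
#' @export
setMethod("validMask", "BrainVolume", function(x) x@valid)

#' @rdname validMask
#' @export
setMethod("validMask", "BrainTimeSeries", function(x) x@valid)

#' @rdname validMask
#' @export
setMethod("validMask", "VertexMap", function(x) x@valid)

#' Per-vertex values of a map
#' @param x a \linkS4class{VertexMap}.
#' @return numeric vector.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "VertexMap", function(x) x@values)

#' Member indices of a mask (1-based)
#' @param x an \linkS4class{IndexMask}.
#' @return integer vector.
#' @export
setGeneric("maskIndices", function(x) standardGeneric("maskIndices"))

#' @rdname maskIndices
#' @export
setMethod("maskIndices", "IndexMask", function(x) x@indices)

#' Mask cardinality
#' @param x an \linkS4class{IndexMask}.
#' @return integer.
#' @export
setGeneric("maskSize", function(x) standardGeneric("maskSize"))

#' @rdname maskSize
#' @export
setMethod("maskSize", "IndexMask", function(x) length(x@indices))

## ---- parent fingerprints --------------------------------------------------

#' Fingerprint of a parent object for mask/map compatibility checks
#'
#' A cheap structural fingerprint: grid dimensions, voxel size and affine for
#' volumes; vertex/face counts, hemisphere and coordinate checksums for
#' surfaces. Two objects with equal fingerprints are treated as the same
#' parent space.
#'
#' @param x a \linkS4class{BrainVolume}, \linkS4class{BrainTimeSeries} or
#'   \linkS4class{CorticalSurface}.
#' @return a character scalar.
#' @export
setGeneric("parentFingerprint", function(x) standardGeneric("parentFingerprint"))

#' @rdname parentFingerprint
#' @export
setMethod("parentFingerprint", "BrainVolume", function(x)
  paste("vol", paste(dim(x@data), collapse = "x"),
        paste(signif(x@voxelSize, 8), collapse = ","),
        paste(signif(as.vector(x@transform), 8), collapse = ","),
        sep = "|"))

#' @rdname parentFingerprint
#' @export
setMethod("parentFingerprint", "BrainTimeSeries", function(x)
  paste("vol", paste(dim(x@data)[1:3], collapse = "x"),
        paste(signif(x@voxelSize, 8), collapse = ","),
        paste(signif(as.vector(x@transform), 8), collapse = ","),
        sep = "|"))

#' @rdname parentFingerprint
#' @export
setMethod("parentFingerprint", "CorticalSurface", function(x)
  paste("surf", nVertices(x), nFaces(x), x@hemisphere,
        signif(sum(x@verticesWhite), 10), signif(sum(x@verticesPial), 10),
        signif(sum(as.numeric(x@faces)), 10), sep = "|"))

## ---- errors ---------------------------------------------------------------

#' Construct a named corticomap error condition
#'
#' All anticipated failures raise conditions with class
#' \code{c("corticomap_<id>", "corticomap_error", "error", "condition")} so
#' callers can match them by id.
#'
#' @param id short identifier, e.g. "grid_mismatch".
#' @param message human-readable message.
#' @return a condition object (to be passed to \code{stop}).
#' @export
corticomapError <- function(id, message) {
  structure(class = c(paste0("corticomap_", id), "corticomap_error",
                      "error", "condition"),
            list(message = message, call = sys.call(-1)))
}

#' Check that two grids are identical
#'
#' Inter-image comparisons require identical grids; this package refuses to
#' resample implicitly (registration is an upstream concern). See
#' \code{\link{resampleNearest}} for the explicit opt-in.
#'
#' @param a,b volumes or time series.
#' @return invisibly TRUE, or raises \code{corticomap_grid_mismatch}.
#' @export
checkSameGrid <- function(a, b) {
  if (!identical(parentFingerprint(a), parentFingerprint(b)))
    stop(corticomapError("grid_mismatch",
      "images are not on the same grid; resample explicitly first"))
  invisible(TRUE)
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Explicit opt-in used when two images were prepared on different grids.
#' Each target voxel takes the value of the source voxel nearest in world
#' coordinates; targets falling outside the source grid are flagged invalid.
#'
#' @param vol source \linkS4class{BrainVolume}.
#' @param target \linkS4class{BrainVolume} defining the output grid.
#' @return a \linkS4class{BrainVolume} on the target grid.
#' @export
resampleNearest <- function(vol, target) {
  dt <- dim(target@data)
  idx <- as.matrix(expand.grid(i = seq_len(dt[1]) - 1L,
                               j = seq_len(dt[2]) - 1L,
                               k = seq_len(dt[3]) - 1L))
  world <- cbind(idx, 1) %*% t(target@transform)
  src <- world %*% t(solve(vol@transform))
  ijk <- round(src[, 1:3])
  ds <- dim(vol@data)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < ds[1] &
        ijk[, 2] >= 0 & ijk[, 2] < ds[2] &
        ijk[, 3] >= 0 & ijk[, 3] < ds[3]
  out <- rep(NA_real_, nrow(ijk))
  lin <- 1L + ijk[ok, 1] + ds[1] * (ijk[ok, 2] + ds[2] * ijk[ok, 3])
  vals <- vol@data[lin]
  vals[!vol@valid[lin]] <- NA_real_
  out[ok] <- vals
  brainVolume(array(out, dt), voxelSize = target@voxelSize,
              transform = target@transform, spaceTag = target@spaceTag)
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume %dx%dx%d, voxel %s mm, space '%s', %d invalid voxel(s)\n",
              d[1], d[2], d[3],
              paste(signif(object@voxelSize, 3), collapse = "x"),
              object@spaceTag, sum(!object@valid)))
})

setMethod("show", "BrainTimeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainTimeSeries %dx%dx%d x %d frames (TR %.3g s), voxel %s mm\n",
              d[1], d[2], d[3], d[4], object@frameInterval,
              paste(signif(object@voxelSize, 3), collapse = "x")))
})

setMethod("show", "CorticalSurface", function(object) {
  cat(sprintf("CorticalSurface (%s): %d vertices, %d faces, total area %.4g mm^2\n",
              object@hemisphere, nVertices(object), nFaces(object),
              sum(vertexAreas(object))))
})

setMethod("show", "VertexMap", function(object) {
  cat(sprintf("VertexMap: %d vertices (%d valid), depth fraction %s\n",
              length(object@values), sum(object@valid),
              ifelse(is.na(object@depthFraction), "NA",
                     format(object@depthFraction))))
})

setMethod("show", "IndexMask", function(object) {
  cat(sprintf("IndexMask (%s): %d of %d\n", object@kind,
              length(object@indices), object@parentSize))
})

setMethod("show", "CorrespondenceResult", function(object) {
  cat(sprintf("Correspondence [%s]: %.2f%% (%d / %d)\n", object@context,
              object@percent, object@nOverlap, object@denominator))
})

setMethod("show", "PermutationNull", function(object) {
  cat(sprintf("PermutationNull: observed %.2f, null mean %.2f (n_perm=%d), p=%.4g\n",
              object@observed, mean(object@nullPercents), object@nPerm,
              object@pValue))
})

setMethod("show", "SectionSeries", function(object) {
  cat(sprintf("SectionSeries (%s): %d sections, pixel %.3g mm, spacing %.3g mm, thickness %.3g um\n",
              object@orientation, length(object@images), object@pixelSize,
              object@spacing, object@thickness))
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d positions, %.1f-%.1f um from pial\n",
              length(object@positions),
              if (length(object@positions)) min(object@positions) else NA,
              if (length(object@positions)) max(object@positions) else NA))
})

setMethod("show", "RetinotopyResult", function(object) {
  cat(sprintf("RetinotopyResult: grid %s, stimulus %.4g Hz, %d frames\n",
              paste(dim(object@phase), collapse = "x"),
              object@stimulusFrequency, object@nFrames))
})
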