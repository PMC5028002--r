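## Surface geometry: midthickness, per-vertex areas, thickness, adjacency.

#' Midthickness coordinates of a surface
#'
#' The mean of white and pial coordinates. Areal quantities in this package
#' are measured on this surface: a single least-biased layer when the layer
#' used for area measurement is not otherwise pinned down.
#'
#' @param surface a \linkS4class{CorticalSurface}.
#' @return N x 3 matrix, mm.
#' @export
midthickness <- function(surface) {
  (surface@verticesWhite + surface@verticesPial) / 2
}

triangleAreas <- function(coords, faces) {
  a <- coords[faces[, 1], , drop = FALSE]
  b <- coords[faces[, 2], , drop = FALSE]
  c_ <- coords[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-vertex surface area
#'
#' One third of the summed areas of the triangles incident to each vertex,
#' computed on the midthickness surface. Per-vertex areas sum to the total
#' mesh area.
#'
#' @param surface a \linkS4class{CorticalSurface}.
#' @param layer "mid" (default), "white" or "pial".
#' @return numeric vector of length \code{nVertices(surface)}, mm^2.
#' @export
vertexAreas <- function(surface, layer = c("mid", "white", "pial")) {
  layer <- match.arg(layer)
  coords <- switch(layer, mid = midthickness(surface),
                   white = surface@verticesWhite,
                   pial = surface@verticesPial)
  ta <- triangleAreas(coords, surface@faces)
  share <- rep(ta / 3, times = 3)
  idx <- as.vector(surface@faces)
  as.vector(tapply2(share, idx, nVertices(surface)))
}

## fast grouped sum over a fixed-length index range
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Cortical thickness per vertex
#'
#' Euclidean distance between paired white and pial coordinates.
#'
#' @param surface a \linkS4class{CorticalSurface}.
#' @return numeric vector, mm.
#' @export
corticalThickness <- function(surface) {
  d <- surface@verticesPial - surface@verticesWhite
  sqrt(rowSums(d^2))
}

#' Unique undirected edges of a surface mesh
#'
#' @param surface a \linkS4class{CorticalSurface}.
#' @return 2-column integer matrix of 1-based vertex indices.
#' @export
surfaceEdges <- function(surface) {
  f <- surface@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Edge-connected component of marked vertices containing a seed
#'
#' @param members logical vector or integer indices of marked vertices.
#' @param surface the parent \linkS4class{CorticalSurface}.
#' @param seedVertex 1-based index of the seed, which must be marked.
#' @return integer indices of the component containing the seed.
#' @export
vertexComponent <- function(members, surface, seedVertex) {
  n <- nVertices(surface)
  inset <- logical(n)
  if (is.logical(members)) inset[members] <- TRUE else inset[members] <- TRUE
  if (!inset[seedVertex])
    stop(corticomapError("seed_not_in_mask", "seed vertex is not in the mask"))
  e <- surfaceEdges(surface)
  keep <- inset[e[, 1]] & inset[e[, 2]]
  g <- igraph::graph_from_edgelist(e[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sort(which(comp == comp[seedVertex] & inset))
}

#' Geodesic distances from a vertex along mesh edges
#'
#' Shortest-path (Dijkstra) distance over the midthickness mesh with
#' Euclidean edge lengths; an upper-bound approximation to the true surface
#' geodesic that is accurate on the regular meshes used here.
#'
#' @param surface a \linkS4class{CorticalSurface}.
#' @param from 1-based source vertex index.
#' @return numeric vector of distances, mm.
#' @export
geodesicDistances <- function(surface, from) {
  coords <- midthickness(surface)
  e <- surfaceEdges(surface)
  w <- sqrt(rowSums((coords[e[, 1], ] - coords[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nVertices(surface) - igraph::vcount(g)))
  as.vector(igraph::distances(g, v = from, weights = w))
}
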