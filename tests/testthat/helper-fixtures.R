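## Shared fixtures and independent brute-force oracles.

## unit cube mesh: 8 vertices, 12 triangles, outward-consistent enough for
## area (orientation does not matter for unsigned area)
cubeSurface <- function(pialOffset = 0) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 2, 3), c(2, 4, 3), c(5, 7, 6), c(6, 7, 8),
             c(1, 3, 5), c(3, 7, 5), c(2, 6, 4), c(4, 6, 8),
             c(1, 5, 2), c(2, 5, 6), c(3, 4, 7), c(4, 8, 7))
  ## outward normals at cube vertices point along the diagonal
  n <- sweep(v, 2, c(0.5, 0.5, 0.5))
  n <- n / sqrt(rowSums(n^2))
  corticalSurface(v, v + pialOffset * n, f)
}

## flat rectangular sheet surface in the z = const plane, spacing h,
## thickness t (white below, pial above)
flatSheetSurface <- function(nx = 11, ny = 11, h = 1, thickness = 1,
                             z0 = 0) {
  g <- expand.grid(x = (seq_len(nx) - 1) * h, y = (seq_len(ny) - 1) * h)
  idx <- matrix(seq_len(nx * ny), nrow = nx)
  v00 <- as.vector(idx[-nx, -ny]); v10 <- as.vector(idx[-1, -ny])
  v01 <- as.vector(idx[-nx, -1]); v11 <- as.vector(idx[-1, -1])
  f <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  white <- cbind(g$x, g$y, z0 - thickness / 2)
  pial <- cbind(g$x, g$y, z0 + thickness / 2)
  corticalSurface(white, pial, f)
}

## icosphere of radius r, subdivided `level` times
icosphere <- function(level = 4, r = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  norm <- function(m) m / sqrt(rowSums(m^2))
  v <- norm(v)
  for (i in seq_len(level)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    nextIdx <- nrow(v)
    newF <- matrix(0L, 0, 3)
    rowsV <- vector("list", 0)
    mid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      nextIdx <<- nextIdx + 1L
      rowsV[[length(rowsV) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      mids[[k]] <- nextIdx
      nextIdx
    }
    for (j in seq_len(nrow(f))) {
      a <- f[j, 1]; b <- f[j, 2]; c_ <- f[j, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                    c(ab, bc, ca))
    }
    v <- norm(rbind(v, do.call(rbind, rowsV)))
    f <- newF
  }
  corticalSurface(v * r, v * r, f)
}

## a small phantom spec for tests (2601 vertices, ~33k voxels)
testSpec <- function(...) {
  base <- list(sheetExtent = c(20, 20), vertexSpacing = 0.4,
               patchCenter = c(10, 10), patchRadius = 4, voxelSize = 0.5,
               noiseSD = 0, biasAmplitude = 0)
  do.call(phantomSpec, utils::modifyList(base, list(...)))
}

## patch-centre vertex of a phantom
patchSeedVertex <- function(ph) {
  pv <- ph$truth@patchVertices
  ctr <- colMeans(ph$truth@sheetCoords[pv, , drop = FALSE])
  pv[which.min(rowSums((ph$truth@sheetCoords[pv, , drop = FALSE] -
                          matrix(ctr, length(pv), 2, byrow = TRUE))^2))]
}

## ---- independent oracles ----------------------------------------------------

## brute-force connected components of TRUE voxels (iterative BFS)
oracleComponents <- function(mask3d, connectivity) {
  d <- dim(mask3d)
  offAll <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offAll))
  off <- switch(as.character(connectivity),
                `6` = offAll[nz == 1, , drop = FALSE],
                `18` = offAll[nz >= 1 & nz <= 2, , drop = FALSE],
                `26` = offAll[nz >= 1, , drop = FALSE])
  seen <- array(FALSE, d)
  comps <- list()
  for (start in which(mask3d)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      p <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        q <- p + off[r, ]
        if (any(q < 1) || any(q > d)) next
        lin <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (mask3d[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

## brute-force two-sample KS statistic over pooled points
oracleKS <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  max(abs(vapply(pool, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

## brute-force Pearson r
oraclePearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
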