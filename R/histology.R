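## Histology arm: cortical intensity profiles, robust smoothing, profile
## comparison, myelinated-length measurement and section-series area
## aggregation, plus the printed-table summary and method-agreement
## statistics.

## bilinear interpolation of image(im) at mm coordinates (x = rows, y = cols)
bilinearSample <- function(im, pixelSize, x, y) {
  cx <- x / pixelSize + 0.5  # pixel centre i has coordinate (i - 0.5) * p
  cy <- y / pixelSize + 0.5
  nx <- nrow(im); ny <- ncol(im)
  if (any(cx < 1 - 1e-9 | cx > nx + 1e-9 | cy < 1 - 1e-9 | cy > ny + 1e-9))
    return(rep(NA_real_, length(x)))
  cx <- pmin(pmax(cx, 1), nx); cy <- pmin(pmax(cy, 1), ny)
  i0 <- pmin(floor(cx), nx - 1); j0 <- pmin(floor(cy), ny - 1)
  fx <- cx - i0; fy <- cy - j0
  im[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    im[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    im[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    im[cbind(i0 + 1, j0 + 1)] * fx * fy
}

polylineResample <- function(path, step) {
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- seq(0, total, by = step)
  cbind(stats::approx(s, path[, 1], xout = at)$y,
        stats::approx(s, path[, 2], xout = at)$y, at)
}

#' Cortical intensity profile along a pial-to-white path
#'
#' Walks the path in steps of \code{step} micrometres; at each position,
#' samples \code{nLateral} points perpendicular to the local path direction
#' (spaced one pixel apart, centred on the path) and records their mean and
#' sd. Positions are micrometres from the pial end (the first path point).
#'
#' @param image grayscale matrix (rows = x, cols = y in mm via
#'   \code{pixelSize}).
#' @param pixelSize mm per pixel.
#' @param path K x 2 polyline in image mm coordinates, ordered pial to white.
#' @param step sampling step in micrometres (default 15).
#' @param nLateral lateral samples per position (default 6).
#' @return An \linkS4class{IntensityProfile}.
#' @export
extractProfile <- function(image, pixelSize, path, step = 15, nLateral = 6) {
  stopifnot(step > 0, nLateral >= 1)
  pts <- polylineResample(path, step / 1000)
  k <- nrow(pts)
  ## local tangents by central differences
  tx <- c(pts[2, 1] - pts[1, 1], pts[-(1:2), 1] - pts[1:(k - 2), 1],
          pts[k, 1] - pts[k - 1, 1])
  ty <- c(pts[2, 2] - pts[1, 2], pts[-(1:2), 2] - pts[1:(k - 2), 2],
          pts[k, 2] - pts[k - 1, 2])
  nrm <- sqrt(tx^2 + ty^2)
  nxv <- -ty / nrm; nyv <- tx / nrm
  lat <- (seq_len(nLateral) - (nLateral + 1) / 2) * pixelSize
  mu <- numeric(k); sdv <- numeric(k)
  for (i in seq_len(k)) {
    xs <- pts[i, 1] + lat * nxv[i]
    ys <- pts[i, 2] + lat * nyv[i]
    v <- bilinearSample(image, pixelSize, xs, ys)
    if (any(is.na(v)))
      stop(corticomapError("path_outside_image",
        "profile path (or its lateral samples) exits the image"))
    mu[i] <- mean(v)
    sdv[i] <- if (nLateral > 1) stats::sd(v) else 0
  }
  new("IntensityProfile", positions = pts[, 3] * 1000, mean = mu, sd = sdv,
      n = rep(as.integer(nLateral), k))
}

#' Robust local-quadratic smoothing of a profile
#'
#' Locally weighted least squares with a second-degree polynomial model and
#' bisquare robustness reweighting (loess, family = "symmetric"): the
#' sliding-average smoother conventionally applied to myeloarchitecture
#' profiles. Exactly quadratic inputs are reproduced; gross outliers are
#' downweighted rather than followed.
#'
#' @param profile an \linkS4class{IntensityProfile} with >= 5 points.
#' @param span smoothing span as a fraction of the points (default 0.5).
#' @return a smoothed \linkS4class{IntensityProfile}.
#' @export
smoothProfile <- function(profile, span = 0.5) {
  k <- length(profile@positions)
  if (k < 5L)
    stop(corticomapError("too_few_points",
      "need at least 5 profile points to smooth"))
  if (span * k < 3)
    stop(corticomapError("span_too_small",
      "span leaves windows with fewer than 3 points"))
  ## loess warns about degenerate neighbourhoods on exact-fit inputs
  ## (zero residuals); those are expected here and muffled
  fit <- withCallingHandlers(
    stats::loess(profile@mean ~ profile@positions, span = span,
                 degree = 2, family = "symmetric",
                 control = stats::loess.control(surface = "direct",
                                                iterations = 6)),
    warning = function(w) {
      if (grepl(paste0("pseudoinverse|neighborhood|condition number|",
                       "zero-width|singularit|^at +[-0-9.e]|^radius +[0-9.e]"),
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- profile
  out@mean <- as.numeric(stats::predict(fit))
  out
}

#' Compare two intensity profiles with a two-sample KS test
#'
#' Two-sample Kolmogorov-Smirnov statistic D = sup |ECDF_a - ECDF_b| on the
#' raw per-position mean values, with the asymptotic p-value.
#'
#' @param a,b \linkS4class{IntensityProfile} objects with >= 2 points each.
#' @return list with elements \code{D} and \code{p}.
#' @export
compareProfiles <- function(a, b) {
  if (length(a@mean) < 2L || length(b@mean) < 2L)
    stop(corticomapError("too_few_points",
      "need at least 2 points in each profile"))
  ks <- suppressWarnings(stats::ks.test(a@mean, b@mean, exact = FALSE))
  list(D = unname(ks$statistic), p = unname(ks$p.value))
}

#' Myelinated length along the pial surface of one section
#'
#' Walks the pial trace; under each position, samples the deep-cortex stain
#' intensity at \code{deepFraction} of the local cortical depth (toward the
#' white trace) and marks it myelinated when darker than
#' \code{stainThreshold}. Returns the total pial arc length of the
#' contiguous myelinated runs, with the run list attached.
#'
#' @param image grayscale section matrix.
#' @param pixelSize mm per pixel.
#' @param stainThreshold intensity below which stain counts as dense myelin;
#'   must lie within the image's value range.
#' @param pialTrace K x 2 polyline, image mm coordinates.
#' @param whiteTrace K x 2 polyline paired with \code{pialTrace}.
#' @param deepFraction depth at which stain is sampled, as a fraction of
#'   pial-to-white distance (default 0.7, the deep band).
#' @param step sampling step along the trace, mm.
#' @return total length in mm; attribute "runs" is a data.frame of run
#'   start/end arc positions and lengths.
#' @export
sectionMyelinLength <- function(image, pixelSize, stainThreshold, pialTrace,
                                whiteTrace, deepFraction = 0.7,
                                step = pixelSize) {
  rng <- range(image)
  if (stainThreshold < rng[1] || stainThreshold > rng[2])
    stop(corticomapError("threshold_out_of_range",
      "stain threshold lies outside the image value range"))
  pp <- polylineResample(pialTrace, step)
  ## pair each resampled pial point with the white trace by arc fraction
  pw <- polylineResample(whiteTrace, step)
  k <- min(nrow(pp), nrow(pw))
  idx <- seq_len(k)
  px <- pp[idx, 1] + deepFraction * (pw[idx, 1] - pp[idx, 1])
  py <- pp[idx, 2] + deepFraction * (pw[idx, 2] - pp[idx, 2])
  v <- bilinearSample(image, pixelSize, px, py)
  if (any(is.na(v)))
    stop(corticomapError("path_outside_image",
      "pial trace (or its deep samples) exits the image"))
  dark <- v < stainThreshold
  r <- rle(dark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = pp[starts[r$values], 3],
                     end = pp[ends[r$values], 3])
  runs$length <- runs$end - runs$start
  total <- sum(runs$length)
  attr(total, "runs") <- runs
  total
}

#' Aggregate per-section lengths into an area
#'
#' Trapezoidal aggregation across consecutive retained sections:
#' sum over pairs of (l_i + l_(i+1))/2 * spacing. Zero-length sections in
#' the series participate, tapering the ends. Section thickness is carried
#' as metadata only: the spacing between retained sections already spans the
#' cut tissue. \code{endCaps = TRUE} optionally adds thickness-based end
#' caps (thickness in mm x the terminal lengths).
#'
#' @param lengths per-section myelinated lengths, mm (>= 2 sections).
#' @param spacing mm between consecutive sections.
#' @param thickness section thickness in micrometres (used only when
#'   \code{endCaps}).
#' @param endCaps add thickness end caps (default FALSE).
#' @return area in mm^2.
#' @export
aggregateArea <- function(lengths, spacing, thickness = NULL,
                          endCaps = FALSE) {
  if (length(lengths) < 2L)
    stop(corticomapError("too_few_sections", "need at least 2 sections"))
  stopifnot(spacing > 0)
  area <- sum((lengths[-1] + lengths[-length(lengths)]) / 2) * spacing
  if (endCaps) {
    if (is.null(thickness))
      stop(corticomapError("missing_thickness",
        "endCaps = TRUE needs the section thickness"))
    area <- area + (thickness / 1000) *
      (lengths[1] + lengths[length(lengths)]) / 2
  }
  area
}

#' Myelinated length per section of a series
#'
#' Convenience wrapper applying \code{\link{sectionMyelinLength}} to every
#' section of a \linkS4class{SectionSeries}.
#'
#' @param series a \linkS4class{SectionSeries}.
#' @param stainThreshold stain intensity threshold.
#' @param pialTraces,whiteTraces lists of polylines, one per section.
#' @param deepFraction depth fraction for stain sampling.
#' @return numeric vector of lengths, mm.
#' @export
seriesMyelinLengths <- function(series, stainThreshold, pialTraces,
                                whiteTraces, deepFraction = 0.7) {
  vapply(seq_along(series@images), function(k)
    as.numeric(sectionMyelinLength(series@images[[k]], series@pixelSize,
                                   stainThreshold, pialTraces[[k]],
                                   whiteTraces[[k]], deepFraction)),
    numeric(1))
}

#' Column and pooled summaries of per-hemisphere area tables
#'
#' Arithmetic mean and sample sd (n - 1 denominator) per column, ignoring
#' missing entries; columns with a single non-missing value report a mean
#' but a missing sd (never zero). \code{pool} names groups of columns to
#' additionally summarize pooled (e.g. both hemispheres of one method).
#'
#' @param table data.frame of numeric columns (NA = missing); non-numeric
#'   columns (e.g. subject ids) are ignored.
#' @param pool named list of character vectors of column names to pool.
#' @return data.frame with columns \code{column}, \code{n}, \code{mean},
#'   \code{sd}.
#' @export
summarizeAreas <- function(table, pool = list()) {
  num <- table[vapply(table, is.numeric, logical(1))]
  summ <- function(v, name) {
    v <- v[!is.na(v)]
    if (!length(v))
      stop(corticomapError("empty_group",
        paste("no values in group", name)))
    data.frame(column = name, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  rows <- lapply(names(num), function(nm) summ(num[[nm]], nm))
  for (nm in names(pool)) {
    v <- unlist(num[pool[[nm]]], use.names = FALSE)
    rows[[length(rows) + 1L]] <- summ(v, nm)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement between sMRI and histology area measurements
#'
#' Pearson correlation (two-sided test) over complete (sMRI, histology)
#' area pairs; incomplete pairs are dropped with a message.
#'
#' @param smri,histology paired per-hemisphere areas, mm^2 (NA = missing).
#' @return list with \code{r}, \code{p} and \code{n} (complete pairs).
#' @export
methodAgreement <- function(smri, histology) {
  stopifnot(length(smri) == length(histology))
  ok <- !is.na(smri) & !is.na(histology)
  if (sum(!ok))
    message("methodAgreement: dropping ", sum(!ok), " incomplete pair(s)")
  if (sum(ok) < 3L)
    stop(corticomapError("too_few_pairs",
      "need at least 3 complete pairs"))
  x <- smri[ok]; y <- histology[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(corticomapError("zero_variance",
      "zero variance in one of the variables"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Published per-hemisphere areas of the macaque MT + MST complex
#'
#' The printed per-subject table of myelin surface areas (mm^2) measured
#' with in vivo sMRI and with Gallyas histology in Rhesus macaques, shipped
#' as package data; dashes in the printed table are missing values.
#'
#' @return data.frame with columns subject, mriLh, histLh, mriRh, histRh.
#' @export
macaqueAreaTable <- function() {
  path <- system.file("extdata", "table1_mt_mst_areas.tsv",
                      package = "corticomap", mustWork = TRUE)
  utils::read.delim(path, na.strings = "NA")
}

## ---- section I/O (ASCII PGM + PNG) -----------------------------------------

#' Write a section image as plain-text PGM (P2)
#'
#' @param image numeric matrix; values are rounded and clamped to [0, 255].
#' @param path output .pgm path.
#' @return invisibly, \code{path}.
#' @export
writeSectionPGM <- function(image, path) {
  v <- pmin(pmax(round(image), 0), 255)
  con <- file(path, "w")
  on.exit(close(con))
  ## PGM is row-major with width = columns; write the transpose
  writeLines(c("P2", paste(nrow(v), ncol(v)), "255",
               apply(t(v), 1, paste, collapse = " ")), con)
  invisible(path)
}

#' Read a plain-text PGM (P2) section image
#'
#' @param path .pgm path.
#' @return numeric matrix.
#' @export
readSectionPGM <- function(path) {
  if (!file.exists(path))
    stop(corticomapError("file_not_found", paste("no such file:", path)))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!identical(trimws(lines[1]), "P2"))
    stop(corticomapError("not_pgm", "not an ASCII PGM (P2) file"))
  toks <- scan(text = paste(lines[-1], collapse = " "), quiet = TRUE)
  w <- toks[1]; h <- toks[2]
  matrix(toks[-(1:3)], nrow = w, ncol = h)
}

#' Write a section series to a directory with a JSON sidecar
#'
#' Sections go to \code{section_###.pgm} (plus \code{.png} when the png
#' package is available and \code{png = TRUE}); pixel size, spacing,
#' thickness and positions go to \code{series.json}.
#'
#' @param series a \linkS4class{SectionSeries}.
#' @param dir output directory (created if needed).
#' @param png also write PNG copies (default FALSE).
#' @return invisibly, \code{dir}.
#' @export
writeSectionSeries <- function(series, dir, png = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(series@images)) {
    writeSectionPGM(series@images[[k]],
                    file.path(dir, sprintf("section_%03d.pgm", k)))
    if (png && requireNamespace("png", quietly = TRUE)) {
      img <- pmin(pmax(series@images[[k]], 0), 255) / 255
      png::writePNG(t(img), file.path(dir, sprintf("section_%03d.png", k)))
    }
  }
  meta <- list(pixelSize = series@pixelSize, spacing = series@spacing,
               thickness = series@thickness, positions = series@positions,
               orientation = series@orientation,
               nSections = length(series@images))
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a section series written by \code{\link{writeSectionSeries}}
#'
#' @param dir directory containing section_###.pgm and series.json.
#' @return A \linkS4class{SectionSeries}.
#' @export
readSectionSeries <- function(dir) {
  metaPath <- file.path(dir, "series.json")
  if (!file.exists(metaPath))
    stop(corticomapError("file_not_found", "series.json not found"))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^section_\\d+\\.pgm$",
                           full.names = TRUE))
  images <- lapply(files, readSectionPGM)
  new("SectionSeries", images = images, pixelSize = meta$pixelSize,
      spacing = meta$spacing, thickness = meta$thickness,
      positions = as.numeric(meta$positions),
      orientation = meta$orientation)
}
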