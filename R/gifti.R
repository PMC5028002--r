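## GIFTI-like surface geometry I/O on top of xml2.
##
## One file carries three data arrays: white pointset, pial pointset and the
## shared triangle array (0-based indices on disk). ASCII, Base64Binary and
## GZipBase64Binary encodings are read; ASCII is written.

giftiTypeName <- c(pointset = "NIFTI_INTENT_POINTSET",
                   triangle = "NIFTI_INTENT_TRIANGLE")

#' Read a surface from a GIFTI geometry file
#'
#' Expects a white pointset, a pial pointset and a triangle array in one
#' file (as written by \code{\link{writeSurface}}); pointsets are matched to
#' layers via their \code{Name} metadata ("white"/"pial"), falling back to
#' file order. Face indices are converted from 0-based to 1-based.
#'
#' @param path path to a .gii file.
#' @return A \linkS4class{CorticalSurface}.
#' @export
readSurface <- function(path) {
  if (!file.exists(path))
    stop(corticomapError("file_not_found", paste("no such file:", path)))
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(arrays))
    stop(corticomapError("not_gifti", "no DataArray elements found"))
  points <- list(); tris <- NULL
  for (arr in arrays) {
    intent <- xml2::xml_attr(arr, "Intent")
    vals <- decodeGiftiArray(arr)
    if (identical(intent, giftiTypeName[["pointset"]])) {
      nm <- giftiArrayName(arr)
      points[[length(points) + 1L]] <- list(name = nm, coords = vals)
    } else if (identical(intent, giftiTypeName[["triangle"]])) {
      tris <- vals + 1L
    }
  }
  if (length(points) < 2L || is.null(tris))
    stop(corticomapError("not_gifti",
      "file must contain two pointsets (white, pial) and a triangle array"))
  names_ <- vapply(points, function(p) p$name %||% "", character(1))
  iw <- match("white", names_); ip <- match("pial", names_)
  if (is.na(iw) || is.na(ip)) { iw <- 1L; ip <- 2L }
  hemi <- giftiHemisphere(doc)
  corticalSurface(points[[iw]]$coords, points[[ip]]$coords, tris,
                  hemisphere = hemi)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

giftiArrayName <- function(arr) {
  mds <- xml2::xml_find_all(arr, "./MetaData/MD")
  for (md in mds) {
    nm <- xml2::xml_text(xml2::xml_find_first(md, "./Name"))
    if (identical(nm, "Name"))
      return(xml2::xml_text(xml2::xml_find_first(md, "./Value")))
  }
  NA_character_
}

giftiHemisphere <- function(doc) {
  mds <- xml2::xml_find_all(doc, "./MetaData/MD")
  for (md in mds) {
    nm <- xml2::xml_text(xml2::xml_find_first(md, "./Name"))
    if (identical(nm, "AnatomicalStructurePrimary")) {
      v <- xml2::xml_text(xml2::xml_find_first(md, "./Value"))
      if (grepl("Right", v, ignore.case = TRUE)) return("right")
      return("left")
    }
  }
  "left"
}

decodeGiftiArray <- function(arr) {
  enc <- xml2::xml_attr(arr, "Encoding")
  dtype <- xml2::xml_attr(arr, "DataType")
  order <- xml2::xml_attr(arr, "ArrayIndexingOrder")
  d0 <- as.integer(xml2::xml_attr(arr, "Dim0"))
  d1 <- as.integer(xml2::xml_attr(arr, "Dim1"))
  if (is.na(d1)) d1 <- 1L
  txt <- xml2::xml_text(xml2::xml_find_first(arr, "./Data"))
  isInt <- grepl("INT", dtype)
  vals <- if (identical(enc, "ASCII")) {
    scan(text = txt, quiet = TRUE)
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, "gzip")
    endian <- if (identical(xml2::xml_attr(arr, "Endian"), "BigEndian"))
      "big" else "little"
    if (isInt) readBin(raw, "integer", n = d0 * d1, size = 4L, endian = endian)
    else readBin(raw, "numeric", n = d0 * d1,
                 size = if (grepl("FLOAT64", dtype)) 8L else 4L,
                 endian = endian)
  } else {
    stop(corticomapError("not_gifti", paste("unsupported encoding:", enc)))
  }
  if (length(vals) != d0 * d1)
    stop(corticomapError("not_gifti", "data length does not match Dim0 x Dim1"))
  m <- if (identical(order, "ColumnMajorOrder"))
    matrix(vals, nrow = d0, ncol = d1)
  else
    matrix(vals, nrow = d0, ncol = d1, byrow = TRUE)
  if (isInt) storage.mode(m) <- "integer"
  m
}

#' Write a surface as a GIFTI geometry file
#'
#' ASCII encoding; face indices are written 0-based.
#'
#' @param surface a \linkS4class{CorticalSurface}.
#' @param path output .gii path.
#' @return invisibly, \code{path}.
#' @export
writeSurface <- function(surface, path) {
  hemi <- if (surface@hemisphere == "right") "CortexRight" else "CortexLeft"
  fmtPoints <- function(m) paste(apply(m, 1, function(r)
    paste(formatC(r, digits = 9, format = "g"), collapse = " ")),
    collapse = "\n")
  fmtTris <- function(m) paste(apply(m - 1L, 1, paste, collapse = " "),
                               collapse = "\n")
  arr <- function(intent, dtype, m, name, body) {
    sprintf(paste0(
      '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder"',
      ' Dimensionality="2" Dim0="%d" Dim1="%d" Encoding="ASCII"',
      ' Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
      '<MetaData><MD><Name>Name</Name><Value>%s</Value></MD></MetaData>\n',
      '<Data>%s</Data>\n</DataArray>'),
      intent, dtype, nrow(m), ncol(m), name, body)
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="3">\n',
    '<MetaData><MD><Name>AnatomicalStructurePrimary</Name><Value>', hemi,
    '</Value></MD></MetaData>\n',
    arr(giftiTypeName[["pointset"]], "NIFTI_TYPE_FLOAT32",
        surface@verticesWhite, "white", fmtPoints(surface@verticesWhite)), "\n",
    arr(giftiTypeName[["pointset"]], "NIFTI_TYPE_FLOAT32",
        surface@verticesPial, "pial", fmtPoints(surface@verticesPial)), "\n",
    arr(giftiTypeName[["triangle"]], "NIFTI_TYPE_INT32",
        surface@faces, "faces", fmtTris(surface@faces)), "\n",
    '</GIFTI>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Write a per-vertex map as a GIFTI functional file
#'
#' Single ASCII data array with NIFTI_INTENT_NONE; invalid vertices are
#' written as NaN.
#'
#' @param map a \linkS4class{VertexMap}.
#' @param path output .gii path.
#' @return invisibly, \code{path}.
#' @export
writeVertexMap <- function(map, path) {
  v <- map@values
  v[!map@valid] <- NaN
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n',
    sprintf(paste0(
      '<DataArray Intent="NIFTI_INTENT_NONE" DataType="NIFTI_TYPE_FLOAT32"',
      ' ArrayIndexingOrder="RowMajorOrder" Dimensionality="1" Dim0="%d"',
      ' Encoding="ASCII" Endian="LittleEndian">\n<Data>%s</Data>\n</DataArray>\n'),
      length(v), paste(formatC(v, digits = 9, format = "g"), collapse = "\n")),
    '</GIFTI>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Read a per-vertex map written by \code{\link{writeVertexMap}}
#'
#' @param path .gii path.
#' @param surface the parent \linkS4class{CorticalSurface}.
#' @param depthFraction optional depth-fraction annotation.
#' @return A \linkS4class{VertexMap}.
#' @export
readVertexMap <- function(path, surface, depthFraction = NA_real_) {
  if (!file.exists(path))
    stop(corticomapError("file_not_found", paste("no such file:", path)))
  doc <- xml2::read_xml(path)
  arr <- xml2::xml_find_first(doc, ".//DataArray")
  vals <- as.numeric(decodeGiftiArray(arr))
  vertexMap(vals, surface, depthFraction = depthFraction)
}
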