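## Mask algebra and plain-text mask I/O.

checkSameParent <- function(a, b) {
  if (!identical(a@parentRef, b@parentRef) ||
      !identical(a@parentSize, b@parentSize) ||
      !identical(a@kind, b@kind))
    stop(corticomapError("parent_mismatch",
      "masks do not share a parent object"))
  invisible(TRUE)
}

newMaskLike <- function(template, indices) {
  new("IndexMask", indices = sort(unique(as.integer(indices))),
      parentRef = template@parentRef, parentSize = template@parentSize,
      kind = template@kind)
}

#' Set algebra on masks
#'
#' Exact set semantics on the member indices of two masks sharing a parent;
#' the result is sorted and unique.
#'
#' @param a,b \linkS4class{IndexMask} objects with the same parent.
#' @param op "union", "intersection" or "difference" (a minus b).
#' @return An \linkS4class{IndexMask}.
#' @export
maskAlgebra <- function(a, b, op = c("union", "intersection", "difference")) {
  op <- match.arg(op)
  checkSameParent(a, b)
  idx <- switch(op,
    union = union(a@indices, b@indices),
    intersection = intersect(a@indices, b@indices),
    difference = setdiff(a@indices, b@indices))
  newMaskLike(a, idx)
}

#' @rdname maskAlgebra
#' @export
maskUnion <- function(a, b) maskAlgebra(a, b, "union")

#' @rdname maskAlgebra
#' @export
maskIntersection <- function(a, b) maskAlgebra(a, b, "intersection")

#' @rdname maskAlgebra
#' @export
maskDifference <- function(a, b) maskAlgebra(a, b, "difference")

#' Write a mask as a plain-text index list
#'
#' One 0-based integer per line (0-based to match the voxel-index convention
#' of the NIfTI world transform), preceded by comment lines recording the
#' parent fingerprint, size and kind so that round-trips can be checked.
#'
#' @param mask an \linkS4class{IndexMask}.
#' @param path output text path.
#' @return invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# kind: ", mask@kind),
               paste0("# parentSize: ", mask@parentSize),
               paste0("# parentRef: ", mask@parentRef),
               format(mask@indices - 1L, scientific = FALSE, trim = TRUE)),
             con)
  invisible(path)
}

#' Read a mask written by \code{\link{writeMask}}
#'
#' @param path text path.
#' @param parent optional parent object; if supplied, its fingerprint must
#'   match the stored one.
#' @return An \linkS4class{IndexMask}.
#' @export
readMask <- function(path, parent = NULL) {
  if (!file.exists(path))
    stop(corticomapError("file_not_found", paste("no such file:", path)))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  getField <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  kind <- getField("kind")
  parentSize <- as.integer(getField("parentSize"))
  parentRef <- getField("parentRef")
  if (!is.null(parent)) {
    fp <- parentFingerprint(parent)
    if (!identical(fp, parentRef))
      stop(corticomapError("parent_mismatch",
        "stored mask parent does not match the supplied parent"))
  }
  new("IndexMask", indices = sort(unique(as.integer(body) + 1L)),
      parentRef = parentRef, parentSize = parentSize, kind = kind)
}

#' Logical membership vector of a mask
#'
#' @param mask an \linkS4class{IndexMask}.
#' @return logical vector of length \code{mask@parentSize}.
#' @export
maskToLogical <- function(mask) {
  out <- logical(mask@parentSize)
  out[mask@indices] <- TRUE
  out
}
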