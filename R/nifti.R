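## Minimal single-file NIfTI-1 (.nii / .nii.gz) codec.
##
## No NIfTI reader is available in this R installation, so the header is
## decoded directly. Scope: single-file ("n+1") images, 3D or 4D, datatypes
## uint8/int16/int32/uint16/float32/float64, scl slope/intercept honoured,
## sform preferred over qform, both endiannesses on read; writes are always
## little-endian float32 (or float64 on request) with an sform.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

#' Read a NIfTI-1 volume or time series
#'
#' Single-file NIfTI-1 images only; 3D inputs return a
#' \linkS4class{BrainVolume}, 4D inputs a \linkS4class{BrainTimeSeries}.
#' Scaling (scl_slope/scl_inter) is applied; the grid-to-world transform is
#' taken from the sform when set, else from the qform, else from pixdim.
#' Non-finite voxels are flagged in the validity mask.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A \linkS4class{BrainVolume} or \linkS4class{BrainTimeSeries}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    stop(corticomapError("file_not_found", paste("no such file:", path)))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L)
    stop(corticomapError("not_nifti", "file too short for a NIfTI-1 header"))
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L)
      stop(corticomapError("not_nifti", "not a NIfTI-1 file (bad sizeof_hdr)"))
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (magic != "n+1")
    stop(corticomapError("not_nifti",
      "not a single-file NIfTI-1 image (magic != 'n+1')"))
  geti16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2L,
                                     endian = endian)
  getf32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "numeric", n = n, size = 4L,
                                     endian = endian)
  dims <- geti16(40L, 8L)
  nd <- dims[1]
  if (!nd %in% c(3L, 4L))
    stop(corticomapError("bad_dimensionality",
      sprintf("expected a 3D or 4D image, got %dD", nd)))
  datatype <- geti16(70L, 1L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    stop(corticomapError("unsupported_datatype",
      paste("unsupported NIfTI datatype code:", datatype)))
  pixdim <- getf32(76L, 8L)
  vox_offset <- getf32(108L, 1L)
  scl_slope <- getf32(112L, 1L)
  scl_inter <- getf32(116L, 1L)
  qform_code <- geti16(252L, 1L)
  sform_code <- geti16(254L, 1L)
  srow <- matrix(getf32(280L, 12L), nrow = 3, byrow = TRUE)
  nvox <- prod(dims[2:(nd + 1)])
  ## skip from end of header to vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox)
    stop(corticomapError("not_nifti", "truncated NIfTI data section"))
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  transform <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    quaternionToTransform(getf32(256L, 3L), getf32(268L, 3L),
                          pixdim[2:4], pixdim[1])
  } else {
    diag(c(abs(pixdim[2:4]), 1))
  }
  vs <- abs(pixdim[2:4])
  vs[vs == 0] <- 1
  if (nd == 3L) {
    brainVolume(array(vals, dims[2:4]), voxelSize = vs, transform = transform)
  } else {
    tr <- pixdim[5]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    brainTimeSeries(array(vals, dims[2:5]), voxelSize = vs,
                    transform = transform, frameInterval = tr)
  }
}

quaternionToTransform <- function(q_bcd, offset, pixdim3, qfac) {
  b <- q_bcd[1]; c_ <- q_bcd[2]; d <- q_bcd[3]
  a <- sqrt(max(0, 1 - b^2 - c_^2 - d^2))
  R <- matrix(c(
    a*a + b*b - c_*c_ - d*d, 2*(b*c_ - a*d),          2*(b*d + a*c_),
    2*(b*c_ + a*d),          a*a + c_*c_ - b*b - d*d, 2*(c_*d - a*b),
    2*(b*d - a*c_),          2*(c_*d + a*b),          a*a + d*d - b*b - c_*c_),
    nrow = 3, byrow = TRUE)
  if (!is.finite(qfac) || qfac == 0) qfac <- 1
  scales <- c(pixdim3[1], pixdim3[2], pixdim3[3] * qfac)
  M <- R %*% diag(scales)
  rbind(cbind(M, offset), c(0, 0, 0, 1))
}

#' Write a volume or time series as single-file NIfTI-1
#'
#' Little-endian, with the object's transform stored as the sform
#' (sform_code = 2). Invalid voxels are written as NaN so that the validity
#' mask round-trips.
#'
#' @param x a \linkS4class{BrainVolume} or \linkS4class{BrainTimeSeries}.
#' @param path output path; ".gz" suffix triggers gzip compression.
#' @param datatype "float32" (default) or "float64".
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(x, path, datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  is4d <- is(x, "BrainTimeSeries")
  data <- x@data
  if (is4d) {
    nan3 <- !x@valid
    if (any(nan3)) {
      for (t in seq_len(dim(data)[4])) {
        frame <- data[, , , t]
        frame[nan3] <- NaN
        data[, , , t] <- frame
      }
    }
  } else {
    data[!x@valid] <- NaN
  }
  dims <- dim(data)
  nd <- length(dims)
  dimfield <- rep(1L, 8L); dimfield[1] <- nd
  dimfield[2:(nd + 1)] <- dims
  pixdim <- rep(0, 8)
  pixdim[1] <- 1
  pixdim[2:4] <- x@voxelSize
  if (is4d) pixdim[5] <- x@frameInterval
  dtcode <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  size <- bitpix / 8L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  w_chr <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r[seq_len(min(length(r), n))],
               raw(max(0L, n - length(r)))), con)
  }
  w_i32(348L)                      # sizeof_hdr
  w_chr("", 10L); w_chr("", 18L)   # data_type, db_name
  w_i32(0L); w_i16(0L)             # extents, session_error
  writeBin(charToRaw("r"), con)    # regular
  writeBin(raw(1L), con)           # dim_info
  w_i16(dimfield)                  # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1..p3
  w_i16(0L)                        # intent_code
  w_i16(dtcode); w_i16(bitpix)     # datatype, bitpix
  w_i16(0L)                        # slice_start
  w_f32(pixdim)                    # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L)                        # slice_end
  writeBin(raw(2L), con)           # slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_chr("corticomap", 80L)         # descrip
  w_chr("", 24L)                   # aux_file
  w_i16(0L); w_i16(2L)             # qform_code, sform_code
  w_f32(rep(0, 6))                 # quatern b,c,d + qoffset x,y,z
  w_f32(x@transform[1, ]); w_f32(x@transform[2, ]); w_f32(x@transform[3, ])
  w_chr("", 16L)                   # intent_name
  w_chr("n+1", 4L)                 # magic
  w_i32(0L)                        # extension flag (none)
  writeBin(as.numeric(data), con, size = size, endian = "little")
  invisible(path)
}
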