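#' Read a NIfTI-1 image
#'
#' Minimal NIfTI-1 reader for uncompressed `.nii` and gzipped `.nii.gz`
#' single-file images. Supports the datatypes produced by common fMRI tooling
#' (uint8, int16, int32, float32, float64, uint16) and applies the
#' `scl_slope` / `scl_inter` scaling when set. Byte order is detected from the
#' header. No R NIfTI package is assumed; this reader exists so that 4D BOLD
#' volumes and integer atlas images can be consumed directly.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return numeric array with attributes `pixdim` (grid spacings, seconds in
#'   slot 4 for 4D data) and `datatype` (NIfTI datatype code).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "' in ", path)
  dim <- readBin(hdr_raw[41:56], "integer", n = 8L, size = 2L, endian = endian)
  ndim <- dim[1]
  if (ndim < 1L || ndim > 7L) stop("bad ndim ", ndim, " in ", path)
  dims <- dim[2:(1 + ndim)]
  datatype <- readBin(hdr_raw[71:72], "integer", size = 2L, endian = endian)
  pixdim <- readBin(hdr_raw[77:108], "numeric", n = 8L, size = 4L, endian = endian)
  vox_offset <- readBin(hdr_raw[109:112], "numeric", size = 4L, endian = endian)
  scl_slope <- readBin(hdr_raw[113:116], "numeric", size = 4L, endian = endian)
  scl_inter <- readBin(hdr_raw[117:120], "numeric", size = 4L, endian = endian)

  # skip from byte 348 to vox_offset (extensions); gz streams cannot seek
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)

  n <- prod(dims)
  vals <- switch(as.character(datatype),
    "2"   = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
    "4"   = as.numeric(readBin(con, "integer", n = n, size = 2L, endian = endian)),
    "8"   = as.numeric(readBin(con, "integer", n = n, size = 4L, endian = endian)),
    "16"  = readBin(con, "numeric", n = n, size = 4L, endian = endian),
    "64"  = readBin(con, "numeric", n = n, size = 8L, endian = endian),
    "512" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = endian)),
    stop("unsupported NIfTI datatype code ", datatype, " in ", path)
  )
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  out <- array(vals, dim = dims)
  attr(out, "pixdim") <- pixdim[2:(1 + ndim)]
  attr(out, "datatype") <- datatype
  out
}

#' Write a NIfTI-1 image
#'
#' Minimal single-file NIfTI-1 writer (`.nii` or `.nii.gz`). Integer-valued
#' arrays (e.g. atlas label images) are stored as int32, everything else as
#' float64. An identity sform is written; `pixdim` carries grid spacing and,
#' for 4D data, the repetition time in seconds in the fourth slot.
#'
#' @param img numeric array, 1 to 7 dimensions.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param pixdim numeric vector of per-dimension spacings (recycled defaults
#'   to 1; give `c(dx, dy, dz, tr)` for 4D BOLD data).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, pixdim = NULL) {
  dims <- dim(img) %||% length(img)
  ndim <- length(dims)
  if (ndim > 7L) stop("NIfTI supports at most 7 dimensions")
  if (is.null(pixdim)) pixdim <- rep(1, ndim)
  if (length(pixdim) < ndim) pixdim <- c(pixdim, rep(1, ndim - length(pixdim)))

  integral <- all(is.finite(img)) && all(img == round(img)) &&
    max(abs(img)) < 2^31
  datatype <- if (integral) 8L else 64L
  bitpix <- if (integral) 32L else 64L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))

  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                        # sizeof_hdr
  wpad(10L); wpad(18L)                # data_type, db_name
  wi(0L, 4L); wi(0L, 2L)              # extents, session_error
  writeBin(charToRaw("r"), con)       # regular
  wpad(1L)                            # dim_info
  dimfield <- c(ndim, dims, rep(1L, 7L - ndim))
  wi(dimfield, 2L)                    # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)          # intent_p1..3, intent_code
  wi(datatype, 2L); wi(bitpix, 2L); wi(0L, 2L)  # datatype, bitpix, slice_start
  wf(c(1, pixdim[seq_len(ndim)], rep(1, 7L - ndim)))  # pixdim[8], qfac = 1
  wf(352); wf(1); wf(0)               # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); wpad(1L); wpad(1L)      # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                   # cal_max, cal_min, slice_duration, toffset
  wi(0L, 4L); wi(0L, 4L)              # glmax, glmin
  wpad(80L); wpad(24L)                # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)              # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))      # quatern, qoffset
  wf(c(pixdim[1], 0, 0, 0))           # srow_x
  wf(c(0, if (ndim >= 2) pixdim[2] else 1, 0, 0))
  wf(c(0, 0, if (ndim >= 3) pixdim[3] else 1, 0))
  wpad(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wpad(4L)                            # extension flag -> data at 352

  if (integral) {
    wi(as.vector(img), 4L)
  } else {
    writeBin(as.numeric(as.vector(img)), con, size = 8L, endian = "little")
  }
  invisible(path)
}
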