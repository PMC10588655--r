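# Minimal NIfTI-1 I/O in base R. No NIfTI package is assumed; the format's
# single-file variant (.nii, optionally gzipped) is simple enough to read
# and write directly: a 348-byte header, a 4-byte extension flag, then the
# voxel data. Supported on read: uint8, int16, int32, float32, float64 with
# scl_slope/scl_inter scaling. Written as float32 (or int16 for integer
# arrays), RAS-aligned diagonal affine from the voxel size.

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' @param img numeric (written float32) or integer (written int16) array,
#'   3-D or 4-D.
#' @param path output path ending in .nii or .nii.gz.
#' @param voxel_size_mm per-axis voxel size in mm (length 3).
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size_mm = c(1, 1, 1)) {
  nd <- length(dim(img))
  stopifnot(nd %in% c(3L, 4L), length(voxel_size_mm) == 3)
  integer_data <- is.integer(img)
  datatype <- if (integer_data) 4L else 16L      # int16 / float32
  bitpix <- if (integer_data) 16L else 32L
  dims <- c(nd, dim(img), rep(1L, 7 - nd))
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                    # sizeof_hdr
  writeBin(raw(36), con)                         # data_type..dim_info
  wi(dims, 2)                                    # dim[8]
  wf(c(0, 0, 0))                                 # intent_p1..p3
  wi(0L, 2)                                      # intent_code
  wi(datatype, 2); wi(bitpix, 2); wi(0L, 2)      # datatype, bitpix, slice_start
  wf(c(1, voxel_size_mm, rep(1, 4)))             # pixdim[8] (qfac = 1)
  wf(352)                                        # vox_offset
  wf(c(1, 0))                                    # scl_slope, scl_inter
  wi(0L, 2)                                      # slice_end
  writeBin(as.raw(c(0L, 10L)), con)              # slice_code, xyzt = mm|sec
  wf(c(0, 0, 0))                                 # cal_max, cal_min, slice_dur
  wf(0)                                          # toffset
  wi(c(0L, 0L), 4)                               # glmax, glmin
  writeBin(raw(80 + 24), con)                    # descrip, aux_file
  wi(c(0L, 1L), 2)                               # qform_code=0, sform_code=1
  wf(rep(0, 6))                                  # quatern b,c,d, qoffset x,y,z
  wf(c(voxel_size_mm[1], 0, 0, 0))               # srow_x
  wf(c(0, voxel_size_mm[2], 0, 0))               # srow_y
  wf(c(0, 0, voxel_size_mm[3], 0))               # srow_z
  writeBin(raw(16), con)                         # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic "n+1\0"
  writeBin(raw(4), con)                          # extension flag
  if (integer_data) wi(as.vector(img), 2) else wf(as.vector(img))
  invisible(path)
}

#' Read a NIfTI-1 volume written by \code{\link{write_nifti}} or compatible
#'
#' @param path .nii or .nii.gz file.
#' @return array (3-D or 4-D) with attribute \code{voxel_size_mm}.
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348L) stop("not a NIfTI-1 file (wrong header size)")
  dims <- ri(40, 2, 8)
  nd <- dims[1]
  if (!nd %in% c(3L, 4L)) stop("only 3-D/4-D volumes supported")
  shape <- dims[2:(1 + nd)]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)
  n <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  dat <- switch(as.character(datatype),
                "2"  = as.numeric(readBin(con, "integer", n, size = 1,
                                          signed = FALSE)),
                "4"  = as.numeric(readBin(con, "integer", n, size = 2,
                                          endian = "little")),
                "8"  = as.numeric(readBin(con, "integer", n, size = 4,
                                          endian = "little")),
                "16" = readBin(con, "double", n, size = 4,
                               endian = "little"),
                "64" = readBin(con, "double", n, size = 8,
                               endian = "little"),
                stop("unsupported NIfTI datatype: ", datatype))
  if (length(dat) != n) stop("truncated NIfTI data")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    dat <- dat * scl_slope + scl_inter
  }
  out <- array(dat, shape)
  attr(out, "voxel_size_mm") <- pixdim[2:4]
  out
}
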