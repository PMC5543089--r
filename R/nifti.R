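# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI package is available in the supported dependency set, so the
# package carries its own reader/writer for the subset it needs: 3D/4D
# volumes, datatypes uint8/int16/int32/float32/float64, sform affine,
# little- or big-endian input, optional gzip. Scaling (scl_slope/scl_inter)
# is applied on read; files are written unscaled with sform_code 2.

nifti_dtypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  name = c("uint8", "int16", "int32", "float32", "float64"),
  stringsAsFactors = FALSE
)

nii_connection <- function(file, open) {
  if (grepl("\\.gz$", file)) gzfile(file, open) else file(file, open)
}

#' Read a NIfTI-1 volume
#'
#' @param file Path to a `.nii` or `.nii.gz` single file.
#' @return List with `data` (3D or 4D array), `affine` (4x4 sform, or the
#'   pixdim-scaled identity if no sform is present), `pixdim` (voxel sizes,
#'   and TR in slot 4 for 4D data), and `tr` (seconds, 4D only).
#' @export
read_nifti <- function(file) {
  con <- nii_connection(file, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
    if (sizeof_hdr != 348L) stopf("'%s' is not a NIfTI-1 file", file)
  }
  int16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                    "integer", n, 2, endian = endian)
  flt32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                    "double", n, 4, endian = endian)
  dim_field <- int16(40, 8)
  ndim <- dim_field[1]
  if (!ndim %in% 3:4) stopf("unsupported NIfTI dimensionality: %d", ndim)
  dims <- dim_field[2:(1 + ndim)]
  datatype <- int16(70, 1)
  row <- match(datatype, nifti_dtypes$code)
  if (is.na(row)) stopf("unsupported NIfTI datatype code %d", datatype)
  pixdim <- flt32(76, 8)[2:8]
  vox_offset <- flt32(108, 1)
  scl_slope <- flt32(112, 1)
  scl_inter <- flt32(116, 1)
  sform_code <- int16(254, 1)
  srow <- matrix(flt32(280, 12), nrow = 3, byrow = TRUE)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("bad NIfTI magic '%s'", magic)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n_vals <- prod(dims)
  vals <- readBin(con, nifti_dtypes$what[row], n_vals,
                  size = nifti_dtypes$size[row], endian = endian,
                  signed = !(datatype == 2L))
  if (length(vals) != n_vals) stopf("truncated NIfTI data in '%s'", file)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1)) else {
    a <- diag(4); diag(a)[1:3] <- pixdim[1:3]; a
  }
  list(data = array(vals, dims), affine = affine, pixdim = pixdim,
       tr = if (ndim == 4L) pixdim[4] else NA_real_)
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D or 4D numeric array.
#' @param file Output path; a `.gz` suffix triggers gzip compression.
#' @param affine 4x4 index(0-based)-to-mm affine, written as the sform.
#' @param tr Repetition time in seconds (4D data), stored in pixdim\[4\].
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"` (default `"float32"`).
#' @return `file`, invisibly.
#' @export
write_nifti <- function(data, file, affine = diag(4), tr = 0,
                        datatype = "float32") {
  dims <- dim(data)
  if (!length(dims) %in% 3:4) stopf("data must be a 3D or 4D array")
  row <- match(datatype, nifti_dtypes$name)
  if (is.na(row)) stopf("unsupported datatype '%s'", datatype)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- nii_connection(file, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info (unused)
  wi(c(length(dims), dims, rep(1L, 7 - length(dims))), 2)  # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                     # intent_p1..intent_code
  wi(nifti_dtypes$code[row], 2)                # datatype
  wi(nifti_dtypes$size[row] * 8L, 2)           # bitpix
  wi(0, 2)                                     # slice_start
  wf(c(1, vs, if (length(dims) == 4L) tr else 0, 0, 0, 0))  # pixdim[8]
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0, 2); writeBin(raw(2), con)              # slice_end, slice_code+xyzt_units
  wf(c(0, 0, 0, 0))                            # cal_max..toffset
  wi(c(0, 0), 4)                               # glmax, glmin
  writeBin(raw(80 + 24), con)                  # descrip, aux_file
  wi(c(0L, 2L), 2)                             # qform_code=0, sform_code=2
  wf(rep(0, 6))                                # quaternions
  wf(t(affine[1:3, , drop = FALSE]))           # srow_x/y/z
  writeBin(raw(16), con)                       # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  storage <- nifti_dtypes$what[row]
  vals <- if (storage == "integer") as.integer(round(data)) else as.double(data)
  writeBin(vals, con, size = nifti_dtypes$size[row], endian = "little")
  invisible(file)
}
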