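# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O (single 3-D volume, float32, 1 mm isotropic by default).
# Written by hand because no NIfTI reader ships with this R stack; gzip is
# handled transparently by base connections.  Covers exactly what the
# preprocessing QC and the phantom exporter need, nothing more.
# ---------------------------------------------------------------------------

#' Write a 3-D volume as NIfTI-1 (.nii or .nii.gz)
#'
#' @param vol 3-D numeric array.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param pixdim voxel size in mm, length 3 (default 1 mm isotropic).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, pixdim = c(1, 1, 1)) {
  stopifnot(length(dim(vol)) == 3, length(pixdim) == 3)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  ws <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L)                                   # sizeof_hdr
  wraw(36L)                                  # data_type..dim_info
  ws(c(3L, dim(vol), 1L, 1L, 1L, 1L))        # dim[8]
  wf(c(0, 0, 0))                             # intent_p1..p3
  ws(0L)                                     # intent_code
  ws(16L)                                    # datatype = float32
  ws(32L)                                    # bitpix
  ws(0L)                                     # slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))               # pixdim[8]
  wf(352)                                    # vox_offset
  wf(1); wf(0)                               # scl_slope, scl_inter
  ws(0L); wraw(2L)                           # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                          # cal_max..toffset
  wi(c(0L, 0L))                              # glmax, glmin
  wraw(80L + 24L)                            # descrip, aux_file
  ws(c(0L, 1L))                              # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                    # quatern, qoffset
  wf(c(pixdim[1], 0, 0, 0))                  # srow_x
  wf(c(0, pixdim[2], 0, 0))                  # srow_y
  wf(c(0, 0, pixdim[3], 0))                  # srow_z
  wraw(16L)                                  # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1L)  # magic
  wraw(4L)                                   # extension flag
  writeBin(as.numeric(vol), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read and validate a NIfTI-1 header
#'
#' Returns a diagnosis rather than throwing, so QC can fail closed.
#'
#' @param path file path (.nii or .nii.gz).
#' @return list with `ok` (logical), `reason`, and on success `dim`,
#'   `datatype`, `pixdim`, `vox_offset`.
#' @export
read_nifti_header <- function(path) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (!file.exists(path)) return(fail("missing file"))
  hdr <- tryCatch({
    con <- gzfile(path, "rb")
    on.exit(close(con))
    raw348 <- readBin(con, "raw", 348L)
    if (length(raw348) < 348L) stop("short header")
    raw348
  }, error = function(e) NULL)
  if (is.null(hdr)) return(fail("invalid header"))
  rd_i <- function(off) readBin(hdr[(off + 1):(off + 4)], "integer",
                                size = 4L, endian = "little")
  rd_s <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                   n = n, size = 2L, endian = "little")
  rd_f <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "numeric",
                                   n = n, size = 4L, endian = "little")
  if (rd_i(0) != 348L) return(fail("invalid header"))
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) return(fail("invalid header"))
  dims <- rd_s(40, 8L)
  nd <- dims[1]
  if (nd < 1 || nd > 7) return(fail("invalid header"))
  list(ok = TRUE, reason = NA_character_,
       dim = dims[2:(1 + nd)],
       datatype = rd_s(70, 1L),
       pixdim = rd_f(76, 8L)[2:(1 + nd)],
       vox_offset = rd_f(108, 1L))
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or any float32/float64/
#' int16/uint8 single-frame NIfTI)
#'
#' @param path file path.
#' @return list with `data` (3-D array) and `pixdim`.
#' @export
read_nifti <- function(path) {
  hdr <- read_nifti_header(path)
  if (!hdr$ok) stop("read_nifti: ", hdr$reason, " (", path, ")")
  con <- gzfile(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", as.integer(hdr$vox_offset)))
  n <- prod(hdr$dim)
  dat <- switch(as.character(hdr$datatype),
    `2`  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    `4`  = as.numeric(readBin(con, "integer", n, size = 2L,
                              endian = "little")),
    `16` = readBin(con, "numeric", n, size = 4L, endian = "little"),
    `64` = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("read_nifti: unsupported datatype ", hdr$datatype)
  )
  if (length(dat) < n) stop("read_nifti: truncated data section")
  list(data = array(dat, dim = hdr$dim), pixdim = hdr$pixdim)
}
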