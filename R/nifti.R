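# Minimal single-file NIfTI-1 (.nii, uncompressed) I/O. The pre-installed R
# stack has no NIfTI package, so the format's 348-byte header is written
# directly: float32 data, scanner-anatomical diagonal affine from the voxel
# size, no extensions.

#' Write a volume as NIfTI-1
#'
#' @param vol numeric 3D or 4D array (time last).
#' @param file output path ending in `.nii`.
#' @param voxel_size_mm voxel edge lengths (length 3).
#' @param tr_s repetition time stored in pixdim[4] for 4D data.
#' @return The file path, invisibly.
#' @export
write_nifti <- function(vol, file, voxel_size_mm = 1.5, tr_s = 2) {
  dims <- dim(vol)
  ndim <- length(dims)
  stopifnot(ndim %in% c(3L, 4L))
  vx <- rep(voxel_size_mm, length.out = 3L)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L)                      # sizeof_hdr
  writeBin(raw(36L), con)                             # unused
  dim_field <- integer(8L)
  dim_field[1L] <- ndim
  dim_field[2:(1L + ndim)] <- dims
  dim_field[dim_field == 0L] <- 1L
  writeBin(as.integer(dim_field), con, size = 2L)     # dim
  writeBin(raw(14L), con)                             # intent params etc.
  writeBin(16L, con, size = 2L)                       # datatype: float32
  writeBin(32L, con, size = 2L)                       # bitpix
  writeBin(0L, con, size = 2L)                        # slice_start
  pixdim <- c(1, vx, if (ndim == 4L) tr_s else 1, 1, 1, 1)
  writeBin(as.numeric(pixdim), con, size = 4L)        # pixdim
  writeBin(352, con, size = 4L)                       # vox_offset
  writeBin(c(1, 0), con, size = 4L)                   # scl_slope, scl_inter
  writeBin(raw(3L), con)                              # slice_end, slice_code
  writeBin(as.raw(10L), con)                          # xyzt_units: mm + s
  writeBin(numeric(4L), con, size = 4L)               # cal_max..toffset
  writeBin(raw(8L), con)                              # glmax, glmin
  writeBin(raw(104L), con)                            # descrip + aux_file
  writeBin(c(0L, 1L), con, size = 2L)                 # qform, sform codes
  writeBin(numeric(6L), con, size = 4L)               # quaternions/offsets
  srow <- rbind(c(vx[1L], 0, 0, 0), c(0, vx[2L], 0, 0), c(0, 0, vx[3L], 0))
  writeBin(as.numeric(t(srow)), con, size = 4L)       # srow_x/y/z
  writeBin(raw(16L), con)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)      # magic
  writeBin(raw(4L), con)                              # extension flag
  writeBin(as.numeric(vol), con, size = 4L)
  invisible(file)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Supports uncompressed single-file float32/float64/int16/uint8 data.
#'
#' @param file path to a `.nii` file.
#' @return List with `data` (array), `voxel_size_mm`, `tr_s`.
#' @export
read_nifti <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1L, size = 4L)
  if (hdr_size != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348)")
  invisible(readBin(con, "raw", 36L))
  dim_field <- readBin(con, "integer", 8L, size = 2L)
  invisible(readBin(con, "raw", 14L))
  datatype <- readBin(con, "integer", 1L, size = 2L)
  invisible(readBin(con, "integer", 1L, size = 2L))   # bitpix
  invisible(readBin(con, "integer", 1L, size = 2L))   # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L)
  ndim <- dim_field[1L]
  dims <- dim_field[2:(1L + ndim)]
  seek(con, vox_offset)
  n <- prod(dims)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2L)),
    "16" = readBin(con, "numeric", n, size = 4L),
    "64" = readBin(con, "numeric", n, size = 8L),
    stop("unsupported NIfTI datatype ", datatype))
  list(data = array(data, dims), voxel_size_mm = pixdim[2:4],
       tr_s = if (ndim == 4L) pixdim[5L] else NA_real_)
}

#' Write a paradigm as a tab-separated event table
#'
#' Columns `onset_s`, `duration_s`, `finger`.
#'
#' @param paradigm a `paradigm_er` or `paradigm_pe`.
#' @param file output path.
#' @export
write_events_tsv <- function(paradigm, file) {
  ev <- if (inherits(paradigm, "paradigm_pe")) paradigm$epochs else paradigm$events
  utils::write.table(ev, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a tab-separated event table
#'
#' @param file path to a TSV with `onset_s`, `duration_s`, `finger`.
#' @param tr_s repetition time.
#' @param run_duration_s total run duration; default last onset + 20 s
#'   rounded up to a volume.
#' @return A `paradigm_er` object.
#' @export
read_events_tsv <- function(file, tr_s = 2, run_duration_s = NULL) {
  ev <- utils::read.table(file, header = TRUE, sep = "\t")
  if (is.null(run_duration_s))
    run_duration_s <- ceiling((max(ev$onset_s) + 20) / tr_s) * tr_s
  structure(list(events = ev, run_duration_s = run_duration_s, tr_s = tr_s,
                 trial_model_duration_s = ev$duration_s[1L]),
            class = "paradigm_er")
}
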