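#' Write a 3-D or 4-D array as a NIfTI-1 volume
#'
#' Minimal single-file (.nii) NIfTI-1 writer: float32 or int16 data,
#' little-endian, identity-scaled, with voxel sizes in \code{pixdim}. Intended
#' for exchanging synthetic volumes and winner maps with standard neuroimaging
#' tools; no R NIfTI package is required at run time.
#'
#' @param x numeric or integer array with 3 or 4 dimensions.
#' @param path output file name (conventionally \code{.nii}).
#' @param pixdim voxel dimensions (mm / s), recycled to length 4.
#' @param datatype \code{"float32"} or \code{"int16"}.
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = c(2, 2, 2, 2), datatype = "float32") {
  nd <- length(dim(x))
  if (is.null(dim(x)) || !(nd %in% c(3, 4))) stop("x must be a 3-D or 4-D array")
  dt <- match.arg(datatype, c("float32", "int16"))
  code <- c(float32 = 16L, int16 = 4L)[dt]
  bitpix <- c(float32 = 32L, int16 = 16L)[dt]
  dims <- rep(1L, 8); dims[1] <- nd; dims[1 + seq_len(nd)] <- dim(x)
  pd <- rep(0, 8); pd[1] <- 1; pd[1 + seq_len(4)] <- rep(pixdim, length.out = 4)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  wi(348L, 4)                      # sizeof_hdr
  writeBin(raw(35), con)           # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)        # dim_info
  wi(dims, 2)                      # dim[8]
  wf(rep(0, 3))                    # intent_p1-3
  wi(0L, 2)                        # intent_code
  wi(code, 2)                      # datatype
  wi(bitpix, 2)                    # bitpix
  wi(0L, 2)                        # slice_start
  wf(pd)                           # pixdim[8]
  wf(352)                          # vox_offset
  wf(c(1, 0))                      # scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 0L)), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                   # cal_max, cal_min, slice_duration
  wf(0)                            # toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  writeBin(raw(80 + 24), con)      # descrip, aux_file
  wi(c(0L, 0L), 2)                 # qform_code, sform_code
  wf(rep(0, 6))                    # quatern b,c,d, qoffset x,y,z
  wf(c(pd[2], 0, 0, 0))            # srow_x
  wf(c(0, pd[3], 0, 0))            # srow_y
  wf(c(0, 0, pd[4], 0))            # srow_z
  writeBin(raw(16), con)           # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); writeBin(as.raw(0L), con)
  writeBin(raw(4), con)            # extension flag
  stopifnot(seek(con) == 352)
  if (dt == "float32") {
    writeBin(as.double(as.vector(x)), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(as.vector(x))), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by \code{\link{write_nifti}}
#'
#' Supports uncompressed single-file little-endian NIfTI-1 with float32,
#' float64, int16, int32 or uint8 data and identity scaling.
#'
#' @param path input .nii file.
#' @param expect_4d require a 4-D image (clear error on 3-D input).
#' @return array with attribute \code{pixdim}.
#' @export
read_nifti <- function(path, expect_4d = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, integer(), 1, size = 4, endian = "little")
  if (!identical(hdr_size, 348L)) stop("not a NIfTI-1 file (bad header size): ", path)
  seek(con, 40)
  dims <- readBin(con, integer(), 8, size = 2, endian = "little")
  nd <- dims[1]
  if (nd < 3 || nd > 7) stop("unsupported image dimensionality: ", nd)
  seek(con, 70)
  code <- readBin(con, integer(), 1, size = 2, endian = "little")
  seek(con, 76)
  pd <- readBin(con, double(), 8, size = 4, endian = "little")
  vox_offset <- readBin(con, double(), 1, size = 4, endian = "little")
  shape <- dims[1 + seq_len(nd)]
  if (expect_4d && nd != 4) {
    stop("expected a 4-D (voxels x time) image but got ", nd, "-D: ", path)
  }
  n <- prod(shape)
  seek(con, vox_offset)
  data <- switch(as.character(code),
    "2" = as.numeric(readBin(con, integer(), n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, integer(), n, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, integer(), n, size = 4, endian = "little")),
    "16" = readBin(con, double(), n, size = 4, endian = "little"),
    "64" = readBin(con, double(), n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", code)
  )
  out <- array(data, shape)
  attr(out, "pixdim") <- pd[1 + seq_len(4)]
  out
}

#' Read / write a canonical RDM as a delimited table
#'
#' @param rdm 5 x 5 RDM matrix.
#' @param path CSV file.
#' @return \code{read_rdm_csv}: an \code{rdm} matrix; the writer returns
#'   \code{path} invisibly.
#' @export
write_rdm_csv <- function(rdm, path) {
  utils::write.csv(as.data.frame(unclass(rdm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("RDM table must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("RDM table must be symmetric")
  structure(m, class = c("rdm", "matrix"))
}

#' Read / write a pipeline configuration as JSON
#'
#' The configuration is a plain named list (see \code{\link{pipeline_config}})
#' and is fully serialisable; every stochastic element of the pipeline is
#' driven by the single \code{seed} it carries.
#'
#' @param config a \code{\link{pipeline_config}} list.
#' @param path JSON file.
#' @return the reader returns a \code{pipeline_config}; the writer returns
#'   \code{path} invisibly.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}
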