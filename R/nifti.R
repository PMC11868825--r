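#  Minimal NIfTI-1 reader/writer (.nii / .nii.gz), little-endian with
#  byte-swap detection on read.  No pre-installed NIfTI package exists in the
#  supported environment, so the 348-byte fixed header is handled directly;
#  only the fields the pipeline needs (dim, datatype, pixdim, vox_offset,
#  scaling, sform) are interpreted.

.nifti_datatypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double", size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE), # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE))# uint16

.nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 image
#'
#' Reads `.nii` or `.nii.gz` single-file NIfTI-1 volumes (integer and float
#' datatypes, slope/intercept scaling applied, both endiannesses).
#'
#' @param path file path.
#' @return a list of class `nifti_image`: `img` (numeric array), `pixdim`
#'   (voxel sizes), `affine` (4 x 4 sform matrix, or a pixdim-scaled default
#'   if no sform is present), `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path,
                               call. = FALSE)
  rd <- function(off, what, n, size, endian = "little", signed = TRUE)
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, "big") != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path, call. = FALSE)
  dim0 <- rd(40L, "integer", 8L, 2L, endian)
  nd <- dim0[1]
  if (nd < 1L || nd > 7L) stop("bad NIfTI dim[0]", call. = FALSE)
  dims <- dim0[2:(1 + nd)]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  pixdim <- rd(76L, "double", 8L, 4L, endian)[2:(1 + min(nd, 3L))]
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  sform_code <- rd(254L, "integer", 1L, 2L, endian)
  srow <- matrix(rd(280L, "double", 12L, 4L, endian), 3, 4, byrow = TRUE)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  # skip from end of header to the data offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data: ", path, call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 &&
                                                  scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1)) else {
    a <- diag(4)
    diag(a)[1:length(pixdim)] <- pixdim
    a
  }
  structure(list(img = array(vals, dims), pixdim = pixdim, affine = affine,
                 datatype = datatype), class = "nifti_image")
}

#' Write a NIfTI-1 image
#'
#' Writes a numeric array as a single-file little-endian NIfTI-1 volume,
#' float64 by default so values (including the `NaN` sentinel) round-trip
#' exactly.  `NA` values are serialized as `NaN`.
#'
#' @param img numeric array (1-7 dimensions).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 voxel-to-world matrix written as the sform (default:
#'   diagonal of `pixdim`).
#' @param pixdim voxel sizes (mm) for the spatial dimensions.
#' @param datatype NIfTI datatype code: 64 (float64, default) or 16
#'   (float32).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, affine = NULL, pixdim = c(1, 1, 1),
                        datatype = 64L) {
  if (!datatype %in% c(16L, 64L))
    stop("write supports datatype 16 (float32) or 64 (float64)",
         call. = FALSE)
  dims <- dim(img)
  if (is.null(dims)) dims <- length(img)
  nd <- length(dims)
  if (nd > 7L) stop("too many dimensions", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[seq_along(pixdim)] <- pixdim
  }
  dim_field <- as.integer(c(nd, dims, rep(1L, 7L - nd)))
  pd_field <- c(1, pixdim, rep(1, 7 - length(pixdim)))[1:8]
  size <- if (datatype == 64L) 8L else 4L
  hdr <- raw(348)
  put <- function(hdr, off, x, what, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, 348L, "integer", 4L)
  hdr <- put(hdr, 40L, dim_field, "integer", 2L)
  hdr <- put(hdr, 70L, as.integer(datatype), "integer", 2L)
  hdr <- put(hdr, 72L, as.integer(size * 8L), "integer", 2L)
  hdr <- put(hdr, 76L, pd_field, "double", 4L)
  hdr <- put(hdr, 108L, 352, "double", 4L)     # vox_offset
  hdr <- put(hdr, 112L, 1, "double", 4L)       # scl_slope
  hdr <- put(hdr, 116L, 0, "double", 4L)       # scl_inter
  hdr <- put(hdr, 254L, 1L, "integer", 2L)     # sform_code
  hdr <- put(hdr, 280L, as.numeric(t(affine[1:3, ])), "double", 4L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  vals <- as.double(img)
  vals[is.na(vals)] <- NaN
  con <- .nii_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                        # extension flag
  writeBin(vals, con, size = size, endian = "little")
  invisible(path)
}
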