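#' Read FSL-style b-value / b-vector text files
#'
#' `.bval`: whitespace-separated b-values on one line; `.bvec`: three lines
#' (x, y, z components per volume).  Columns of the b-vector table are
#' normalized to unit length; zero columns (b = 0 volumes) are preserved.
#'
#' @param bval_path,bvec_path file paths.
#' @return `read_bvals` returns a numeric vector; `read_bvecs` a 3 x n
#'   matrix.
#' @export
read_bvals <- function(bval_path) {
  v <- scan(bval_path, what = numeric(), quiet = TRUE)
  if (length(v) == 0L || any(!is.finite(v)) || any(v < 0))
    stop("invalid b-value file: ", bval_path, call. = FALSE)
  v
}

#' @rdname read_bvals
#' @export
read_bvecs <- function(bvec_path) {
  rows <- lapply(readLines(bvec_path), function(l)
    scan(text = l, what = numeric(), quiet = TRUE))
  rows <- rows[vapply(rows, length, 1L) > 0L]
  if (length(rows) != 3L)
    stop("b-vector file must have 3 rows (FSL convention): ", bvec_path,
         call. = FALSE)
  m <- do.call(rbind, rows)
  nrm <- sqrt(colSums(m^2))
  nz <- nrm > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, nrm[nz], "/")
  m
}

#' Write a scheme as FSL-style bval/bvec files
#'
#' @param scheme an [acquisition_scheme].
#' @param bval_path,bvec_path output paths.
#' @return `bval_path`, invisibly.
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(sprintf("%g", scheme$bvals), collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(sprintf("%.10g", r), collapse = " ")), bvec_path)
  invisible(bval_path)
}

#' Read a diffusion dataset (NIfTI + bval/bvec, optional mask)
#'
#' Geometry-checked loading of a 4-D diffusion-weighted volume with its
#' acquisition tables.  Volume count must match the bval/bvec entry count;
#' non-finite voxels are an error.  A missing mask yields a full-extent mask
#' with a warning.
#'
#' @param dwi_path 4-D NIfTI path.
#' @param bval_path,bvec_path FSL-style text files.
#' @param mask_path optional 3-D NIfTI mask (non-zero = inside).
#' @return list with `dwi` (4-D array), `scheme` ([acquisition_scheme]),
#'   `mask` (3-D logical), `affine`, `pixdim`.
#' @export
read_dataset <- function(dwi_path, bval_path, bvec_path, mask_path = NULL) {
  nii <- read_nifti(dwi_path)
  if (length(dim(nii$img)) != 4L)
    stop("expected a 4-D volume: ", dwi_path, call. = FALSE)
  if (any(!is.finite(nii$img)))
    stop("non-finite voxels in ", dwi_path, call. = FALSE)
  bvals <- read_bvals(bval_path)
  bvecs <- read_bvecs(bvec_path)
  if (length(bvals) != dim(nii$img)[4])
    stop(sprintf("count mismatch: %d b-values vs %d volumes",
                 length(bvals), dim(nii$img)[4]), call. = FALSE)
  if (ncol(bvecs) != length(bvals))
    stop("count mismatch between bval and bvec files", call. = FALSE)
  scheme <- acquisition_scheme(bvals, bvecs)
  mask <- if (is.null(mask_path)) {
    warning("no mask supplied; using the full image extent", call. = FALSE)
    array(TRUE, dim(nii$img)[1:3])
  } else {
    m <- read_nifti(mask_path)$img
    if (!identical(dim(m)[1:3], dim(nii$img)[1:3]))
      stop("mask geometry does not match image", call. = FALSE)
    array(m != 0, dim(nii$img)[1:3])
  }
  list(dwi = nii$img, scheme = scheme, mask = mask, affine = nii$affine,
       pixdim = nii$pixdim)
}

#' Write parameter maps as NIfTI files plus run metadata
#'
#' Writes `d12.nii.gz`, `alpha.nii.gz`, `ip.nii.gz` and `mse.nii.gz` carrying
#' the reference affine (undefined voxels serialized as `NaN`), and a
#' `qdi_run.txt` metadata file recording the supplied configuration entries
#' and the package version.
#'
#' @param maps a [parameter_maps] object.
#' @param affine 4 x 4 voxel-to-world matrix of the source image.
#' @param out_dir output directory (created if needed).
#' @param pixdim voxel sizes, mm.
#' @param metadata named list appended to the metadata file.
#' @return named character vector of written file paths, invisibly.
#' @export
write_maps <- function(maps, affine, out_dir, pixdim = c(1, 1, 1),
                       metadata = list()) {
  if (!inherits(maps, "parameter_maps"))
    stop("`maps` must be a parameter_maps object", call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- c()
  for (par in c("d12", "alpha", "ip", "mse")) {
    p <- file.path(out_dir, paste0(par, ".nii.gz"))
    write_nifti(maps[[par]], p, affine = affine, pixdim = pixdim)
    paths[par] <- p
  }
  p <- file.path(out_dir, "mask.nii.gz")
  write_nifti(maps$mask * 1, p, affine = affine, pixdim = pixdim)
  paths["mask"] <- p
  meta <- c(
    sprintf("qdimri_version: %s",
            as.character(utils::packageVersion("qdimri"))),
    sprintf("n_fitted_voxels: %d", sum(maps$mask)),
    vapply(names(metadata), function(k)
      sprintf("%s: %s", k, paste(format(metadata[[k]]), collapse = " ")),
      character(1)))
  mp <- file.path(out_dir, "qdi_run.txt")
  writeLines(meta, mp)
  paths["metadata"] <- mp
  invisible(paths)
}

#' Read parameter maps back from a [write_maps()] directory
#'
#' @param dir directory containing `d12.nii.gz` etc.
#' @return a [parameter_maps] object.
#' @export
read_maps <- function(dir) {
  get <- function(par) read_nifti(file.path(dir, paste0(par, ".nii.gz")))$img
  mask <- get("mask")
  parameter_maps(d12 = get("d12"), alpha = get("alpha"), ip = get("ip"),
                 mse = get("mse"), mask = array(mask != 0, dim(mask)))
}
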