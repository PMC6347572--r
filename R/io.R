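#' Write a 3-D or 4-D array as NIfTI with a given affine
#'
#' @param arr numeric array.
#' @param affine 4 x 4 voxel-to-world matrix (0-based indices, mm).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(arr, affine, path) {
  im <- RNifti::asNifti(arr)
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path file path.
#' @return list with `data` (array) and `affine`.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = as.array(im), affine = aff)
}

#' Read a diffusion-weighted series with FSL-style gradient table
#'
#' `bvec` is parsed as 3 rows x N columns (image coordinates), `bval` as a
#' single row of N values. Columns are renormalised to unit length (with a
#' warning beyond 1e-3 deviation); zero vectors are only accepted at b = 0.
#'
#' @param nii_path 4-D NIfTI path.
#' @param bval_path,bvec_path gradient table paths.
#' @return list with `signal` (4-D array), `scheme`
#'   ([gradient_scheme()]) and `affine`.
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path) {
  vol <- read_nifti_volume(nii_path)
  if (length(dim(vol$data)) != 4L)
    stop("expected a 4-D volume: ", nii_path)
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3L)
    stop("bvec must have 3 rows (got ", nrow(bvec), ")")
  n <- dim(vol$data)[4L]
  if (length(bval) != n || ncol(bvec) != n)
    stop("gradient table count mismatch: volume has ", n,
         " volumes, bval ", length(bval), ", bvec ", ncol(bvec))
  scheme <- gradient_scheme(bval, t(bvec))
  list(signal = vol$data, scheme = scheme, affine = vol$affine)
}

#' Write a diffusion-weighted series with FSL-style gradient table
#'
#' @param signal 4-D array.
#' @param scheme a [gradient_scheme()].
#' @param affine voxel-to-world matrix.
#' @param prefix output prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @return named character vector of the three paths, invisibly.
#' @export
write_dwi <- function(signal, scheme, affine, prefix) {
  stopifnot(dim(signal)[4L] == n_volumes(scheme))
  nii <- paste0(prefix, ".nii.gz")
  write_nifti_volume(signal, affine, nii)
  bval <- paste0(prefix, ".bval")
  writeLines(paste(format(scheme$bvalues, trim = TRUE), collapse = " "),
             bval)
  bvec <- paste0(prefix, ".bvec")
  utils::write.table(t(scheme$directions), bvec, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(nii = nii, bval = bval, bvec = bvec))
}

#' Read/write zonal response text files
#'
#' Plain-text layout: one row per shell in ascending b, whitespace-separated
#' even-degree zonal coefficients (l = 0, 2, ..., lmax). Shell b-values are
#' carried in a `# shells: ...` comment line. Round trips are lossless to
#' full double precision.
#'
#' @param response a [zonal_response()].
#' @param path file path.
#' @return `write_response`: the path, invisibly; `read_response`: a
#'   [zonal_response()].
#' @export
write_response <- function(response, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# shells:",
                   paste(format(response$shell_bvalues, digits = 17,
                                trim = TRUE), collapse = " ")), con)
  for (i in seq_len(nrow(response$coeffs)))
    writeLines(paste(format(response$coeffs[i, ], digits = 17,
                            trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_response
#' @param shell_bvalues optional override when the file has no shells
#'   comment.
#' @export
read_response <- function(path, shell_bvalues = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  shell_line <- grep("^#\\s*shells:", lines, value = TRUE)
  if (length(shell_line) && is.null(shell_bvalues))
    shell_bvalues <- scan(text = sub("^#\\s*shells:", "", shell_line[1L]),
                          quiet = TRUE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- lapply(lines, function(l) scan(text = l, quiet = TRUE))
  nc <- vapply(rows, length, 0L)
  if (length(unique(nc)) != 1L)
    stop("ragged response file: rows have ", paste(unique(nc), collapse = "/"),
         " columns")
  coeffs <- do.call(rbind, rows)
  if (is.null(shell_bvalues)) shell_bvalues <- seq_len(nrow(coeffs)) - 1
  if (length(shell_bvalues) != nrow(coeffs))
    stop("shell count (", length(shell_bvalues),
         ") does not match row count (", nrow(coeffs), ")")
  zonal_response(coeffs, shell_bvalues)
}

#' Read/write SH coefficient volumes as 4-D NIfTI
#'
#' The fourth dimension holds coefficients in the package's frozen ordering
#' (see [sh_basis()]); the degree is implied by the coefficient count.
#'
#' @param x an [sh_volume()].
#' @param path `.nii`/`.nii.gz` path.
#' @return `write_sh_volume`: path, invisibly; `read_sh_volume`: an
#'   [sh_volume()].
#' @export
write_sh_volume <- function(x, path) {
  write_nifti_volume(x$data, x$affine, path)
}

#' @rdname write_sh_volume
#' @export
read_sh_volume <- function(path) {
  v <- read_nifti_volume(path)
  if (length(dim(v$data)) == 3L) dim(v$data) <- c(dim(v$data), 1L)
  sh_volume(v$data, affine = v$affine)
}

#' Read/write displacement fields as 4-D NIfTI vector images
#'
#' Three components along the fourth dimension, world-space millimetres.
#'
#' @param field a [displacement_field()].
#' @param path file path.
#' @return `write_displacement_field`: path, invisibly;
#'   `read_displacement_field`: a [displacement_field()] (no inverse).
#' @export
write_displacement_field <- function(field, path) {
  write_nifti_volume(field$disp, field$affine, path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  v <- read_nifti_volume(path)
  displacement_field(v$data, v$affine)
}

#' Write a rendered phantom subject to a directory
#'
#' Emits `dwi.nii.gz` + `dwi.bval`/`dwi.bvec`, `mask.nii.gz`, and
#' ground-truth maps (`truth_iso`, `truth_ay`, `truth_ao`, `truth_t`,
#' `truth_labels`).
#'
#' @param dwi a `phantom_dwi` (see [render_phantom()]).
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(dwi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dwi(dwi$signal, dwi$scheme, dwi$affine, file.path(dir, "dwi"))
  write_nifti_volume(dwi$mask * 1, dwi$affine, file.path(dir, "mask.nii.gz"))
  tr <- dwi$truth
  write_nifti_volume(tr$iso, dwi$affine, file.path(dir, "truth_iso.nii.gz"))
  write_nifti_volume(tr$a_young, dwi$affine,
                     file.path(dir, "truth_ay.nii.gz"))
  write_nifti_volume(tr$a_old, dwi$affine, file.path(dir, "truth_ao.nii.gz"))
  write_nifti_volume(tr$t, dwi$affine, file.path(dir, "truth_t.nii.gz"))
  write_nifti_volume(tr$labels, dwi$affine,
                     file.path(dir, "truth_labels.nii.gz"))
  invisible(dir)
}
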