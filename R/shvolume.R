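#' SH coefficient volume
#'
#' A 3-D voxel grid carrying one even real SH coefficient vector per voxel
#' (one tissue component's ODF field, or any SH-valued image). Data are
#' stored as a 4-D array `nx x ny x nz x n_coeffs`, with coefficients in the
#' package's frozen ordering (see [sh_basis()]). Geometry follows the NIfTI
#' convention: the `affine` maps 0-based voxel indices to world coordinates
#' in mm.
#'
#' @param data 4-D numeric array (a 3-D array is promoted to lmax = 0).
#' @param affine 4 x 4 voxel-to-world matrix; default scales by `voxel_size`.
#' @param voxel_size voxel edge length(s) in mm (used when `affine` missing).
#' @return object of class `sh_volume` with fields `data`, `affine`, `lmax`.
#' @export
sh_volume <- function(data, affine = NULL, voxel_size = 1.5) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  lmax <- lmax_from_n_coeffs(dim(data)[4L])
  if (is.null(affine)) {
    vs <- rep(voxel_size, length.out = 3L)
    affine <- diag(c(vs, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine not invertible")
  structure(list(data = data, affine = affine, lmax = lmax),
            class = "sh_volume")
}

#' @export
print.sh_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("sh_volume: ", paste(d[1:3], collapse = " x "),
      " voxels, lmax = ", x$lmax,
      " (", d[4L], " coefficients), voxel size ",
      paste(signif(voxel_size(x), 3), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Grid shape / voxel size of an sh_volume
#' @param x an `sh_volume`.
#' @return integer 3-vector (grid) or numeric 3-vector (mm).
#' @export
grid_shape <- function(x) dim(x$data)[1:3]

#' @rdname grid_shape
#' @export
voxel_size <- function(x) sqrt(colSums(x$affine[1:3, 1:3]^2))

#' Per-voxel DC (mean) amplitude of an SH volume
#'
#' The mean amplitude over the sphere equals `c00 / sqrt(4*pi)`; the density
#' (integral over the sphere) equals `c00 * sqrt(4*pi)`. The multi-tissue
#' normalisation target of a summed mean amplitude of `1/(4*pi)` is
#' equivalent to unit summed density.
#'
#' @param x an `sh_volume`.
#' @param what `"mean"` (default) or `"density"`.
#' @return 3-D array over the grid.
#' @export
dc_amplitude <- function(x, what = c("mean", "density")) {
  what <- match.arg(what)
  f <- if (what == "mean") 1 / sqrt(4 * pi) else sqrt(4 * pi)
  x$data[, , , 1L] * f
}

# truncate (or zero-pad) an sh_volume to a new lmax
sh_truncate <- function(x, lmax) {
  n_new <- n_sh_coeffs(lmax)
  d <- dim(x$data)
  if (n_new == d[4L]) return(x)
  out <- array(0, c(d[1:3], n_new))
  n_copy <- min(n_new, d[4L])
  out[, , , seq_len(n_copy)] <- x$data[, , , seq_len(n_copy)]
  sh_volume(out, affine = x$affine)
}

#' Convert between 0-based voxel indices and world coordinates
#'
#' @param ijk numeric matrix `n x 3` of 0-based voxel indices.
#' @param xyz numeric matrix `n x 3` of world coordinates (mm).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return `n x 3` matrix in the other coordinate system.
#' @export
voxel_to_world <- function(ijk, affine) {
  sweep(ijk %*% t(affine[1:3, 1:3]), 2L, affine[1:3, 4L], "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(xyz, affine) {
  inv <- solve(affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4L], "+")
}

# all voxel centres of a grid as 0-based index matrix (n x 3), x fastest
grid_index_matrix <- function(shape) {
  as.matrix(expand.grid(i = seq_len(shape[1L]) - 1L,
                        j = seq_len(shape[2L]) - 1L,
                        k = seq_len(shape[3L]) - 1L))
}
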