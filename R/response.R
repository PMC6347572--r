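#' Zonal (axially symmetric) multi-shell response function
#'
#' A tissue response function is the rotationally symmetric per-shell signal
#' kernel of a canonically oriented (z-aligned) fibre population or isotropic
#' compartment. Only the m = 0 ("zonal") even-degree SH coefficients are
#' non-zero; they are stored as a `n_shells x (lmax/2 + 1)` matrix, one row
#' per shell in ascending b, columns for degrees `l = 0, 2, ..., lmax`.
#'
#' @param coeffs numeric matrix (or vector for a single shell) of zonal
#'   coefficients.
#' @param shell_bvalues numeric vector of representative shell b-values.
#' @return object of class `zonal_response` with fields `coeffs`,
#'   `shell_bvalues`, `lmax`.
#' @export
zonal_response <- function(coeffs, shell_bvalues) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 1L)
  coeffs <- as.matrix(coeffs)
  storage.mode(coeffs) <- "double"
  if (nrow(coeffs) != length(shell_bvalues))
    stop("row count (", nrow(coeffs), ") must equal number of shells (",
         length(shell_bvalues), ")")
  lmax <- 2L * (ncol(coeffs) - 1L)
  structure(list(coeffs = coeffs, shell_bvalues = as.numeric(shell_bvalues),
                 lmax = lmax),
            class = "zonal_response")
}

#' @export
print.zonal_response <- function(x, ...) {
  cat("zonal_response: ", nrow(x$coeffs), " shells (b = ",
      paste(round(x$shell_bvalues), collapse = "/"),
      "), lmax = ", x$lmax, "\n", sep = "")
  invisible(x)
}

# match response shells to scheme shells (within scheme$shell_tol);
# returns per-scheme-shell row index into response$coeffs
match_shells <- function(response, scheme) {
  tol <- if (!is.null(scheme$shell_tol)) scheme$shell_tol else 50
  idx <- vapply(scheme$shell_bvalues, function(b) {
    hit <- which(abs(response$shell_bvalues - b) <= tol)
    if (length(hit) != 1L)
      stop("response shells (b = ",
           paste(round(response$shell_bvalues), collapse = "/"),
           ") do not cover scheme shell b = ", round(b))
    hit
  }, 0L)
  idx
}

#' Forward convolution matrix of a zonal response
#'
#' Builds the linear map from ODF SH coefficients to the predicted signal in
#' every volume of a gradient scheme, using the spherical convolution
#' theorem: the signal coefficient of degree l is the ODF coefficient
#' multiplied by `sqrt(4*pi / (2l + 1))` times the kernel's zonal coefficient
#' at that degree and the volume's shell. Degrees above the response's lmax
#' act as a zero kernel.
#'
#' @param response a [zonal_response()].
#' @param scheme a [gradient_scheme()]; every scheme shell must match a
#'   response shell.
#' @param lmax even degree of the ODF representation.
#' @return matrix `n_volumes x n_sh_coeffs(lmax)`.
#' @export
zonal_forward_matrix <- function(response, scheme, lmax) {
  stopifnot(lmax >= 0, lmax %% 2 == 0)
  rows <- match_shells(response, scheme)
  B <- sh_basis(scheme$directions, lmax)
  idx <- sh_degrees(lmax)
  fac <- matrix(0, n_volumes(scheme), length(idx$l))
  for (j in seq_along(idx$l)) {
    l <- idx$l[j]
    if (l <= response$lmax) {
      rl <- response$coeffs[rows[scheme$shell_index], l / 2 + 1L]
      fac[, j] <- sqrt(4 * pi / (2 * l + 1)) * rl
    }
  }
  B * fac
}

#' Full SH coefficients of a zonal kernel rotated onto an axis
#'
#' Uses the SH addition theorem: rotating the z-aligned zonal kernel onto
#' axis `n` yields coefficients `c_lm = r_l * sqrt(4*pi/(2l+1)) * Y_lm(n)`.
#' Rotation onto +z (or -z, by antipodal symmetry) returns the zonal
#' coefficients unchanged in the m = 0 slots.
#'
#' @param response a [zonal_response()].
#' @param axis unit 3-vector.
#' @param lmax even degree of the output (default: response lmax).
#' @return matrix `n_shells x n_sh_coeffs(lmax)` of full SH coefficients.
#' @export
rotate_zonal_to_axis <- function(response, axis, lmax = response$lmax) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("zero axis")
  axis <- axis / nrm
  Y <- drop(sh_basis(matrix(axis, 1L, 3L), lmax))
  idx <- sh_degrees(lmax)
  out <- matrix(0, nrow(response$coeffs), length(idx$l))
  for (j in seq_along(idx$l)) {
    l <- idx$l[j]
    if (l <= response$lmax)
      out[, j] <- response$coeffs[, l / 2 + 1L] * sqrt(4 * pi / (2 * l + 1)) * Y[j]
  }
  out
}

#' Project per-direction samples of an axially symmetric function onto the
#' zonal basis
#'
#' Least-squares fit of zonal (m = 0) coefficients to amplitudes sampled at
#' arbitrary directions, per shell. Used when estimating responses from
#' axis-aligned voxel signals.
#'
#' @param directions `n x 3` unit vectors (assumed already rotated so the
#'   symmetry axis is +z).
#' @param amplitudes numeric vector of length `n`.
#' @param lmax even degree.
#' @return numeric vector of `lmax/2 + 1` zonal coefficients.
#' @export
project_zonal <- function(directions, amplitudes, lmax) {
  B <- sh_basis(directions, lmax)
  idx <- sh_degrees(lmax)
  Bz <- B[, idx$m == 0L, drop = FALSE]
  qr.solve(Bz, amplitudes)
}

# zonal coefficients of an axially symmetric profile f(ctheta) by quadrature
zonal_project_function <- function(f, lmax, n_quad = 4096) {
  q <- sphere_quadrature(n_quad)
  amp <- f(q$directions[, 3L])
  B <- sh_basis(q$directions, lmax)
  idx <- sh_degrees(lmax)
  zon <- which(idx$m == 0L)
  as.numeric(crossprod(B[, zon, drop = FALSE], q$weights * amp))
}
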