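#' Number of coefficients of a real even spherical-harmonics series
#'
#' The package represents antipodally symmetric functions on the sphere
#' (ODFs, dMRI signal shells) in a real, even-degree, orthonormal
#' spherical-harmonics (SH) basis. Coefficients are ordered by ascending
#' even degree `l = 0, 2, ..., lmax`, and within each degree by order
#' `m = -l, ..., l`. This ordering is frozen across the package: on-disk
#' 4-D SH volumes store coefficients along the fourth dimension in exactly
#' this order.
#'
#' @param lmax even non-negative integer, maximum harmonic degree.
#' @return integer, `(lmax/2 + 1) * (lmax + 1)`.
#' @export
n_sh_coeffs <- function(lmax) {
  stopifnot(length(lmax) == 1L, lmax >= 0, lmax %% 2 == 0)
  as.integer((lmax / 2 + 1) * (lmax + 1))
}

#' Infer lmax from a coefficient count
#'
#' @param n integer coefficient count.
#' @return the even `lmax` with `n_sh_coeffs(lmax) == n`; errors if none.
#' @export
lmax_from_n_coeffs <- function(n) {
  l <- 0L
  while (n_sh_coeffs(l) < n) l <- l + 2L
  if (n_sh_coeffs(l) != n)
    stop("coefficient count ", n, " does not match any even lmax")
  l
}

# (l, m) index table for the frozen ordering
sh_degrees <- function(lmax) {
  l <- unlist(lapply(seq(0L, lmax, by = 2L), function(li) rep(li, 2L * li + 1L)))
  m <- unlist(lapply(seq(0L, lmax, by = 2L), function(li) seq(-li, li)))
  list(l = as.integer(l), m = as.integer(m))
}

# Fully normalised associated Legendre values P_lm(x) such that
# Y_lm(theta, phi) = P_lm(cos theta) * exp(i m phi) is orthonormal.
# Standard stable three-term recursion; Condon-Shortley phase folded into
# the sectoral seed. Returns a list indexed [[l+1]][[m+1]] of vectors.
normalised_legendre <- function(x, lmax) {
  s <- sqrt(pmax(0, 1 - x^2))
  P <- vector("list", lmax + 1L)
  for (l in 0:lmax) P[[l + 1L]] <- vector("list", l + 1L)
  P[[1L]][[1L]] <- rep(sqrt(1 / (4 * pi)), length(x))
  if (lmax >= 1L) {
    for (m in 1:lmax) {
      P[[m + 1L]][[m + 1L]] <- -sqrt((2 * m + 1) / (2 * m)) * s * P[[m]][[m]]
    }
    for (m in 0:(lmax - 1L)) {
      P[[m + 2L]][[m + 1L]] <- sqrt(2 * m + 3) * x * P[[m + 1L]][[m + 1L]]
    }
  }
  if (lmax >= 2L) {
    for (m in 0:(lmax - 2L)) {
      for (l in (m + 2L):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[[l + 1L]][[m + 1L]] <-
          a * (x * P[[l]][[m + 1L]] - b * P[[l - 1L]][[m + 1L]])
      }
    }
  }
  P
}

#' Evaluate the real even SH basis at a set of directions
#'
#' Returns the matrix `B` with `B[i, j] = Y_j(d_i)` for the package's frozen
#' real even orthonormal basis, so that `B %*% coeffs` evaluates an SH series
#' at the given directions.
#'
#' @param directions numeric matrix `n x 3` of unit vectors (a single vector
#'   is accepted and treated as one row).
#' @param lmax even non-negative integer.
#' @return numeric matrix `n_directions x n_sh_coeffs(lmax)`.
#' @export
sh_basis <- function(directions, lmax) {
  if (length(lmax) != 1L || lmax < 0 || lmax %% 2 != 0)
    stop("lmax must be a single even non-negative integer")
  directions <- as_direction_matrix(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm < 1e-12)) stop("zero-norm direction")
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit-norm (within 1e-6)")
  directions <- directions / nrm
  z <- pmin(1, pmax(-1, directions[, 3L]))
  phi <- atan2(directions[, 2L], directions[, 1L])
  P <- normalised_legendre(z, lmax)
  idx <- sh_degrees(lmax)
  B <- matrix(0, nrow(directions), length(idx$l))
  for (j in seq_along(idx$l)) {
    l <- idx$l[j]; m <- idx$m[j]
    if (m == 0L) {
      B[, j] <- P[[l + 1L]][[1L]]
    } else if (m > 0L) {
      B[, j] <- sqrt(2) * P[[l + 1L]][[m + 1L]] * cos(m * phi)
    } else {
      B[, j] <- sqrt(2) * P[[l + 1L]][[-m + 1L]] * sin(-m * phi)
    }
  }
  B
}

as_direction_matrix <- function(directions) {
  if (is.null(dim(directions))) {
    stopifnot(length(directions) == 3L)
    directions <- matrix(directions, 1L, 3L)
  }
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3L)
  storage.mode(directions) <- "double"
  dimnames(directions) <- NULL
  directions
}

#' Evaluate an SH series at directions
#'
#' @param coeffs numeric vector of length `n_sh_coeffs(lmax)` for some even
#'   `lmax`, or a matrix with that many rows (one column per series).
#' @param directions unit direction matrix `n x 3`.
#' @return amplitude vector of length `n` (or `n x k` matrix).
#' @export
eval_sh <- function(coeffs, directions) {
  cm <- if (is.null(dim(coeffs))) matrix(coeffs, ncol = 1L) else as.matrix(coeffs)
  lmax <- lmax_from_n_coeffs(nrow(cm))
  out <- sh_basis(directions, lmax) %*% cm
  if (is.null(dim(coeffs))) drop(out) else out
}

#' SH coefficients of a symmetric unit-integral delta function
#'
#' Truncated-series coefficients of an antipodally symmetric delta pair
#' with total integral 1 over the sphere, used to build fibre ODFs and to
#' decompose ODFs onto direction sets (apodised-delta reorientation).
#'
#' @param direction unit 3-vector (or `n x 3` matrix: one column per delta).
#' @param lmax even degree of the truncation.
#' @return coefficient vector (or `n_coeffs x n` matrix).
#' @export
delta_sh <- function(direction, lmax) {
  t(sh_basis(direction, lmax))
}

#' Near-uniform deterministic sphere sampling (Fibonacci spiral)
#'
#' @param n number of points.
#' @param hemisphere if TRUE, points are folded to the z >= 0 hemisphere
#'   (sufficient for antipodally symmetric functions).
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n, hemisphere = FALSE) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(s * cos(phi), s * sin(phi), z)
  if (hemisphere) {
    flip <- d[, 3L] < 0
    d[flip, ] <- -d[flip, ]
  }
  d
}

#' Equal-weight spherical quadrature on a Fibonacci sampling
#'
#' @param n number of nodes (default 4096).
#' @return list with `directions` (`n x 3`) and `weights` (summing to 4*pi).
#' @export
sphere_quadrature <- function(n = 4096) {
  list(directions = fibonacci_sphere(n), weights = rep(4 * pi / n, n))
}

# Rotation matrix taking unit vector `from` onto unit vector `to`
# (Rodrigues; stable at the antipodal limit).
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (c_ < -1 + 1e-12) {
    # pick any axis orthogonal to `from`
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * from) * from
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}
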