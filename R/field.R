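#' Dense displacement field
#'
#' Voxel-wise 3-D displacement in world millimetres, defined on a reference
#' grid with a NIfTI-style voxel-to-world `affine` (0-based indices). The
#' field represents the pull-back mapping `phi(x) = x + u(x)` (world mm): an
#' image resampled through the field takes its value at `phi(x)`. Fields
#' constructed by the registration and phantom modules carry a paired
#' numerical `inverse`.
#'
#' @param disp 4-D array `nx x ny x nz x 3` of displacements (mm).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param inverse optional 4-D array of the inverse displacement.
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(disp, affine, inverse = NULL) {
  stopifnot(length(dim(disp)) == 4L, dim(disp)[4L] == 3L)
  structure(list(disp = disp, affine = as.matrix(affine), inverse = inverse),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$disp)
  mags <- sqrt(apply(x$disp^2, c(1, 2, 3), sum))
  cat("displacement_field: ", paste(d[1:3], collapse = " x "),
      " grid, |u| mean ", signif(mean(mags), 3), " mm, max ",
      signif(max(mags), 3), " mm",
      if (!is.null(x$inverse)) ", with inverse", "\n", sep = "")
  invisible(x)
}

#' Identity displacement field on a grid
#' @param shape integer 3-vector.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return a `displacement_field` of zeros (own inverse).
#' @export
identity_field <- function(shape, affine) {
  z <- array(0, c(shape, 3L))
  displacement_field(z, affine, inverse = z)
}

# --- trilinear interpolation ------------------------------------------------

# arr: array (nx, ny, nz) or (nx, ny, nz, nc); coords: n x 3 matrix of
# 0-based voxel coordinates. Values outside the grid decay to `outside`
# (zero-padding) unless mode = "clamp".
interp_trilinear <- function(arr, coords, outside = 0, mode = c("zero", "clamp")) {
  mode <- match.arg(mode)
  d <- dim(arr)
  if (length(d) == 3L) { dim(arr) <- c(d, 1L); d <- dim(arr) }
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]; nc <- d[4L]
  dim(arr) <- c(nx * ny * nz, nc)
  x <- coords[, 1L]; y <- coords[, 2L]; z <- coords[, 3L]
  if (mode == "clamp") {
    x <- pmin(pmax(x, 0), nx - 1); y <- pmin(pmax(y, 0), ny - 1)
    z <- pmin(pmax(z, 0), nz - 1)
  }
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  out <- matrix(0, length(x), nc)
  wtot <- numeric(length(x))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- i0 + di; jj <- j0 + dj; kk <- k0 + dk
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
         (if (dk) fz else 1 - fz)
    inside <- ii >= 0 & ii < nx & jj >= 0 & jj < ny & kk >= 0 & kk < nz
    w[!inside] <- 0
    lin <- 1 + pmin(pmax(ii, 0), nx - 1) +
           nx * (pmin(pmax(jj, 0), ny - 1) + ny * pmin(pmax(kk, 0), nz - 1))
    out <- out + w * arr[lin, , drop = FALSE]
    wtot <- wtot + w
  }
  if (outside != 0) out <- out + (1 - wtot) * outside
  out
}

# nearest-neighbour lookup, clamped at the boundary
interp_nearest <- function(arr, coords) {
  d <- dim(arr)
  if (length(d) == 3L) { dim(arr) <- c(d, 1L); d <- dim(arr) }
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  dim(arr) <- c(nx * ny * nz, d[4L])
  ii <- pmin(pmax(round(coords[, 1L]), 0), nx - 1)
  jj <- pmin(pmax(round(coords[, 2L]), 0), ny - 1)
  kk <- pmin(pmax(round(coords[, 3L]), 0), nz - 1)
  arr[1 + ii + nx * (jj + ny * kk), , drop = FALSE]
}

# --- field algebra ----------------------------------------------------------

# world coordinates of all grid voxel centres (n x 3)
field_world_grid <- function(field) {
  voxel_to_world(grid_index_matrix(dim(field$disp)[1:3]), field$affine)
}

# apply phi(x) = x + u(x) to world points (n x 3); u interpolated trilinearly
apply_field <- function(field, xyz) {
  vox <- world_to_voxel(xyz, field$affine)
  xyz + interp_trilinear(field$disp, vox, mode = "clamp")
}

#' Compose two displacement fields
#'
#' Returns the field of `phi_a(phi_b(x))`: first `b`, then `a` — matching
#' pull-back resampling order (resampling through the composite equals
#' resampling through `a` then through `b`).
#'
#' @param a,b `displacement_field`s on the same grid.
#' @return a `displacement_field` (inverse composed when both carry one).
#' @export
compose_fields <- function(a, b) {
  shape <- dim(b$disp)[1:3]
  xyz <- field_world_grid(b)
  ub <- matrix(b$disp, prod(shape), 3L)
  ua_at <- interp_trilinear(a$disp, world_to_voxel(xyz + ub, a$affine),
                            mode = "clamp")
  comp <- array(ub + ua_at, c(shape, 3L))
  inv <- NULL
  if (!is.null(a$inverse) && !is.null(b$inverse)) {
    uainv <- matrix(a$inverse, prod(shape), 3L)
    ubinv_at <- interp_trilinear(b$inverse,
                                 world_to_voxel(xyz + uainv, b$affine),
                                 mode = "clamp")
    inv <- array(uainv + ubinv_at, c(shape, 3L))
  }
  displacement_field(comp, b$affine, inverse = inv)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration `v_{n+1}(x) = -u(x + v_n(x))`, adequate for the
#' smooth, small-magnitude fields produced by the registration and phantom
#' modules.
#'
#' @param field a `displacement_field`.
#' @param iterations fixed-point iteration count.
#' @return a `displacement_field` whose `disp` is the inverse (its own
#'   `inverse` slot holds the original field).
#' @export
invert_field <- function(field, iterations = 20L) {
  shape <- dim(field$disp)[1:3]
  xyz <- field_world_grid(field)
  v <- matrix(0, prod(shape), 3L)
  for (it in seq_len(iterations)) {
    v <- -interp_trilinear(field$disp,
                           world_to_voxel(xyz + v, field$affine),
                           mode = "clamp")
  }
  displacement_field(array(v, c(shape, 3L)), field$affine,
                     inverse = field$disp)
}

# separable Gaussian smoothing of a (..., nc) array along the 3 spatial dims;
# sigma in voxels (scalar or 3-vector); boundary handled by kernel
# renormalisation
smooth_array_gaussian <- function(arr, sigma) {
  d <- dim(arr)
  if (length(d) == 3L) { dim(arr) <- c(d, 1L); d <- dim(arr) }
  sigma <- rep(sigma, length.out = 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 1e-8) next
    n <- d[ax]
    r <- max(1L, ceiling(3 * s))
    off <- -r:r
    g <- exp(-off^2 / (2 * s^2))
    K <- matrix(0, n, n)
    for (t in seq_along(off)) {
      src <- seq_len(n) + off[t]
      ok <- src >= 1 & src <= n
      K[cbind(which(ok), src[ok])] <- K[cbind(which(ok), src[ok])] + g[t]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    dp <- dim(a)
    dim(a) <- c(dp[1L], prod(dp[-1L]))
    a <- K %*% a
    dim(a) <- dp
    arr <- aperm(a, order(perm))
  }
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L && length(d) == 3L)
    dim(arr) <- d[1:3]
  arr
}

#' Smooth a displacement field with a Gaussian kernel
#' @param field a `displacement_field`.
#' @param sigma_vox standard deviation in voxels.
#' @return smoothed `displacement_field` (inverse dropped: re-derive if
#'   needed).
#' @export
smooth_field <- function(field, sigma_vox) {
  displacement_field(smooth_array_gaussian(field$disp, sigma_vox),
                     field$affine)
}

#' Random smooth diffeomorphic field
#'
#' Draws Gaussian noise per component, smooths it, scales the result to a
#' target peak magnitude, and exponentiates it as a stationary velocity
#' field (scaling-and-squaring), which guarantees invertibility; the exact
#' inverse (exponential of the negated velocity) is attached.
#'
#' @param shape grid shape (3 integers).
#' @param affine voxel-to-world matrix.
#' @param amplitude_mm peak displacement magnitude (mm); 0 gives identity.
#' @param sigma_vox smoothing of the velocity noise, in voxels.
#' @param seed integer seed (local RNG; does not disturb the global stream).
#' @return a `displacement_field` with inverse.
#' @export
random_smooth_field <- function(shape, affine, amplitude_mm, sigma_vox = 3,
                                seed = 1L) {
  if (amplitude_mm <= 0) return(identity_field(shape, affine))
  v <- with_local_seed(seed, array(stats::rnorm(prod(shape) * 3L), c(shape, 3L)))
  v <- smooth_array_gaussian(v, sigma_vox)
  mag <- sqrt(apply(v^2, c(1, 2, 3), sum))
  v <- v * (amplitude_mm / max(mag))
  exp_velocity_field(v, affine)
}

# scaling-and-squaring exponential of a stationary velocity (mm) array
exp_velocity_field <- function(v, affine, n_squarings = 6L) {
  fwd <- displacement_field(v / 2^n_squarings, affine)
  bwd <- displacement_field(-v / 2^n_squarings, affine)
  for (s in seq_len(n_squarings)) {
    fwd <- compose_fields(fwd, fwd)
    bwd <- compose_fields(bwd, bwd)
  }
  displacement_field(fwd$disp, affine, inverse = bwd$disp)
}

#' Mean inverse-consistency error of a field pair
#'
#' Mean over (optionally masked) voxels of `|phi(phi^{-1}(x)) - x|`,
#' in voxel units.
#'
#' @param field a `displacement_field` carrying an inverse.
#' @param mask optional logical 3-D array.
#' @return scalar mean error (voxels).
#' @export
inverse_consistency_error <- function(field, mask = NULL) {
  if (is.null(field$inverse)) stop("field carries no inverse")
  shape <- dim(field$disp)[1:3]
  xyz <- field_world_grid(field)
  ui <- matrix(field$inverse, prod(shape), 3L)
  uf <- interp_trilinear(field$disp,
                         world_to_voxel(xyz + ui, field$affine),
                         mode = "clamp")
  err <- sqrt(rowSums((ui + uf)^2))
  vs <- mean(sqrt(colSums(field$affine[1:3, 1:3]^2)))
  if (!is.null(mask)) err <- err[as.logical(mask)]
  mean(err) / vs
}

# local Jacobian d(phi)/dx of phi(x) = x + u(x) by central differences;
# returns array (nx, ny, nz, 3, 3) in world coordinates
field_jacobian <- function(field) {
  d <- dim(field$disp)[1:3]
  vs <- sqrt(colSums(field$affine[1:3, 1:3]^2))
  J <- array(0, c(d, 3L, 3L))
  for (comp in 1:3) {
    u <- field$disp[, , , comp]
    for (ax in 1:3) {
      n <- d[ax]
      ip <- pmin(seq_len(n) + 1L, n)
      im <- pmax(seq_len(n) - 1L, 1L)
      denom <- (ip - im) * vs[ax]
      if (ax == 1L) {
        du <- (u[ip, , , drop = FALSE] - u[im, , , drop = FALSE]) /
          array(denom, d)
      } else if (ax == 2L) {
        du <- (u[, ip, , drop = FALSE] - u[, im, , drop = FALSE]) /
          array(rep(denom, each = d[1L]), d)
      } else {
        du <- (u[, , ip, drop = FALSE] - u[, , im, drop = FALSE]) /
          array(rep(denom, each = d[1L] * d[2L]), d)
      }
      J[, , , comp, ax] <- du + (comp == ax)
    }
  }
  J
}

# run expr with a local, restored RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
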