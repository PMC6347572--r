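#' Registration stage description
#'
#' One stage of the multi-resolution schedule: transform model, working
#' voxel size, SH degree, and the update/displacement smoothing kernels
#' expressed as multiples of the stage voxel size (defaults 2.0 and 1.0).
#'
#' @param transform `"rigid"`, `"affine"` or `"nonlinear"`.
#' @param voxel_size_mm working resolution of the stage.
#' @param lmax SH degree used for the cost at this stage.
#' @param sigma_update,sigma_disp Gaussian smoothing of the update and of
#'   the accumulated displacement field, in multiples of `voxel_size_mm`.
#' @param max_iter iteration cap for this stage.
#' @return object of class `registration_stage`.
#' @export
registration_stage <- function(transform = c("rigid", "affine", "nonlinear"),
                               voxel_size_mm = 1.5, lmax = 2L,
                               sigma_update = 2.0, sigma_disp = 1.0,
                               max_iter = 30L) {
  transform <- match.arg(transform)
  structure(list(transform = transform, voxel_size_mm = voxel_size_mm,
                 lmax = as.integer(lmax), sigma_update = sigma_update,
                 sigma_disp = sigma_disp, max_iter = as.integer(max_iter)),
            class = "registration_stage")
}

#' @export
print.registration_stage <- function(x, ...) {
  cat(sprintf("stage: %-9s %.2f mm, lmax %d, sigma %.1f/%.1f, <= %d iter\n",
              x$transform, x$voxel_size_mm, x$lmax, x$sigma_update,
              x$sigma_disp, x$max_iter))
  invisible(x)
}

# --- resampling -------------------------------------------------------------

#' Resample an SH volume to a new voxel size
#'
#' Per-coefficient trilinear interpolation onto a grid covering the same
#' field of view (voxel-centre aligned at the first corner).
#'
#' @param x an [sh_volume()].
#' @param voxel_size_mm target isotropic voxel size.
#' @return an [sh_volume()].
#' @export
resample_sh_volume <- function(x, voxel_size_mm) {
  vs_old <- voxel_size(x)
  gs_old <- grid_shape(x)
  if (max(abs(vs_old - voxel_size_mm)) < 1e-9) return(x)
  gs_new <- pmax(2L, as.integer(round(gs_old * vs_old / voxel_size_mm)))
  aff <- x$affine
  scl <- voxel_size_mm / vs_old
  aff_new <- aff
  aff_new[1:3, 1:3] <- aff[1:3, 1:3] %*% diag(scl)
  # keep voxel-centre of index 0 aligned between grids
  aff_new[1:3, 4L] <- aff[1:3, 4L] +
    aff[1:3, 1:3] %*% ((scl - 1) / 2)
  idx <- grid_index_matrix(gs_new)
  src <- world_to_voxel(voxel_to_world(idx, aff_new), aff)
  vals <- interp_trilinear(x$data, src)
  sh_volume(array(vals, c(gs_new, ncol(vals))), affine = aff_new)
}

# prepare one channel list for a stage: resample + truncate lmax
stage_channels <- function(channels, stage) {
  lapply(channels, function(ch)
    sh_truncate(resample_sh_volume(ch, stage$voxel_size_mm),
                min(ch$lmax, stage$lmax)))
}

# pull back a plain (nx,ny,nz,nc) array through a displacement field
warp_array <- function(arr, field) {
  gs <- dim(arr)[1:3]
  xyz <- field_world_grid(field)
  src <- world_to_voxel(xyz + matrix(field$disp, prod(gs), 3L),
                        field$affine)
  array(interp_trilinear(arr, src), dim(arr))
}

# --- reorientation ----------------------------------------------------------

# SH-space reorientation operator for a constant 3x3 linear map, via
# apodized-delta decomposition on a fixed direction set
sh_reorient_matrix <- function(A, lmax, n_dirs = 300L) {
  g <- reorient_basis(lmax, n_dirs)
  d_new <- t(A %*% t(g$dirs))
  d_new <- d_new / sqrt(rowSums(d_new^2))
  t(sh_basis(d_new, lmax)) %*% g$W
}

# cached direction set and min-norm delta-weight operator W (n_dirs x nc)
reorient_basis <- local({
  cache <- list()
  function(lmax, n_dirs = 300L) {
    key <- paste(lmax, n_dirs)
    if (!is.null(cache[[key]])) return(cache[[key]])
    dirs <- fibonacci_sphere(n_dirs, hemisphere = TRUE)
    B <- sh_basis(dirs, lmax)
    out <- list(dirs = dirs, B = B,
                W = B %*% solve(crossprod(B) + diag(1e-10, ncol(B))))
    cache[[key]] <<- out
    out
  }
})

#' Warp an SH volume through a displacement field with ODF reorientation
#'
#' Coefficients are pulled back by per-coefficient trilinear interpolation
#' at `x + u(x)`; each voxel's ODF is then reoriented by the local Jacobian
#' of the mapping using apodized-delta reorientation (decompose onto a
#' fixed direction set, push the directions through the inverse Jacobian,
#' recompose). Voxels with a singular local Jacobian keep their
#' unreoriented value and are flagged.
#'
#' @param shvol an [sh_volume()].
#' @param field a [displacement_field()] on the same grid.
#' @param reorient apply reorientation (default TRUE).
#' @param n_dirs direction-set size for the reorientation.
#' @return an [sh_volume()]; attribute `flagged` counts singular voxels.
#' @export
reorient <- function(shvol, field, reorient = TRUE, n_dirs = 300L) {
  gs <- grid_shape(shvol)
  stopifnot(all(dim(field$disp)[1:3] == gs))
  xyz <- field_world_grid(field)
  src <- world_to_voxel(xyz + matrix(field$disp, prod(gs), 3L),
                        shvol$affine)
  vals <- interp_trilinear(shvol$data, src)
  lmax <- shvol$lmax
  flagged <- 0L
  if (reorient && lmax > 0L) {
    J <- matrix(field_jacobian(field), prod(gs), 9L)
    g <- reorient_basis(lmax, n_dirs)
    # only voxels with non-trivial ODF and non-identity Jacobian
    ident <- rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = nrow(J))
    dim(ident) <- dim(J)
    nontriv <- which(rowSums(vals[, -1L, drop = FALSE]^2) > 1e-16 &
                     rowSums((J - ident)^2) > 1e-12)
    for (v in nontriv) {
      Jv <- matrix(J[v, ], 3L, 3L)
      dt <- det(Jv)
      if (!is.finite(dt) || abs(dt) < 1e-8) { flagged <- flagged + 1L; next }
      dnew <- t(solve(Jv, t(g$dirs)))
      dnew <- dnew / sqrt(rowSums(dnew^2))
      w <- g$W %*% vals[v, ]
      vals[v, ] <- crossprod(sh_basis(dnew, lmax), w)
    }
  }
  out <- sh_volume(array(vals, c(gs, ncol(vals))), affine = field$affine)
  attr(out, "flagged") <- flagged
  out
}

# --- affine transforms ------------------------------------------------------

# parameter vector -> 4x4 affine (world mm), rotation about `centre`
# params: tx ty tz rx ry rz [sx sy sz kxy kxz kyz]
params_to_affine <- function(p, centre = c(0, 0, 0)) {
  rot1 <- function(a, ax) {
    c_ <- cos(a); s_ <- sin(a)
    if (ax == 1L) matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
    else if (ax == 2L) matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
    else matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  }
  R <- rot1(p[4L], 1L) %*% rot1(p[5L], 2L) %*% rot1(p[6L], 3L)
  L <- R
  if (length(p) >= 12L) {
    S <- diag(exp(p[7:9]))
    K <- diag(3); K[1, 2] <- p[10L]; K[1, 3] <- p[11L]; K[2, 3] <- p[12L]
    L <- R %*% S %*% K
  }
  A <- diag(4)
  A[1:3, 1:3] <- L
  A[1:3, 4L] <- p[1:3] + centre - L %*% centre
  A
}

# half (matrix square root) of an affine: H %*% H == A
affine_half <- function(A) {
  L <- A[1:3, 1:3]
  Lh <- Re(pracma::sqrtm(L)$B)
  H <- diag(4)
  H[1:3, 1:3] <- Lh
  H[1:3, 4L] <- solve(diag(3) + Lh, A[1:3, 4L])
  H
}

affine_inverse <- function(A) solve(A)

# displacement field of an affine map phi(x) = A x (pull-back), on a grid
affine_to_field <- function(A, shape, affine_vox2world) {
  xyz <- voxel_to_world(grid_index_matrix(shape), affine_vox2world)
  new <- sweep(xyz %*% t(A[1:3, 1:3]), 2L, A[1:3, 4L], "+")
  displacement_field(array(new - xyz, c(shape, 3L)), affine_vox2world)
}

#' Resample SH channels through an affine map
#'
#' Pull-back convention: `output(x) = input(A x)`. ODF channels are
#' reoriented with the (constant) Jacobian via a single precomputed
#' SH-space operator.
#'
#' @param channels list of [sh_volume()]s.
#' @param A 4 x 4 affine (world mm).
#' @param reorient_odf reorient anisotropic channels (default TRUE).
#' @return list of [sh_volume()]s on the input grids.
#' @export
warp_channels_affine <- function(channels, A, reorient_odf = TRUE) {
  lapply(channels, function(ch) {
    gs <- grid_shape(ch)
    xyz <- voxel_to_world(grid_index_matrix(gs), ch$affine)
    src_w <- sweep(xyz %*% t(A[1:3, 1:3]), 2L, A[1:3, 4L], "+")
    vals <- interp_trilinear(ch$data, world_to_voxel(src_w, ch$affine))
    if (reorient_odf && ch$lmax > 0L &&
        max(abs(A[1:3, 1:3] - diag(3))) > 1e-12) {
      M <- sh_reorient_matrix(solve(A[1:3, 1:3]), ch$lmax)
      vals <- vals %*% t(M)
    }
    sh_volume(array(vals, c(gs, ncol(vals))), affine = ch$affine)
  })
}

# --- multi-contrast cost ----------------------------------------------------

#' Multi-contrast SSD cost between two channel sets
#'
#' Warps both channel sets to the midway space (half-transforms), reorients
#' them, and returns the weighted average over channels of the sum of
#' squared SH-coefficient differences.
#'
#' @param moving,fixed lists of [sh_volume()] channels on a common grid.
#' @param weights per-channel nonnegative weights (default equal).
#' @param field_pair list with `moving` and `fixed`
#'   [displacement_field()]s (half-warps toward midway), or `NULL` for
#'   identity; alternatively `affine_pair` with 4x4 matrices.
#' @param affine_pair optional list of 4x4 half-affines (`moving`, `fixed`).
#' @param reorient_odf apply reorientation (default TRUE).
#' @return scalar cost.
#' @export
mc_cost <- function(moving, fixed, weights = NULL, field_pair = NULL,
                    affine_pair = NULL, reorient_odf = TRUE) {
  stopifnot(length(moving) == length(fixed))
  if (is.null(weights)) weights <- rep(1, length(moving))
  stopifnot(all(weights >= 0), sum(weights) > 0)
  for (i in seq_along(moving))
    if (!all(grid_shape(moving[[i]]) == grid_shape(fixed[[i]])))
      stop("channel grid mismatch")
  wm <- moving; wf <- fixed
  if (!is.null(affine_pair)) {
    wm <- warp_channels_affine(moving, affine_pair$moving, reorient_odf)
    wf <- warp_channels_affine(fixed, affine_pair$fixed, reorient_odf)
  } else if (!is.null(field_pair)) {
    wm <- lapply(moving, reorient, field = field_pair$moving,
                 reorient = reorient_odf)
    wf <- lapply(fixed, reorient, field = field_pair$fixed,
                 reorient = reorient_odf)
  }
  w <- weights / sum(weights)
  cost <- 0
  for (i in seq_along(wm))
    cost <- cost + w[i] * sum((wm[[i]]$data - wf[[i]]$data)^2)
  cost
}

# --- rigid / affine registration -------------------------------------------

#' Rigid then affine multi-contrast registration
#'
#' Gradient-free (Nelder-Mead) optimisation of [mc_cost()] over rigid, then
#' affine parameters, following the stage list's resolutions and degrees.
#' Both images are moved symmetrically (half-transform each) and the cost
#' is evaluated in the midway space. Divergence (no improvement) returns
#' the best parameters found.
#'
#' @param moving,fixed channel lists ([sh_volume()]s on a common grid).
#' @param stages list of [registration_stage()]s (rigid and/or affine).
#' @param weights per-channel weights.
#' @param reorient_odf reorient ODFs in the cost (default TRUE).
#' @return list of class `affine_registration`: `affine` (4x4 matrix
#'   mapping fixed-space points to moving-space, pull-back convention),
#'   `params`, `cost`.
#' @export
register_rigid_affine <- function(moving, fixed, stages = NULL,
                                  weights = NULL, reorient_odf = TRUE) {
  if (is.null(stages))
    stages <- list(registration_stage("rigid", 3.0, 2L),
                   registration_stage("rigid", 1.5, 2L),
                   registration_stage("affine", 1.5, 2L))
  gs <- grid_shape(moving[[1L]])
  centre <- drop(voxel_to_world(matrix((gs - 1) / 2, 1L, 3L),
                                moving[[1L]]$affine))
  p <- rep(0, 6L)
  best_cost <- Inf
  for (st in stages) {
    mv <- stage_channels(moving, st)
    fx <- stage_channels(fixed, st)
    n_par <- if (st$transform == "rigid") 6L else 12L
    if (length(p) < n_par) p <- c(p, rep(0, 6L))  # extend rigid -> affine
    scale <- c(rep(st$voxel_size_mm, 3L), rep(0.1, 3L),
               if (n_par == 12L) rep(0.05, 6L))
    fn <- function(q) {
      A <- params_to_affine(q * scale, centre)
      H <- affine_half(A)
      mc_cost(mv, fx, weights,
              affine_pair = list(moving = H, fixed = solve(H)),
              reorient_odf = reorient_odf)
    }
    opt <- stats::optim(p / scale, fn, method = "Nelder-Mead",
                        control = list(maxit = 60L * n_par,
                                       reltol = 1e-10))
    # quasi-Newton polish with finite-difference gradients
    opt2 <- try(stats::optim(opt$par, fn, method = "BFGS",
                             control = list(maxit = 50L, reltol = 1e-12)),
                silent = TRUE)
    if (!inherits(opt2, "try-error") && opt2$value <= opt$value) opt <- opt2
    p <- opt$par * scale
    best_cost <- opt$value
  }
  structure(list(affine = params_to_affine(p, centre), params = p,
                 centre = centre, cost = best_cost),
            class = "affine_registration")
}

#' @export
print.affine_registration <- function(x, ...) {
  cat("affine_registration: |t| =",
      signif(sqrt(sum(x$params[1:3]^2)), 3), "mm, cost",
      signif(x$cost, 4), "\n")
  invisible(x)
}

# --- nonlinear (symmetric demons-like) registration -------------------------

# spatial gradient of a (nx,ny,nz,nc) array, central differences, per mm
array_gradient <- function(arr, voxel_size) {
  d <- dim(arr)
  out <- array(0, c(d, 3L))
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * voxel_size[ax]
    if (ax == 1L)
      g <- (arr[ip, , , , drop = FALSE] - arr[im, , , , drop = FALSE]) /
        array(denom, d)
    else if (ax == 2L)
      g <- (arr[, ip, , , drop = FALSE] - arr[, im, , , drop = FALSE]) /
        array(rep(denom, each = d[1L]), d)
    else
      g <- (arr[, , ip, , drop = FALSE] - arr[, , im, , drop = FALSE]) /
        array(rep(denom, each = d[1L] * d[2L]), d)
    out[, , , , ax] <- g
  }
  out
}

#' Symmetric diffeomorphic multi-contrast registration
#'
#' Demons-like symmetric scheme: both images carry a half-warp toward the
#' midway space; each iteration computes the multi-channel SSD force,
#' smooths the update (`sigma_update`), applies it with an adaptive step
#' (halved on cost increase — accepted iterations never increase the cost),
#' and smooths the accumulated displacement (`sigma_disp`). The derivative
#' of the reorientation term is ignored in the force (standard
#' approximation); reorientation is applied when evaluating the cost at
#' stage ends. Warps are upsampled trilinearly between stages.
#'
#' @param moving,fixed channel lists on a common grid.
#' @param stages list of nonlinear [registration_stage()]s.
#' @param init optional `affine_registration` (or 4x4 matrix) initialising
#'   the correspondence.
#' @param weights per-channel weights.
#' @param verbose print per-stage cost.
#' @return list of class `nonlinear_registration`: `forward` (a
#'   [displacement_field()] resampling moving onto the fixed grid),
#'   `inverse`, `half_moving`, `half_fixed`, `cost_trace`.
#' @export
register_nonlinear <- function(moving, fixed, stages = NULL, init = NULL,
                               weights = NULL, verbose = FALSE) {
  if (is.null(stages))
    stages <- list(registration_stage("nonlinear", 3.0, 2L, max_iter = 30L),
                   registration_stage("nonlinear", 1.5, 2L, max_iter = 30L))
  if (is.null(weights)) weights <- rep(1, length(moving))
  w <- weights / sum(weights)
  A <- if (is.null(init)) diag(4) else
    if (inherits(init, "affine_registration")) init$affine else init

  u1 <- u2 <- NULL
  cost_trace <- numeric(0)
  iter_costs <- list()
  for (st in stages) {
    mv <- stage_channels(moving, st)
    fx <- stage_channels(fixed, st)
    gs <- grid_shape(mv[[1L]])
    aff <- mv[[1L]]$affine
    vs <- voxel_size(mv[[1L]])
    if (is.null(u1)) {
      H <- affine_half(A)
      u1 <- affine_to_field(H, gs, aff)
      u2 <- affine_to_field(solve(H), gs, aff)
    } else {
      u1 <- resample_field(u1, gs, aff)
      u2 <- resample_field(u2, gs, aff)
    }
    # stack channels once: (nx, ny, nz, sum nc) with per-channel weights
    Ms <- lapply(mv, function(ch) ch$data)
    Fs <- lapply(fx, function(ch) ch$data)
    chw <- rep(w, vapply(Ms, function(a) dim(a)[4L], 0L))
    M <- array(do.call(c, Ms), c(gs, length(chw)))
    Fx <- array(do.call(c, Fs), c(gs, length(chw)))
    wrow <- rep(chw, each = prod(gs))

    cost_of <- function(ua, ub) {
      sum(wrow * (warp_array(M, ua) - warp_array(Fx, ub))^2)
    }
    step <- 0.4 * st$voxel_size_mm
    cur <- cost_of(u1, u2)
    stage_iter <- cur
    for (it in seq_len(st$max_iter)) {
      wm <- warp_array(M, u1)
      wf <- warp_array(Fx, u2)
      r <- wm - wf
      g <- array_gradient((wm + wf) / 2, vs)
      force <- array(0, c(gs, 3L))
      for (ax in 1:3)
        force[, , , ax] <- apply(r * g[, , , , ax] *
                                   array(wrow, dim(r)), c(1, 2, 3), sum)
      upd <- smooth_array_gaussian(force, st$sigma_update)
      mx <- max(sqrt(apply(upd^2, c(1, 2, 3), sum)))
      if (mx < 1e-12) break
      improved <- FALSE
      for (try in 1:4) {
        d1 <- displacement_field(
          smooth_array_gaussian(u1$disp - step / mx * upd, st$sigma_disp),
          aff)
        d2 <- displacement_field(
          smooth_array_gaussian(u2$disp + step / mx * upd, st$sigma_disp),
          aff)
        new <- cost_of(d1, d2)
        if (new < cur) {
          u1 <- d1; u2 <- d2; cur <- new
          step <- min(step * 1.2, 0.8 * st$voxel_size_mm)
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
      stage_iter <- c(stage_iter, cur)
    }
    iter_costs[[length(iter_costs) + 1L]] <- stage_iter
    cost_trace <- c(cost_trace, cur)
    if (verbose)
      message(sprintf("  nonlinear %.2f mm lmax %d: cost %.5g",
                      st$voxel_size_mm, st$lmax, cur))
  }
  # return fields on the native grid of the inputs
  gs0 <- grid_shape(moving[[1L]])
  aff0 <- moving[[1L]]$affine
  u1 <- resample_field(u1, gs0, aff0)
  u2 <- resample_field(u2, gs0, aff0)
  u1i <- invert_field(u1); u2i <- invert_field(u2)
  fwd <- compose_fields(displacement_field(u1$disp, aff0),
                        displacement_field(u2i$disp, aff0))
  bwd <- compose_fields(displacement_field(u2$disp, aff0),
                        displacement_field(u1i$disp, aff0))
  fwd$inverse <- bwd$disp
  bwd$inverse <- fwd$disp
  structure(list(forward = fwd, inverse = bwd,
                 half_moving = u1, half_fixed = u2,
                 cost_trace = cost_trace, iter_costs = iter_costs),
            class = "nonlinear_registration")
}

#' @export
print.nonlinear_registration <- function(x, ...) {
  cat("nonlinear_registration: cost trace",
      paste(signif(x$cost_trace, 4), collapse = " -> "), "\n")
  invisible(x)
}

# resample a displacement field (mm values) onto a new grid
resample_field <- function(field, shape, affine) {
  if (all(dim(field$disp)[1:3] == shape) &&
      max(abs(field$affine - affine)) < 1e-9) return(field)
  idx <- grid_index_matrix(shape)
  src <- world_to_voxel(voxel_to_world(idx, affine), field$affine)
  vals <- interp_trilinear(field$disp, src, mode = "clamp")
  displacement_field(array(vals, c(shape, 3L)), affine)
}
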