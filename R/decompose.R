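#' Ordered set of tissue responses for deconvolution
#'
#' @param names character vector of unique tissue names.
#' @param responses list of [zonal_response()] objects, one per tissue.
#' @param lmax per-tissue even ODF degree (isotropic tissues use 0).
#' @return object of class `tissue_set`.
#' @export
tissue_set <- function(names, responses, lmax) {
  stopifnot(length(names) == length(responses),
            length(names) == length(lmax),
            !anyDuplicated(names), all(lmax %% 2 == 0))
  structure(list(names = names, responses = responses,
                 lmax = as.integer(lmax)),
            class = "tissue_set")
}

#' Default three-tissue set (Iso at lmax 0, Ay and Ao at lmax 8)
#' @param iso,ay,ao [zonal_response()] objects for CSF-like, young-WM and
#'   old-WM kernels.
#' @param lmax_aniso degree of the anisotropic ODFs (default 8).
#' @return a [tissue_set()].
#' @export
three_tissue_set <- function(iso, ay, ao, lmax_aniso = 8L) {
  tissue_set(c("iso", "ay", "ao"), list(iso, ay, ao),
             c(0L, lmax_aniso, lmax_aniso))
}

#' @export
print.tissue_set <- function(x, ...) {
  cat("tissue_set:", paste(sprintf("%s (lmax %d)", x$names, x$lmax),
                           collapse = ", "), "\n")
  invisible(x)
}

# stacked forward matrix and nonnegativity constraint matrix for a tissue set
build_msmt_system <- function(tissues, scheme, n_constraint_dirs = 300L) {
  Fs <- lapply(seq_along(tissues$names), function(i)
    zonal_forward_matrix(tissues$responses[[i]], scheme, tissues$lmax[i]))
  A <- do.call(cbind, Fs)
  cdirs <- fibonacci_sphere(n_constraint_dirs, hemisphere = TRUE)
  Gs <- lapply(seq_along(tissues$names), function(i) {
    if (tissues$lmax[i] == 0L) matrix(1 / sqrt(4 * pi), 1L, 1L)
    else sh_basis(cdirs, tissues$lmax[i])
  })
  nblk <- vapply(Gs, nrow, 0L)
  cblk <- vapply(Gs, ncol, 0L)
  G <- matrix(0, sum(nblk), sum(cblk))
  r0 <- 0L; c0 <- 0L
  for (i in seq_along(Gs)) {
    G[r0 + seq_len(nblk[i]), c0 + seq_len(cblk[i])] <- Gs[[i]]
    r0 <- r0 + nblk[i]; c0 <- c0 + cblk[i]
  }
  list(A = A, G = G, n_coeffs = cblk)
}

# solve min ||A x - s||^2 s.t. G x >= 0 for one voxel; fast unconstrained
# path, quadprog fallback. Dmat etc are precomputed outside the voxel loop.
solve_msmt_voxel <- function(sys, pre, s, tol = 1e-6) {
  x <- pre$Apinv %*% s
  if (min(pre$G %*% x) >= -tol) return(list(x = drop(x), qp = FALSE))
  # pre$Rinv is the inverse Cholesky factor of the (Tikhonov-regularised)
  # normal matrix, so quadprog skips the per-voxel factorisation
  sol <- try(quadprog::solve.QP(Dmat = pre$Rinv,
                                dvec = drop(crossprod(sys$A, s)),
                                Amat = pre$Gt, bvec = pre$bvec,
                                factorized = TRUE),
             silent = TRUE)
  if (inherits(sol, "try-error")) return(list(x = NULL, qp = TRUE))
  list(x = sol$solution, qp = TRUE)
}

#' Multi-shell multi-tissue constrained spherical deconvolution
#'
#' Per voxel, fits the stacked per-tissue spherical-convolution forward
#' model to the measured signal in the least-squares sense, subject to
#' nonnegativity of every tissue's ODF amplitude on a fixed set of 300
#' near-uniform constraint directions. The problem is convex (a Tikhonov
#' term of 1e-12 on the normal matrix makes it strictly so); interior
#' solutions take a direct least-squares path and active-constraint voxels
#' are solved by a dual-method quadratic program. Voxels whose solve fails
#' are zeroed and flagged in the QC map.
#'
#' @param dwi 4-D signal array or `phantom_dwi`.
#' @param scheme a [gradient_scheme()]; needs at least as many shells as
#'   tissues.
#' @param tissues a [tissue_set()].
#' @param mask logical 3-D array.
#' @param n_constraint_dirs size of the nonnegativity direction set.
#' @param affine voxel-to-world matrix for the output volumes.
#' @return object of class `msmt_fit`: `components` (named list of
#'   [sh_volume()]), `tissues`, `scheme`, `mask`, `qc` (logical array of
#'   failed voxels), `system` (forward/constraint matrices).
#' @export
msmt_csd <- function(dwi, scheme, tissues, mask, n_constraint_dirs = 300L,
                     affine = NULL) {
  if (inherits(dwi, "phantom_dwi")) {
    if (is.null(affine)) affine <- dwi$affine
    if (missing(mask)) mask <- dwi$mask
  }
  sig <- as_signal_matrix(dwi)
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  if (n_shells(scheme) < length(tissues$names))
    stop("need at least as many shells as tissues for identifiability")
  gs <- infer_grid_shape(dwi, array(mask, dim = dim_or_null(dwi, mask)))
  if (is.null(affine)) affine <- diag(4)

  sys <- build_msmt_system(tissues, scheme, n_constraint_dirs)
  p <- ncol(sys$A)
  Dmat <- crossprod(sys$A) + diag(1e-12, p)
  pre <- list(Apinv = solve(Dmat, t(sys$A)), G = sys$G,
              Rinv = backsolve(chol(Dmat), diag(p)),
              Gt = t(sys$G), bvec = rep(0, nrow(sys$G)))

  w <- which(mask)
  X <- matrix(0, p, prod(gs))
  qc <- array(FALSE, gs)
  for (v in w) {
    sol <- solve_msmt_voxel(sys, pre, sig[v, ])
    if (is.null(sol$x)) qc[v] <- TRUE else X[, v] <- sol$x
  }

  comps <- list()
  c0 <- 0L
  for (i in seq_along(tissues$names)) {
    nc <- sys$n_coeffs[i]
    arr <- array(t(X[c0 + seq_len(nc), , drop = FALSE]), c(gs, nc))
    comps[[tissues$names[i]]] <- sh_volume(arr, affine = affine)
    c0 <- c0 + nc
  }
  structure(list(components = comps, tissues = tissues, scheme = scheme,
                 mask = array(mask, gs), qc = qc, system = sys,
                 affine = affine),
            class = "msmt_fit")
}

dim_or_null <- function(dwi, mask) {
  if (inherits(dwi, "phantom_dwi")) dim(dwi$signal)[1:3]
  else if (length(dim(dwi)) == 4L) dim(dwi)[1:3]
  else if (!is.null(dim(mask))) dim(mask) else
    stop("mask must be a 3-D array")
}

#' @export
print.msmt_fit <- function(x, ...) {
  cat("msmt_fit:", paste(x$tissues$names, collapse = "/"), "on",
      sum(x$mask), "voxels;", sum(x$qc), "flagged\n")
  invisible(x)
}

#' One-row model summary of an MSMT fit
#' @param x an `msmt_fit`.
#' @param ... unused.
#' @return tibble with tissue count, voxel count, flagged count.
#' @method glance msmt_fit
#' @export
glance.msmt_fit <- function(x, ...) {
  tibble::tibble(n_tissues = length(x$tissues$names),
                 n_voxels = sum(x$mask), n_flagged = sum(x$qc))
}

#' @importFrom generics glance
#' @export
generics::glance

# predicted signal matrix (nvol x nvox) of an msmt_fit
msmt_predict <- function(fit) {
  gs <- dim(fit$mask)
  X <- do.call(rbind, lapply(seq_along(fit$tissues$names), function(i) {
    d <- fit$components[[i]]$data
    t(matrix(d, prod(gs), dim(d)[4L]))
  }))
  fit$system$A %*% X
}

#' Per-shell residual maps of an MSMT fit, in percent of mean b = 0
#'
#' For each shell, the mean absolute difference between measured and
#' predicted signal over the shell's directions, divided by the in-mask
#' mean b = 0 signal and multiplied by 100.
#'
#' @param dwi 4-D signal array or `phantom_dwi`.
#' @param scheme the scheme used in the fit.
#' @param fit an [msmt_csd()] result (or NULL for a zero prediction).
#' @param mask logical 3-D array.
#' @return list of class `shell_residuals`: `maps` (4-D array, shells on
#'   dim 4), `mean` (named per-shell in-mask means), `b0_reference`.
#' @export
shell_residuals <- function(dwi, scheme, fit, mask) {
  sig <- as_signal_matrix(dwi)
  mask <- as.logical(mask)
  gs <- if (!is.null(fit)) dim(fit$mask) else dim_or_null(dwi, mask)
  b0ref <- mean(sig[mask, scheme$shell_index == 1L])
  if (!is.finite(b0ref) || b0ref <= 0) stop("zero mean b = 0 signal")
  pred <- if (!is.null(fit)) t(msmt_predict(fit)) else 0 * sig
  resid <- abs(sig - pred)
  ns <- n_shells(scheme)
  maps <- array(0, c(gs, ns))
  means <- numeric(ns)
  for (s in seq_len(ns)) {
    m <- rowMeans(resid[, scheme$shell_index == s, drop = FALSE]) /
      b0ref * 100
    maps[, , , s] <- array(m, gs)
    means[s] <- mean(m[mask])
  }
  names(means) <- paste0("b", round(scheme$shell_bvalues))
  structure(list(maps = maps, mean = means, b0_reference = b0ref),
            class = "shell_residuals")
}

#' @export
print.shell_residuals <- function(x, ...) {
  cat("shell_residuals (% of mean b0):",
      paste(sprintf("%s = %.3g", names(x$mean), x$mean), collapse = ", "),
      "\n")
  invisible(x)
}

# --- multi-tissue normalisation --------------------------------------------

# tri-variate polynomial basis of total order `order` on normalised
# 0-centred voxel coordinates
poly3d_basis <- function(gs, order = 3L) {
  idx <- grid_index_matrix(gs)
  u <- sweep(idx, 2L, (gs - 1) / 2) / matrix(pmax(gs - 1, 1), nrow(idx), 3,
                                             byrow = TRUE) * 2
  cols <- list()
  for (a in 0:order) for (b in 0:(order - a)) for (c in 0:(order - a - b))
    cols[[length(cols) + 1L]] <- u[, 1]^a * u[, 2]^b * u[, 3]^c
  do.call(cbind, cols)
}

#' Multi-tissue intensity normalisation
#'
#' Estimates a smooth positive multiplicative field (order-3 tri-variate
#' polynomial in the log domain, alternating field and scale updates) and a
#' single joint scale so that, after dividing all components by the field
#' and the scale, the in-mask spatial mean of the summed DC (mean) ODF
#' amplitudes equals `1/(4*pi)` — equivalently, the summed densities
#' average to 1. All tissues share one field and one scale. Voxels with a
#' non-positive summed amplitude are excluded from the field fit and
#' flagged.
#'
#' @param components named list of [sh_volume()]s (one per tissue).
#' @param mask logical 3-D array.
#' @param order polynomial order of the log-field.
#' @param n_iter alternating update iterations.
#' @param target target mean summed DC amplitude (default `1/(4*pi)`).
#' @return list of class `mt_normalisation`: `components` (corrected),
#'   `field` (3-D array, unit geometric mean in mask), `scale` (global),
#'   `flagged` (logical array).
#' @export
mt_normalise <- function(components, mask, order = 3L, n_iter = 3L,
                         target = 1 / (4 * pi)) {
  stopifnot(length(components) >= 1L)
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  gs <- grid_shape(components[[1L]])
  S <- Reduce(`+`, lapply(components, function(x) dc_amplitude(x, "mean")))
  w <- which(mask)
  flagged <- array(FALSE, gs)
  flagged[w[S[w] <= 0]] <- TRUE
  fitvox <- w[S[w] > 0]
  if (length(fitvox) < 10L) stop("too few positive voxels for field fit")

  B <- poly3d_basis(gs, order)
  logfield <- numeric(prod(gs))
  for (it in seq_len(n_iter)) {
    r <- log(S[fitvox]) - logfield[fitvox]
    cf <- qr.solve(B[fitvox, , drop = FALSE], r)
    logfield <- logfield + drop(B %*% cf)
    logfield <- logfield - mean(logfield[fitvox])   # unit geometric mean
  }
  field <- array(exp(logfield), gs)
  scale <- mean(S[fitvox] / field[fitvox]) / target

  corr <- 1 / (field * scale)
  out <- lapply(components, function(x) {
    sh_volume(x$data * array(corr, dim(x$data)), affine = x$affine)
  })
  names(out) <- names(components)
  structure(list(components = out, field = field, scale = scale,
                 flagged = flagged, target = target),
            class = "mt_normalisation")
}

#' @export
print.mt_normalisation <- function(x, ...) {
  cat(sprintf("mt_normalisation: scale = %.4g, field range [%.3g, %.3g], %d flagged\n",
              x$scale, min(x$field), max(x$field), sum(x$flagged)))
  invisible(x)
}

# --- binary mask morphology -------------------------------------------------

#' Erode or dilate a binary mask (6-connected, n iterations)
#' @param mask logical 3-D array.
#' @param n iterations.
#' @return logical 3-D array.
#' @export
erode_mask <- function(mask, n = 1L) {
  m <- as.array(mask) > 0
  for (i in seq_len(n)) {
    out <- m
    for (ax in 1:3) for (dir in c(-1L, 1L))
      out <- out & shift_mask(m, ax, dir, fill = FALSE)
    m <- out
  }
  m
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, n = 1L) {
  m <- as.array(mask) > 0
  for (i in seq_len(n)) {
    out <- m
    for (ax in 1:3) for (dir in c(-1L, 1L))
      out <- out | shift_mask(m, ax, dir, fill = FALSE)
    m <- out
  }
  m
}

# shift a 3-D logical array by one voxel along `ax`, filling with `fill`
shift_mask <- function(m, ax, dir, fill = FALSE) {
  d <- dim(m)
  idx <- seq_len(d[ax]) + dir
  pad <- idx < 1L | idx > d[ax]
  idx[pad] <- 1L
  s <- if (ax == 1L) m[idx, , , drop = FALSE]
  else if (ax == 2L) m[, idx, , drop = FALSE]
  else m[, , idx, drop = FALSE]
  s <- array(s, d)
  if (any(pad)) {
    if (ax == 1L) s[pad, , ] <- fill
    else if (ax == 2L) s[, pad, ] <- fill
    else s[, , pad] <- fill
  }
  s
}

# --- two-pass protocol ------------------------------------------------------

#' Two-pass subject decomposition with group responses
#'
#' Pass 1 works in the subject's native frame: CSF and single-fibre WM
#' responses are estimated from the subject's own data, a two-tissue
#' decomposition is run, and [mt_normalise()] is applied; the resulting
#' global scale is propagated back onto the subject responses (multiplied
#' by the scale, so that the normalised responses reproduce the normalised
#' densities), making responses comparable across subjects. Pass 2
#' deconvolves with the fixed group responses (Iso/Ay/Ao) and normalises
#' the three-component result.
#'
#' @param dwi 4-D signal array or `phantom_dwi`.
#' @param scheme a [gradient_scheme()].
#' @param mask logical 3-D brain mask.
#' @param group_responses list with elements `iso`, `ay`, `ao`
#'   ([zonal_response()]s).
#' @param lmax_aniso anisotropic ODF degree.
#' @param n_sf single-fibre voxels to keep in pass 1.
#' @param affine voxel-to-world matrix.
#' @return list of class `two_pass_fit`: `native` (pass-1 components,
#'   responses and normalisation), `final` (pass-2 normalised components),
#'   `responses_normalised` (subject responses after back-propagation).
#' @export
two_pass_decompose <- function(dwi, scheme, mask, group_responses,
                               lmax_aniso = 8L, n_sf = 50L, affine = NULL) {
  sig <- as_signal_matrix(dwi)
  if (all(sig == 0)) stop("all-zero image")
  mask <- as.logical(mask)
  gs <- dim_or_null(dwi, mask)
  mask3 <- array(mask, gs)

  # pass 1: subject-native responses
  csf_vox <- select_csf_voxels(dwi, scheme, dilate_mask(mask3, 1L),
                               fraction = 0.1)
  csf_resp <- estimate_zonal_response(dwi, scheme, csf_vox,
                                      c(0, 0, 1), lmax = 0L)
  sf <- select_single_fibre_voxels(dwi, scheme, erode_mask(mask3, 2L),
                                   n_keep = n_sf, lmax = lmax_aniso)
  wm_resp <- estimate_zonal_response(dwi, scheme, sf$voxels, sf$axes,
                                     lmax = lmax_aniso)
  ts2 <- tissue_set(c("iso", "wm"), list(csf_resp, wm_resp),
                    c(0L, lmax_aniso))
  fit2 <- msmt_csd(dwi, scheme, ts2, mask3, affine = affine)
  norm2 <- mt_normalise(fit2$components, mask3)
  csf_resp_n <- zonal_response(csf_resp$coeffs * norm2$scale,
                               csf_resp$shell_bvalues)
  wm_resp_n <- zonal_response(wm_resp$coeffs * norm2$scale,
                              wm_resp$shell_bvalues)

  # pass 2: fixed group responses
  ts3 <- three_tissue_set(group_responses$iso, group_responses$ay,
                          group_responses$ao, lmax_aniso)
  fit3 <- msmt_csd(dwi, scheme, ts3, mask3, affine = affine)
  norm3 <- mt_normalise(fit3$components, mask3)

  structure(list(native = list(fit = fit2, normalisation = norm2,
                               csf_response = csf_resp,
                               wm_response = wm_resp,
                               single_fibre = sf),
                 final = norm3$components,
                 final_normalisation = norm3,
                 responses_normalised = list(iso = csf_resp_n,
                                             wm = wm_resp_n)),
            class = "two_pass_fit")
}
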