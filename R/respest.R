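#' Select CSF voxels by signal decay
#'
#' Ranks in-mask voxels by their mean per-shell signal decay — the ratio of
#' the mean b = 0 signal to the mean signal on the highest shell — and keeps
#' the fastest-decaying `fraction`, after excluding voxels whose b = 0
#' signal falls below a noise floor. Free water decays much faster than any
#' parenchyma at high b, so the surviving set is CSF-dominated. Intended to
#' be run inside a dilated full-brain mask.
#'
#' @param dwi 4-D signal array (or a `phantom_dwi`).
#' @param scheme a [gradient_scheme()].
#' @param mask logical 3-D array.
#' @param fraction fraction of in-mask voxels to keep (0 < fraction < 1).
#' @param noise_floor absolute b = 0 threshold; by default 2x the background
#'   (out-of-mask) signal SD, or 0 when there is no background.
#' @param n_min minimum selection size a fraction must yield (default 10; a
#'   kernel averaged over fewer voxels is unreliable — relax only for
#'   degenerate test inputs).
#' @return integer vector of linear voxel indices (class `csf_selection`,
#'   with attribute `score`).
#' @export
select_csf_voxels <- function(dwi, scheme, mask, fraction = 0.1,
                              noise_floor = NULL, n_min = 10L) {
  sig <- as_signal_matrix(dwi)            # nvox x nvol
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  b0 <- rowMeans(sig[, scheme$shell_index == 1L, drop = FALSE])
  hib <- rowMeans(sig[, scheme$shell_index == n_shells(scheme),
                      drop = FALSE])
  if (is.null(noise_floor)) {
    bg <- b0[!mask]
    noise_floor <- if (length(bg) > 10) 2 * stats::sd(bg) else 0
  }
  cand <- which(mask & b0 > noise_floor)
  n_keep <- ceiling(fraction * sum(mask))
  if (n_keep < n_min) stop("fraction keeps fewer than ", n_min, " voxels")
  if (length(cand) < n_keep) stop("noise floor leaves too few candidates")
  score <- b0[cand] / pmax(hib[cand], .Machine$double.eps)
  # ties broken by ascending linear voxel index (stable order)
  keep <- cand[order(-score, cand)][seq_len(n_keep)]
  structure(sort(keep), score = score[match(sort(keep), cand)],
            class = "csf_selection")
}

# accept phantom_dwi or plain 4-D array; return voxels x volumes matrix
as_signal_matrix <- function(dwi) {
  if (inherits(dwi, "phantom_dwi")) dwi <- dwi$signal
  d <- dim(dwi)
  stopifnot(length(d) == 4L)
  matrix(dwi, prod(d[1:3]), d[4L])
}

#' Find ODF peaks on a dense direction grid
#'
#' Evaluates the SH series on a near-uniform hemisphere grid and returns
#' local maxima (each grid direction compared against its angular
#' neighbours), sorted by amplitude.
#'
#' @param coeffs even SH coefficient vector.
#' @param n_dirs size of the search grid.
#' @return list with `directions` (one row per peak) and `amplitudes`.
#' @export
find_odf_peaks <- function(coeffs, n_dirs = 300L, refine = TRUE) {
  lmax <- lmax_from_n_coeffs(length(coeffs))
  grid <- peak_grid(n_dirs, lmax = lmax)
  amp <- drop(grid$basis %*% coeffs)
  pk <- peaks_from_amplitudes(amp, grid)
  if (refine && nrow(pk$directions)) {
    pk$directions <- t(apply(pk$directions, 1L, function(d)
      refine_peak(coeffs, d)))
    pk$amplitudes <- drop(sh_basis(pk$directions, lmax) %*% coeffs)
    ord <- order(-pk$amplitudes)
    pk$directions <- pk$directions[ord, , drop = FALSE]
    pk$amplitudes <- pk$amplitudes[ord]
  }
  pk
}

# cached hemisphere search grid with angular neighbour lists and SH basis
peak_grid <- local({
  cache <- list()
  function(n_dirs = 300L, lmax = 8L) {
    key <- paste(n_dirs, lmax)
    if (!is.null(cache[[key]])) return(cache[[key]])
    dirs <- fibonacci_sphere(n_dirs, hemisphere = TRUE)
    # neighbours: directions within ~2.5x the mean nearest-neighbour angle,
    # counting antipodal proximity
    dot <- abs(dirs %*% t(dirs))
    diag(dot) <- 0
    ang <- acos(pmin(dot, 1))
    thr <- 2.5 * mean(apply(ang, 1, min))
    nb <- lapply(seq_len(n_dirs), function(i) which(ang[i, ] <= thr))
    out <- list(directions = dirs, neighbours = nb,
                basis = sh_basis(dirs, lmax))
    cache[[key]] <<- out
    out
  }
})

#' Iteratively select single-fibre voxels and estimate their axes
#'
#' Bootstrap: deconvolve the highest-b shell with a sharp initial kernel
#' (lightly Laplace-Beltrami regularised, which keeps the per-voxel ODFs
#' usable at this shell's noise level), score each candidate voxel by the
#' dominance of its largest ODF peak — the amplitude margin between the
#' first and second peak, so that strong coherent single-fibre voxels
#' outrank weak but "clean" noise ODFs — keep the `n_keep` most dominant,
#' re-estimate the response from the kept voxels, and repeat until the
#' selected set is stable (Jaccard overlap >= 0.99) or `max_iter` is
#' reached. Voxels with a
#' tensor FA below `fa_min` are excluded up front (automated stand-in for
#' manual mask editing, removing isotropic, crossing-dominated and
#' cortex-like voxels; the 0.15 default sits below immature deep-WM FA but
#' above neonatal grey matter and free water). Run inside an eroded brain
#' mask to restrict to deep WM.
#'
#' @param dwi 4-D signal array or `phantom_dwi`.
#' @param scheme a [gradient_scheme()].
#' @param mask logical 3-D array (eroded deep-WM mask expected).
#' @param n_keep number of voxels to keep.
#' @param lmax SH degree of the single-shell deconvolution (default 8).
#' @param fa_min FA pre-filter threshold.
#' @param max_iter iteration cap.
#' @return list of class `sf_selection`: `voxels` (linear indices), `axes`
#'   (matrix, one unit vector per voxel), `response` (the final
#'   [zonal_response()] on the highest shell), `iterations`, `converged`.
#' @export
select_single_fibre_voxels <- function(dwi, scheme, mask, n_keep = 50L,
                                       lmax = 8L, fa_min = 0.15,
                                       max_iter = 10L) {
  sig <- as_signal_matrix(dwi)
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  cand <- which(mask)
  d <- infer_grid_shape(dwi, mask)
  fa <- tensor_fa(dwi, scheme, array(mask, d))
  if (length(cand) > 1L && fa_min > 0) {
    fav <- as.numeric(fa$fa)[cand]
    # gate at the in-mask upper FA quartile, floored at fa_min: in mature
    # brains this follows the rising parenchymal FA and keeps the pool
    # bundle-dominated, while the floor protects immature brains whose
    # deep-WM FA barely exceeds the background
    gate <- max(fa_min, stats::quantile(fav, 0.75, names = FALSE))
    keep <- fav >= gate
    if (sum(keep) >= 10L) cand <- cand[keep]
  }
  n_keep <- min(n_keep, length(cand))
  # fibre axes for the realignment step come from the tensor fit's
  # principal eigenvector: it pools the higher-SNR low-b shells and is far
  # more stable than the high-b ODF peak for broad immature kernels
  tensor_axis <- function(v) {
    th <- fa$tensors[match(v, fa$voxels), ]
    D <- matrix(c(th["xx"], th["xy"], th["xz"],
                  th["xy"], th["yy"], th["yz"],
                  th["xz"], th["yz"], th["zz"]), 3L, 3L)
    if (anyNA(D)) return(c(0, 0, 1))
    eigen(D, symmetric = TRUE)$vectors[, 1L]
  }

  hishell <- which(scheme$shell_index == n_shells(scheme))
  sub_scheme <- gradient_scheme(scheme$bvalues[hishell],
                                scheme$directions[hishell, , drop = FALSE])
  shi <- sig[cand, hishell, drop = FALSE]

  # sharp initial kernel (high-anisotropy tensor), per-shell zonal
  init <- zonal_response(
    tensor_zonal(sub_scheme$shell_bvalues, 1.7e-3, 0.2e-3, lmax),
    sub_scheme$shell_bvalues)

  response <- init
  selected <- cand
  converged <- FALSE
  it <- 0L
  grid <- peak_grid(300L, lmax)
  idxl <- sh_degrees(lmax)
  lb_penalty <- (idxl$l * (idxl$l + 1))^2
  lb_penalty <- lb_penalty / max(lb_penalty, 1)
  for (it in seq_len(max_iter)) {
    Fm <- zonal_forward_matrix(response, sub_scheme, lmax)
    lam <- 0.1 * mean(diag(crossprod(Fm)))
    sol <- solve(crossprod(Fm) + diag(lam * lb_penalty), t(Fm))
    coefs <- t(sol %*% t(shi))                # candidates x n_coeffs
    amps <- coefs %*% t(grid$basis)           # candidates x n_dirs
    dom <- apply(amps, 1L, function(a) {
      pk <- peaks_from_amplitudes(a, grid)
      if (length(pk$amplitudes) == 0L || pk$amplitudes[1L] <= 0) return(0)
      p2 <- if (length(pk$amplitudes) > 1L) max(pk$amplitudes[2L], 0) else 0
      pk$amplitudes[1L] - p2
    })
    new_sel <- cand[order(-dom, cand)][seq_len(n_keep)]
    axes <- t(vapply(new_sel, tensor_axis, numeric(3L)))
    jac <- length(intersect(selected, new_sel)) /
      length(union(selected, new_sel))
    selected <- new_sel
    upd <- estimate_zonal_response(dwi, scheme, selected, axes,
                                   lmax = lmax, shells = "highest")
    # damped update stabilises the ranking near the selection cutoff
    response <- if (it == 1L) upd else
      zonal_response(0.5 * response$coeffs + 0.5 * upd$coeffs,
                     upd$shell_bvalues)
    if (it > 1L && jac >= 0.99) { converged <- TRUE; break }
  }
  if (!converged)
    warning("single-fibre selection did not converge in ", max_iter,
            " iterations")
  ord <- order(selected)
  structure(list(voxels = selected[ord], axes = axes[ord, , drop = FALSE],
                 response = response, iterations = it,
                 converged = converged),
            class = "sf_selection")
}

#' Refine an ODF peak direction by local search
#'
#' Iteratively evaluates the SH series on shrinking caps of directions
#' around the current estimate and moves to the argmax, giving sub-degree
#' precision on top of a coarse grid peak.
#'
#' @param coeffs even SH coefficient vector.
#' @param direction approximate peak direction.
#' @param radius_deg initial cap radius.
#' @param n_cap directions per cap.
#' @param n_iter shrink iterations.
#' @return unit 3-vector.
#' @export
refine_peak <- function(coeffs, direction, radius_deg = 12, n_cap = 60L,
                        n_iter = 4L) {
  d <- direction / sqrt(sum(direction^2))
  lmax <- lmax_from_n_coeffs(length(coeffs))
  r <- radius_deg * pi / 180
  for (it in seq_len(n_iter)) {
    R <- rotation_between(c(0, 0, 1), d)
    i <- seq_len(n_cap) - 0.5
    ct <- 1 - (1 - cos(r)) * i / n_cap
    phi <- pi * (1 + sqrt(5)) * i
    st <- sqrt(pmax(0, 1 - ct^2))
    cap <- cbind(st * cos(phi), st * sin(phi), ct) %*% t(R)
    amp <- drop(sh_basis(cap, lmax) %*% coeffs)
    d <- cap[which.max(amp), ]
    r <- r / 2.5
  }
  d
}

peaks_from_amplitudes <- function(amp, grid) {
  is_peak <- vapply(seq_along(amp), function(i) {
    all(amp[i] >= amp[grid$neighbours[[i]]])
  }, TRUE)
  ord <- order(-amp[is_peak])
  list(directions = grid$directions[is_peak, , drop = FALSE][ord, , drop = FALSE],
       amplitudes = amp[is_peak][ord])
}

infer_grid_shape <- function(dwi, mask) {
  if (inherits(dwi, "phantom_dwi")) return(dim(dwi$signal)[1:3])
  if (!is.null(dim(mask))) return(dim(mask))
  stop("cannot infer grid shape")
}

#' Estimate a zonal response from voxels with known fibre axes
#'
#' For each voxel, the gradient directions are rotated so that the voxel's
#' fibre axis maps onto +z, the per-shell signal is projected onto the zonal
#' (m = 0) SH basis, and the per-voxel coefficient rows are averaged.
#'
#' @param dwi 4-D signal array or `phantom_dwi`.
#' @param scheme a [gradient_scheme()].
#' @param voxels linear voxel indices (or a `csf_selection`).
#' @param axes one unit axis per voxel (`n x 3`); a single vector is
#'   recycled.
#' @param lmax even degree of the zonal fit.
#' @param shells `"all"` or `"highest"`.
#' @return a [zonal_response()].
#' @export
estimate_zonal_response <- function(dwi, scheme, voxels, axes, lmax = 8L,
                                    shells = c("all", "highest")) {
  shells <- match.arg(shells)
  sig <- as_signal_matrix(dwi)
  voxels <- as.integer(voxels)
  if (length(voxels) == 0L) stop("empty voxel set")
  axes <- as_direction_matrix(axes)
  if (nrow(axes) == 1L) axes <- axes[rep(1L, length(voxels)), , drop = FALSE]
  stopifnot(nrow(axes) == length(voxels))
  shell_ids <- if (shells == "highest") n_shells(scheme) else
    seq_len(n_shells(scheme))
  ncol_out <- lmax / 2 + 1L
  acc <- matrix(0, length(shell_ids), ncol_out)
  for (v in seq_along(voxels)) {
    R <- rotation_between(axes[v, ], c(0, 0, 1))
    rot_dirs <- scheme$directions %*% t(R)
    for (si in seq_along(shell_ids)) {
      vols <- shell_volumes(scheme, shell_ids[si])
      # b = 0 shells carry no angular information: zonal l = 0 term only
      lm_here <- if (scheme$shell_bvalues[shell_ids[si]] <
                     scheme$shell_tol) 0L else min(lmax, 2L * (length(vols) %/% 2L))
      lm_here <- min(lm_here, lmax)
      z <- project_zonal(rot_dirs[vols, , drop = FALSE],
                         sig[voxels[v], vols], lm_here)
      acc[si, seq_len(lm_here / 2 + 1L)] <-
        acc[si, seq_len(lm_here / 2 + 1L)] + z
    }
  }
  zonal_response(acc / length(voxels), scheme$shell_bvalues[shell_ids])
}

#' Fit the two-kernel maturation mixture
#'
#' Solves the unconstrained linear least-squares problem
#' `argmin_{alpha, beta} || alpha * R_y + beta * R_o - R_t ||^2` over all
#' stacked zonal coefficients. Weights may be negative.
#'
#' @param r_young,r_old,r_target [zonal_response()] objects sharing shells
#'   and lmax.
#' @return list of class `mixture_fit`: `alpha`, `beta`, `residual_norm`,
#'   `fitted` (a `zonal_response`).
#' @export
fit_response_mixture <- function(r_young, r_old, r_target) {
  stopifnot(nrow(r_young$coeffs) == nrow(r_old$coeffs),
            nrow(r_young$coeffs) == nrow(r_target$coeffs),
            ncol(r_young$coeffs) == ncol(r_old$coeffs))
  nct <- min(ncol(r_young$coeffs), ncol(r_target$coeffs))
  X <- cbind(as.numeric(r_young$coeffs[, seq_len(nct)]),
             as.numeric(r_old$coeffs[, seq_len(nct)]))
  y <- as.numeric(r_target$coeffs[, seq_len(nct)])
  cr <- abs(stats::cor(X[, 1L], X[, 2L]))
  if (!is.finite(cr) || cr > 1 - 1e-10)
    stop("young and old responses are collinear; mixture weights not identifiable")
  ab <- qr.solve(X, y)
  structure(list(alpha = ab[1L], beta = ab[2L],
                 residual_norm = sqrt(sum((X %*% ab - y)^2)),
                 fitted = zonal_response(
                   matrix(X %*% ab, nrow(r_target$coeffs), nct),
                   r_target$shell_bvalues)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: alpha = %.4f, beta = %.4f, |resid| = %.3g\n",
              x$alpha, x$beta, x$residual_norm))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Broom-style one-row summary of a mixture fit
#' @param x a `mixture_fit`.
#' @param ... unused.
#' @return a tibble with columns alpha, beta, residual_norm.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta,
                 residual_norm = x$residual_norm)
}

#' Robust polynomial age-curve fit (Huber loss)
#'
#' Iteratively reweighted least squares for a degree-`degree` polynomial
#' under the Huber loss with `delta = 1.345 * MAD` of the current residuals
#' (the standard 95%-efficiency tuning constant). When all residuals fall
#' within delta the fit equals ordinary least squares; a (near-)exact fit
#' short-circuits to OLS.
#'
#' @param ages numeric predictor (weeks).
#' @param values numeric response.
#' @param degree polynomial degree (default 3).
#' @param max_iter IRLS iteration cap.
#' @return list of class `age_curve`: `coefficients` (intercept first),
#'   `degree`, `fitted`, plus `predict()` support.
#' @export
fit_age_curves <- function(ages, values, degree = 3L, max_iter = 50L) {
  stopifnot(length(ages) == length(values))
  if (length(ages) < degree + 1L)
    stop("need at least degree + 1 points")
  X <- stats::poly(ages, degree = degree, raw = TRUE)
  X <- cbind(1, unclass(X))
  beta <- qr.solve(X, values)
  for (it in seq_len(max_iter)) {
    r <- drop(values - X %*% beta)
    s <- stats::mad(r, center = 0)
    if (s < 1e-10 * max(1, max(abs(values)))) break    # exact fit: OLS
    delta <- 1.345 * s
    w <- ifelse(abs(r) <= delta, 1, delta / abs(r))
    beta_new <- qr.solve(sqrt(w) * X, sqrt(as.numeric(w)) * values)
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  structure(list(coefficients = as.numeric(beta), degree = degree,
                 ages = ages, fitted = as.numeric(X %*% beta)),
            class = "age_curve")
}

#' @export
predict.age_curve <- function(object, newdata = object$ages, ...) {
  X <- cbind(1, unclass(stats::poly(newdata, degree = object$degree,
                                    raw = TRUE)))
  as.numeric(X %*% object$coefficients)
}

#' @export
print.age_curve <- function(x, ...) {
  cat("age_curve: degree", x$degree, "coefficients",
      paste(signif(x$coefficients, 4), collapse = ", "), "\n")
  invisible(x)
}
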