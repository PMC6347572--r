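#' Diffusion tensor fit and fractional anisotropy
#'
#' Weighted linear least-squares fit of the log-signal tensor model on
#' volumes with b <= `bmax` (default 1000 s/mm^2, where the mono-tensor
#' model is adequate), with weights proportional to the squared predicted
#' signal (one reweighted pass after an OLS initialisation). FA is computed
#' from the tensor eigenvalues and clamped to [0, 1]. Voxels with
#' non-positive signals are flagged and given FA 0.
#'
#' @param dwi 4-D signal array or `phantom_dwi`.
#' @param scheme a [gradient_scheme()].
#' @param mask logical 3-D array.
#' @param bmax highest b-value included in the fit.
#' @return list of class `fa_map`: `fa` (3-D array), `md` (mean
#'   diffusivity, mm^2/s), `tensors` (n_mask x 6: xx, yy, zz, xy, xz, yz),
#'   `flagged` (logical array).
#' @export
tensor_fa <- function(dwi, scheme, mask, bmax = 1000) {
  sig <- as_signal_matrix(dwi)
  mask <- as.logical(mask)
  gs <- dim_or_null(dwi, mask)
  use <- which(scheme$bvalues <= bmax + scheme$shell_tol)
  nzb <- sum(scheme$bvalues[use] > scheme$shell_tol)
  if (nzb < 6L) stop("need >= 6 diffusion-weighted directions at b <= ", bmax)
  g <- scheme$directions[use, , drop = FALSE]
  b <- scheme$bvalues[use]
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])

  fa <- array(0, gs); md <- array(0, gs)
  flagged <- array(FALSE, gs)
  w <- which(mask)
  tensors <- matrix(NA_real_, length(w), 6L,
                    dimnames = list(NULL, c("xx", "yy", "zz", "xy", "xz", "yz")))
  Xp <- solve(crossprod(X), t(X))          # OLS operator
  for (vi in seq_along(w)) {
    v <- w[vi]
    s <- sig[v, use]
    if (any(s <= 0)) { flagged[v] <- TRUE; next }
    y <- log(s)
    th <- Xp %*% y
    wt <- as.numeric(exp(X %*% th))^2       # WLS pass
    th <- qr.solve(sqrt(wt) * X, sqrt(wt) * y)
    D <- matrix(c(th[2], th[5], th[6],
                  th[5], th[3], th[7],
                  th[6], th[7], th[4]), 3, 3)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    tensors[vi, ] <- th[c(2, 3, 4, 5, 6, 7)]
    mdv <- mean(ev)
    md[v] <- mdv
    denom <- sum(ev^2)
    if (denom > 0)
      fa[v] <- min(1, max(0, sqrt(1.5 * sum((ev - mdv)^2) / denom)))
  }
  structure(list(fa = fa, md = md, tensors = tensors, voxels = w,
                 flagged = flagged),
            class = "fa_map")
}

#' @export
print.fa_map <- function(x, ...) {
  inm <- x$fa[x$voxels]
  cat(sprintf("fa_map: %d voxels, FA median %.3f [%.3f, %.3f]\n",
              length(x$voxels), stats::median(inm),
              stats::quantile(inm, 0.05), stats::quantile(inm, 0.95)))
  invisible(x)
}

#' Phantom ROI registry (17 named regions)
#'
#' Defines 17 regions of interest on a phantom's label image, mirroring a
#' region set spanning commissural-like segments, projection-like bundle
#' parts, a crossing, CSF, cortex-like rim sectors and background
#' parenchyma. The five `bundle_y_seg*` regions segment the
#' posterior-anterior bundle along its length, so their programmed
#' maturation onsets differ: segment 1 (posterior) matures earliest,
#' segment 5 (anterior) latest. Anatomical fidelity is not claimed.
#'
#' @param truth a [phantom_truth()] (or any object with `labels`, `mask`).
#' @return named list of 17 logical 3-D arrays.
#' @export
default_roi_registry <- function(truth) {
  lab <- truth$labels
  gs <- dim(lab)
  L <- phantom_labels()
  idx <- grid_index_matrix(gs)
  xi <- array(idx[, 1], gs); yi <- array(idx[, 2], gs)
  zi <- array(idx[, 3], gs)
  thirds <- function(v, lo, hi, k, of) v >= lo + (k - 1) * (hi - lo + 1) / of &
    v < lo + k * (hi - lo + 1) / of

  bx <- lab == L["bundle_x"]
  by <- lab == L["bundle_y"]
  cross <- lab == L["crossing"]
  ctx <- lab == L["cortex"]
  bg <- lab == L["background"]
  ymid <- (gs[2] - 1) / 2
  zmid <- (gs[3] - 1) / 2

  rois <- list(
    csf_ventricles = lab == L["csf"],
    bundle_x_left = bx & thirds(xi, 0, gs[1] - 1, 1, 3),
    bundle_x_centre = bx & thirds(xi, 0, gs[1] - 1, 2, 3),
    bundle_x_right = bx & thirds(xi, 0, gs[1] - 1, 3, 3),
    crossing_core = cross
  )
  for (k in 1:5) {
    rois[[paste0("bundle_y_seg", k)]] <- by & thirds(yi, 0, gs[2] - 1, k, 5)
  }
  rois$cortex_posterior <- ctx & yi < ymid
  rois$cortex_anterior <- ctx & yi >= ymid
  rois$cortex_superior <- ctx & zi >= zmid
  rois$background_posterior <- bg & yi < ymid
  rois$background_anterior <- bg & yi >= ymid
  rois$deep_wm_union <- bx | by | cross
  rois$parenchyma_all <- bx | by | cross | bg

  empty <- names(rois)[!vapply(rois, any, TRUE)]
  if (length(empty)) stop("empty ROI(s): ", paste(empty, collapse = ", "))
  rois
}

#' ROI time-courses of component densities across weekly templates
#'
#' For every week, region and tissue, the mean and standard deviation of
#' the DC (mean) ODF amplitude over the region's voxels, in long format.
#' ROIs are defined once on the common grid and apply to every week.
#'
#' @param weekly named list: week label -> named list of [sh_volume()]
#'   components.
#' @param rois named list of logical 3-D arrays (e.g.
#'   [default_roi_registry()]).
#' @return a tibble with columns `week`, `roi`, `tissue`, `mean`, `sd`,
#'   `n_voxels`.
#' @export
roi_timecourses <- function(weekly, rois) {
  stopifnot(length(weekly) >= 1L, length(rois) >= 1L)
  empty <- names(rois)[!vapply(rois, any, TRUE)]
  if (length(empty)) stop("empty ROI(s): ", paste(empty, collapse = ", "))
  rows <- list()
  for (wk in names(weekly)) {
    comps <- weekly[[wk]]
    for (tis in names(comps)) {
      dc <- dc_amplitude(comps[[tis]], "mean")
      for (rn in names(rois)) {
        vals <- dc[rois[[rn]]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          week = wk, roi = rn, tissue = tis,
          mean = mean(vals),
          sd = if (length(vals) > 1L) stats::sd(vals) else 0,
          n_voxels = length(vals))
      }
    }
  }
  do.call(rbind, rows)
}
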