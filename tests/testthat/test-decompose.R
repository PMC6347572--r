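test_that("noiseless three-tissue deconvolution recovers the truth exactly", {
  tr <- fx("truth38")
  fit <- fx("fit3_noiseless")
  expect_equal(sum(fit$qc), 0L)
  dens <- lapply(fit$components, function(x) dc_amplitude(x, "density"))
  m <- tr$mask
  expect_lt(sqrt(mean((dens$iso[m] - tr$iso[m])^2)), 1e-4)
  expect_lt(sqrt(mean((dens$ay[m] - tr$a_young[m])^2)), 1e-4)
  expect_lt(sqrt(mean((dens$ao[m] - tr$a_old[m])^2)), 1e-4)

  # pure-CSF voxels carry no anisotropic density
  csf <- tr$labels == phantom_labels()["csf"]
  expect_lt(max(dens$ay[csf]), 1e-3)
  expect_lt(max(dens$ao[csf]), 1e-3)

  # fibre directions recovered: ODF peak within 2 degrees at bundle voxels
  v <- which(tr$labels == phantom_labels()["bundle_y"])[7]
  a <- arrayInd(v, dim(tr$mask))
  pk <- find_odf_peaks(fit$components$ay$data[a[1], a[2], a[3], ] +
                         fit$components$ao$data[a[1], a[2], a[3], ])
  expect_lt(axis_error_deg(pk$directions[1, ], true_fibre_dir(tr, v)), 2)
})

test_that("noisy density recovery stays within the stochastic tolerance", {
  tr <- fx("truth38")
  fit <- fx("fit3_noisy")
  bf <- fx("dwi_noisy")$bias_field
  dens <- lapply(fit$components, function(x) dc_amplitude(x, "density"))
  m <- tr$mask
  # truth as rendered: modulated by the known bias field
  rmse_tot <- sqrt(mean(((dens$iso[m] + dens$ay[m] + dens$ao[m]) -
                           (tr$iso + tr$a_young + tr$a_old)[m] * bf[m])^2))
  expect_lt(rmse_tot, 0.05)
})

test_that("per-voxel solver matches an independent dual-NNLS oracle", {
  # 100 random single-voxel instances at lmax 4
  bv <- c(0, 400, 1000, 2600)
  r0 <- analytic_responses(0, bv); r1 <- analytic_responses(1, bv)
  ts <- three_tissue_set(r0$iso, r0$aniso, r1$aniso, lmax_aniso = 4L)
  sch <- fx("scheme")
  sys <- neomti:::build_msmt_system(ts, sch)
  p <- ncol(sys$A)
  Dmat <- crossprod(sys$A) + diag(1e-12, p)
  pre <- list(Apinv = solve(Dmat, t(sys$A)), G = sys$G,
              Rinv = backsolve(chol(Dmat), diag(p)),
              Gt = t(sys$G), bvec = rep(0, nrow(sys$G)))
  obj <- function(x, s) sum((sys$A %*% x - s)^2)
  set.seed(99)
  worst <- 0
  for (k in 1:100) {
    # mixture signal plus noise so constraints activate in many instances
    x0 <- c(runif(1, 0, 0.3) / sqrt(4 * pi),
            drop(delta_sh(fibonacci_sphere(50)[sample(50, 1), ], 4L)) *
              runif(1, 0, 1),
            rep(0, n_sh_coeffs(4)))
    s <- drop(sys$A %*% x0) + rnorm(nrow(sys$A), sd = 0.05)
    got <- neomti:::solve_msmt_voxel(sys, pre, s)$x
    ref <- oracle_constrained_ls(sys$A, s, sys$G)
    worst <- max(worst, abs(obj(got, s) - obj(ref, s)))
    expect_gte(min(sys$G %*% got), -1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("solution optimality: objective never exceeds truth's objective", {
  tr <- fx("truth38"); sch <- fx("scheme")
  fit <- fx("fit3_noisy")
  sig <- neomti:::as_signal_matrix(fx("dwi_noisy"))
  comp <- neomti:::truth_sh_components(tr, 8L)
  bf <- as.numeric(fx("dwi_noisy")$bias_field)
  A <- fit$system$A
  m <- which(tr$mask)
  set.seed(1)
  for (v in sample(m, 60)) {
    xhat <- c(fit$components$iso$data[arrayInd(v, dim(tr$mask))[1],
                                      arrayInd(v, dim(tr$mask))[2],
                                      arrayInd(v, dim(tr$mask))[3], ],
              fit$components$ay$data[arrayInd(v, dim(tr$mask))[1],
                                     arrayInd(v, dim(tr$mask))[2],
                                     arrayInd(v, dim(tr$mask))[3], ],
              fit$components$ao$data[arrayInd(v, dim(tr$mask))[1],
                                     arrayInd(v, dim(tr$mask))[2],
                                     arrayInd(v, dim(tr$mask))[3], ])
    xtrue <- c(comp$iso[, v], comp$ay[, v], comp$ao[, v]) * bf[v]
    s <- sig[v, ]
    expect_lte(sum((A %*% xhat - s)^2), sum((A %*% xtrue - s)^2) + 1e-6)
  }
})

test_that("shell residuals: noiseless floor, zero fit, error contract", {
  tr <- fx("truth38"); sch <- fx("scheme")
  res0 <- shell_residuals(fx("dwi0"), sch, fx("fit3_noiseless"), tr$mask)
  expect_lt(max(res0$maps[rep(tr$mask, n_shells(sch))]), 0.1)

  # zero-component fit: residual equals 100 * mean|signal| / mean(b0)
  resz <- shell_residuals(fx("dwi0"), sch, NULL, tr$mask)
  sig <- neomti:::as_signal_matrix(fx("dwi0"))
  b0 <- mean(sig[tr$mask, sch$shell_index == 1L])
  for (s in seq_len(n_shells(sch))) {
    manual <- 100 * mean(rowMeans(abs(sig[tr$mask, sch$shell_index == s,
                                          drop = FALSE]))) / b0
    expect_equal(unname(resz$mean[s]), manual, tolerance = 1e-10)
  }

  zero <- array(0, dim(fx("dwi0")$signal))
  expect_error(shell_residuals(zero, sch, NULL, tr$mask), "zero mean b")
})

test_that("three tissues fit no worse than two on every shell", {
  tr <- fx("truth38"); sch <- fx("scheme")
  fit3 <- fx("fit3_noiseless")
  fit2 <- msmt_csd(fx("dwi0"), sch, fx("tissues2"), tr$mask)
  r3 <- shell_residuals(fx("dwi0"), sch, fit3, tr$mask)
  r2 <- shell_residuals(fx("dwi0"), sch, fit2, tr$mask)
  expect_true(all(r3$mean <= r2$mean + 1e-9))
})

test_that("nonnegativity holds on the constraint set for noisy fits", {
  fit <- fx("fit3_noisy")
  G <- fit$system$G
  m <- which(fit$mask)
  X <- rbind(matrix(fit$components$iso$data, prod(dim(fit$mask)), 1)[m, ,
                                                                     drop = FALSE],
             NULL)
  # stack all coefficients voxel-wise and evaluate the constraints
  gs <- dim(fit$mask)
  Xall <- t(cbind(matrix(fit$components$iso$data, prod(gs), 1),
                  matrix(fit$components$ay$data, prod(gs), 45),
                  matrix(fit$components$ao$data, prod(gs), 45)))[, m]
  expect_gte(min(G %*% Xall), -1e-6)
})

test_that("mt_normalise: identity, bias recovery, scale invariance, target", {
  tr <- fx("truth38")
  # an input that already satisfies the target with a flat field
  gs <- dim(tr$mask)
  flat <- array(0, c(gs, 1L))
  flat[, , , 1L] <- 1 / sqrt(4 * pi)      # unit density everywhere
  comp0 <- list(iso = sh_volume(flat, voxel_size = 1.5))
  n0 <- mt_normalise(comp0, tr$mask)
  expect_equal(n0$scale, 1, tolerance = 1e-9)
  expect_equal(range(n0$field), c(1, 1), tolerance = 1e-9)
  expect_equal(n0$components$iso$data, comp0$iso$data, tolerance = 1e-9)

  # known polynomial bias field: recovered within Pearson 0.95; the
  # corrected mean summed DC amplitude hits 1/(4*pi) within 1e-6
  fit <- fx("fit3_noisy")
  nrm <- mt_normalise(fit$components, tr$mask)
  S <- Reduce(`+`, lapply(nrm$components,
                          function(x) dc_amplitude(x, "mean")))
  expect_equal(mean(S[tr$mask]), 1 / (4 * pi), tolerance = 1e-6 / (4 * pi))
  expect_gte(stats::cor(as.numeric(nrm$field[tr$mask]),
                        as.numeric(fx("dwi_noisy")$bias_field[tr$mask])),
             0.95)

  # doubling all inputs changes only the scale
  doubled <- lapply(fit$components, function(x)
    sh_volume(2 * x$data, affine = x$affine))
  nrm2 <- mt_normalise(doubled, tr$mask)
  expect_equal(nrm2$scale / nrm$scale, 2, tolerance = 1e-9)
  expect_equal(nrm2$components$ay$data, nrm$components$ay$data,
               tolerance = 1e-9)

  expect_error(mt_normalise(list(), tr$mask))
  expect_error(mt_normalise(comp0, array(FALSE, gs)), "empty mask")
})

test_that("two-pass protocol: self-consistency and degenerate input", {
  tr <- fx("truth38"); sch <- fx("scheme")
  r <- fx("responses")
  grp <- list(iso = r$iso, ay = r$ay, ao = r$ao)
  dwib <- render_phantom(tr, sch, seed = 2L, snr = Inf,
                         bias_amplitude = 0.1)
  tp <- suppressWarnings(
    two_pass_decompose(dwib, sch, tr$mask, grp, n_sf = 40L))

  # pass-2 output is normalised: mean summed DC amplitude = 1/(4*pi)
  S <- Reduce(`+`, lapply(tp$final, function(x) dc_amplitude(x, "mean")))
  expect_equal(mean(S[tr$mask]), 1 / (4 * pi), tolerance = 1e-6)

  # where one anisotropic component vanishes, the pass-2 split matches the
  # pass-1 WM density (same signal, equivalent models)
  dens2 <- dc_amplitude(tp$native$normalisation$components$wm, "density")
  dens3 <- dc_amplitude(tp$final$ay, "density") +
    dc_amplitude(tp$final$ao, "density")
  core <- tr$labels %in% phantom_labels()[c("bundle_x", "bundle_y")]
  expect_lt(stats::median(abs(dens3[core] - dens2[core]) /
                            pmax(dens2[core], 0.1)), 0.2)

  expect_error(two_pass_decompose(array(0, dim(dwib$signal)), sch,
                                  tr$mask, grp), "all-zero")
})

test_that("normalised subject responses agree across same-age subjects", {
  spec <- fx("spec"); sch <- fx("scheme")
  r <- fx("responses")
  grp <- list(iso = r$iso, ay = r$ay, ao = r$ao)
  resp <- list()
  for (i in 1:2) {
    base <- phantom_truth(spec, 40)
    wf <- random_smooth_field(spec$grid_shape, base$affine, 1.5,
                              seed = 40L + i)
    tri <- neomti:::warp_truth(base, wf)
    dwii <- render_phantom(tri, sch, seed = 50L + i, snr = Inf,
                           bias_amplitude = 0.08)
    tp <- suppressWarnings(
      two_pass_decompose(dwii, sch, tri$mask, grp, n_sf = 80L))
    resp[[i]] <- tp$responses_normalised$wm$coeffs
  }
  # per-coefficient agreement within 5% of the per-shell DC magnitude
  rel <- abs(resp[[1]] - resp[[2]]) / abs(resp[[1]][, 1L])
  expect_lt(max(rel), 0.05)
})
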