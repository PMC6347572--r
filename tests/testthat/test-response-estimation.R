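test_that("CSF voxel selection lands in true CSF and honours the count contract", {
  tr <- fx("truth38"); sch <- fx("scheme")
  sel <- select_csf_voxels(fx("dwi_noisy"), sch, dilate_mask(tr$mask, 1L))
  expect_gte(mean(tr$labels[sel] == phantom_labels()["csf"]), 0.9)

  # uniform image: still exactly ceiling(fraction * N) voxels, stable order
  gs <- c(6L, 6L, 4L)
  uni <- array(1, c(gs, n_volumes(sch)))
  m <- array(TRUE, gs)
  sel_u <- select_csf_voxels(uni, sch, m, fraction = 0.5, noise_floor = 0)
  expect_length(sel_u, ceiling(0.5 * prod(gs)))
  expect_equal(as.integer(sel_u), seq_len(ceiling(0.5 * prod(gs))))

  # two voxels with distinct decays: the faster-decaying one wins
  two <- array(1, c(2L, 1L, 1L, n_volumes(sch)))
  two[1, 1, 1, sch$shell_index == 4L] <- 0.05  # fast decay
  two[2, 1, 1, sch$shell_index == 4L] <- 0.80
  m2 <- array(TRUE, c(2L, 1L, 1L))
  expect_error(select_csf_voxels(two, sch, m2, fraction = 0.5),
               "fewer than 10")
  sel_2 <- select_csf_voxels(two, sch, m2, fraction = 0.5, noise_floor = 0,
                             n_min = 1L)
  expect_equal(as.integer(sel_2), 1L)

  expect_error(select_csf_voxels(two, sch, array(FALSE, c(2L, 1L, 1L))),
               "empty mask")
})

test_that("single-fibre selection finds bundle voxels with accurate axes", {
  tr <- fx("truth38"); sch <- fx("scheme")
  L <- phantom_labels()
  sf <- suppressWarnings(
    select_single_fibre_voxels(fx("dwi_noisy"), sch,
                               erode_mask(tr$mask, 2L), n_keep = 50L))
  inb <- tr$labels[sf$voxels] %in% L[c("bundle_x", "bundle_y")]
  expect_gte(mean(inb), 0.9)
  expect_lte(mean(tr$labels[sf$voxels] == L["crossing"]), 0.1)

  # noiseless single-voxel mask: that voxel, axis within 5 degrees
  v <- which(tr$labels == L["bundle_x"])[10]
  m1 <- array(FALSE, dim(tr$mask)); m1[v] <- TRUE
  sf1 <- suppressWarnings(
    select_single_fibre_voxels(fx("dwi0"), sch, m1, n_keep = 5L,
                               fa_min = 0))
  expect_equal(as.integer(sf1$voxels), v)
  expect_lt(axis_error_deg(sf1$axes[1, ], true_fibre_dir(tr, v)), 5)

  # n_keep >= |mask| returns the whole mask
  mk <- array(FALSE, dim(tr$mask))
  mk[which(tr$labels == L["bundle_y"])[1:8]] <- TRUE
  sf8 <- suppressWarnings(
    select_single_fibre_voxels(fx("dwi0"), sch, mk, n_keep = 100L,
                               fa_min = 0))
  expect_setequal(sf8$voxels, which(mk))
})

test_that("zonal response estimation recovers the generating kernel", {
  tr <- fx("truth38"); sch <- fx("scheme")
  L <- phantom_labels()
  vox <- which(tr$labels == L["bundle_x"])
  axes <- t(vapply(vox, function(v) true_fibre_dir(tr, v), numeric(3)))
  est <- estimate_zonal_response(fx("dwi0"), sch, vox, axes, lmax = 8L)
  gen <- phantom_effective_response(
    analytic_responses(mean(tr$t[vox]), sch$shell_bvalues, 8L)$aniso)
  expect_lt(max(abs(est$coeffs - gen$coeffs)) / max(abs(gen$coeffs)), 1e-3)

  # permutation invariance
  p <- sample(length(vox))
  est_p <- estimate_zonal_response(fx("dwi0"), sch, vox[p],
                                   axes[p, , drop = FALSE], lmax = 8L)
  expect_equal(est$coeffs, est_p$coeffs, tolerance = 1e-12)

  # isotropic signal: l > 0 coefficients vanish
  visó <- which(tr$labels == L["csf"])[1:5]
  est_iso <- estimate_zonal_response(fx("dwi0"), sch, visó,
                                     c(0, 0, 1), lmax = 8L)
  expect_lt(max(abs(est_iso$coeffs[, -1L])) / max(abs(est_iso$coeffs)),
            1e-6)

  # single voxel with +z axis equals the plain zonal projection
  vz <- which(tr$labels == L["csf"])[1]
  est_1 <- estimate_zonal_response(fx("dwi0"), sch, vz, c(0, 0, 1),
                                   lmax = 4L)
  sig <- neomti:::as_signal_matrix(fx("dwi0"))
  for (s in 2:4) {
    vols <- shell_volumes(sch, s)
    z <- project_zonal(sch$directions[vols, ], sig[vz, vols], 4L)
    expect_equal(est_1$coeffs[s, ], z, tolerance = 1e-10)
  }

  expect_error(estimate_zonal_response(fx("dwi0"), sch, integer(0),
                                       c(0, 0, 1)), "empty voxel set")
})

test_that("mixture fit solves the stated least-squares problem", {
  r <- fx("responses")
  f1 <- fit_response_mixture(r$ay, r$ao, r$ay)
  expect_equal(c(f1$alpha, f1$beta), c(1, 0), tolerance = 1e-10)
  expect_lt(f1$residual_norm, 1e-10)

  mix <- zonal_response(0.3 * r$ay$coeffs + 0.7 * r$ao$coeffs,
                        r$ay$shell_bvalues)
  f2 <- fit_response_mixture(r$ay, r$ao, mix)
  expect_equal(c(f2$alpha, f2$beta), c(0.3, 0.7), tolerance = 1e-10)

  # noisy target matches an independent pseudoinverse oracle
  set.seed(21)
  noisy <- zonal_response(mix$coeffs + matrix(rnorm(length(mix$coeffs),
                                                    sd = 0.05),
                                              nrow(mix$coeffs)),
                          mix$shell_bvalues)
  f3 <- fit_response_mixture(r$ay, r$ao, noisy)
  X <- cbind(as.numeric(r$ay$coeffs), as.numeric(r$ao$coeffs))
  oracle <- drop(MASS::ginv(X) %*% as.numeric(noisy$coeffs))
  expect_equal(c(f3$alpha, f3$beta), oracle, tolerance = 1e-8)
  # weights are unconstrained: a negative-weight target must fit exactly
  neg <- zonal_response(-0.2 * r$ay$coeffs + 1.1 * r$ao$coeffs,
                        r$ay$shell_bvalues)
  fneg <- fit_response_mixture(r$ay, r$ao, neg)
  expect_equal(c(fneg$alpha, fneg$beta), c(-0.2, 1.1), tolerance = 1e-8)

  expect_error(fit_response_mixture(r$ay, zonal_response(
    2 * r$ay$coeffs, r$ay$shell_bvalues), mix), "collinear")

  expect_named(tidy(f2), c("alpha", "beta", "residual_norm"))
})

test_that("robust age-curve fit: OLS reduction and outlier resistance", {
  x <- seq(33, 44, length.out = 15)
  beta_true <- c(2, -0.5, 0.03, 0.001)
  y <- drop(cbind(1, x, x^2, x^3) %*% beta_true)
  f <- fit_age_curves(x, y)
  expect_equal(f$coefficients, beta_true, tolerance = 1e-8)

  # gross outlier: Huber fit stays closer (sup-norm) to the truth than OLS
  y_out <- y; y_out[8] <- y[8] + 50
  fh <- fit_age_curves(x, y_out)
  ols <- stats::lm(y_out ~ poly(x, 3, raw = TRUE))
  grid <- seq(33, 44, length.out = 100)
  truthv <- drop(cbind(1, grid, grid^2, grid^3) %*% beta_true)
  err_h <- max(abs(predict(fh, grid) - truthv))
  err_ols <- max(abs(predict(ols, data.frame(x = grid)) - truthv))
  expect_lt(err_h, err_ols)

  # an independent robust-regression implementation agrees that the
  # robust fit beats OLS, and ours is at least as close to the truth
  rlm_fit <- MASS::rlm(y_out ~ poly(x, 3, raw = TRUE), psi = MASS::psi.huber)
  err_rlm <- max(abs(predict(rlm_fit, data.frame(x = grid)) - truthv))
  expect_lt(err_rlm, err_ols)
  expect_lt(err_h, err_rlm + 0.1)

  fc <- fit_age_curves(x, rep(3, 15), degree = 3)
  expect_equal(fc$coefficients, c(3, 0, 0, 0), tolerance = 1e-8)
  expect_error(fit_age_curves(x[1:3], y[1:3], degree = 3), "at least")
})

test_that("CSF and single-fibre selections are disjoint on the default phantom", {
  tr <- fx("truth38"); sch <- fx("scheme")
  csf <- select_csf_voxels(fx("dwi_noisy"), sch, dilate_mask(tr$mask, 1L))
  sf <- suppressWarnings(
    select_single_fibre_voxels(fx("dwi_noisy"), sch,
                               erode_mask(tr$mask, 2L), n_keep = 50L))
  expect_length(intersect(as.integer(csf), sf$voxels), 0L)
})
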