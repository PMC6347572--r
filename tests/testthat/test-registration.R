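test_that("reorientation: identity, translation, global rotation", {
  tr <- fx("truth38")
  wm <- fx("reg_channels")$wm
  gs <- grid_shape(wm)

  idf <- identity_field(gs, wm$affine)
  out <- reorient(wm, idf)
  expect_equal(out$data, wm$data, tolerance = 1e-9)
  expect_equal(attr(out, "flagged"), 0L)

  # pure translation: no reorientation, amplitudes preserved up to
  # interpolation error at an interior voxel moved by a whole voxel
  tf <- identity_field(gs, wm$affine)
  tf$disp[, , , 1L] <- 1.5
  out_t <- reorient(wm, tf)
  v <- which(tr$labels == phantom_labels()["bundle_x"])[5]
  a <- arrayInd(v, dim(tr$mask))
  expect_equal(out_t$data[a[1] - 1L, a[2], a[3], ], wm$data[a[1], a[2], a[3], ],
               tolerance = 1e-9)

  # 90-degree rotation of the x-aligned bundle ODF: peak lands on +y
  co <- wm$data[a[1], a[2], a[3], ]
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  co_rot <- drop(neomti:::sh_reorient_matrix(Rz90, wm$lmax) %*% co)
  pk <- find_odf_peaks(co_rot)
  expect_lt(axis_error_deg(pk$directions[1, ], c(0, 1, 0)), 2)
})

test_that("reorientation preserves the ODF integral under volume-preserving maps", {
  wm <- fx("reg_channels")$wm
  tr <- fx("truth38")
  # rotation (volume-preserving): integral = c00 * sqrt(4*pi) unchanged
  v <- which(tr$labels == phantom_labels()["bundle_y"])[4]
  a <- arrayInd(v, dim(tr$mask))
  co <- wm$data[a[1], a[2], a[3], ]
  ang <- 35 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  co_rot <- drop(neomti:::sh_reorient_matrix(R, wm$lmax) %*% co)
  expect_lt(abs(co_rot[1] - co[1]) / co[1], 0.01)
})

test_that("multi-contrast cost: zero at identity, weight handling, brute-force oracle", {
  ch <- fx("reg_channels")
  mv <- list(ch$iso, ch$wm)
  expect_equal(mc_cost(mv, mv), 0)

  # weights (1, 0) equal the single-channel cost
  fx2 <- list(ch$iso, ch$wm)
  mv2 <- lapply(fx2, function(x) sh_volume(x$data * 1.1, affine = x$affine))
  expect_equal(mc_cost(mv2, fx2, weights = c(1, 0)),
               mc_cost(mv2[1], fx2[1]))

  # random pair: brute-force voxel/coefficient summation
  set.seed(2)
  a1 <- sh_volume(array(rnorm(5 * 4 * 3 * 6), c(5, 4, 3, 6)), voxel_size = 2)
  a2 <- sh_volume(array(rnorm(5 * 4 * 3 * 6), c(5, 4, 3, 6)), voxel_size = 2)
  b1 <- sh_volume(array(rnorm(5 * 4 * 3 * 1), c(5, 4, 3, 1)), voxel_size = 2)
  b2 <- sh_volume(array(rnorm(5 * 4 * 3 * 1), c(5, 4, 3, 1)), voxel_size = 2)
  manual <- 0.25 * sum((a1$data - a2$data)^2) + 0.75 * sum((b1$data - b2$data)^2)
  expect_equal(mc_cost(list(a1, b1), list(a2, b2), weights = c(0.25, 0.75)),
               manual, tolerance = 1e-8)

  expect_error(mc_cost(list(a1), list(sh_volume(array(0, c(2, 2, 2, 6)),
                                                voxel_size = 2))),
               "grid mismatch")
})

test_that("rigid registration recovers translations and rotations", {
  ch <- fx("reg_channels")
  mv <- list(ch$iso, ch$wm)
  stages <- list(registration_stage("rigid", 3.0, 2L),
                 registration_stage("rigid", 1.5, 2L))

  # moving = fixed: identity within 0.1 mm / 0.1 degree
  reg0 <- register_rigid_affine(mv, mv, stages = stages)
  expect_lt(sqrt(sum(reg0$affine[1:3, 4]^2)), 0.1)
  expect_lt(max(abs(reg0$affine[1:3, 1:3] - diag(3))), 0.1 * pi / 180 + 1e-6)

  # known 3 mm translation recovered within 0.3 mm
  A_t <- diag(4); A_t[1, 4] <- 3
  mov_t <- warp_channels_affine(mv, A_t)
  reg_t <- register_rigid_affine(mov_t, mv, stages = stages)
  expect_lt(sqrt(sum((reg_t$affine[1:3, 4] - c(-3, 0, 0))^2)), 0.3)

  # known 10-degree rotation about z recovered within 1 degree, with
  # correct reorientation (bundle peak realigned within 2 degrees)
  tr <- fx("truth38")
  a10 <- 10 * pi / 180
  Rz <- diag(4)
  Rz[1:2, 1:2] <- matrix(c(cos(a10), sin(a10), -sin(a10), cos(a10)), 2, 2)
  ctr <- drop(voxel_to_world(matrix((dim(tr$mask) - 1) / 2, 1, 3),
                             tr$affine))
  Rz[1:3, 4] <- ctr - Rz[1:3, 1:3] %*% ctr
  mov_r <- warp_channels_affine(mv, Rz)
  reg_r <- register_rigid_affine(mov_r, mv, stages = stages)
  Rexp <- solve(Rz)[1:3, 1:3]           # pull-back inverse
  Rrec <- reg_r$affine[1:3, 1:3]
  angerr <- acos(pmin(1, (sum(diag(crossprod(Rrec, Rexp))) - 1) / 2)) *
    180 / pi
  expect_lt(angerr, 1)
  back <- warp_channels_affine(mov_r, reg_r$affine)[[2]]
  v <- which(tr$labels == phantom_labels()["bundle_x"])[5]
  aidx <- arrayInd(v, dim(tr$mask))
  pk <- find_odf_peaks(back$data[aidx[1], aidx[2], aidx[3], ])
  expect_lt(axis_error_deg(pk$directions[1, ], c(1, 0, 0)), 2)
})

test_that("nonlinear registration recovers a known smooth warp", {
  ch <- fx("reg_channels")
  tr <- fx("truth38")
  mv <- list(ch$iso, ch$wm)
  wtrue <- random_smooth_field(dim(tr$mask), tr$affine,
                               amplitude_mm = 3, sigma_vox = 3, seed = 11)
  mov <- lapply(mv, function(x) reorient(x, wtrue))
  stages <- list(registration_stage("nonlinear", 3.0, 2L, max_iter = 40L),
                 registration_stage("nonlinear", 1.5, 2L, max_iter = 40L))
  reg <- register_nonlinear(mov, mv, stages = stages)
  err <- wtrue$inverse - reg$forward$disp
  em <- sqrt(apply(err^2, c(1, 2, 3), sum)) / 1.5
  expect_lt(mean(em[tr$mask]), 0.5)
  expect_lt(inverse_consistency_error(reg$forward, tr$mask), 0.1)
  # accepted iterations never increase the cost (within each stage)
  for (tr_c in reg$iter_costs) expect_true(all(diff(tr_c) <= 1e-12))

  # moving = fixed: final cost below initial, tiny field
  reg0 <- register_nonlinear(mv, mv,
                             stages = list(registration_stage("nonlinear",
                                                              3.0, 2L,
                                                              max_iter = 10L)))
  m0 <- sqrt(apply(reg0$forward$disp^2, c(1, 2, 3), sum)) / 1.5
  expect_lt(max(m0), 0.2)
})

test_that("nonlinear registration is symmetric under argument swap", {
  ch <- fx("reg_channels")
  tr <- fx("truth38")
  mv <- list(ch$iso, ch$wm)
  wtrue <- random_smooth_field(dim(tr$mask), tr$affine,
                               amplitude_mm = 2, sigma_vox = 3, seed = 17)
  mov <- lapply(mv, function(x) reorient(x, wtrue))
  stages <- list(registration_stage("nonlinear", 3.0, 2L, max_iter = 30L),
                 registration_stage("nonlinear", 1.5, 2L, max_iter = 30L))
  ab <- register_nonlinear(mov, mv, stages = stages)
  ba <- register_nonlinear(mv, mov, stages = stages)
  d <- ab$forward$disp - ba$inverse$disp
  em <- sqrt(apply(d^2, c(1, 2, 3), sum)) / 1.5
  expect_lt(mean(em[tr$mask]), 0.3)
})
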