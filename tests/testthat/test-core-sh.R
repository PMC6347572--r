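test_that("sh_basis: constant degree-0 term, antipodal symmetry, input checks", {
  d <- fibonacci_sphere(17)
  B0 <- sh_basis(d, 0)
  expect_equal(dim(B0), c(17L, 1L))
  expect_equal(as.numeric(B0), rep(1 / sqrt(4 * pi), 17), tolerance = 1e-12)

  B <- sh_basis(rbind(d, -d), 8)
  expect_equal(B[1:17, ], B[18:34, ], tolerance = 1e-12)

  expect_error(sh_basis(d, 3), "even")
  expect_error(sh_basis(c(0, 0, 0), 4), "zero-norm")
  expect_error(sh_basis(c(0, 0, 1.1), 4), "unit-norm")
})

test_that("basis is orthonormal under dense quadrature", {
  q <- sphere_quadrature(10000)
  B <- sh_basis(q$directions, 8)
  G <- crossprod(B, q$weights * B)
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-3)
})

test_that("eval_sh matches direct term-by-term summation", {
  set.seed(42)
  co <- rnorm(n_sh_coeffs(6))
  d <- fibonacci_sphere(50)
  B <- sh_basis(d, 6)
  direct <- vapply(seq_len(50), function(i)
    sum(B[i, ] * co), 0)  # explicit per-direction summation
  expect_equal(eval_sh(co, d), direct, tolerance = 1e-10)

  iso <- c(1 / sqrt(4 * pi), rep(0, n_sh_coeffs(4) - 1L))
  expect_equal(eval_sh(iso, d), rep(1 / (4 * pi), 50), tolerance = 1e-12)
  expect_equal(eval_sh(rep(0, n_sh_coeffs(2)), d), rep(0, 50))
  expect_error(eval_sh(rep(0, 7), d), "does not match")
})

test_that("Parseval: coefficient norm equals quadrature integral of squared amplitude", {
  set.seed(7)
  co <- rnorm(n_sh_coeffs(8))
  q <- sphere_quadrature(8192)
  amp <- eval_sh(co, q$directions)
  expect_equal(sum(co^2), sum(q$weights * amp^2), tolerance = 1e-3)
})

test_that("forward matrix obeys the spherical convolution theorem", {
  # oracle: numerical spherical convolution on a dense quadrature grid
  r <- zonal_project_function(function(ct) exp(-2.5 * (1 - ct^2)), 8)
  resp <- zonal_response(matrix(r, 1L), 0)
  d <- fibonacci_sphere(30)
  sch <- gradient_scheme(rep(0, 30), d)
  set.seed(3)
  f <- rnorm(n_sh_coeffs(4))
  pred <- zonal_forward_matrix(resp, sch, 4) %*% f

  q <- sphere_quadrature(8192)
  fu <- eval_sh(f, q$directions)
  kz <- numeric(n_sh_coeffs(8))
  kz[sh_degrees(8)$m == 0L] <- r
  num <- vapply(seq_len(30), function(i) {
    ct <- drop(q$directions %*% d[i, ])
    kv <- eval_sh(kz, cbind(sqrt(pmax(0, 1 - ct^2)), 0, ct))
    sum(q$weights * fu * kv)
  }, 0)
  expect_lt(max(abs(pred - num)) / max(abs(num)), 1e-4)
})

test_that("forward matrix: isotropic ODF, zero kernel, shell handling", {
  bv <- c(0, 1000)
  r <- matrix(c(5, 4, 0.5, -0.8), 2, 2)  # l = 0, 2 per shell
  resp <- zonal_response(r, bv)
  d <- fibonacci_sphere(12)
  sch <- gradient_scheme(rep(bv, each = 12), rbind(d, d))

  # unit-density isotropic ODF: signal per shell = mean kernel amplitude,
  # constant over directions
  iso <- c(1 / sqrt(4 * pi), rep(0, n_sh_coeffs(4) - 1L))
  s <- drop(zonal_forward_matrix(resp, sch, 4) %*% iso)
  expect_equal(s[1:12], rep(r[1, 1] / sqrt(4 * pi), 12), tolerance = 1e-12)
  expect_equal(diff(range(s[1:12])), 0, tolerance = 1e-12)
  expect_equal(diff(range(s[13:24])), 0, tolerance = 1e-12)

  zero <- zonal_response(matrix(0, 2, 2), bv)
  expect_true(all(zonal_forward_matrix(zero, sch, 4) == 0))

  other <- zonal_response(matrix(1, 1, 2), 3000)
  expect_error(zonal_forward_matrix(other, sch, 4), "do not cover")

  # degrees above the response lmax act as zero kernel
  Fm <- zonal_forward_matrix(resp, sch, 8)
  idx <- sh_degrees(8)
  expect_true(all(Fm[, idx$l > 2] == 0))
})

test_that("delta ODF convolved along z reproduces the kernel profile", {
  bv <- c(0, 2600)
  k <- phantom_kernels()$old
  resp <- zonal_response(tensor_zonal(bv, k["par"], k["perp"], 8), bv)
  theta <- seq(0, pi, length.out = 25)
  d <- cbind(sin(theta), 0, cos(theta))
  d[1, ] <- c(0, 0, 1); d[25, ] <- c(0, 0, -1)
  sch <- gradient_scheme(rep(2600, 25), d)
  delta <- drop(delta_sh(c(0, 0, 1), 8))
  pred <- drop(zonal_forward_matrix(resp, sch, 8)[, ] %*% delta)
  # oracle: dense quadrature convolution of the truncated delta
  q <- sphere_quadrature(8192)
  fu <- eval_sh(delta, q$directions)
  kz <- numeric(n_sh_coeffs(8)); kz[sh_degrees(8)$m == 0L] <- resp$coeffs[2, ]
  num <- vapply(seq_len(25), function(i) {
    ct <- drop(q$directions %*% d[i, ])
    sum(q$weights * fu * eval_sh(kz, cbind(sqrt(pmax(0, 1 - ct^2)), 0, ct)))
  }, 0)
  expect_lt(max(abs(pred - num)) / max(abs(num)), 1e-3)
})

test_that("zonal rotation: +z / -z identity and rotation-of-argument oracle", {
  bv <- c(0, 1000, 2600)
  k <- phantom_kernels()$young
  resp <- zonal_response(tensor_zonal(bv, k["par"], k["perp"], 8), bv)

  up <- rotate_zonal_to_axis(resp, c(0, 0, 1), 8)
  dn <- rotate_zonal_to_axis(resp, c(0, 0, -1), 8)
  idx <- sh_degrees(8)
  expect_equal(up[, idx$m == 0L], resp$coeffs, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(max(abs(up[, idx$m != 0L])), 0, tolerance = 1e-12)
  expect_equal(up, dn, tolerance = 1e-12)

  rx <- rotate_zonal_to_axis(resp, c(1, 0, 0), 8)
  d100 <- fibonacci_sphere(100)
  R <- rotation_between(c(0, 0, 1), c(1, 0, 0))
  for (s in 1:3) {
    a_rot <- eval_sh(rx[s, ], d100)
    zc <- numeric(n_sh_coeffs(8)); zc[idx$m == 0L] <- resp$coeffs[s, ]
    a_arg <- eval_sh(zc, d100 %*% R)
    expect_equal(a_rot, a_arg, tolerance = 1e-8)
  }

  expect_error(rotate_zonal_to_axis(resp, c(0, 0, 0)), "zero axis")
})

test_that("amplitudes of the even basis are antipodally symmetric", {
  set.seed(11)
  for (lmax in c(2L, 4L, 8L)) {
    co <- rnorm(n_sh_coeffs(lmax))
    d <- fibonacci_sphere(64)
    expect_equal(eval_sh(co, d), eval_sh(co, -d), tolerance = 1e-12)
  }
})
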