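#' Multi-shell acquisition specification
#'
#' Defaults emulate a neonatal multi-shell HARDI protocol: 300 volumes over
#' four shells at b = 0 (n = 20), 400 (n = 64), 1000 (n = 88) and
#' 2600 s/mm^2 (n = 128), 1.5 mm isotropic voxels. The phantom grid is
#' desk-scale (24 x 24 x 16 voxels) rather than brain-scale.
#'
#' @param shell_bvalues numeric vector of shell b-values (s/mm^2).
#' @param shell_counts volumes per shell.
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param grid_shape integer 3-vector.
#' @param snr signal-to-noise ratio referenced to the b = 0 signal.
#' @param noise one of `"rician"` or `"none"`.
#' @param bias_amplitude log-amplitude of the multiplicative bias field
#'   (0 disables it; 0.1 means roughly +/-10% modulation).
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(shell_bvalues = c(0, 400, 1000, 2600),
                             shell_counts = c(20L, 64L, 88L, 128L),
                             voxel_size_mm = 1.5,
                             grid_shape = c(24L, 24L, 16L),
                             snr = 30,
                             noise = c("rician", "none"),
                             bias_amplitude = 0.1) {
  noise <- match.arg(noise)
  stopifnot(length(shell_bvalues) == length(shell_counts),
            all(shell_counts > 0), snr > 0)
  structure(list(shell_bvalues = shell_bvalues,
                 shell_counts = as.integer(shell_counts),
                 voxel_size_mm = voxel_size_mm,
                 grid_shape = as.integer(grid_shape),
                 snr = snr, noise = noise,
                 bias_amplitude = bias_amplitude),
            class = "acquisition_spec")
}

#' Default multi-shell gradient scheme for an acquisition
#'
#' Per-shell near-uniform (Fibonacci hemisphere) direction sets of the
#' stated sizes; each shell's set is decorrelated from the others by a
#' deterministic seed-derived rotation. A shell of size 1 gets the +z
#' direction.
#'
#' @param spec an [acquisition_spec()].
#' @param seed integer; the scheme is fully deterministic given the seed.
#' @return a [gradient_scheme()].
#' @export
default_scheme <- function(spec = acquisition_spec(), seed = 1L) {
  dirs <- NULL; bv <- NULL
  for (s in seq_along(spec$shell_bvalues)) {
    n <- spec$shell_counts[s]
    b <- spec$shell_bvalues[s]
    if (b == 0) {
      d <- matrix(rep(c(0, 0, 1), n), ncol = 3L, byrow = TRUE)
    } else if (n == 1L) {
      d <- matrix(c(0, 0, 1), 1L, 3L)
    } else {
      d <- fibonacci_sphere(n, hemisphere = TRUE)
      ang <- with_local_seed(seed + 1000L * s, stats::runif(3, 0, 2 * pi))
      Rz <- matrix(c(cos(ang[1]), sin(ang[1]), 0,
                     -sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, 3)
      Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                     sin(ang[2]), 0, cos(ang[2])), 3, 3)
      d <- d %*% (Rz %*% Ry)
    }
    dirs <- rbind(dirs, d)
    bv <- c(bv, rep(b, n))
  }
  gradient_scheme(bv, dirs)
}

# --- analytic tissue kernels ------------------------------------------------

# documented phantom diffusivity constants (mm^2/s)
phantom_kernels <- function() {
  list(iso_adc  = 3.0e-3,                       # CSF-like free water
       young    = c(par = 1.9e-3, perp = 1.2e-3), # immature WM: low
                                                  # anisotropy, fast decay
       old      = c(par = 1.7e-3, perp = 0.40e-3)) # mature WM: high
                                                   # anisotropy, slow decay
}

# zonal coefficients of an axially symmetric tensor kernel
tensor_zonal <- function(bvalues, lpar, lperp, lmax, n_quad = 4096) {
  t(vapply(bvalues, function(b) {
    zonal_project_function(function(ct) exp(-b * (lperp + (lpar - lperp) * ct^2)),
                           lmax, n_quad = n_quad)
  }, numeric(lmax / 2 + 1)))
}

#' Analytic phantom response functions
#'
#' Returns the isotropic (CSF-like mono-exponential) kernel and the
#' maturation-weighted anisotropic kernel `(1 - t) * R_y + t * R_o`, where
#' `R_y` and `R_o` are fixed axially symmetric tensor kernels representing
#' immature and mature white matter. With increasing `t` the kernel sharpens
#' and its decay across b-values slows.
#'
#' @param t maturation weight in `[0, 1]`.
#' @param shell_bvalues shell b-values (s/mm^2).
#' @param lmax even degree of the anisotropic kernel (default 8).
#' @return list with `zonal_response` elements `iso` (lmax 0) and `aniso`.
#' @export
analytic_responses <- function(t, shell_bvalues = c(0, 400, 1000, 2600),
                               lmax = 8L) {
  if (length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("maturation weight t must lie in [0, 1]")
  k <- phantom_kernels()
  iso <- zonal_response(
    matrix(exp(-shell_bvalues * k$iso_adc) * sqrt(4 * pi), ncol = 1L),
    shell_bvalues)
  ry <- phantom_wm_kernel("young", shell_bvalues, lmax)
  ro <- phantom_wm_kernel("old", shell_bvalues, lmax)
  aniso <- zonal_response((1 - t) * ry$coeffs + t * ro$coeffs, shell_bvalues)
  list(iso = iso, aniso = aniso)
}

#' Age-extremal phantom WM kernels
#' @param which `"young"` or `"old"`.
#' @param shell_bvalues shell b-values.
#' @param lmax even degree.
#' @return a `zonal_response`.
#' @export
phantom_wm_kernel <- function(which = c("young", "old"),
                              shell_bvalues = c(0, 400, 1000, 2600),
                              lmax = 8L) {
  which <- match.arg(which)
  k <- phantom_kernels()[[which]]
  zonal_response(tensor_zonal(shell_bvalues, k["par"], k["perp"], lmax),
                 shell_bvalues)
}

# --- phantom anatomy --------------------------------------------------------

#' Ground-truth phantom anatomy at a given age
#'
#' Builds the base anatomy on the acquisition grid: an ellipsoidal brain mask, a
#' central CSF "ventricle" block, two orthogonal fibre bundles (one along x,
#' one along y) crossing at 90 degrees in the centre, a one-voxel
#' cortex-like rim with radially oriented fibres, and isotropic-dominated
#' background parenchyma. The maturation weight `t` in `[0, 1]` increases
#' with age and from anterior (+y) to posterior (-y), encoding the
#' posterior-to-anterior maturation gradient; per-voxel anisotropic density
#' splits as `a_young = (1 - t) * rho`, `a_old = t * rho`.
#'
#' @param spec an [acquisition_spec()].
#' @param age_weeks postmenstrual age in weeks; the cohort range 33-44 maps
#'   linearly onto the age factor in `[0, 1]`.
#' @return object of class `phantom_truth`: arrays `iso`, `a_young`,
#'   `a_old`, `t` over the grid, `mask`, integer `labels` (see
#'   `phantom_labels()`), fibre `directions` (`nx x ny x nz x 2 x 3`) and
#'   per-fibre densities `fibre_density` (`... x 2`), plus the affine.
#' @export
phantom_truth <- function(spec = acquisition_spec(), age_weeks = 40) {
  gs <- spec$grid_shape
  nx <- gs[1L]; ny <- gs[2L]; nz <- gs[3L]
  affine <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  idx <- grid_index_matrix(gs)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2; cz <- (nz - 1) / 2
  # ellipsoidal mask with one voxel margin
  r2 <- ((idx[, 1] - cx) / (nx / 2 - 1))^2 +
        ((idx[, 2] - cy) / (ny / 2 - 1))^2 +
        ((idx[, 3] - cz) / (nz / 2 - 1))^2
  mask <- array(r2 <= 1, gs)
  rim <- array(r2 <= 1 & r2 > 0.88, gs)

  lab <- array(0L, gs) # 0 background(out), codes from phantom_labels()
  L <- phantom_labels()
  lab[mask] <- L["background"]
  lab[rim & mask] <- L["cortex"]

  clampi <- function(v, n) pmin(pmax(v, 1L), n)   # robust to small grids
  # central CSF block ("ventricles")
  csf <- array(FALSE, gs)
  csf[clampi((round(cx) - 5):(round(cx) + 6), nx),
      clampi((round(cy) - 5):(round(cy) + 6), ny),
      clampi((round(cz) - 2):(round(cz) + 3), nz)] <- TRUE
  csf <- csf & mask & !rim
  lab[csf] <- L["csf"]

  # bundle A along x (left-right), bundle B along y (posterior-anterior),
  # offset below the ventricles so they cross each other, not the CSF block
  zb <- clampi((round(cz) - 5):(round(cz) - 3), nz)
  bundleA <- array(FALSE, gs); bundleB <- array(FALSE, gs)
  bundleA[, clampi((round(cy) - 2):(round(cy) + 1), ny), zb] <- TRUE
  bundleB[clampi((round(cx) - 2):(round(cx) + 1), nx), , zb] <- TRUE
  bundleA <- bundleA & mask & !rim & !csf
  bundleB <- bundleB & mask & !rim & !csf
  crossing <- bundleA & bundleB
  lab[bundleA] <- L["bundle_x"]
  lab[bundleB] <- L["bundle_y"]
  lab[crossing] <- L["crossing"]

  # maturation weight: ramp with a spatially varying onset — posterior
  # (-y) regions start maturing at 33 weeks, anterior (+y) regions only
  # after ~37 weeks, all reaching full maturity by 44 weeks. The onset
  # delay (not just the amplitude) differs across space, which is what
  # region-wise time courses are meant to detect.
  age_f <- pmin(1, pmax(0, (age_weeks - 33) / (44 - 33)))
  ygrad <- 1 - idx[, 2] / (ny - 1)          # posterior = 1, anterior = 0
  # power-law ramp: maturation rises strictly with age everywhere and
  # reaches 1 at 44 weeks in all voxels, but posterior voxels (exponent
  # 0.7, concave, early-rising) lead anterior voxels (exponent 2.5,
  # convex, late-rising) — so regional time courses differ in onset, not
  # just amplitude
  tfield <- array(age_f^(2.5 - 1.8 * ygrad), gs)

  iso <- array(0, gs)
  fdir <- array(0, c(gs, 2L, 3L))
  fden <- array(0, c(gs, 2L))

  set_fibre <- function(sel, slot, dir_mat, dens) {
    w <- which(sel)
    if (!length(w)) return(invisible())
    if (is.null(dim(dir_mat))) dir_mat <- matrix(dir_mat, length(w), 3,
                                                 byrow = TRUE)
    n <- prod(gs)
    for (c3 in 1:3) fdir[w + n * (slot - 1L) + 2L * n * (c3 - 1L)] <<-
        dir_mat[, c3]
    fden[w + n * (slot - 1L)] <<- dens
  }

  # deep WM carries no free-water compartment: bundle voxels are unit-density
  # single fibres, the crossing splits 50/50
  # summed density is 1 everywhere in the mask (free water plus tissue),
  # matching the unit-density normalisation model
  iso[lab == L["csf"]] <- 1
  iso[lab == L["background"]] <- 0.4
  iso[lab == L["cortex"]] <- 0.65

  set_fibre(lab == L["bundle_x"], 1L, c(1, 0, 0), 1.0)
  set_fibre(lab == L["bundle_y"], 1L, c(0, 1, 0), 1.0)
  set_fibre(lab == L["crossing"], 1L, c(1, 0, 0), 0.5)
  set_fibre(lab == L["crossing"], 2L, c(0, 1, 0), 0.5)
  # background parenchyma: two balanced orthogonal fibres per voxel with
  # spatially incoherent orientation — anisotropic enough to decay unlike
  # free water, but never single-fibre dominant
  wbg <- which(lab == L["background"])
  if (length(wbg)) {
    d1 <- fibonacci_sphere(max(7, length(wbg)))[seq_along(wbg), ,
                                                drop = FALSE]
    ref <- cbind(-d1[, 2], d1[, 1], 0)
    deg <- sqrt(rowSums(ref^2)) < 1e-6
    if (any(deg))
      ref[deg, ] <- matrix(c(1, 0, 0), sum(deg), 3, byrow = TRUE)
    d2 <- ref / sqrt(rowSums(ref^2))
    set_fibre(lab == L["background"], 1L, d1, 0.3)
    set_fibre(lab == L["background"], 2L, d2, 0.3)
  }
  # cortex: radial fibres, moderate density
  wctx <- which(lab == L["cortex"])
  ctxdir <- idx[wctx, , drop = FALSE] - matrix(c(cx, cy, cz),
                                               length(wctx), 3, byrow = TRUE)
  ctxdir <- ctxdir / sqrt(rowSums(ctxdir^2))
  set_fibre(lab == L["cortex"], 1L, ctxdir, 0.35)

  rho <- fden[, , , 1L] + fden[, , , 2L]
  structure(list(iso = iso,
                 a_young = (1 - tfield) * rho,
                 a_old = tfield * rho,
                 t = tfield, mask = mask, labels = lab,
                 directions = fdir, fibre_density = fden,
                 affine = affine, age_weeks = age_weeks, spec = spec),
            class = "phantom_truth")
}

#' Phantom region label codes
#' @return named integer vector.
#' @export
phantom_labels <- function() {
  c(csf = 1L, bundle_x = 2L, bundle_y = 3L, crossing = 4L,
    cortex = 5L, background = 6L)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth: ", paste(dim(x$mask), collapse = " x "),
      " grid, age ", x$age_weeks, " w, ", sum(x$mask), " voxels in mask\n",
      sep = "")
  invisible(x)
}

#' Zonal coefficients of the apodized fibre kernel
#'
#' The phantom's "delta-like" fibre ODF: a Watson-profile lobe
#' `exp(-kappa (1 - (n.u)^2))`, with the concentration chosen automatically
#' as the sharpest value whose band-limited projection remains strictly
#' positive on the sphere (so the true ODF never activates the
#' deconvolution's nonnegativity constraints). Unit integral.
#'
#' @param lmax even degree.
#' @return numeric vector of zonal coefficients (degrees 0, 2, ..., lmax).
#' @export
apodized_fibre_zonal <- local({
  cache <- list()
  function(lmax = 8L) {
    key <- as.character(lmax)
    if (!is.null(cache[[key]])) return(cache[[key]])
    probe <- fibonacci_sphere(4000)
    idx <- sh_degrees(lmax)
    best <- NULL
    for (kap in seq(2, 12, by = 0.25)) {
      z <- zonal_project_function(function(ct) exp(-kap * (1 - ct^2)), lmax)
      z <- z / (z[1L] * sqrt(4 * pi))      # unit integral
      v <- numeric(length(idx$l)); v[idx$m == 0L] <- z
      if (min(sh_basis(probe, lmax) %*% v) >= 1e-4) best <- z else break
    }
    cache[[key]] <<- best
    best
  }
})

#' Effective (dispersion-convolved) phantom response
#'
#' The response function observable in phantom data: the analytic tissue
#' kernel convolved with the apodized fibre ODF, i.e. each degree-l zonal
#' coefficient multiplied by `z_l * sqrt(4*pi / (2l + 1))` where `z_l` are
#' the apodized kernel's zonal coefficients. Response estimation from
#' rendered data recovers this, not the raw kernel — exactly as in-vivo
#' estimates absorb intra-voxel orientation dispersion.
#'
#' @param response an anisotropic [zonal_response()].
#' @return a [zonal_response()] with the same shells and lmax.
#' @export
phantom_effective_response <- function(response) {
  z <- apodized_fibre_zonal(response$lmax)
  l <- seq(0L, response$lmax, by = 2L)
  fac <- z * sqrt(4 * pi / (2 * l + 1))
  zonal_response(sweep(response$coeffs, 2L, fac, "*"),
                 response$shell_bvalues)
}

# full SH coefficients of the apodized fibre kernel aligned with `direction`
apodized_delta_sh <- function(direction, lmax = 8L) {
  z <- apodized_fibre_zonal(lmax)
  resp <- zonal_response(matrix(z, 1L), 0)
  drop(rotate_zonal_to_axis(resp, direction, lmax))
}

# per-voxel SH coefficient matrices (n_coeffs x n_vox) of the three tissues
truth_sh_components <- function(truth, lmax = 8L) {
  gs <- dim(truth$mask)
  nv <- prod(gs)
  nc <- n_sh_coeffs(lmax)
  iso <- matrix(0, 1L, nv)
  # density rho -> c00 = rho / sqrt(4*pi) (density = c00 * sqrt(4*pi))
  iso[1L, ] <- as.numeric(truth$iso) / sqrt(4 * pi)
  ay <- matrix(0, nc, nv); ao <- matrix(0, nc, nv)
  tf <- as.numeric(truth$t)
  # apodized delta = plain delta with per-degree weights w_l (unit integral,
  # strictly positive on the sphere)
  idxl <- sh_degrees(lmax)
  z <- apodized_fibre_zonal(lmax)
  wl <- z[idxl$l / 2 + 1L] * sqrt(4 * pi / (2 * idxl$l + 1))
  for (slot in 1:2) {
    dens <- as.numeric(truth$fibre_density[, , , slot])
    w <- which(dens > 0)
    if (!length(w)) next
    dirs <- cbind(as.numeric(truth$directions[, , , slot, 1L]),
                  as.numeric(truth$directions[, , , slot, 2L]),
                  as.numeric(truth$directions[, , , slot, 3L]))[w, , drop = FALSE]
    D <- delta_sh(dirs, lmax) * wl       # nc x length(w)
    ay[, w] <- ay[, w] + D * rep(dens[w] * (1 - tf[w]), each = nc)
    ao[, w] <- ao[, w] + D * rep(dens[w] * tf[w], each = nc)
  }
  list(iso = iso, ay = ay, ao = ao)
}

# --- rendering --------------------------------------------------------------

#' Render the multi-shell dMRI signal of a phantom
#'
#' Noiseless signal is the sum over tissues of the spherical convolution of
#' each tissue ODF with its kernel: isotropic compartment with the CSF-like
#' kernel, each fibre split between the young kernel (weight `1 - t`) and
#' the old kernel (weight `t`). Optional Rician noise (magnitude of complex
#' Gaussian, sigma = mean in-mask b0 / SNR) and an optional smooth
#' multiplicative polynomial bias field are then applied.
#'
#' @param truth a [phantom_truth()].
#' @param scheme a [gradient_scheme()].
#' @param seed integer seed for noise and bias reproducibility.
#' @param snr SNR at b = 0 (`Inf` for noiseless); default from the acquisition.
#' @param bias_amplitude log-amplitude of the bias field; defaults to the
#'   spec's; 0 disables.
#' @param lmax rendering degree.
#' @return list of class `phantom_dwi`: `signal` (4-D array), `scheme`,
#'   `mask`, `truth`, `bias_field` (3-D array, 1 when disabled), `sigma`.
#' @export
render_phantom <- function(truth, scheme = default_scheme(truth$spec),
                           seed = 1L,
                           snr = truth$spec$snr,
                           bias_amplitude = truth$spec$bias_amplitude,
                           lmax = 8L) {
  if (any(truth$iso < 0) || any(truth$fibre_density < 0))
    stop("negative density in phantom truth")
  comp <- truth_sh_components(truth, lmax)
  bv <- scheme$shell_bvalues
  resp0 <- analytic_responses(0, bv, lmax)
  resp1 <- analytic_responses(1, bv, lmax)
  Fiso <- zonal_forward_matrix(resp0$iso, scheme, 0L)
  Fy <- zonal_forward_matrix(resp0$aniso, scheme, lmax)
  Fo <- zonal_forward_matrix(resp1$aniso, scheme, lmax)
  S <- Fiso %*% comp$iso + Fy %*% comp$ay + Fo %*% comp$ao  # nvol x nvox
  gs <- dim(truth$mask)
  b0mean <- mean(S[scheme$shell_index == 1L, as.logical(truth$mask)])

  bias <- array(1, gs)
  if (bias_amplitude > 0) {
    idx <- grid_index_matrix(gs)
    u <- sweep(idx, 2L, (gs - 1) / 2) / matrix(gs, nrow(idx), 3, byrow = TRUE)
    cf <- with_local_seed(seed + 7L, stats::rnorm(9))
    lf <- cf[1] * u[, 1] + cf[2] * u[, 2] + cf[3] * u[, 3] +
      cf[4] * u[, 1] * u[, 2] + cf[5] * u[, 2] * u[, 3] +
      cf[6] * u[, 1] * u[, 3] +
      cf[7] * u[, 1]^2 + cf[8] * u[, 2]^2 + cf[9] * u[, 3]^2
    inm <- as.logical(truth$mask)
    lf <- lf - mean(lf[inm])
    lf <- lf / max(abs(lf[inm])) * bias_amplitude   # peak in-mask log-amplitude
    bias <- array(exp(lf), gs)
    S <- S * rep(as.numeric(bias), each = nrow(S))
  }

  sigma <- 0
  if (is.finite(snr)) {
    sigma <- b0mean / snr
    nois <- with_local_seed(seed, {
      n1 <- matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
      n2 <- matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
      sqrt((S + n1)^2 + n2^2)
    })
    S <- nois
  }

  signal <- aperm(array(S, c(nrow(S), gs)), c(2, 3, 4, 1))
  structure(list(signal = signal, scheme = scheme, mask = truth$mask,
                 truth = truth, bias_field = bias, sigma = sigma,
                 affine = truth$affine),
            class = "phantom_dwi")
}

#' @export
print.phantom_dwi <- function(x, ...) {
  d <- dim(x$signal)
  cat("phantom_dwi: ", paste(d[1:3], collapse = " x "), " x ", d[4L],
      " volumes, sigma = ", signif(x$sigma, 3), "\n", sep = "")
  invisible(x)
}

# --- cohort -----------------------------------------------------------------

#' Generate a phantom cohort with known inter-subject warps
#'
#' One base anatomy per age, deformed per subject by a random smooth
#' diffeomorphic warp (returned with its exact inverse) and rendered with
#' subject-specific noise. Label, density and maturation fields are pulled
#' back through the warp (nearest-neighbour for labels and fibre sets,
#' preserving discrete structure); fibre directions are reoriented by the
#' local Jacobian.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param ages postmenstrual ages in weeks, recycled to `n_subjects`.
#' @param seed integer master seed.
#' @param spec an [acquisition_spec()].
#' @param warp_amplitude_mm peak warp magnitude (mm); 0 gives identical
#'   anatomies.
#' @return list of class `phantom_cohort`; element `subjects` is a list with
#'   per-subject `dwi` (a `phantom_dwi`), `truth`, `warp`
#'   (a [displacement_field()] mapping subject space to base space) and
#'   `age_weeks`; element `scheme` is the shared gradient scheme.
#' @export
make_cohort <- function(n_subjects, ages = 40, seed = 1L,
                        spec = acquisition_spec(),
                        warp_amplitude_mm = 2) {
  stopifnot(n_subjects >= 2)
  ages <- rep(ages, length.out = n_subjects)
  scheme <- default_scheme(spec, seed = seed)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    base <- phantom_truth(spec, age_weeks = ages[i])
    warp <- random_smooth_field(spec$grid_shape, base$affine,
                                amplitude_mm = warp_amplitude_mm,
                                sigma_vox = 3, seed = seed + 131L * i)
    truth_i <- warp_truth(base, warp)
    dwi <- render_phantom(truth_i, scheme, seed = seed + 977L * i)
    subjects[[i]] <- list(dwi = dwi, truth = truth_i, warp = warp,
                          age_weeks = ages[i])
  }
  structure(list(subjects = subjects, scheme = scheme, spec = spec,
                 ages = ages, seed = seed),
            class = "phantom_cohort")
}

# pull a phantom_truth back through a displacement field (subject(x) =
# base(x + u(x))), reorienting fibre directions by the local Jacobian
warp_truth <- function(truth, warp) {
  gs <- dim(truth$mask)
  xyz <- field_world_grid(warp)
  src <- world_to_voxel(xyz + matrix(warp$disp, prod(gs), 3L), truth$affine)
  out <- truth
  nnpull <- function(a) array(interp_nearest(a, src), dim(a))
  out$labels <- array(as.integer(interp_nearest(truth$labels, src)), gs)
  out$mask <- array(interp_nearest(truth$mask * 1, src) > 0.5, gs)
  out$iso <- nnpull(truth$iso)
  out$t <- nnpull(truth$t)
  for (slot in 1:2) out$fibre_density[, , , slot] <-
      nnpull(truth$fibre_density[, , , slot])
  J <- field_jacobian(warp)
  Jm <- matrix(J, prod(gs), 9L)
  for (slot in 1:2) {
    dm <- interp_nearest(array(truth$directions[, , , slot, ],
                               c(gs, 3L)), src)
    # directions transform by the inverse Jacobian of the pull-back map
    newd <- matrix(0, prod(gs), 3L)
    nz <- rowSums(dm^2) > 0
    for (w in which(nz)) {
      Jv <- matrix(Jm[w, ], 3L, 3L)
      v <- solve(Jv, dm[w, ])
      newd[w, ] <- v / sqrt(sum(v^2))
    }
    out$directions[, , , slot, ] <- array(newd, c(gs, 3L))
  }
  rho <- out$fibre_density[, , , 1L] + out$fibre_density[, , , 2L]
  out$a_young <- (1 - out$t) * rho
  out$a_old <- out$t * rho
  out
}
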