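# Shared fixtures, memoised so each expensive object is built once per run.
.fx <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!is.null(.fx[[name]])) return(.fx[[name]])
  .fx[[name]] <- switch(
    name,
    spec = acquisition_spec(),
    scheme = default_scheme(fx("spec"), seed = 1L),
    truth38 = phantom_truth(fx("spec"), age_weeks = 38),
    # noiseless, bias-free render of the 38-week phantom
    dwi0 = render_phantom(fx("truth38"), fx("scheme"), seed = 1L,
                          snr = Inf, bias_amplitude = 0),
    # default study conditions: SNR 30, 10% bias, seed 1
    dwi_noisy = render_phantom(fx("truth38"), fx("scheme"), seed = 1L),
    responses = {
      bv <- fx("scheme")$shell_bvalues
      list(iso = analytic_responses(0, bv)$iso,
           ay = analytic_responses(0, bv)$aniso,
           ao = analytic_responses(1, bv)$aniso,
           mid = analytic_responses(0.5, bv)$aniso)
    },
    tissues3 = with(fx("responses"), three_tissue_set(iso, ay, ao)),
    tissues2 = with(fx("responses"),
                    tissue_set(c("iso", "wm"), list(iso, mid), c(0L, 8L))),
    fit3_noiseless = msmt_csd(fx("dwi0"), fx("scheme"), fx("tissues3"),
                              fx("truth38")$mask),
    fit3_noisy = msmt_csd(fx("dwi_noisy"), fx("scheme"), fx("tissues3"),
                          fx("truth38")$mask),
    # two-contrast (iso + mid-age WM at lmax 4) registration channels from
    # the noiseless phantom
    reg_channels = {
      bv <- fx("scheme")$shell_bvalues
      ts <- tissue_set(c("iso", "wm"),
                       list(fx("responses")$iso, fx("responses")$mid),
                       c(0L, 4L))
      fit <- msmt_csd(fx("dwi0"), fx("scheme"), ts, fx("truth38")$mask)
      list(iso = fit$components$iso, wm = fit$components$wm)
    },
    stop("unknown fixture: ", name)
  )
  .fx[[name]]
}

# angular error in degrees between two axes (antipodally symmetric)
axis_error_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# true first-fibre direction at a linear voxel index
true_fibre_dir <- function(truth, v, slot = 1L) {
  a <- arrayInd(v, dim(truth$mask))
  truth$directions[a[1L], a[2L], a[3L], slot, ]
}

# Independent brute-force solver for min ||Ax - b||^2 s.t. Gx >= 0
# (test oracle): the dual is the NNLS problem min_{lam >= 0}
# ||R^-T G^T lam + R^-T A^T b||^2 with Q = A^T A = R^T R, solved by a
# from-scratch Lawson-Hanson active-set NNLS; the primal optimum is then
# x = Q^-1 (A^T b + G^T lam). Strong duality makes this exact. The dual is
# solved on a restricted constraint support (grown until the primal is
# feasible), which keeps the passive set small and convergence fast even
# though the dual has far more variables than the problem's rank; the step
# computation guards degenerate (tied/rank-deficient) pivots.
nnls_lawson_hanson <- function(C, d, tol = 1e-10, max_iter = 300L) {
  m <- ncol(C)
  x <- rep(0, m); P <- logical(m)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- drop(crossprod(C, d - C %*% x))
    cand <- which(!P & w > 1e-8 * max(1, max(abs(w))))
    if (!length(cand)) break
    P[cand[which.max(w[cand])]] <- TRUE
    inner <- 0L
    repeat {
      inner <- inner + 1L
      s <- rep(0, m)
      s[P] <- qr.coef(qr(C[, P, drop = FALSE]), d)
      bad <- P & is.na(s)
      if (any(bad)) { P[bad] <- FALSE; s[bad] <- 0; next }
      if (!any(P) || min(s[P]) > tol || inner > 2L * sum(P) + 5L) {
        x <- pmax(s, 0)
        break
      }
      neg <- P & s <= tol
      den <- x[neg] - s[neg]
      ratio <- ifelse(den > tol, x[neg] / den, 0)
      alpha <- min(ratio)
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
  }
  x
}

oracle_constrained_ls <- function(A, b, G) {
  Atb <- drop(crossprod(A, b))
  R <- chol(crossprod(A) + diag(1e-12, ncol(A)))
  x_uc <- backsolve(R, backsolve(R, Atb, transpose = TRUE))
  amp <- drop(G %*% x_uc)
  S <- which(amp < 0.05 * max(abs(amp)))   # near-active constraint support
  if (!length(S)) S <- which.min(amp)
  lam_full <- rep(0, nrow(G))
  x <- drop(x_uc)
  for (round in 1:20) {
    C <- backsolve(R, t(G[S, , drop = FALSE]), transpose = TRUE)
    d <- -backsolve(R, Atb, transpose = TRUE)
    lam <- nnls_lawson_hanson(C, d)
    lam_full[] <- 0; lam_full[S] <- lam
    x <- drop(backsolve(R, backsolve(R, Atb + drop(crossprod(G, lam_full)),
                                     transpose = TRUE)))
    viol <- setdiff(which(drop(G %*% x) < -1e-9), S)
    if (!length(viol)) break
    S <- sort(union(S, viol))
  }
  # KKT polish: exact equality solve on the detected active support; kept
  # only when the multipliers are nonnegative and the primal is feasible
  polish <- function(x, lam_S) {
    act <- S[lam_S > 1e-8 * max(lam_S, 1e-300)]
    if (!length(act)) return(list(ok = min(G %*% x) >= -1e-8, x = x))
    GA <- G[act, , drop = FALSE]
    Q <- crossprod(A) + diag(1e-12, ncol(A))
    K <- rbind(cbind(Q, -t(GA)),
               cbind(GA, matrix(0, length(act), length(act))))
    sol <- try(solve(K, c(Atb, rep(0, length(act)))), silent = TRUE)
    if (inherits(sol, "try-error")) return(list(ok = FALSE, x = x))
    xp <- sol[seq_len(ncol(A))]
    mult <- sol[-seq_len(ncol(A))]
    if (min(mult) >= -1e-8 && min(G %*% xp) >= -1e-8)
      list(ok = TRUE, x = xp) else list(ok = FALSE, x = x)
  }
  p1 <- polish(x, lam_full[S])
  if (p1$ok) return(p1$x)
  # certificate failed (degenerate support): walk an epsilon ladder of
  # primal near-active sets until one passes the KKT certificate
  Q <- crossprod(A) + diag(1e-12, ncol(A))
  amp_x <- drop(G %*% x)
  scale_amp <- max(abs(amp_x), 1e-300)
  for (eps in c(1e-8, 1e-6, 1e-5, 1e-4, 1e-3) * scale_amp) {
    act <- which(amp_x < eps)
    if (!length(act) || length(act) >= ncol(A)) next
    GA <- G[act, , drop = FALSE]
    K <- rbind(cbind(Q, -t(GA)),
               cbind(GA, matrix(0, length(act), length(act))))
    sol <- try(solve(K, c(Atb, rep(0, length(act)))), silent = TRUE)
    if (inherits(sol, "try-error")) next
    xp <- sol[seq_len(ncol(A))]
    mult <- sol[-seq_len(ncol(A))]
    if (min(mult) >= -1e-8 && min(G %*% xp) >= -1e-8) return(xp)
  }
  x
}
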