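#' Multi-shell gradient scheme
#'
#' Bundles per-volume diffusion gradient directions and b-values, grouped
#' into shells. A volume belongs to a shell when its b-value lies within
#' `shell_tol` (default 50 s/mm^2) of the shell centre; the representative
#' shell b-value is the mean over member volumes. Zero gradient vectors are
#' only admissible at b = 0 and are stored as +z.
#'
#' @param bvalues numeric vector of per-volume b-values (s/mm^2).
#' @param directions `n x 3` matrix of gradient directions (unit vectors;
#'   zero vectors allowed at b = 0).
#' @param shell_tol shell-grouping half-width in s/mm^2.
#' @return an object of class `gradient_scheme` with fields `directions`,
#'   `bvalues`, `shell_index` (1-based shell per volume) and `shell_bvalues`.
#' @export
gradient_scheme <- function(bvalues, directions, shell_tol = 50) {
  directions <- as_direction_matrix(directions)
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stop("directions (", nrow(directions), ") and bvalues (",
         length(bvalues), ") count mismatch")
  nrm <- sqrt(rowSums(directions^2))
  zero <- nrm < 1e-8
  if (any(zero & bvalues > shell_tol))
    stop("zero gradient vector at b > 0")
  if (any(zero)) {
    directions[zero, ] <- matrix(c(0, 0, 1), sum(zero), 3, byrow = TRUE)
    nrm[zero] <- 1
  }
  if (any(abs(nrm - 1) > 1e-3))
    warning("non-unit gradient vectors renormalised (max deviation ",
            signif(max(abs(nrm - 1)), 3), ")")
  directions <- directions / nrm

  ord <- order(bvalues)
  shell_of <- integer(length(bvalues))
  centres <- numeric(0)
  members <- list()
  for (i in ord) {
    b <- bvalues[i]
    hit <- which(abs(centres - b) <= shell_tol)
    if (length(hit) >= 1L) {
      k <- hit[1L]
      members[[k]] <- c(members[[k]], i)
      centres[k] <- mean(bvalues[members[[k]]])
    } else {
      centres <- c(centres, b)
      members[[length(centres)]] <- i
    }
    shell_of[i] <- 0L # assigned below once centres are final
  }
  # final assignment with settled centres, in ascending-b shell order
  ordc <- order(centres)
  shell_bvalues <- vapply(members[ordc], function(ix) mean(bvalues[ix]), 0)
  for (k in seq_along(ordc)) shell_of[members[[ordc[k]]]] <- k

  structure(
    list(directions = directions, bvalues = bvalues,
         shell_index = shell_of, shell_bvalues = shell_bvalues,
         shell_tol = shell_tol),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("gradient_scheme:", length(x$bvalues), "volumes,",
      length(x$shell_bvalues), "shells\n")
  n <- tabulate(x$shell_index, nbins = length(x$shell_bvalues))
  cat(sprintf("  b = %s (n = %s)\n",
              paste(round(x$shell_bvalues), collapse = "/"),
              paste(n, collapse = "/")))
  invisible(x)
}

#' Number of shells / volumes of a scheme
#' @param scheme a `gradient_scheme`.
#' @return integer count.
#' @export
n_shells <- function(scheme) length(scheme$shell_bvalues)

#' @rdname n_shells
#' @export
n_volumes <- function(scheme) length(scheme$bvalues)

#' Volume indices of one shell
#' @param scheme a `gradient_scheme`.
#' @param shell 1-based shell index (ascending b).
#' @return integer vector of volume indices.
#' @export
shell_volumes <- function(scheme, shell) which(scheme$shell_index == shell)
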