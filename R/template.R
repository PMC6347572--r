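#' The full 28-stage template-building schedule
#'
#' Six rigid followed by six affine stages with voxel sizes decreasing from
#' 3.3 mm to 1 mm (within each block: lmax 2 for the first four stages,
#' lmax 4 thereafter), then 16 nonlinear stages: eight stepping 3.3 mm to
#' 1 mm at lmax 2, then eight at full resolution with lmax 4. Update and
#' displacement smoothing are 2.0 and 1.0 times the stage voxel size
#' throughout.
#'
#' @param max_iter per-stage iteration cap.
#' @return list of 28 [registration_stage()]s.
#' @export
default_schedule <- function(max_iter = 30L) {
  out <- list()
  vox6 <- seq(3.3, 1.0, length.out = 6L)
  lmax6 <- c(2L, 2L, 2L, 2L, 4L, 4L)
  for (i in 1:6) out[[length(out) + 1L]] <-
    registration_stage("rigid", vox6[i], lmax6[i], max_iter = max_iter)
  for (i in 1:6) out[[length(out) + 1L]] <-
    registration_stage("affine", vox6[i], lmax6[i], max_iter = max_iter)
  vox8 <- seq(3.3, 1.0, length.out = 8L)
  for (i in 1:8) out[[length(out) + 1L]] <-
    registration_stage("nonlinear", vox8[i], 2L, max_iter = max_iter)
  for (i in 1:8) out[[length(out) + 1L]] <-
    registration_stage("nonlinear", 1.0, 4L, max_iter = max_iter)
  out
}

#' Reduced desk-scale schedule (default for template building)
#'
#' Six stages — two rigid, one affine, three nonlinear — at resolutions
#' suited to the 24 x 24 x 16 phantom grid. The full 28-stage schedule
#' ([default_schedule()]) remains available via the `schedule` argument of
#' [build_template()].
#'
#' @param max_iter per-stage iteration cap.
#' @return list of 6 [registration_stage()]s.
#' @export
desk_schedule <- function(max_iter = 25L) {
  list(registration_stage("rigid", 3.0, 2L, max_iter = max_iter),
       registration_stage("rigid", 2.0, 2L, max_iter = max_iter),
       registration_stage("affine", 2.0, 2L, max_iter = max_iter),
       registration_stage("nonlinear", 3.0, 2L, max_iter = max_iter),
       registration_stage("nonlinear", 1.5, 2L, max_iter = max_iter),
       registration_stage("nonlinear", 1.5, 4L, max_iter = max_iter))
}

# apply a subject's composed transform (one interpolation) to its channels
apply_subject_transform <- function(channels, tf, reorient_odf = TRUE) {
  lapply(channels, function(ch) reorient(ch, tf, reorient = reorient_odf))
}

# mean of channel lists
average_channels <- function(list_of_channel_sets) {
  n <- length(list_of_channel_sets)
  out <- list_of_channel_sets[[1L]]
  for (i in seq_along(out)) {
    acc <- out[[i]]$data
    for (j in 2:n) acc <- acc + list_of_channel_sets[[j]][[i]]$data
    out[[i]] <- sh_volume(acc / n, affine = out[[i]]$affine)
  }
  out
}

# mean ODF peak amplitude over up-to-`n_sample` voxels with the strongest
# anisotropic energy (template sharpness proxy)
template_sharpness <- function(channels, n_sample = 40L) {
  ch <- channels[[length(channels)]]      # anisotropic channel
  if (ch$lmax == 0L) return(NA_real_)
  gs <- grid_shape(ch)
  en <- matrix(ch$data, prod(gs), dim(ch$data)[4L])
  pw <- rowSums(en[, -1L, drop = FALSE]^2)
  vox <- order(-pw)[seq_len(min(n_sample, sum(pw > 0)))]
  g <- peak_grid(120L, ch$lmax)
  mean(apply(en[vox, , drop = FALSE] %*% t(g$basis), 1L, max))
}

#' Unbiased groupwise template construction
#'
#' Iterates over the schedule: at every stage each subject is registered to
#' the leave-one-out average of the other subjects' currently transformed
#' images, its composed transform is updated, and the average is rebuilt.
#' Rigid and affine corrections compose into the subject's affine; nonlinear
#' corrections compose into its displacement field. After every nonlinear
#' stage the mean displacement over subjects is subtracted from all
#' transforms (warp demeaning), keeping the template unbiased. Each
#' subject's image is always resampled exactly once, through its composed
#' transform.
#'
#' @param images list of channel-sets (each a list of [sh_volume()]s on a
#'   common grid).
#' @param schedule list of [registration_stage()]s; default
#'   [desk_schedule()].
#' @param weights per-channel registration weights.
#' @param verbose print stage progress.
#' @return list of class `template_build`: `template` (channel-set),
#'   `transforms` (per-subject [displacement_field()]s, pull-back from
#'   template space to subject space), `affines`, `sharpness` (element 1:
#'   unaligned baseline, then one value per stage), `cost_log`.
#' @export
build_template <- function(images, schedule = desk_schedule(),
                           weights = NULL, verbose = FALSE) {
  n <- length(images)
  stopifnot(n >= 2L)
  gs <- grid_shape(images[[1L]][[1L]])
  aff <- images[[1L]][[1L]]$affine
  affines <- rep(list(diag(4)), n)
  fields <- rep(list(NULL), n)            # nonlinear part (template grid)
  cost_log <- list()

  # total pull-back: image(x) = orig(A_i(phi_nl(x))) — the affine (settled
  # in the rigid/affine block, which precedes all nonlinear stages) is
  # applied after the nonlinear part
  composed_transform <- function(i) {
    af <- affine_to_field(affines[[i]], gs, aff)
    if (is.null(fields[[i]])) af else compose_fields(af, fields[[i]])
  }
  transform_subject <- function(i) {
    if (is.null(fields[[i]]))            # constant Jacobian: fast path
      warp_channels_affine(images[[i]], affines[[i]])
    else
      apply_subject_transform(images[[i]], composed_transform(i))
  }

  transformed <- lapply(seq_len(n), transform_subject)
  # stage-0 baseline: sharpness of the unaligned average
  sharp <- template_sharpness(average_channels(transformed))

  for (si in seq_along(schedule)) {
    st <- schedule[[si]]
    tot <- lapply(seq_along(transformed[[1L]]), function(ci) {
      acc <- transformed[[1L]][[ci]]$data
      for (j in 2:n) acc <- acc + transformed[[j]][[ci]]$data
      acc
    })
    stage_costs <- numeric(n)
    for (i in seq_len(n)) {
      loo <- lapply(seq_along(tot), function(ci) {
        sh_volume((tot[[ci]] - transformed[[i]][[ci]]$data) / (n - 1L),
                  affine = aff)
      })
      if (st$transform %in% c("rigid", "affine")) {
        reg <- register_rigid_affine(transformed[[i]], loo,
                                     stages = list(st), weights = weights)
        affines[[i]] <- affines[[i]] %*% reg$affine
        stage_costs[i] <- reg$cost
      } else {
        reg <- register_nonlinear(transformed[[i]], loo,
                                  stages = list(st), weights = weights)
        corr <- reg$forward
        fields[[i]] <- if (is.null(fields[[i]])) corr else
          compose_fields(fields[[i]], corr)
        stage_costs[i] <- utils::tail(reg$cost_trace, 1L)
      }
      transformed[[i]] <- transform_subject(i)
      tot <- lapply(seq_along(tot), function(ci)
        (loo[[ci]]$data * (n - 1L)) + transformed[[i]][[ci]]$data)
    }
    if (st$transform %in% c("rigid", "affine")) {
      # affine demeaning: remove the (element-wise mean) group transform so
      # the template does not drift; exact for translations, first-order
      # for rotations/scalings
      M <- Reduce(`+`, affines) / n
      Minv <- solve(M)
      for (i in seq_len(n)) affines[[i]] <- affines[[i]] %*% Minv
      transformed <- lapply(seq_len(n), transform_subject)
    }
    if (st$transform == "nonlinear") {
      # warp demeaning: subtract the voxel-wise mean displacement
      mu <- Reduce(`+`, lapply(fields, function(f) f$disp)) / n
      if (max(abs(mu)) > 1e-9) {
        for (i in seq_len(n)) {
          fields[[i]] <- displacement_field(fields[[i]]$disp - mu, aff)
        }
        transformed <- lapply(seq_len(n), transform_subject)
      }
    }
    template <- average_channels(transformed)
    sharp <- c(sharp, template_sharpness(template))
    cost_log[[si]] <- stage_costs
    if (verbose)
      message(sprintf("stage %d/%d (%s %.2f mm): mean cost %.5g",
                      si, length(schedule), st$transform, st$voxel_size_mm,
                      mean(stage_costs)))
  }
  transforms <- lapply(seq_len(n), function(i) {
    tf <- composed_transform(i)
    inv <- invert_field(tf)
    tf$inverse <- inv$disp
    tf
  })
  structure(list(template = template, transforms = transforms,
                 affines = affines, fields = fields,
                 sharpness = sharp, cost_log = cost_log,
                 schedule = schedule),
            class = "template_build")
}

#' @export
print.template_build <- function(x, ...) {
  cat("template_build:", length(x$transforms), "subjects,",
      length(x$schedule), "stages; sharpness",
      paste(signif(x$sharpness, 3), collapse = " -> "), "\n")
  invisible(x)
}

#' Weekly templates in a single common space
#'
#' Builds one common template from all subjects, then averages each weekly
#' group's transformed images (using the common-template transforms, so
#' each subject is interpolated exactly once end-to-end).
#'
#' @param images list of channel-sets.
#' @param weeks group label per subject (e.g. integer week); every group
#'   needs >= 2 subjects.
#' @param schedule list of [registration_stage()]s.
#' @param weights per-channel weights.
#' @param verbose print progress.
#' @return list of class `weekly_templates`: `common` (the
#'   [build_template()] result), `weekly` (named list: week -> channel
#'   set), `weeks`.
#' @export
build_weekly_and_common <- function(images, weeks,
                                    schedule = desk_schedule(),
                                    weights = NULL, verbose = FALSE) {
  stopifnot(length(images) == length(weeks))
  tb <- table(weeks)
  if (any(tb < 2L))
    stop("week group(s) with < 2 subjects: ",
         paste(names(tb)[tb < 2L], collapse = ", "))
  common <- build_template(images, schedule = schedule, weights = weights,
                           verbose = verbose)
  transformed <- lapply(seq_along(images), function(i)
    apply_subject_transform(images[[i]], common$transforms[[i]]))
  wk_levels <- sort(unique(weeks))
  weekly <- lapply(wk_levels, function(wk)
    average_channels(transformed[weeks == wk]))
  names(weekly) <- as.character(wk_levels)
  structure(list(common = common, weekly = weekly, weeks = weeks),
            class = "weekly_templates")
}

#' @export
print.weekly_templates <- function(x, ...) {
  cat("weekly_templates:", length(x$weekly), "weeks (",
      paste(names(x$weekly), collapse = ", "), ")\n")
  invisible(x)
}
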