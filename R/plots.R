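#' Plot per-shell response-function profiles
#'
#' Shows each shell's signal profile as a function of the angle to the
#' fibre axis, evaluated from the zonal coefficients.
#'
#' @param response a [zonal_response()].
#' @param n_angles angular sampling density.
#' @return a ggplot object.
#' @export
plot_response <- function(response, n_angles = 91L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  theta <- seq(0, pi / 2, length.out = n_angles)
  dirs <- cbind(sin(theta), 0, cos(theta))
  rows <- list()
  for (s in seq_len(nrow(response$coeffs))) {
    full <- drop(rotate_zonal_to_axis(
      zonal_response(response$coeffs[s, , drop = FALSE],
                     response$shell_bvalues[s]),
      c(0, 0, 1), response$lmax))
    rows[[s]] <- tibble::tibble(
      b = response$shell_bvalues[s],
      angle_deg = theta * 180 / pi,
      signal = drop(sh_basis(dirs, response$lmax) %*% full))
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, y = .data$signal,
                                   colour = factor(.data$b))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "angle to fibre axis (degrees)", y = "signal",
                  colour = "b (s/mm²)") +
    ggplot2::theme_minimal()
}

#' Plot ROI time-courses
#'
#' Mean component density per week with across-voxel SD ribbons, faceted
#' by region.
#'
#' @param timecourses tibble from [roi_timecourses()].
#' @param rois optional subset of ROI names.
#' @return a ggplot object.
#' @export
plot_timecourses <- function(timecourses, rois = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- timecourses
  if (!is.null(rois)) df <- df[df$roi %in% rois, ]
  df$week_num <- as.numeric(df$week)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$week_num, y = .data$mean,
                                   colour = .data$tissue,
                                   fill = .data$tissue)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "postmenstrual age (weeks)",
                  y = "mean DC amplitude") +
    ggplot2::theme_minimal()
}
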