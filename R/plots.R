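#' Plot a distance-conditioned gray value probability distribution
#'
#' Heat map of the GVPD (distance bins on the x axis, gray values on the
#' y axis, per-bin probability as fill) with an optional moving-average
#' gray curve overlaid.
#'
#' @param gvpd output of [compute_gvpd()].
#' @param curve optional output of [moving_average_curve()].
#' @return A ggplot object.
#' @export
plot_gvpd <- function(gvpd, curve = NULL) {
  keep <- which(gvpd$nonempty)
  df <- expand.grid(distance = gvpd$bin_centers[keep], gray = 0:255)
  df$prob <- as.vector(gvpd$probs[keep, , drop = FALSE])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$gray,
                                        fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "probability", trans = "sqrt") +
    ggplot2::labs(x = "distance from reference [µm]",
                  y = "gray value") +
    ggplot2::theme_minimal()
  if (!is.null(curve))
    p <- p + ggplot2::geom_line(
      data = curve, inherit.aes = FALSE,
      ggplot2::aes(x = .data$distance, y = .data$mean_gray), color = "black")
  p
}

#' Plot the mineralized-fraction profile and its transition zone
#'
#' @param profile output of [mineral_profile()].
#' @param zone optional output of [detect_transition_zone()]; drawn as
#'   dashed verticals at the 5% and 95% crossings.
#' @return A ggplot object.
#' @export
plot_mineral_profile <- function(profile, zone = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin_center,
                                             y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from Haversian canal [µm]",
                  y = expression(V[MM] / V[TM])) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(zone))
    p <- p + ggplot2::geom_vline(xintercept = c(zone$front, zone$end),
                                 linetype = "dashed", color = "red")
  p
}

#' Plot ring-shell mineral fractions across stages
#'
#' One line per shell distance D, stages ordered along the x axis;
#' error bars show the standard error across replicate regions.
#'
#' @param shells a [shell_profile()].
#' @return A ggplot object.
#' @export
plot_shell_profile <- function(shells) {
  df <- as.data.frame(shells)
  stage_order <- c("0", "UNSTAGED", "I", "II", "III", "IV", "V")
  df$stage <- factor(df$stage, levels = intersect(stage_order, df$stage))
  df$D <- factor(df$D)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$mean_fraction,
                                   color = .data$D, group = .data$D)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_fraction - .data$se,
                                        ymax = .data$mean_fraction + .data$se),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::labs(x = "mineralization stage",
                  y = expression(V[MM] / V[TM]),
                  color = "D [µm]") +
    ggplot2::theme_minimal()
}

#' Plot a volume-weighted foci histogram
#'
#' @param fh a [foci_histogram()].
#' @return A ggplot object.
#' @export
plot_foci_histogram <- function(fh) {
  if (fh$n_foci == 0) stop("empty foci histogram")
  dc <- head(fh$dist_breaks, -1) + diff(fh$dist_breaks) / 2
  vc <- sqrt(head(fh$vol_breaks, -1) * tail(fh$vol_breaks, -1))
  df <- expand.grid(distance = dc, volume = vc)
  df$prob <- as.vector(fh$cells)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$volume,
                                   fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "volume-weighted\nprobability") +
    ggplot2::labs(x = "distance to nearest canaliculus [µm]",
                  y = expression("focus volume [" * µ * m^3 * "]"),
                  title = sprintf("group %s (n = %d)", fh$group, fh$n_foci)) +
    ggplot2::theme_minimal()
}

# write a plot without requiring an interactive device
save_plot <- function(p, path, width = 7, height = 5) {
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
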