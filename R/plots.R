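# ggplot2 helpers for the standard result types.

#' Plot group speed-distribution curves
#'
#' Mean per-bin percentage of frame-to-frame step speeds per group, with a
#' ribbon of +/- 1 SEM across animals.
#'
#' @param profile A group profile from [group_speed_profile()].
#' @return A ggplot object.
#' @export
plot_speed_profile <- function(profile) {
  p <- as_tibble(profile)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$bin_mid, y = .data$mean_pct,
                                  colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                                      ymax = .data$mean_pct + .data$sem_pct),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame-to-frame speed (µm/s)",
                  y = "% of steps (mean ± SEM across animals)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_classic()
}

#' Plot a per-animal metric by group
#'
#' One point per animal with the group mean +/- SEM overlaid, the standard
#' presentation for animal-level transport metrics.
#'
#' @param summary A per-animal summary ([animal_summary()] /
#'   [quantify_cohort()]).
#' @param metric Name of the metric column (default mean speed).
#' @return A ggplot object.
#' @export
plot_animal_metric <- function(summary, metric = "mean_speed_um_s") {
  s <- as_tibble(summary)
  stopifnot(metric %in% names(s))
  agg <- dplyr::summarise(
    dplyr::group_by(s, .data$group),
    m = mean(.data[[metric]]),
    sem = stats::sd(.data[[metric]]) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(s, ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::geom_pointrange(
      data = agg,
      ggplot2::aes(x = .data$group, y = .data$m,
                   ymin = .data$m - .data$sem, ymax = .data$m + .data$sem),
      inherit.aes = FALSE, colour = "red3", shape = 3
    ) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}

#' Autoplot a group comparison
#'
#' Contrast estimates with adjusted p-value annotations.
#'
#' @param object An `endo_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.endo_comparison <- function(object, ...) {
  cc <- object$contrasts
  cc$label <- sprintf("adj p = %.3g", cc$p_adjusted)
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$contrast, y = .data$estimate)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4,
                       size = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "red3", `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = sprintf("estimate (%s)", object$metric),
                  title = sprintf("%s — %s", object$metric, object$test)) +
    ggplot2::theme_classic()
}
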