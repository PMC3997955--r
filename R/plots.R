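#' Plot group means with Duncan letters
#'
#' Bar chart of the group means with standard-error bars and the compact
#' letter display above each bar — the usual presentation of a phenotyping
#' comparison.
#'
#' @param object A [duncan_mrt()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.duncan_mrt <- function(object, ...) {
  df <- object$groups
  df$group <- factor(df$group, levels = df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se), width = 0.25) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$mean + .data$se, label = .data$letters),
      vjust = -0.6) +
    ggplot2::labs(x = NULL, y = "mean",
                  subtitle = sprintf(
                    "Duncan's test, alpha = %g; shared letters = not separated",
                    object$alpha)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot wilting and recovery time courses
#'
#' Non-withered (solid) and recovered (dashed) percentage curves per
#' cultivar over the observation days.
#'
#' @param timecourses Long-form time-course table (`cultivar`, `day`,
#'   `d_pct`, `r_pct`).
#' @return A ggplot.
#' @export
plot_timecourses <- function(timecourses) {
  long <- tidyr::pivot_longer(timecourses, c("d_pct", "r_pct"),
                              names_to = "curve", values_to = "pct")
  long$curve <- dplyr::recode(long$curve, d_pct = "non-withered (drought)",
                              r_pct = "recovered (re-irrigation)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$pct,
                                     colour = .data$cultivar,
                                     linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "day", y = "% of plants", colour = NULL,
                  linetype = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot soil moisture monitoring series
#'
#' @param smc Soil-moisture table (`cultivar`, `condition`, `day`, `smc`).
#' @return A ggplot.
#' @export
plot_smc <- function(smc) {
  ggplot2::ggplot(smc, ggplot2::aes(x = .data$day, y = .data$smc,
                                    colour = .data$cultivar)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "day", y = "soil moisture content (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
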