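#' Plot a stability profile
#'
#' Bar chart of the whole-brain and per-network temporal correlation
#' coefficients of one subject.
#'
#' @param object A `stability_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_profile
#' @export
autoplot.stability_profile <- function(object, ...) {
  dat <- tidy(object)
  dat <- dat[dat$level != "node", ]
  dat$unit <- factor(dat$unit, levels = unique(dat$unit))
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$unit,
                               y = .data$temporal_correlation)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "temporal correlation coefficient",
      title = paste0("Temporal stability: ", object$subject_id)
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Group comparison plot of cohort stability
#'
#' Boxplots of whole-brain and per-network temporal correlation
#' coefficients split by group.
#'
#' @param profiles List of `stability_profile` objects.
#' @param pheno Phenotype table with `subject_id` and `group`.
#' @return A ggplot object.
#' @export
plot_group_stability <- function(profiles, pheno) {
  dat <- tidy_profiles(profiles, level = c("whole_brain", "network"))
  dat <- dplyr::inner_join(dat, pheno[, c("subject_id", "group")],
                           by = "subject_id")
  dat$unit <- factor(dat$unit, levels = unique(dat$unit))
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$unit,
                               y = .data$temporal_correlation,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "temporal correlation coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
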