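#' Plot per-plot NRI values
#'
#' Points by plot, coloured by site; filled symbols mark plots whose rank
#' test is significant. The dashed line at 0 is the random-assembly
#' expectation.
#'
#' @param object A `phylocomm_nri` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phylocomm_nri <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[is.finite(d$nri), ]
  d$significant <- isTRUE_vec(d$significant)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$plot, y = .data$nri,
                                  colour = .data$site, shape = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(y = "NRI", x = NULL, shape = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Plot a conservatism-test null distribution
#'
#' Histogram of tip-permutation scores with the observed score marked;
#' a conserved trait sits in the left tail.
#'
#' @param object A `phylocomm_cons` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phylocomm_cons <- function(object, ...) {
  d <- tibble::tibble(score = object$perm_scores)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = paste(object$type, "score"), y = "permutations",
                  title = sprintf("observed = %.3g, p = %.3g",
                                  object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot group means with Tukey letters
#'
#' Mean +/- 1 SD per group, annotated with the compact letter display:
#' groups sharing a letter do not differ significantly.
#'
#' @param object A `phylocomm_anova` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phylocomm_anova <- function(object, ...) {
  d <- object$letters
  d$sd0 <- ifelse(is.na(d$sd), 0, d$sd)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd0,
                                        ymax = .data$mean + .data$sd0),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + .data$sd0, label = .data$letters),
                       vjust = -0.6) +
    ggplot2::labs(x = object$by, y = paste0(object$element, " (permil)")) +
    ggplot2::theme_minimal()
}

#' Plot NRI against the environmental gradients
#'
#' Scatter of NRI versus rainfall, elevation and temperature with least
#' squares lines, faceted by variable, annotated with Pearson r.
#'
#' @param nri_env A `phylocomm_nri_env` object.
#' @param nri_results,env The tables given to
#'   [correlate_nri_environment()].
#' @return A ggplot.
#' @export
plot_nri_environment <- function(nri_env, nri_results, env) {
  vars <- c("rainfall_mm", "elevation_m", "temperature_C")
  d <- dplyr::inner_join(
    tibble::tibble(plot = nri_results$plot, nri = nri_results$nri),
    tibble::as_tibble(env), by = "plot")
  d <- d[is.finite(d$nri), ]
  long <- tidyr::pivot_longer(d, dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  lab <- nri_env$correlations
  lab$text <- sprintf("r = %.3f, p = %.3g", lab$r, lab$p)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$nri)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$site)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$text),
                       x = Inf, y = Inf, hjust = 1.05, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(y = "NRI", x = NULL) +
    ggplot2::theme_minimal()
}
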