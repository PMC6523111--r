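#' Tidy a Fitch reconstruction
#'
#' @param x A `phylocomm_fitch` object.
#' @param ... Unused.
#' @return Tibble, one row per node: `node`, `label`, `is_tip`,
#'   `mpr_states` (states in some MPR, pipe-separated), `resolved`.
#' @export
tidy.phylocomm_fitch <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  n_all <- n_tip + x$tree$Nnode
  tibble::tibble(
    node = seq_len(n_all),
    label = node_names(x$tree),
    is_tip = seq_len(n_all) <= n_tip,
    mpr_states = apply(x$node_sets, 1, function(r) paste(x$states[r], collapse = "|")),
    resolved = unname(x$resolved)
  )
}

#' Tidy a squared-change reconstruction
#'
#' @param x A `phylocomm_sqcp` object.
#' @param ... Unused.
#' @return Tibble: `node`, `label`, `is_tip`, `value`.
#' @export
tidy.phylocomm_sqcp <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  n_all <- n_tip + x$tree$Nnode
  tibble::tibble(node = seq_len(n_all), label = node_names(x$tree),
                 is_tip = seq_len(n_all) <= n_tip, value = unname(x$values))
}

#' @rdname tidy.phylocomm_sqcp
#' @export
glance.phylocomm_sqcp <- function(x, ...) {
  tibble::tibble(score = x$score, branch_weighted = x$branch_weighted,
                 n_tips = length(x$tree$tip.label))
}

#' @rdname tidy.phylocomm_fitch
#' @export
glance.phylocomm_fitch <- function(x, ...) {
  tibble::tibble(score = x$score, n_states = length(x$states),
                 n_tips = length(x$tree$tip.label))
}

#' Tidy / glance a conservatism test
#'
#' @param x A `phylocomm_cons` object.
#' @param ... Unused.
#' @return `glance()`: one row with `observed`, `p_value`, `n_perm`,
#'   `type`; `tidy()`: the permuted scores.
#' @export
glance.phylocomm_cons <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p_value,
                 n_perm = x$n_perm, type = x$type)
}

#' @rdname glance.phylocomm_cons
#' @export
tidy.phylocomm_cons <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$perm_scores), score = x$perm_scores)
}

#' Tidy / glance an ANOVA + Tukey result
#'
#' @param x A `phylocomm_anova` object.
#' @param ... Unused.
#' @return `tidy()`: the Tukey HSD pairs (`comparison`, `diff`, `lwr`,
#'   `upr`, `p_adj`); `glance()`: the omnibus row.
#' @export
tidy.phylocomm_anova <- function(x, ...) x$pairs

#' @rdname tidy.phylocomm_anova
#' @export
glance.phylocomm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p,
                 element = x$element, by = x$by)
}

#' Tidy an NRI-environment correlation
#'
#' @param x A `phylocomm_nri_env` object.
#' @param ... Unused.
#' @return The per-variable Pearson correlation tibble.
#' @export
tidy.phylocomm_nri_env <- function(x, ...) x$correlations

#' Summaries of an NRI table
#'
#' @param x A `phylocomm_nri` tibble.
#' @param ... Unused.
#' @return `glance()`: one row per site with mean/SD NRI and counts of
#'   significant plots.
#' @export
glance.phylocomm_nri <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      n_plots = dplyr::n(),
      mean_nri = mean(.data$nri, na.rm = TRUE),
      sd_nri = sd(.data$nri, na.rm = TRUE),
      n_clustered = sum(.data$direction == "clustered", na.rm = TRUE),
      n_overdispersed = sum(.data$direction == "overdispersed", na.rm = TRUE),
      .groups = "drop")
}
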