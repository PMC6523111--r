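#' Stable-isotope delta notation
#'
#' Converts a sample's heavy-to-light isotope ratio into per-mil deviation
#' from an international standard:
#' \deqn{\delta X = (R_{sample} / R_{standard} - 1) \times 10^3}
#' (V-PDB for carbon, atmospheric N2 for nitrogen).
#'
#' @param r_sample Isotopic ratio(s) of the sample (>= 0).
#' @param r_standard Isotopic ratio of the standard (> 0).
#' @return Delta value(s) in per mil.
#' @examples
#' delta_value(1.02 * 0.0112372, 0.0112372)  # +20 permil
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(r_standard <= 0)) stop("r_standard must be positive", call. = FALSE)
  if (any(r_sample < 0)) stop("r_sample must be non-negative", call. = FALSE)
  (r_sample / r_standard - 1) * 1e3
}

# Join termite rows to per-species metadata when grouping needs it.
isotope_groups <- function(table, by, traits, sample_type) {
  stopifnot(is.data.frame(table))
  need <- c("type", "site", "d15N", "d13C")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("isotope table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  tab <- dplyr::filter(table, .data$type == sample_type)
  if (by == "site") {
    tab$group <- as.character(tab$site)
    return(tab)
  }
  if (sample_type != "termite") {
    stop("grouping by ", by, " requires termite samples", call. = FALSE)
  }
  if (is.null(traits) || !by %in% names(traits)) {
    stop("grouping by ", by, " needs a traits table with a '", by, "' column", call. = FALSE)
  }
  unknown <- setdiff(unique(tab$species), traits$species)
  if (length(unknown)) {
    stop("species missing from traits table: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab$group <- as.character(traits[[by]][match(tab$species, traits$species)])
  tab
}

#' Per-group isotope summaries
#'
#' Mean and sample standard deviation (n - 1 denominator; `NA` for a
#' single measurement) of a delta value, by site, feeding group or
#' family. Feeding group and family come from the traits table join and
#' apply to termite samples.
#'
#' @param table Isotope tibble with columns `sample_id`, `type`
#'   (`termite`/`litter`/`soil`), `site`, `plot`, `species` (termite rows),
#'   `d15N`, `d13C`.
#' @param by `"site"`, `"feeding_group"` or `"family"`.
#' @param element `"d15N"` or `"d13C"`.
#' @param traits Per-species tibble (`species`, `feeding_group`, optional
#'   `family`); required unless `by = "site"`.
#' @param sample_type Which sample type to summarise (default `"termite"`).
#' @return Tibble ordered by group: `group`, `n`, `mean`, `sd`.
#' @export
summarize_isotopes <- function(table, by = c("site", "feeding_group", "family"),
                               element = c("d15N", "d13C"), traits = NULL,
                               sample_type = "termite") {
  by <- match.arg(by)
  element <- match.arg(element)
  tab <- isotope_groups(table, by, traits, sample_type)
  tab$value <- tab[[element]]
  if (any(!is.finite(tab$value))) stop("non-finite delta values", call. = FALSE)
  tab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(.data$group)
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Fixed-effects one-way ANOVA of a delta value across groups, followed by
#' all-pairs Tukey HSD (Tukey-Kramer under unequal n) and a compact letter
#' display: groups sharing a letter are not significantly different at
#' `alpha`. Groups with fewer than 2 observations are excluded from the
#' test with a warning. When the between-group sum of squares is zero the
#' omnibus is reported as F = 0, p = 1 and all groups share one letter.
#'
#' @inheritParams summarize_isotopes
#' @param alpha Significance level for the letter display.
#' @return Object of class `phylocomm_anova`. [glance()] gives the omnibus
#'   row (`F`, `df_between`, `df_within`, `p`), [tidy()] the Tukey pairs,
#'   and `$letters` a per-group tibble (`group`, `n`, `mean`, `sd`,
#'   `letters`).
#' @export
anova_tukey <- function(table, by = c("site", "feeding_group", "family"),
                        element = c("d15N", "d13C"), traits = NULL,
                        sample_type = "termite", alpha = 0.05) {
  by <- match.arg(by)
  element <- match.arg(element)
  tab <- isotope_groups(table, by, traits, sample_type)
  tab$value <- tab[[element]]
  counts <- table(tab$group)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "), call. = FALSE)
    tab <- tab[!tab$group %in% small, ]
  }
  groups <- sort(unique(tab$group))
  if (length(groups) < 2) stop("need at least 2 groups with >= 2 observations", call. = FALSE)
  tab$group <- factor(tab$group, levels = groups)

  fit <- aov(value ~ group, data = tab)
  an <- summary(fit)[[1]]
  ss_between <- an["group", "Sum Sq"]
  if (ss_between <= .Machine$double.eps * sum(tab$value^2 + 1)) {
    f <- 0; p <- 1
    pairs <- tibble::tibble(
      comparison = utils::combn(groups, 2, paste, collapse = "-"),
      diff = 0, lwr = 0, upr = 0, p_adj = 1)
  } else {
    f <- an["group", "F value"]
    p <- an["group", "Pr(>F)"]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pairs <- tibble::tibble(comparison = rownames(tk),
                            diff = tk[, "diff"], lwr = tk[, "lwr"],
                            upr = tk[, "upr"], p_adj = tk[, "p adj"])
  }
  letters <- tukey_letters(groups, pairs, alpha)
  summ <- tab |>
    dplyr::group_by(group = as.character(.data$group)) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(.data$group)
  summ$letters <- letters[summ$group]

  structure(list(
    F = f, df_between = an["group", "Df"], df_within = an["Residuals", "Df"],
    p = p, pairs = pairs, letters = summ, element = element, by = by,
    alpha = alpha, fit = fit
  ), class = "phylocomm_anova")
}

# Compact letter display by insert-and-absorb over the significant pairs.
# Pairs are processed in sorted order and letter sets sorted, so the
# partition does not depend on the input order of groups.
tukey_letters <- function(groups, pairs, alpha) {
  groups <- sort(groups)
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  cols <- list(groups)
  if (nrow(sig)) {
    sp <- strsplit(sig$comparison, "-", fixed = TRUE)
    ord <- order(vapply(sp, paste, "", collapse = "-"))
    for (k in ord) {
      g1 <- sp[[k]][1]; g2 <- sp[[k]][2]
      new_cols <- list()
      for (col in cols) {
        if (g1 %in% col && g2 %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, function(x) min(match(x, groups)), 1))]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' @export
print.phylocomm_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s by %s: F_%d,%d = %.3f, p = %.4g\n",
              x$element, x$by, x$df_between, x$df_within, x$F, x$p))
  print(x$letters)
  invisible(x)
}

#' Correlate NRI with plot environment
#'
#' Pearson correlation (two-sided t test, df = n - 2) of per-plot NRI with
#' rainfall, elevation and temperature, plus an ordinary least squares fit
#' of NRI on the three standardized covariates with a site fixed factor
#' (model label `"ols_site_fixed"`).
#'
#' @param nri_results Tibble from [run_pool_analysis()] (columns `plot`,
#'   `nri`).
#' @param env Tibble with columns `plot`, `site`, `rainfall_mm`,
#'   `elevation_m`, `temperature_C`.
#' @return Object of class `phylocomm_nri_env`: `$correlations` tibble
#'   (`variable`, `n`, `r`, `t`, `df`, `p`, zero-variance covariates
#'   flagged by `NA` r), `$model` the OLS fit, `$model_label`. [tidy()]
#'   returns the correlation tibble.
#' @export
correlate_nri_environment <- function(nri_results, env) {
  vars <- c("rainfall_mm", "elevation_m", "temperature_C")
  miss <- setdiff(c("plot", vars), names(env))
  if (length(miss)) stop("environment table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- dplyr::inner_join(
    tibble::tibble(plot = nri_results$plot, nri = nri_results$nri),
    tibble::as_tibble(env), by = "plot")
  d <- d[is.finite(d$nri), ]
  if (nrow(d) < 3) stop("need at least 3 plots with defined NRI", call. = FALSE)
  cors <- purrr::map_dfr(vars, function(v) {
    x <- d[[v]]
    if (sd(x) == 0) {
      return(tibble::tibble(variable = v, n = nrow(d), r = NA_real_,
                            t = NA_real_, df = nrow(d) - 2L, p = NA_real_))
    }
    r <- cor(d$nri, x)
    df <- nrow(d) - 2L
    tstat <- r * sqrt(df / (1 - r^2))
    tibble::tibble(variable = v, n = nrow(d), r = r, t = tstat, df = df,
                   p = 2 * pt(-abs(tstat), df))
  })
  model <- NULL
  if ("site" %in% names(d) && length(unique(d$site)) > 1) {
    md <- d
    use <- vars[vapply(vars, function(v) sd(md[[v]]) > 0, logical(1))]
    for (v in use) md[[v]] <- as.numeric(scale(md[[v]]))
    if (length(use)) {
      fml <- stats::reformulate(c(use, "factor(site)"), response = "nri")
      model <- lm(fml, data = md)
    }
  }
  structure(list(correlations = cors, model = model,
                 model_label = "ols_site_fixed"),
            class = "phylocomm_nri_env")
}

#' @export
print.phylocomm_nri_env <- function(x, ...) {
  cat("Pearson correlations of NRI with plot environment:\n")
  print(x$correlations)
  if (!is.null(x$model)) {
    cat("\nOLS with site fixed factor (", x$model_label, "):\n", sep = "")
    print(summary(x$model)$coefficients)
  }
  invisible(x)
}
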