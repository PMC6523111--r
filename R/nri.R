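#' Net Relatedness Index for every plot of a community
#'
#' For each plot, the observed MPD is compared with MPDs of the same plot
#' row in null communities generated by [independent_swap()] randomization
#' of the pooled presence/absence matrix:
#' \deqn{NRI = -(MPD_{obs} - \bar{MPD}_{null}) / sd(MPD_{null})}
#' so positive NRI means co-occurring species are more closely related
#' than expected (phylogenetic clustering) and negative NRI less related
#' (overdispersion). Significance uses the two-tailed rank test of
#' [rank_test()].
#'
#' Null matrices are drawn from a single swap chain: one burn-in schedule,
#' then one sample every `10 * (number of occupied cells)` successful
#' swaps. When `weighted = TRUE` the null communities reuse each species'
#' observed positive abundances, permuted uniformly across that species'
#' null occurrences; the swaps themselves always act on occurrence data.
#'
#' @param community Tibble/data frame with columns `plot`, `site`, then one
#'   column per species holding non-negative integer abundances.
#' @param tree A `phylo` whose tips cover every species column.
#' @param pool `"regional"` (all species observed anywhere) or `"site"`
#'   (each plot randomized among the plots and species of its own site).
#' @param n_rand Number of null randomizations `R` (default 9999).
#' @param weighted Abundance-weighted MPD? Default `TRUE`.
#' @param rng_seed Seed for the whole analysis run; all null chains derive
#'   from it deterministically.
#' @param alpha Two-tailed level for the rank test.
#' @return A tibble of class `phylocomm_nri`, one row per plot: `plot`,
#'   `site`, `pool`, `richness`, `mpd_obs`, `null_mean`, `null_sd`, `nri`,
#'   `rank`, `n_rand`, `significant`, `direction` (`clustered`,
#'   `overdispersed` or `none`), `degenerate`. Plots with fewer than two
#'   species, and plots whose null MPD spread is zero, are kept as flagged
#'   `NA` rows rather than dropped.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' com <- tibble::tibble(
#'   plot = c("p1", "p2", "p3"), site = "s1",
#'   A = c(2L, 0L, 1L), B = c(1L, 1L, 0L),
#'   C = c(0L, 2L, 1L), D = c(1L, 1L, 1L)
#' )
#' run_pool_analysis(com, tr, pool = "regional", n_rand = 99, rng_seed = 1)
#' @export
run_pool_analysis <- function(community, tree, pool = c("regional", "site"),
                              n_rand = 9999, weighted = TRUE, rng_seed = NULL,
                              alpha = 0.05) {
  pool <- match.arg(pool)
  parts <- community_parts(community, tree)
  dist <- patristic_distances(tree)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (pool == "regional") {
    keep <- colSums(parts$abund) > 0
    res <- nri_engine(parts$abund[, keep, drop = FALSE], dist, n_rand, weighted, alpha)
  } else {
    res <- dplyr::bind_rows(lapply(unique(parts$site), function(s) {
      rows <- parts$site == s
      ab <- parts$abund[rows, , drop = FALSE]
      ab <- ab[, colSums(ab) > 0, drop = FALSE]
      nri_engine(ab, dist, n_rand, weighted, alpha)
    }))
    res <- res[match(rownames(parts$abund), res$plot), ]
  }
  out <- tibble::tibble(
    plot = res$plot,
    site = parts$site[match(res$plot, rownames(parts$abund))],
    pool = pool
  )
  out <- dplyr::bind_cols(out, res[setdiff(names(res), "plot")])
  new_nri_tbl(out, n_rand = n_rand, weighted = weighted, alpha = alpha)
}

#' NRI of a single plot against an explicit species pool
#'
#' Same null model as [run_pool_analysis()], but the candidate pool is
#' given directly; the presence matrix entering the swaps is restricted to
#' the pool's species (all plots keep their rows, so occurrence totals are
#' preserved).
#'
#' @inheritParams run_pool_analysis
#' @param plot Plot id (must match one row of `community`).
#' @param species_pool Character vector of tree tips to randomize over;
#'   defaults to every species observed anywhere in `community`.
#' @return One-row tibble as in [run_pool_analysis()] (`pool = "custom"`).
#' @export
nri <- function(community, tree, plot, species_pool = NULL, n_rand = 9999,
                weighted = TRUE, rng_seed = NULL, alpha = 0.05) {
  parts <- community_parts(community, tree)
  if (!plot %in% rownames(parts$abund)) stop("unknown plot: ", plot, call. = FALSE)
  ab <- parts$abund
  if (is.null(species_pool)) {
    species_pool <- colnames(ab)[colSums(ab) > 0]
  }
  if (!all(species_pool %in% tree$tip.label)) {
    stop("pool species not in tree: ",
         paste(setdiff(species_pool, tree$tip.label), collapse = ", "), call. = FALSE)
  }
  ab <- ab[, intersect(colnames(ab), species_pool), drop = FALSE]
  dist <- patristic_distances(tree)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  res <- nri_engine(ab, dist, n_rand, weighted, alpha)
  res <- res[res$plot == plot, ]
  out <- tibble::tibble(plot = plot,
                        site = parts$site[match(plot, rownames(parts$abund))],
                        pool = "custom")
  out <- dplyr::bind_cols(out, res[setdiff(names(res), "plot")])
  new_nri_tbl(out, n_rand = n_rand, weighted = weighted, alpha = alpha)
}

new_nri_tbl <- function(x, n_rand, weighted, alpha) {
  structure(x, class = c("phylocomm_nri", class(tibble::tibble())),
            n_rand = n_rand, weighted = weighted, alpha = alpha)
}

# Core: one pooled abundance matrix -> per-plot NRI rows.
nri_engine <- function(ab, dist, n_rand, weighted, alpha,
                       interval_mult = 10, budget_mult = 100) {
  plots <- rownames(ab)
  pres <- (ab > 0) * 1L
  richness <- rowSums(pres)
  eligible <- richness >= 2
  if (any(!eligible)) {
    warning("plot(s) with fewer than 2 species reported as NA: ",
            paste(plots[!eligible], collapse = ", "), call. = FALSE)
  }
  sub <- dist[colnames(ab), colnames(ab), drop = FALSE]
  obs <- unname(batch_mpd(if (weighted) ab else pres, sub))

  ones <- sum(pres)
  interval <- max(interval_mult * ones, 1)
  ser <- cpp_swap_series(pres, n_rand, interval, budget_mult * interval)
  if (ser$short_chain) {
    warning("swap attempt budget exhausted; matrix may have no swappable checkerboard",
            call. = FALSE)
  }
  nulls <- ser$nulls
  nmpd <- matrix(NA_real_, n_rand, nrow(ab))
  for (k in seq_len(n_rand)) {
    nk <- matrix(nulls[((k - 1) * length(pres) + 1):(k * length(pres))],
                 nrow = nrow(ab))
    a <- if (weighted) permute_null_abundances(ab, pres, nk) else nk
    nmpd[k, ] <- batch_mpd(a, sub)
  }

  null_mean <- colMeans(nmpd)
  null_sd <- apply(nmpd, 2, sd)
  nri_val <- ifelse(null_sd > 0, -(obs - null_mean) / null_sd, NA_real_)
  degenerate <- eligible & !(null_sd > 0)

  rows <- lapply(seq_along(plots), function(i) {
    if (!eligible[i]) {
      return(tibble::tibble(
        plot = plots[i], richness = as.integer(richness[i]), mpd_obs = NA_real_,
        null_mean = NA_real_, null_sd = NA_real_, nri = NA_real_,
        rank = NA_integer_, n_rand = n_rand, significant = NA,
        direction = NA_character_, degenerate = FALSE))
    }
    rt <- rank_test(obs[i], nmpd[, i], alpha)
    sig <- rt$significant && !degenerate[i]
    dir <- "none"
    if (sig && !is.na(nri_val[i])) {
      if (nri_val[i] > 0) dir <- "clustered" else if (nri_val[i] < 0) dir <- "overdispersed"
    }
    tibble::tibble(
      plot = plots[i], richness = as.integer(richness[i]), mpd_obs = obs[i],
      null_mean = null_mean[i], null_sd = null_sd[i], nri = nri_val[i],
      rank = rt$rank, n_rand = n_rand,
      significant = if (degenerate[i]) NA else rt$significant,
      direction = dir, degenerate = degenerate[i])
  })
  dplyr::bind_rows(rows)
}

# MPD of every row of an abundance (or binary) matrix at once, using
# a' D a = 2 * sum_{i<j} a_i a_j d_ij (diag(D) = 0).
batch_mpd <- function(a, dist) {
  num <- rowSums((a %*% dist) * a)
  den <- rowSums(a)^2 - rowSums(a^2)
  ifelse(den > 0, num / den, NA_real_)
}

# Carry each species' observed positive abundances to its null occurrences
# by uniform permutation (column sums are swap-invariant, so counts match).
permute_null_abundances <- function(ab, pres, null_pres) {
  a <- matrix(0, nrow(ab), ncol(ab))
  for (j in seq_len(ncol(ab))) {
    vals <- ab[pres[, j] == 1L, j]
    rows <- which(null_pres[, j] == 1L)
    if (length(vals)) a[rows, j] <- vals[sample.int(length(vals))]
  }
  a
}

# Split a community tibble (plot, site, species...) into validated parts.
community_parts <- function(community, tree = NULL) {
  community <- as.data.frame(community)
  if (!all(c("plot", "site") %in% names(community))) {
    stop("community must have 'plot' and 'site' columns", call. = FALSE)
  }
  sp_cols <- setdiff(names(community), c("plot", "site"))
  if (length(sp_cols) == 0) stop("community has no species columns", call. = FALSE)
  ab <- as.matrix(community[, sp_cols, drop = FALSE])
  if (!is.numeric(ab) || any(ab < 0)) stop("abundances must be non-negative numbers", call. = FALSE)
  if (any(ab != round(ab))) stop("abundances must be integers", call. = FALSE)
  if (anyDuplicated(community$plot)) stop("duplicate plot ids", call. = FALSE)
  rownames(ab) <- as.character(community$plot)
  if (!is.null(tree)) {
    missing <- setdiff(sp_cols, tree$tip.label)
    if (length(missing)) {
      stop("species not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  list(abund = ab, site = setNames(as.character(community$site), as.character(community$plot)))
}
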