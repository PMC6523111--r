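#' Mean pairwise phylogenetic distance of one assemblage
#'
#' MPD is the average patristic distance among the species present in a
#' plot. Unweighted, it is the mean over all unordered pairs of present
#' species; abundance-weighted, each pair is weighted by the product of
#' the two species' abundances:
#' \deqn{MPD_w = \sum_{i<j} a_i a_j d_{ij} / \sum_{i<j} a_i a_j.}
#'
#' @param abundances Named non-negative numeric vector of per-species
#'   counts for one plot; names must appear in `dist`.
#' @param dist Patristic distance matrix from [patristic_distances()].
#' @param weighted Weight pairs by abundance products? Default `TRUE`.
#' @return The MPD (branch-length units), or `NA_real_` with a warning
#'   when fewer than 2 species are present.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' d <- patristic_distances(tr)
#' mpd(c(A = 2, B = 1, C = 0), d)
#' @export
mpd <- function(abundances, dist, weighted = TRUE) {
  stopifnot(is.numeric(abundances), !is.null(names(abundances)))
  if (any(abundances < 0)) stop("negative abundance", call. = FALSE)
  present <- names(abundances)[abundances > 0]
  if (!all(present %in% rownames(dist))) {
    stop("species missing from distance matrix: ",
         paste(setdiff(present, rownames(dist)), collapse = ", "), call. = FALSE)
  }
  if (length(present) < 2) {
    warning("MPD undefined: fewer than 2 species present", call. = FALSE)
    return(NA_real_)
  }
  sub <- dist[present, present, drop = FALSE]
  if (!weighted) return(mean(sub[upper.tri(sub)]))
  a <- abundances[present]
  w <- tcrossprod(a)
  ut <- upper.tri(sub)
  sum(w[ut] * sub[ut]) / sum(w[ut])
}

#' Independent-swap randomization of a binary occurrence matrix
#'
#' Repeatedly finds 2x2 checkerboard submatrices (`[[1,0],[0,1]]` or its
#' mirror) on random row and column pairs and flips them, which preserves
#' every row and column total. The chain stops after `n_swaps` successful
#' swaps or after an attempt budget of `budget_mult * n_swaps` random
#' submatrix draws, whichever comes first; an exhausted budget (e.g. a
#' matrix with no checkerboard at all) returns the current state with a
#' warning.
#'
#' @param presence Binary (0/1) integer matrix, plots x species.
#' @param n_swaps Number of successful swaps to perform.
#' @param rng_seed Optional seed; when `NULL` the current RNG state is used.
#' @param budget_mult Attempt budget as a multiple of `n_swaps`.
#' @return A binary matrix with the same dimnames, row sums and column sums
#'   as `presence`.
#' @export
independent_swap <- function(presence, n_swaps, rng_seed = NULL, budget_mult = 100) {
  m <- check_binary_matrix(presence)
  stopifnot(n_swaps >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (n_swaps == 0) return(m)
  res <- cpp_independent_swap(m, n_swaps, max(budget_mult * n_swaps, 1000))
  if (res$swaps_done < n_swaps) {
    warning("attempt budget exhausted after ", res$swaps_done,
            " successful swaps (matrix may have no swappable checkerboard)",
            call. = FALSE)
  }
  out <- res$matrix
  dimnames(out) <- dimnames(m)
  out
}

check_binary_matrix <- function(presence) {
  stopifnot(is.matrix(presence))
  m <- presence
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("matrix is not binary", call. = FALSE)
  m
}

#' Two-tailed rank test against a null distribution
#'
#' The observed value is ranked among the null values, ties counted half:
#' `rank = 1 + #(null < obs) + 0.5 * #(null == obs)`, rounded half up.
#' With `R` null values the two-tailed test at level `alpha` flags ranks
#' `>= ceiling((1 - alpha/2) * (R + 1))` or `<= floor((alpha/2) * (R + 1))`;
#' at `R = 9999`, `alpha = 0.05` the critical ranks are 9750 and 250.
#'
#' @param obs Observed statistic.
#' @param nulls Numeric vector of null statistics (non-empty).
#' @param alpha Two-tailed significance level.
#' @return A one-row tibble: `rank`, `n_null`, `lower_critical`,
#'   `upper_critical`, `significant`, `tail` (`"high"`, `"low"` or `"none"`).
#' @export
rank_test <- function(obs, nulls, alpha = 0.05) {
  stopifnot(length(nulls) >= 1, is.finite(obs))
  crit <- rank_critical_values(length(nulls), alpha)
  r <- 1 + sum(nulls < obs) + 0.5 * sum(nulls == obs)
  r <- floor(r + 0.5)  # round half up
  tail <- if (r >= crit[["upper"]]) "high" else if (r <= crit[["lower"]]) "low" else "none"
  tibble::tibble(
    rank = as.integer(r), n_null = length(nulls),
    lower_critical = crit[["lower"]], upper_critical = crit[["upper"]],
    significant = tail != "none", tail = tail
  )
}

#' Critical ranks of the two-tailed rank test
#'
#' @param n_null Number of null randomizations.
#' @param alpha Two-tailed significance level.
#' @return Named integer vector with elements `lower` and `upper`.
#' @export
rank_critical_values <- function(n_null, alpha = 0.05) {
  c(lower = as.integer(floor((alpha / 2) * (n_null + 1))),
    upper = as.integer(ceiling((1 - alpha / 2) * (n_null + 1))))
}
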