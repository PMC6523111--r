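#' Read the pipeline's CSV inputs
#'
#' Thin validating readers for the four tabular inputs. Community CSV:
#' `plot`, `site`, then one abundance column per species (header = species
#' labels, which must match the tree's tips). Trait CSV: `species`,
#' `feeding_group` (I-IV), `d15N`, `d13C`, optional `family`. Isotope CSV:
#' `sample_id`, `type` (termite/litter/soil), `site`, `plot`, `species`,
#' `d15N`, `d13C`. Environment CSV: `plot`, `site`, `rainfall_mm`,
#' `elevation_m`, `temperature_C`.
#'
#' @param path CSV file path.
#' @param tree Optional `phylo` used to cross-check species labels.
#' @return A validated tibble.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_community <- function(path, tree = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  invisible(community_parts(x, tree))
  x
}

#' @rdname read_inputs
#' @export
read_traits <- function(path, tree = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species", "feeding_group", "d15N", "d13C")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("trait table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(x$feeding_group %in% c("I", "II", "III", "IV"))) {
    stop("feeding_group must be one of I, II, III, IV", call. = FALSE)
  }
  if (anyDuplicated(x$species)) stop("duplicate species in trait table", call. = FALSE)
  if (!is.null(tree)) {
    miss <- setdiff(tree$tip.label, x$species)
    if (length(miss)) stop("trait table misses tree species: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname read_inputs
#' @export
read_isotopes <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "type", "site", "plot", "species", "d15N", "d13C")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("isotope table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(x$type %in% c("termite", "litter", "soil"))) {
    stop("sample type must be termite, litter or soil", call. = FALSE)
  }
  if (any(x$type == "termite" & is.na(x$species))) {
    stop("termite rows must carry a species label", call. = FALSE)
  }
  x
}

#' @rdname read_inputs
#' @export
read_environment <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("plot", "site", "rainfall_mm", "elevation_m", "temperature_C")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("environment table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  x
}
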