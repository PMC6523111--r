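#' Configuration of the synthetic study
#'
#' Bundles every knob of the generator. The defaults emulate the scale and
#' summary statistics of a three-site tropical dry-forest termite survey:
#' a 32-species regional pool, 3 sites of 5 plots, mean plot richness 8,
#' delta traits centred on 6.0 permil (d15N) and -27.0 permil (d13C) with
#' Brownian rates chosen so tip spreads land near 3.8 and 1.2 permil, and
#' a rainfall gradient along which the wettest site filters
#' environmentally and the driest site is competitive.
#'
#' @param n_species Species in the regional pool.
#' @param n_sites Number of sites.
#' @param plots_per_site Plots per site.
#' @param assembly Per-site assembly mode: `"random"`, `"filtering"` or
#'   `"competition"` (recycled to `n_sites`).
#' @param strength Per-site assembly strength (>= 0): filtering decay per
#'   permil of d15N distance from the site optimum; competition exclusion
#'   radius as a fraction of the mean pairwise patristic distance.
#' @param birth_rate Yule speciation rate.
#' @param sigma_d15N,sigma_d13C Brownian rates (permil per sqrt branch
#'   unit).
#' @param root_d15N,root_d13C Root (ancestral) delta values, permil.
#' @param fg_jump_rate Feeding-group stepwise jump rate per branch unit.
#' @param richness_mean Mean of the truncated Poisson plot richness.
#' @param rainfall_mm,elevation_m,temperature_C Per-site environment means
#'   (wettest site first).
#' @param env_noise_sd Plot-level noise SDs for the three variables.
#' @return A list of class `phylocomm_config`.
#' @export
simulation_config <- function(n_species = 32, n_sites = 3, plots_per_site = 5,
                              assembly = c("filtering", "random", "competition"),
                              strength = c(1, 0, 0.5),
                              birth_rate = 1,
                              sigma_d15N = 2.2, sigma_d13C = 0.7,
                              root_d15N = 6.0, root_d13C = -27.0,
                              fg_jump_rate = 0.1,
                              richness_mean = 8,
                              rainfall_mm = c(1500, 1100, 700),
                              elevation_m = c(300, 180, 60),
                              temperature_C = c(26.5, 27.0, 27.7),
                              env_noise_sd = c(rainfall = 60, elevation = 20, temperature = 0.3)) {
  stopifnot(n_species >= 2, n_sites >= 1, plots_per_site >= 1,
            all(strength >= 0), birth_rate > 0, richness_mean >= 2)
  assembly <- rep_len(assembly, n_sites)
  if (!all(assembly %in% c("random", "filtering", "competition"))) {
    stop("assembly modes must be random, filtering or competition", call. = FALSE)
  }
  cfg <- list(
    n_species = n_species, n_sites = n_sites, plots_per_site = plots_per_site,
    assembly = assembly,
    strength = rep_len(strength, n_sites), birth_rate = birth_rate,
    sigma_d15N = sigma_d15N, sigma_d13C = sigma_d13C,
    root_d15N = root_d15N, root_d13C = root_d13C,
    fg_jump_rate = fg_jump_rate, richness_mean = richness_mean,
    rainfall_mm = rep_len(rainfall_mm, n_sites),
    elevation_m = rep_len(elevation_m, n_sites),
    temperature_C = rep_len(temperature_C, n_sites),
    env_noise_sd = env_noise_sd
  )
  structure(cfg, class = "phylocomm_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' While `k` lineages are alive the next speciation waits an
#' `Exp(k * birth_rate)` time; the tree is stopped one waiting time after
#' reaching `n_species` lineages, so the expected root-to-tip depth is
#' `sum(1/k, k = 2..n) / birth_rate`. The result is ultrametric.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param rng_seed Optional seed.
#' @return A rooted ultrametric `phylo` with tips `s01`, `s02`, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, rng_seed = NULL) {
  stopifnot(n_species >= 2, birth_rate > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- n_species
  # lineage bookkeeping: each active lineage has a start time and a parent
  # node id; node ids are assigned ape-style at the end.
  birth <- numeric(2 * n - 1)   # start time of the edge above each unit
  parent <- integer(2 * n - 1)
  is_tip <- logical(2 * n - 1)
  # unit 1 = root (no edge above); its two children start the process
  active <- c(2L, 3L)
  parent[2:3] <- 1L
  birth[2:3] <- 0
  nxt <- 3L
  t_now <- 0
  for (k in 2:n) {
    t_now <- t_now + rexp(1, k * birth_rate)
    if (k == n) break
    i <- active[sample.int(length(active), 1)]
    # lineage i speciates at t_now: becomes internal, spawns two units
    c1 <- nxt + 1L; c2 <- nxt + 2L; nxt <- nxt + 2L
    parent[c(c1, c2)] <- i
    birth[c(c1, c2)] <- t_now
    active <- c(setdiff(active, i), c1, c2)
  }
  is_tip[active] <- TRUE
  end_time <- ifelse(is_tip, t_now, 0)
  # internal units end where their children begin
  for (u in seq_len(nxt)) if (parent[u] > 1L && !is_tip[parent[u]]) {
    end_time[parent[u]] <- birth[u]
  }
  units <- seq_len(nxt)
  tips <- units[is_tip[units]]
  ints <- c(1L, setdiff(units[!is_tip[units]], 1L))
  id <- integer(nxt)
  id[tips] <- seq_along(tips)
  id[ints] <- n + seq_along(ints)
  edges <- units[units != 1L]
  tree <- list(
    edge = cbind(id[parent[edges]], id[edges]),
    edge.length = end_time[edges] - birth[edges],
    tip.label = sprintf("s%02d", seq_len(n)),
    Nnode = n - 1L
  )
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree)
}

#' Simulate phylogenetically structured niche traits
#'
#' d15N and d13C evolve by Brownian motion along branches from the
#' configured root values, so variance grows as `sigma^2 *` path length
#' and close relatives share similar signatures. The feeding group (I-IV)
#' evolves by a sparse stepwise Markov jump process along the humification
#' ladder (I <-> II <-> III <-> IV) starting from group II, so clades
#' share groups. A `family` label splits the tree at its deepest
#' bipartition(s) into up to 3 clades.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param config A [simulation_config()].
#' @param rng_seed Optional seed.
#' @return Trait tibble: `species`, `feeding_group`, `d15N`, `d13C`,
#'   `family`.
#' @export
simulate_traits <- function(tree, config = simulation_config(), rng_seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]

  d15 <- numeric(n_all); d13 <- numeric(n_all); fg <- integer(n_all)
  d15[root] <- config$root_d15N; d13[root] <- config$root_d13C; fg[root] <- 2L
  groups <- c("I", "II", "III", "IV")
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; c <- edges[i, 2]; b <- elen[i]
    d15[c] <- d15[p] + rnorm(1, 0, config$sigma_d15N * sqrt(b))
    d13[c] <- d13[p] + rnorm(1, 0, config$sigma_d13C * sqrt(b))
    g <- fg[p]
    n_jump <- rpois(1, config$fg_jump_rate * b)
    if (n_jump > 0) for (j in seq_len(n_jump)) {
      g <- if (g == 1L) 2L else if (g == 4L) 3L else g + sample(c(-1L, 1L), 1)
    }
    fg[c] <- g
  }
  fam <- family_labels(tree)
  tibble::tibble(
    species = tree$tip.label,
    feeding_group = groups[fg[seq_len(n_tip)]],
    d15N = d15[seq_len(n_tip)], d13C = d13[seq_len(n_tip)],
    family = fam
  )
}

# Family labels from the deepest splits: the root's child clades, the
# largest one split once more when the root is binary (giving 3 clades).
family_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  clades <- as.list(tree$edge[tree$edge[, 1] == root, 2])
  if (length(clades) == 2) {
    sizes <- vapply(clades, function(k) clade_size(tree, k), 1L)
    big <- which.max(sizes)
    k <- clades[[big]]
    if (k > n_tip) {
      clades <- c(clades[-big], as.list(tree$edge[tree$edge[, 1] == k, 2]))
    }
  }
  fam <- character(n_tip)
  for (i in seq_along(clades)) {
    fam[clade_tips(tree, clades[[i]])] <- paste0("fam", LETTERS[i])
  }
  fam
}

clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, ch[ch <= n_tip])
    stack <- c(stack, ch[ch > n_tip])
  }
  out
}

clade_size <- function(tree, node) length(clade_tips(tree, node))

#' Simulate plot communities and environments
#'
#' Per plot, richness is a Poisson draw (mean `richness_mean`) truncated
#' to at least 2 and at most the pool size, and species enter by the
#' site's assembly mode: *random* samples uniformly; *filtering* weights
#' species by `exp(-strength * |d15N - site optimum|)` (conserved traits
#' make this cluster relatives); *competition* adds species sequentially,
#' rejecting candidates whose minimum patristic distance to the residents
#' is below `strength *` (mean pairwise distance) — richness is truncated
#' with a warning when no candidate remains. Abundances of occupied cells
#' are i.i.d. geometric; plot environments are site means plus Gaussian
#' noise.
#'
#' @param tree,traits Outputs of [simulate_tree()] and [simulate_traits()].
#' @param config A [simulation_config()].
#' @param rng_seed Optional seed.
#' @return List with `community` (tibble: `plot`, `site`, species columns)
#'   and `environment` (tibble: `plot`, `site`, `rainfall_mm`,
#'   `elevation_m`, `temperature_C`).
#' @export
simulate_communities <- function(tree, traits, config = simulation_config(),
                                 rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sp <- tree$tip.label
  stopifnot(setequal(sp, traits$species))
  dist <- patristic_distances(tree)
  dbar <- mean(dist[upper.tri(dist)])
  trait <- setNames(traits$d15N, traits$species)[sp]
  optima <- quantile(trait, probs = seq(0.25, 0.75, length.out = config$n_sites))

  plots <- list(); envs <- list()
  for (s in seq_len(config$n_sites)) {
    mode <- config$assembly[s]
    strength <- config$strength[s]
    for (p in seq_len(config$plots_per_site)) {
      k <- max(2L, min(length(sp), rpois(1, config$richness_mean)))
      members <- switch(
        mode,
        random = sample(sp, k),
        filtering = {
          w <- exp(-strength * abs(trait - optima[s]))
          sample(sp, k, prob = w)
        },
        competition = {
          radius <- strength * dbar
          res <- character(0)
          for (cand in sample(sp)) {
            if (length(res) == k) break
            if (length(res) == 0 || min(dist[cand, res]) >= radius) res <- c(res, cand)
          }
          if (length(res) < k) {
            warning("competition made richness ", k, " infeasible; truncated to ",
                    length(res), call. = FALSE)
          }
          res
        })
      ab <- setNames(rep(0L, length(sp)), sp)
      ab[members] <- as.integer(rgeom(length(members), 0.35) + 1L)
      plot_id <- sprintf("site%d_plot%d", s, p)
      plots[[plot_id]] <- ab
      envs[[plot_id]] <- tibble::tibble(
        plot = plot_id, site = paste0("site", s),
        rainfall_mm = config$rainfall_mm[s] + rnorm(1, 0, config$env_noise_sd[["rainfall"]]),
        elevation_m = config$elevation_m[s] + rnorm(1, 0, config$env_noise_sd[["elevation"]]),
        temperature_C = config$temperature_C[s] + rnorm(1, 0, config$env_noise_sd[["temperature"]]))
    }
  }
  ab_mat <- do.call(rbind, plots)
  community <- dplyr::bind_cols(
    tibble::tibble(plot = rownames(ab_mat),
                   site = sub("_plot\\d+$", "", rownames(ab_mat))),
    tibble::as_tibble(ab_mat))
  list(community = community, environment = dplyr::bind_rows(envs))
}

#' Simulate an isotope measurement table
#'
#' Termite rows: for every species occupying a site, 3 replicate workers
#' whose delta values are the species trait mean plus Gaussian residual.
#' Litter rows: 15 per site around a common baseline plus per-site
#' offsets (default: the driest, last site is +1.5 permil in both
#' elements). Soil rows: 5 per site with no site effect.
#'
#' @param traits Trait tibble from [simulate_traits()].
#' @param communities Output of [simulate_communities()].
#' @param residual_sd Termite residual SDs, `c(d15N = ..., d13C = ...)`.
#' @param litter_site_offsets Matrix/data frame with columns `d15N`,
#'   `d13C`, one row per site, added to the litter baseline; `NULL` uses
#'   the default gradient (last site +1.5 permil).
#' @param rng_seed Optional seed.
#' @return Isotope tibble: `sample_id`, `type`, `site`, `plot`, `species`,
#'   `d15N`, `d13C`.
#' @export
simulate_isotope_table <- function(traits, communities,
                                   residual_sd = c(d15N = 1.2, d13C = 0.6),
                                   litter_site_offsets = NULL,
                                   rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  community <- communities$community
  sites <- unique(community$site)
  n_site <- length(sites)
  if (is.null(litter_site_offsets)) {
    litter_site_offsets <- cbind(d15N = rep(0, n_site), d13C = rep(0, n_site))
    litter_site_offsets[n_site, ] <- c(1.5, 1.5)
  }
  litter_base <- c(d15N = 2.0, d13C = -28.5); litter_sd <- c(0.8, 0.7)
  soil_base <- c(d15N = 5.5, d13C = -26.5); soil_sd <- c(0.8, 0.6)

  rows <- list(); idx <- 0
  add <- function(type, site, plot, species, d15, d13) {
    idx <<- idx + 1
    rows[[idx]] <<- tibble::tibble(
      sample_id = sprintf("%s_%04d", type, idx), type = type, site = site,
      plot = plot, species = species, d15N = d15, d13C = d13)
  }
  parts <- community_parts(community)
  for (s in sites) {
    ab <- parts$abund[parts$site == s, , drop = FALSE]
    present <- colnames(ab)[colSums(ab) > 0]
    for (spp in present) {
      tr <- traits[traits$species == spp, ]
      for (r in 1:3) {
        add("termite", s, NA_character_, spp,
            tr$d15N + rnorm(1, 0, residual_sd[["d15N"]]),
            tr$d13C + rnorm(1, 0, residual_sd[["d13C"]]))
      }
    }
    si <- match(s, sites)
    site_plots <- unique(community$plot[community$site == s])
    for (r in 1:15) {
      add("litter", s, site_plots[(r - 1) %% length(site_plots) + 1], NA_character_,
          litter_base[["d15N"]] + litter_site_offsets[si, "d15N"] + rnorm(1, 0, litter_sd[1]),
          litter_base[["d13C"]] + litter_site_offsets[si, "d13C"] + rnorm(1, 0, litter_sd[2]))
    }
    for (r in 1:5) {
      add("soil", s, site_plots[(r - 1) %% length(site_plots) + 1], NA_character_,
          soil_base[["d15N"]] + rnorm(1, 0, soil_sd[1]),
          soil_base[["d13C"]] + rnorm(1, 0, soil_sd[2]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete synthetic study
#'
#' Chains [simulate_tree()], [simulate_traits()],
#' [simulate_communities()] and [simulate_isotope_table()] under one seed.
#' Identical config + seed reproduce the outputs exactly.
#'
#' @param config A [simulation_config()].
#' @param rng_seed Seed for the whole dataset.
#' @return List: `tree`, `traits`, `community`, `environment`, `isotopes`,
#'   `config`, `rng_seed`.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_species = 8), rng_seed = 1)
#' sim$community
#' @export
simulate_dataset <- function(config = simulation_config(), rng_seed = 1) {
  set.seed(rng_seed)
  tree <- simulate_tree(config$n_species, config$birth_rate)
  traits <- simulate_traits(tree, config)
  com <- simulate_communities(tree, traits, config)
  iso <- simulate_isotope_table(traits, com)
  list(tree = tree, traits = traits, community = com$community,
       environment = com$environment, isotopes = iso,
       config = config, rng_seed = rng_seed)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `tree.nwk`, `community.csv`, `traits.csv`, `isotopes.csv`,
#' `environment.csv` and a `provenance.json` (config, seed, package
#' version) into `dir`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_csv(sim$community, file.path(dir, "community.csv"))
  readr::write_csv(sim$traits, file.path(dir, "traits.csv"))
  readr::write_csv(sim$isotopes, file.path(dir, "isotopes.csv"))
  readr::write_csv(sim$environment, file.path(dir, "environment.csv"))
  jsonlite::write_json(
    list(config = unclass(sim$config), rng_seed = sim$rng_seed,
         package_version = as.character(utils::packageVersion("phylocomm"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
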