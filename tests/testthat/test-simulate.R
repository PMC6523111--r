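test_that("Yule trees are ultrametric, minimal at n = 2, and deterministic", {
  tr <- simulate_tree(2, rng_seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$Nnode, 1)
  d <- ape::node.depth.edgelength(tr)[1:2]
  expect_lt(diff(range(d)), 1e-12)

  t1 <- simulate_tree(32, rng_seed = 9)
  t2 <- simulate_tree(32, rng_seed = 9)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
})

test_that("mean Yule depth matches the closed form sum 1/k", {
  set.seed(161)
  n <- 16
  depths <- replicate(1000, {
    tr <- simulate_tree(n, birth_rate = 1)
    ape::node.depth.edgelength(tr)[1]
  })
  expected <- sum(1 / (2:n))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("Brownian traits: zero rate collapses to the root; variance grows as sigma^2 * depth", {
  tr <- simulate_tree(8, rng_seed = 4)
  cfg0 <- simulation_config(n_species = 8, sigma_d15N = 0, sigma_d13C = 0)
  tr0 <- simulate_traits(tr, cfg0, rng_seed = 1)
  expect_true(all(tr0$d15N == cfg0$root_d15N))
  expect_true(all(tr0$d13C == cfg0$root_d13C))

  set.seed(171)
  cfg <- simulation_config(n_species = 8, sigma_d15N = 2.2)
  depth <- ape::node.depth.edgelength(tr)[1]
  tip1 <- replicate(500, simulate_traits(tr, cfg)$d15N[1])
  v <- var(tip1)
  target <- cfg$sigma_d15N^2 * depth
  se_v <- v * sqrt(2 / (length(tip1) - 1))
  expect_lt(abs(v - target), 3 * se_v)
})

test_that("feeding groups are valid and cladewise-clumped under sparse jumps", {
  sim <- simulate_dataset(simulation_config(), rng_seed = 31)
  expect_true(all(sim$traits$feeding_group %in% c("I", "II", "III", "IV")))
  # sparse jumps mean few parsimony changes relative to tips
  st <- setNames(sim$traits$feeding_group, sim$traits$species)
  f <- fitch_unordered(sim$tree, st)
  expect_lte(f$score, 10)
})

test_that("filtering with zero strength is distributed like random assembly", {
  tr <- simulate_tree(16, rng_seed = 6)
  cfg_f <- simulation_config(n_species = 16, n_sites = 1, plots_per_site = 300,
                             assembly = "filtering", strength = 0)
  cfg_r <- simulation_config(n_species = 16, n_sites = 1, plots_per_site = 300,
                             assembly = "random", strength = 0)
  traits <- simulate_traits(tr, cfg_f, rng_seed = 8)
  com_f <- simulate_communities(tr, traits, cfg_f, rng_seed = 10)$community
  com_r <- simulate_communities(tr, traits, cfg_r, rng_seed = 12)$community
  occ_f <- colSums(as.matrix(com_f[, tr$tip.label]) > 0)
  occ_r <- colSums(as.matrix(com_r[, tr$tip.label]) > 0)
  # per-species occupancy frequencies indistinguishable
  expect_gt(suppressWarnings(
    stats::chisq.test(cbind(occ_f, occ_r))$p.value), 0.01)
})

test_that("community and environment tables satisfy downstream contracts", {
  sim <- simulate_dataset(simulation_config(), rng_seed = 41)
  parts <- phylocomm:::community_parts(sim$community, sim$tree)
  expect_equal(nrow(parts$abund), 15)
  expect_true(all(parts$abund >= 0))
  expect_true(all(rowSums(parts$abund > 0) >= 2))
  expect_setequal(unique(sim$environment$site), unique(sim$community$site))
  expect_equal(nrow(sim$environment), 15)
  expect_setequal(sim$traits$species, sim$tree$tip.label)
})

test_that("infeasible richness under competition is truncated with a warning", {
  tr <- simulate_tree(8, rng_seed = 3)
  cfg <- simulation_config(n_species = 8, n_sites = 1, plots_per_site = 2,
                           assembly = "competition", strength = 2,
                           richness_mean = 8)
  traits <- simulate_traits(tr, cfg, rng_seed = 5)
  expect_warning(simulate_communities(tr, traits, cfg, rng_seed = 7),
                 "truncated")
})

test_that("isotope tables mirror the sampling design and are noiseless at sd 0", {
  sim <- simulate_dataset(simulation_config(), rng_seed = 51)
  iso0 <- simulate_isotope_table(sim$traits,
                                 list(community = sim$community),
                                 residual_sd = c(d15N = 0, d13C = 0),
                                 rng_seed = 2)
  term <- iso0[iso0$type == "termite", ]
  m <- merge(term, sim$traits, by = "species")
  expect_equal(m$d15N.x, m$d15N.y)
  expect_equal(m$d13C.x, m$d13C.y)
  # design counts: 15 litter and 5 soil rows per site, 3 termite reps
  expect_true(all(table(iso0$site[iso0$type == "litter"]) == 15))
  expect_true(all(table(iso0$site[iso0$type == "soil"]) == 5))
  expect_true(all(table(term$site, term$species) %in% c(0, 3)))
})

test_that("the default litter offset makes the dry site detectably enriched", {
  set.seed(181)
  sim <- simulate_dataset(simulation_config(), rng_seed = 61)
  hits <- 0
  for (i in 1:100) {
    iso <- simulate_isotope_table(sim$traits, list(community = sim$community))
    a <- anova_tukey(iso, by = "site", element = "d15N", sample_type = "litter")
    l <- setNames(a$letters$letters, a$letters$group)
    dry <- "site3"
    others <- setdiff(names(l), dry)
    hits <- hits + all(!vapply(others, function(o) grepl(l[[dry]], l[[o]], fixed = TRUE),
                               logical(1)), nchar(l[[dry]]) == 1)
  }
  expect_gte(hits, 90)
})

test_that("soil has no site effect: ANOVA p-values are roughly uniform", {
  set.seed(191)
  sim <- simulate_dataset(simulation_config(), rng_seed = 71)
  ps <- replicate(200, {
    iso <- simulate_isotope_table(sim$traits, list(community = sim$community))
    glance(anova_tukey(iso, by = "site", element = "d15N", sample_type = "soil"))$p_value
  })
  expect_lt(suppressWarnings(stats::ks.test(ps, "punif")$statistic), 0.12)
})

test_that("identical config and seed give byte-identical datasets", {
  s1 <- simulate_dataset(simulation_config(), rng_seed = 99)
  s2 <- simulate_dataset(simulation_config(), rng_seed = 99)
  expect_identical(s1$community, s2$community)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$isotopes, s2$isotopes)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
})

test_that("datasets round-trip through the plain-text writers and readers", {
  sim <- simulate_dataset(simulation_config(n_species = 8), rng_seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  tr <- read_newick(file.path(dir, "tree.nwk"))
  com <- read_community(file.path(dir, "community.csv"), tr)
  traits <- read_traits(file.path(dir, "traits.csv"), tr)
  iso <- read_isotopes(file.path(dir, "isotopes.csv"))
  env <- read_environment(file.path(dir, "environment.csv"))
  expect_setequal(tr$tip.label, sim$tree$tip.label)
  expect_equal(com$plot, sim$community$plot)
  expect_equal(traits$feeding_group, sim$traits$feeding_group)
  expect_equal(nrow(iso), nrow(sim$isotopes))
  expect_equal(env$rainfall_mm, sim$environment$rainfall_mm, tolerance = 1e-6)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$rng_seed, 3)
})
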