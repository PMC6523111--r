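---
title: "Methods: phylogenetic community structure, trait mapping and isotope statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic community structure, trait mapping and isotope statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

phylocomm asks a classic community-ecology question at desk scale: are the
species that co-occur in a plot more, or less, closely related than chance
would predict, and do their niche traits explain why? The motivating system
is termite assemblages surveyed along an aridity gradient — several sites of
a few standardized transect plots each, a regional pool of a few dozen
species on a molecular phylogeny, feeding niches classified into the four
trophic groups of the humification gradient (I dead wood, II wood/litter,
III humus, IV true soil) and quantified by stable-isotope signatures
(δ¹⁵N tracks diet humification, δ¹³C the C3/C4 carbon source) — but every
stage is generic.

This vignette is the package's own account of its methods: the statistics it
computes, the null models and their assumptions, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical corner cases.

## 1. MPD and the Net Relatedness Index

For a plot holding species set $S$ with abundances $a_i$, the mean pairwise
phylogenetic distance is

$$\mathrm{MPD} = \frac{\sum_{i<j\in S} a_i a_j\, d_{ij}}{\sum_{i<j\in S} a_i a_j},$$

with $d_{ij}$ the patristic distance (sum of branch lengths on the tip-to-tip
path). Unit abundances give the unweighted mean over distinct pairs. Note the
denominator excludes conspecific self-pairs; some implementations (e.g.
picante) include them, which rescales the value by
$\left((\sum a)^2 - \sum a^2\right)/(\sum a)^2$ but not the conclusions.

The Net Relatedness Index standardizes the observed MPD against a null
distribution:

$$\mathrm{NRI} = -\,\frac{\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null}}{\mathrm{sd}(\mathrm{MPD}_{null})},$$

so positive values mean co-occurring species are more related than expected
(phylogenetic clustering, consistent with environmental filtering of
conserved niches) and negative values mean overdispersion (consistent with
competitive exclusion among relatives). Because both numerator and
denominator are in branch-length units, NRI is invariant to rescaling all
branch lengths — a property the tests exercise.

### The independent-swap null

Null communities come from the independent-swap randomization of the binary
plot × species occurrence matrix: 2×2 checkerboard submatrices
(`[[1,0],[0,1]]` and its mirror) are flipped, which preserves every species'
occurrence total and every plot's richness. Defaults, exposed as
configuration:

* each null matrix is sampled after 10 × (number of occupied cells)
  successful swaps, with one such schedule as burn-in — long enough that
  successive samples are effectively decorrelated at the matrix sizes the
  package targets;
* the attempt budget is 100 × the target swap count; a matrix with no
  swappable checkerboard (e.g. all-ones) is returned unchanged with a
  warning;
* swaps act on occurrences only. When abundance-weighted MPD is requested
  (the default), each species' observed positive abundances are carried to
  its null occurrences by uniform permutation, so the null preserves each
  species' abundance distribution as well as both margins.

Two caveats are worth knowing. First, the successful-swap chain's stationary
distribution is not exactly uniform over the fixed-margin class (it weights
states by their number of checkerboards); on exhaustively enumerable
fixtures the induced error in NRI measures at about 0.02–0.03, and the test
suite bounds it at 0.05. Second, because the null conditions on occurrence
totals, a filtering pressure shared identically by *every* plot is invisible
to it — the signal comes from plots differing from the rest of the matrix.
This is why the synthetic study (like the field design it mirrors) mixes
assembly modes across sites under one regional pool.

### Rank test and pools

Significance uses a two-tailed rank test: the observed MPD is ranked among
the $R$ null values, ties counted half
($\mathrm{rank} = 1 + \#\{null < obs\} + 0.5\,\#\{null = obs\}$, rounded half
up), and flagged when rank $\ge \lceil(1-\alpha/2)(R+1)\rceil$ or
$\le \lfloor(\alpha/2)(R+1)\rfloor$ — at $R = 9999$, $\alpha = 0.05$ the
critical ranks are 9750 and 250. The half-count keeps the two-sided test
unbiased under discrete nulls.

`run_pool_analysis()` runs every plot against either the regional pool (all
species observed anywhere; the whole matrix is swapped) or a site-specific
pool (each site's plots and species swapped separately). Plots with fewer
than two species are reported as flagged `NA` rows, never dropped silently;
a degenerate null (zero spread) flags the row rather than producing an
infinite NRI.

```{r}
library(phylocomm)
sim <- simulate_dataset(simulation_config(), rng_seed = 7)
res <- run_pool_analysis(sim$community, sim$tree, pool = "regional",
                         n_rand = 199, rng_seed = 7)
glance(res)
```

## 2. Parsimony trait mapping

`fitch_unordered()` reconstructs ancestral states of a categorical character
under unordered parsimony (every state change costs 1): the classic
downpass/uppass gives the per-node sets of states attainable in some
most-parsimonious reconstruction (MPR), a canonical resolved MPR (parent's
state preferred on the way down, ties broken by state order), and the score.
Polytomies are folded left-to-right into pairwise intersection-else-union
steps; the reported score is therefore the parsimony score of that binary
expansion, which for a true multifurcation can undercut the multifurcating
optimum — on binary trees the score is exact, and the tests arbitrate it
against an independent Sankoff dynamic program and phangorn.

Because a claim like "soil-feeding evolved only once" is a statement over
*all* MPRs, `count_transitions()` reports, besides the canonical
resolution's count of `from → to` edges, the exact minimum and maximum of
that count over every MPR, via a Sankoff-style program that tracks optimal
transition counts alongside costs.

`squared_change_parsimony()` maps continuous characters (the per-species
mean δ¹⁵N or δ¹³C) by minimizing $\sum_e (x_{parent} - x_{child})^2$ with
unit edge weights — the classic squared-change convention that ignores
branch lengths; a branch-weighted variant (squared change divided by branch
length, equivalent to the maximum-likelihood Brownian reconstruction) is
available but off by default. The minimizer solves the linear system in
which each internal node is the mean of its neighbours; the solution is
unique, always lies inside the observed tip range, and matches a
general-purpose numeric optimizer to 10⁻⁶ in the tests.

### Conservatism by tip permutation

`conservatism_test()` quantifies phylogenetic signal without model fitting:
shuffle the tip assignment, recompute the parsimony score (Fitch for
categorical, squared-change for continuous), and report
$p = (1 + \#\{score_{perm} \le score_{obs}\})/(n_{perm}+1)$. The +1 keeps p
away from zero; a constant character gives p = 1 by construction. This is a
deliberate alternative to likelihood indices (Pagel's λ, Blomberg's K),
matching the package's parsimony framing; it tests exchangeability of tips,
not a specific evolutionary model.

```{r}
ct <- conservatism_test(sim$tree, setNames(sim$traits$d15N, sim$traits$species),
                        n_perm = 199, rng_seed = 2)
glance(ct)
```

## 3. Isotope statistics

δ-notation converts isotope ratios to per-mil deviations from the
international standard, $\delta X = (R_{sample}/R_{standard} - 1)\times10^3$.
Summaries report per-group n, mean and the $n-1$ sample SD (`NA`, not 0, for
singletons). Group comparisons use fixed-effects one-way ANOVA with Tukey
HSD all-pairs tests (Tukey–Kramer under unequal n) and a compact letter
display computed by insert-and-absorb over the significant pairs, processed
in sorted order so the partition is independent of input order. Measurement
precision (about 0.1‰ for carbon, 0.2‰ for nitrogen at these sample masses)
is far below the between-group differences of interest and is not propagated
as errors-in-variables.

`correlate_nri_environment()` relates per-plot NRI to rainfall, elevation
and temperature by Pearson correlation (two-sided t, df = n − 2) and also
fits ordinary least squares of NRI on the standardized covariates plus a
site fixed factor. A mixed model with a site random intercept is the
textbook choice here, but with a handful of sites the random-effect variance
is weakly identified and typically estimated at (numerically) zero, making
the fixed-factor OLS the honest equivalent; the result carries the label
`ols_site_fixed` so downstream users see which model produced it. With only
a few sites, the covariates and the site factor are substantially collinear
— the per-variable correlations are the robust summary, the multivariate fit
is indicative.

Degenerate inputs are defined rather than accidental: all-constant data
report F = 0, p = 1, one shared letter (avoiding 0/0); groups with fewer
than two observations are excluded from the omnibus with a warning;
zero-variance covariates are flagged `NA` rather than crashing the fit.

## 4. The synthetic study generator

`simulate_dataset()` generates the full data structure the analyses consume,
so the pipeline can be exercised, calibrated and power-checked without any
field data. What it emulates, and the defaults (all in
`simulation_config()`), chosen once to mirror the motivating survey's scale
and printed summary statistics:

* **Tree** — Yule pure-birth, 32 tips, rate 1: while $k$ lineages are alive
  the next split waits $\mathrm{Exp}(k\lambda)$; the tree stops one waiting
  time after reaching $n$ tips, so the expected depth is
  $\sum_{k=2}^{n} 1/k \approx 3.04$. Ultrametric by construction.
* **Traits** — δ¹⁵N and δ¹³C evolve by Brownian motion from roots 6.0‰ and
  −27.0‰ with rates 2.2 and 0.7 ‰ per √(branch unit), putting tip spreads
  near 3.8‰ and 1.2‰ — the survey's reported termite SDs. Feeding groups
  take a sparse stepwise jump process along the humification ladder
  (I↔II↔III↔IV, rate 0.1 per branch unit, root II): roughly three shifts on
  a total tree length of ~31, so clades share groups, as the trait-mapping
  stage assumes.
* **Communities** — 3 sites × 5 plots, plot richness Poisson with mean 8
  truncated to [2, pool]. Site 1 (wet) *filters*: species enter with weight
  $\exp(-s\,|δ^{15}N - \text{site optimum}|)$, $s = 1$ per ‰ — a species
  2.3‰ off-optimum is 10× less likely than one at the optimum. Site 2 is
  *random*. Site 3 (dry) *competes*: candidates are rejected when their
  minimum patristic distance to the residents falls below $s' \times$ mean
  pairwise distance, $s' = 0.5$; infeasible richness is truncated with a
  warning. Abundances are i.i.d. geometric (the analyses should not, and per
  the tests do not, depend on the abundance shape). Environments are site
  means (rainfall 1500/1100/700 mm, elevation 300/180/60 m, temperature
  26.5/27.0/27.7 °C) plus plot noise — the dry, warm, low site is the
  competitive one, mirroring the aridity-gradient hypothesis.
* **Isotopes** — three replicate workers per species per occupied site
  around the species mean (residual SD 1.2/0.6 ‰), 15 litter rows per site
  with the last (dry) site offset +1.5‰ in both elements, and 5 soil rows
  per site with no site effect — so litter shows a detectable site signal
  and soil is a built-in negative control.

What the generator does **not** emulate: spatial autocorrelation among
plots, colony demography, intraspecific trait structure, non-equilibrium
climate, or any correlation between abundance and traits. Passing tests
therefore demonstrate that the statistics do what they claim under their own
assumptions — correct nulls, calibrated type-I error near 0.05, recovery of
the direction of filtering vs. competition, detection of Brownian
conservatism — not that any particular field dataset satisfies those
assumptions.

## 5. Problem sizes, reproducibility, limitations

The shipped tests and the acceptance script run the Monte-Carlo stages at
sizes chosen for a laptop: 199–9999 null randomizations depending on the
question (9999 where a printed critical value is at stake, 199 for
calibration sweeps), 1000 plots for the type-I check, 200 plots per assembly
mode for direction recovery, and 100 replicates for power-style summaries.
All randomness flows from a single user-supplied seed per run; the swap
chain consumes R's RNG stream (via Rcpp), so `set.seed` reproduces entire
analyses bit for bit.

Known limitations, stated plainly: the swap null's slight non-uniformity
(above); the folded-polytomy parsimony score (above); letters from the
insert-absorb display are a readable summary, not a substitute for the
underlying Tukey p-values, which are always returned; and site-specific
pools with very few plots per site have little power — the same small-n
caveat the motivating field design faces.
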