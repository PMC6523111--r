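# Independent oracles used across the suite. These deliberately share no
# code with the package: graph search for patristic distances, explicit
# enumeration for null models and parsimony, a generic optimizer for
# squared-change reconstructions, and direct sums of squares for ANOVA.

# Patristic distances by breadth-first search over the unrooted edge graph.
bfs_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  adj <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]; w <- tree$edge.length[i]
    adj[[p]] <- rbind(adj[[p]], c(c, w))
    adj[[c]] <- rbind(adj[[c]], c(p, w))
  }
  D <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (start in seq_len(n_tip)) {
    dist <- rep(NA_real_, n_all)
    dist[start] <- 0
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][k, 2]
          queue <- c(queue, u)
        }
      }
    }
    D[start, ] <- dist[seq_len(n_tip)]
  }
  D
}

# All binary matrices with the given row and column sums.
enumerate_margin_matrices <- function(rs, cs) {
  out <- list()
  rec <- function(rows, cs_left) {
    i <- length(rows) + 1
    if (i > length(rs)) {
      if (all(cs_left == 0)) out[[length(out) + 1]] <<- do.call(rbind, rows)
      return()
    }
    if (rs[i] == 0) {
      rec(c(rows, list(rep(0L, length(cs_left)))), cs_left)
      return()
    }
    cols <- which(cs_left > 0)
    if (length(cols) < rs[i]) return()
    sel_all <- utils::combn(cols, rs[i])
    for (j in seq_len(ncol(sel_all))) {
      r <- rep(0L, length(cs_left)); r[sel_all[, j]] <- 1L
      rec(c(rows, list(r)), cs_left - r)
    }
  }
  rec(list(), cs)
  out
}

# Exhaustively enumerated standardized effect size of a plot's unweighted
# MPD under the uniform fixed-margins null.
exact_ses <- function(pres, dist, plot_row) {
  sp <- colnames(pres)
  mpd_row <- function(r) {
    pr <- sp[r == 1]
    s <- dist[pr, pr]
    mean(s[upper.tri(s)])
  }
  mats <- enumerate_margin_matrices(rowSums(pres), colSums(pres))
  vals <- vapply(mats, function(m) mpd_row(m[plot_row, ]), numeric(1))
  -(mpd_row(pres[plot_row, ]) - mean(vals)) / sd(vals)
}

# Sankoff dynamic program with unit costs; handles polytomies natively.
sankoff_score <- function(tree, tip_states) {
  states <- sort(unique(as.character(tip_states)))
  ns <- length(states)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  INF <- 1e9
  cost <- matrix(0, n_all, ns)
  for (i in seq_len(n_tip)) {
    cost[i, ] <- INF
    cost[i, match(tip_states[[tree$tip.label[i]]], states)] <- 0
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1]; c <- ord$edge[i, 2]
    add <- vapply(seq_len(ns), function(s) min(cost[c, ] + (seq_len(ns) != s)), numeric(1))
    cost[p, ] <- cost[p, ] + add
  }
  min(cost[n_tip + 1, ])
}

# Squared-change objective minimized by a generic gradient optimizer.
numeric_sqcp <- function(tree, tip_values, branch_weighted = FALSE) {
  n_tip <- length(tree$tip.label)
  tipv <- tip_values[tree$tip.label]
  w <- if (branch_weighted) 1 / tree$edge.length else rep(1, nrow(tree$edge))
  val <- function(x, node) if (node <= n_tip) tipv[[node]] else x[node - n_tip]
  obj <- function(x) {
    sum(w * (vapply(seq_len(nrow(tree$edge)), function(i) {
      val(x, tree$edge[i, 1]) - val(x, tree$edge[i, 2])
    }, numeric(1)))^2)
  }
  grad <- function(x) {
    g <- numeric(tree$Nnode)
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
      dd <- 2 * w[i] * (val(x, p) - val(x, c))
      if (p > n_tip) g[p - n_tip] <- g[p - n_tip] + dd
      if (c > n_tip) g[c - n_tip] <- g[c - n_tip] - dd
    }
    g
  }
  fit <- stats::optim(rep(mean(tipv), tree$Nnode), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  list(values = fit$par, score = fit$value)
}

# One-way ANOVA F from explicit sums of squares.
anova_f_oracle <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_b <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  k <- length(unique(groups)); n <- length(values)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

# Small community fixture shared by NRI tests: 4 tips, 3 plots.
fixture_tree <- function() read_newick("((A:1,B:1):1,(C:1,D:2):0.5);")

fixture_community <- function() {
  tibble::tibble(
    plot = c("p1", "p2", "p3"), site = "s1",
    A = c(1L, 0L, 1L), B = c(1L, 1L, 0L), C = c(0L, 1L, 1L), D = c(1L, 1L, 0L)
  )
}

random_states <- function(tree, k = 3) {
  setNames(sample(c("I", "II", "III", "IV")[seq_len(k)], length(tree$tip.label),
                  replace = TRUE), tree$tip.label)
}
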