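# Binarize a rooted tree's polytomies by left-to-right folding:
# children (c1, c2, ..., ck) become ((...((c1,c2),c3)...), ck) with pseudo
# nodes on the spine. Original node ids are preserved (a polytomy keeps its
# id as the topmost fold); pseudo nodes get fresh ids.
binarize_tree <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    kids[[p]] <- c(kids[[p]], c)
  }
  children <- vector("list", n_all)
  parent <- integer(n_all)
  nxt <- n_all
  add_node <- function() {
    nxt <<- nxt + 1L
    children[[nxt]] <<- integer(0)
    parent[nxt] <<- 0L
    nxt
  }
  for (v in (n_tip + 1):n_all) {
    ch <- kids[[v]]
    if (length(ch) <= 2) {
      children[[v]] <- ch
    } else {
      cur <- ch[1]
      for (j in 2:(length(ch) - 1)) {
        length(parent) <- max(length(parent), nxt + 1L)
        p <- add_node()
        children[[p]] <- c(cur, ch[j])
        cur <- p
      }
      children[[v]] <- c(cur, ch[length(ch)])
    }
  }
  total <- nxt
  length(parent) <- total
  for (v in seq_len(total)) for (c in children[[v]]) parent[c] <- v
  root <- setdiff((n_tip + 1):n_all, tree$edge[, 2])[1]
  # iterative postorder
  post <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(v, post)
    stack <- c(stack, children[[v]])
  }
  list(children = children, parent = parent, root = root,
       postorder = post, n_tip = n_tip, n_orig = n_all, n_total = total)
}

#' Unordered (Fitch) parsimony ancestral states
#'
#' Reconstructs ancestral states of a categorical character (e.g. termite
#' feeding groups I-IV) under unordered parsimony: the score is the
#' minimum number of state changes on the rooted tree needed to explain
#' the tip states, every change costing 1 regardless of which states are
#' involved. The classic downpass/uppass gives, per node, the set of
#' states occurring in at least one most-parsimonious reconstruction
#' (MPR), plus one canonical resolved MPR obtained by preferring the
#' parent's state on the way down (ties otherwise broken by state order).
#'
#' Polytomies are folded left-to-right into pairwise (intersection-else-
#' union) steps.
#'
#' @param tree A rooted `phylo`.
#' @param tip_states Named character/factor vector, one state per tip.
#' @return An object of class `phylocomm_fitch`: fields `score`,
#'   `states` (level order used), `node_sets` (tips + internal nodes),
#'   `resolved` (canonical MPR state per node), `tree`. Use [tidy()] for a
#'   per-node tibble and [count_transitions()] for edge counts.
#' @examples
#' tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' fit <- fitch_unordered(tr, c(a = "I", b = "I", c = "IV", d = "IV"))
#' fit$score
#' @export
fitch_unordered <- function(tree, tip_states) {
  stopifnot(inherits(tree, "phylo"))
  tree <- validate_phylo(tree)
  tip_states <- resolve_tip_data(tree, tip_states, "state")
  states <- if (is.factor(tip_states)) levels(tip_states) else sort(unique(as.character(tip_states)))
  s_idx <- match(as.character(tip_states), states)
  bin <- binarize_tree(tree)
  ns <- length(states)

  down <- matrix(FALSE, bin$n_total, ns)
  score <- 0L
  for (v in bin$postorder) {
    ch <- bin$children[[v]]
    if (length(ch) == 0) {
      down[v, s_idx[v]] <- TRUE
    } else if (length(ch) == 1) {
      down[v, ] <- down[ch, ]
    } else {
      inter <- down[ch[1], ] & down[ch[2], ]
      if (any(inter)) down[v, ] <- inter
      else { down[v, ] <- down[ch[1], ] | down[ch[2], ]; score <- score + 1L }
    }
  }

  # uppass: MPR-union sets (Swofford & Maddison rule) + canonical resolution
  final <- down
  resolved <- integer(bin$n_total)
  pre <- rev(bin$postorder)
  for (v in pre) {
    if (v == bin$root) {
      final[v, ] <- down[v, ]
      resolved[v] <- which(down[v, ])[1]
      next
    }
    p <- bin$parent[v]
    ch <- bin$children[[v]]
    if (length(ch) >= 2) {
      if (all(final[p, ] <= down[v, ])) {            # F(p) subset of D(v)
        final[v, ] <- final[p, ]
      } else if (any(down[ch[1], ] & down[ch[2], ])) { # v formed by intersection
        final[v, ] <- down[v, ] | (final[p, ] & (down[ch[1], ] | down[ch[2], ]))
      } else {
        final[v, ] <- down[v, ] | final[p, ]
      }
    } else {
      final[v, ] <- down[v, ]
    }
    resolved[v] <- if (down[v, resolved[p]]) resolved[p] else which(down[v, ])[1]
  }

  keep <- seq_len(bin$n_orig)
  structure(list(
    tree = tree, states = states, score = score,
    node_sets = final[keep, , drop = FALSE],
    down_sets = down, bin = bin,
    resolved = setNames(states[resolved[keep]], node_names(tree)),
    resolved_all = resolved,
    tip_states = setNames(as.character(tip_states), tree$tip.label)
  ), class = "phylocomm_fitch")
}

resolve_tip_data <- function(tree, x, what) {
  if (is.null(names(x))) stop(what, " vector must be named by species", call. = FALSE)
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) {
    stop("missing ", what, " for species: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x[tree$tip.label]
}

node_names <- function(tree) {
  n_tip <- length(tree$tip.label)
  c(tree$tip.label, paste0("node", seq_len(tree$Nnode) + n_tip))
}

#' Count parsimony transitions into a state
#'
#' Number of edges on which the parent's reconstructed state lies in
#' `from_states` and the child's equals `to_state` (and differs from the
#' parent's). Reported for the canonical resolution of
#' [fitch_unordered()] together with the exact minimum and maximum over
#' all most-parsimonious reconstructions, computed by a Sankoff-style
#' dynamic program with unit costs — a claim like "state IV evolved only
#' once" is a statement about that range.
#'
#' @param asr A `phylocomm_fitch` object.
#' @param from_states Character vector of admissible parent states.
#' @param to_state Single child state.
#' @return One-row tibble: `from`, `to`, `count` (canonical resolution),
#'   `mpr_min`, `mpr_max`.
#' @export
count_transitions <- function(asr, from_states, to_state) {
  stopifnot(inherits(asr, "phylocomm_fitch"), length(to_state) == 1)
  states <- asr$states
  bin <- asr$bin
  from_i <- match(from_states, states)
  from_i <- from_i[!is.na(from_i)]
  to_i <- match(to_state, states)
  if (is.na(to_i) || length(from_i) == 0) {
    # states never observed at the tips cannot take part in any MPR change
    return(tibble::tibble(from = paste(from_states, collapse = "|"),
                          to = to_state, count = 0L, mpr_min = 0L, mpr_max = 0L))
  }

  res <- asr$resolved_all
  canonical <- 0L
  for (v in seq_len(bin$n_total)) {
    p <- bin$parent[v]
    if (p == 0L) next
    if (res[p] %in% from_i && res[v] == to_i && res[p] != res[v]) canonical <- canonical + 1L
  }

  # Sankoff DP: cost(v,s) = min changes in subtree given state s at v;
  # among optimal choices track min/max focal-transition counts.
  ns <- length(states)
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(INF, bin$n_total, ns)
  cmin <- matrix(0L, bin$n_total, ns)
  cmax <- matrix(0L, bin$n_total, ns)
  tip_idx <- match(asr$tip_states, states)
  for (v in bin$postorder) {
    ch <- bin$children[[v]]
    if (length(ch) == 0) {
      cost[v, tip_idx[v]] <- 0L
      next
    }
    cost[v, ] <- 0L
    for (s in seq_len(ns)) {
      for (c in ch) {
        tot <- cost[c, ] + as.integer(seq_len(ns) != s)
        best <- min(tot)
        opt <- which(tot == best)
        focal <- as.integer(s %in% from_i & opt == to_i & opt != s)
        cost[v, s] <- cost[v, s] + best
        cmin[v, s] <- cmin[v, s] + min(cmin[c, opt] + focal)
        cmax[v, s] <- cmax[v, s] + max(cmax[c, opt] + focal)
      }
    }
  }
  r <- bin$root
  opt <- which(cost[r, ] == min(cost[r, ]))
  tibble::tibble(
    from = paste(from_states, collapse = "|"), to = to_state,
    count = canonical,
    mpr_min = min(cmin[r, opt]), mpr_max = max(cmax[r, opt])
  )
}

#' Squared-change parsimony reconstruction of a continuous character
#'
#' Assigns values to internal nodes minimizing the summed squared change
#' over edges, \eqn{\sum_e (x_{parent(e)} - x_{child(e)})^2}, with unit
#' edge weights by default (branch lengths are ignored, the classic
#' "squared parsimony" convention); with `branch_weighted = TRUE` each
#' edge's squared change is divided by its branch length. The minimizer
#' solves the linear system in which every internal node equals the
#' (weighted) mean of its neighbours, so reconstructed values always lie
#' within the observed tip range.
#'
#' @param tree A rooted `phylo`.
#' @param tip_values Named finite numeric vector, one value per tip.
#' @param branch_weighted Divide squared changes by branch length?
#' @return An object of class `phylocomm_sqcp`: `values` (tips then
#'   internal nodes), `score` (the minimized sum), `tree`,
#'   `branch_weighted`. Use [tidy()] for a per-node tibble.
#' @examples
#' tr <- read_newick("(a:1,b:1,c:1);")
#' squared_change_parsimony(tr, c(a = 0, b = 0, c = 3))$values
#' @export
squared_change_parsimony <- function(tree, tip_values, branch_weighted = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  tree <- validate_phylo(tree)
  tip_values <- resolve_tip_data(tree, tip_values, "value")
  if (!all(is.finite(tip_values))) {
    stop("non-finite value for species: ",
         paste(names(tip_values)[!is.finite(tip_values)], collapse = ", "), call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  w <- if (branch_weighted) {
    if (any(tree$edge.length <= 0)) stop("branch_weighted needs positive branch lengths", call. = FALSE)
    1 / tree$edge.length
  } else rep(1, nrow(tree$edge))

  A <- matrix(0, n_int, n_int)
  b <- numeric(n_int)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1] - n_tip
    c <- tree$edge[i, 2]
    A[p, p] <- A[p, p] + w[i]
    if (c > n_tip) {
      ci <- c - n_tip
      A[ci, ci] <- A[ci, ci] + w[i]
      A[p, ci] <- A[p, ci] - w[i]
      A[ci, p] <- A[ci, p] - w[i]
    } else {
      b[p] <- b[p] + w[i] * tip_values[c]
    }
  }
  internal <- solve(A, b)
  values <- setNames(c(unname(tip_values), internal), node_names(tree))
  diffs <- values[tree$edge[, 1]] - values[tree$edge[, 2]]
  score <- sum(w * diffs^2)
  structure(list(tree = tree, values = values, score = score,
                 branch_weighted = branch_weighted),
            class = "phylocomm_sqcp")
}

#' Tip-permutation test of phylogenetic trait conservatism
#'
#' Shuffles the tip assignment of the character and recomputes the
#' parsimony score — Fitch score for a categorical character,
#' squared-change score for a continuous one. A conserved trait sits in
#' few clades and so has a lower observed score than almost all
#' permutations; the p-value is
#' `(1 + #{permuted score <= observed}) / (n_perm + 1)`.
#'
#' @param tree A rooted `phylo`.
#' @param tip_data Named vector: character/factor for the categorical
#'   test, numeric for the continuous one.
#' @param n_perm Number of permutations (at least 99).
#' @param rng_seed Optional seed.
#' @return Object of class `phylocomm_cons`: `observed`, `perm_scores`,
#'   `p_value`, `type`. [glance()] gives a one-row tibble; [autoplot()]
#'   draws the null distribution.
#' @export
conservatism_test <- function(tree, tip_data, n_perm = 999, rng_seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  tip_data <- resolve_tip_data(tree, tip_data, "trait")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  categorical <- is.character(tip_data) || is.factor(tip_data)
  score_fun <- if (categorical) {
    function(x) fitch_unordered(tree, x)$score
  } else {
    function(x) squared_change_parsimony(tree, x)$score
  }
  obs <- score_fun(tip_data)
  nm <- names(tip_data)
  perm <- vapply(seq_len(n_perm), function(i) {
    score_fun(setNames(unname(tip_data)[sample.int(length(tip_data))], nm))
  }, numeric(1))
  p <- (1 + sum(perm <= obs)) / (n_perm + 1)
  structure(list(observed = obs, perm_scores = perm, p_value = p,
                 n_perm = n_perm,
                 type = if (categorical) "fitch" else "squared_change"),
            class = "phylocomm_cons")
}

#' Export a reconstruction as an annotated Newick string
#'
#' Internal node labels carry the reconstructed state (canonical MPR) or
#' value (3 decimal places).
#'
#' @param asr A `phylocomm_fitch` or `phylocomm_sqcp` object.
#' @param path Optional file; if `NULL` the string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_annotated_newick <- function(asr, path = NULL) {
  tr <- asr$tree
  n_tip <- length(tr$tip.label)
  lab <- if (inherits(asr, "phylocomm_fitch")) {
    unname(asr$resolved[(n_tip + 1):(n_tip + tr$Nnode)])
  } else if (inherits(asr, "phylocomm_sqcp")) {
    sprintf("%.3f", unname(asr$values[(n_tip + 1):(n_tip + tr$Nnode)]))
  } else stop("unsupported object", call. = FALSE)
  tr$node.label <- lab
  write_newick(tr, path)
}

#' @export
print.phylocomm_fitch <- function(x, ...) {
  cat("Fitch parsimony ASR:", length(x$tree$tip.label), "tips,",
      length(x$states), "states; score =", x$score, "changes\n")
  invisible(x)
}

#' @export
print.phylocomm_sqcp <- function(x, ...) {
  cat("Squared-change parsimony ASR:", length(x$tree$tip.label),
      "tips; score =", format(x$score, digits = 6),
      if (x$branch_weighted) "(branch-weighted)\n" else "(unit weights)\n")
  invisible(x)
}

#' @export
print.phylocomm_cons <- function(x, ...) {
  cat("Trait conservatism (", x$type, " score): observed = ",
      format(x$observed, digits = 6), ", p = ", format(x$p_value, digits = 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}
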