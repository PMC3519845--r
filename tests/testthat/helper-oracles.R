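# Independent brute-force oracles, kept deliberately separate from the
# package's implementations: distance-matrix-based tree construction and
# explicit recursive descendant counting for BN; combinatorial arithmetic
# for the hypergeometric tail.

# BN oracle: per root, assign each node's parent as the lexicographically
# smallest neighbor one step closer to the root (identical tie-break to the
# implementation, arrived at from igraph's distance matrix rather than a
# BFS frontier), then count descendants by explicit recursion.
oracle_bn <- function(net) {
  g <- as_igraph(net)
  ids <- sort(igraph::V(g)$name)
  d <- igraph::distances(g)
  adj <- lapply(stats::setNames(ids, ids), function(v)
    sort(names(igraph::neighbors(g, v))))
  score <- stats::setNames(numeric(length(ids)), ids)
  for (v in ids) {
    tree_nodes <- ids[is.finite(d[v, ids])]
    n_tree <- length(tree_nodes)
    if (n_tree < 2) next
    children <- stats::setNames(vector("list", n_tree), tree_nodes)
    for (w in setdiff(tree_nodes, v)) {
      preds <- adj[[w]][d[v, adj[[w]]] == d[v, w] - 1]
      par <- min(preds)
      children[[par]] <- c(children[[par]], w)
    }
    desc_count <- function(w) {
      if (is.null(children[[w]])) return(0L)
      sum(vapply(children[[w]], function(c) 1L + desc_count(c), 0L))
    }
    for (w in setdiff(tree_nodes, v))
      if (desc_count(w) >= n_tree / 4) score[w] <- score[w] + 1
  }
  score
}

# Exact upper-tail hypergeometric probability by binomial-coefficient sums.
oracle_hyper_tail <- function(k, K, n, N) {
  tot <- choose(N, n)
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / tot
}

# Is node x on some minimal-length path from seed s to the nearest members
# of group G?  Uses the all-pairs distance matrix only.
on_min_seed_group_path <- function(d, s, members, x, max_len) {
  dm <- d[s, members]
  dstar <- suppressWarnings(min(dm))
  if (!is.finite(dstar) || dstar > max_len) return(FALSE)
  nearest <- members[dm == dstar]
  any(vapply(nearest, function(g)
    is.finite(d[s, x]) && is.finite(d[x, g]) &&
      d[s, x] + d[x, g] == dstar, TRUE))
}
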