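# Topological essentiality scoring: shortest-path-tree bottleneck counts
# (BN), maximum-neighborhood-component statistics (MNC, DMNC), degree, and
# the DSS double-screening scheme combining DMNC with MNC. All scores are
# computed on the simple undirected topology.

#' Build a rooted shortest-path (BFS) tree
#'
#' Constructs the breadth-first shortest-path tree rooted at a node,
#' spanning the root's connected component. When a node is reachable from
#' several predecessors at the previous depth, its parent is the one with
#' the lexicographically smallest id — a deterministic tie-break, since the
#' shortest-path tree is otherwise not unique. `subtree_weight` is the
#' strict descendant count of each node (leaves weigh 0), equal to the
#' number of shortest paths from the root that pass through the node.
#'
#' @param net An [interaction_network()].
#' @param root A node id present in the network.
#' @return An object of class `sp_tree`: list with `root`, `parent` (named
#'   character; tree nodes except the root), `depth` (named integer),
#'   `subtree_weight` (named integer) and `n_tree` (number of tree nodes).
#' @export
build_sp_tree <- function(net, root) {
  stopifnot(inherits(net, "interaction_network"))
  adj <- adjacency_list(net)
  if (!root %in% names(adj))
    stop("unknown root node: ", root, call. = FALSE)
  .sp_tree(adj, root)
}

# BFS level-by-level with the frontier visited in ascending id order, so a
# node's first discoverer is its lexicographically smallest predecessor.
.sp_tree <- function(adj, root) {
  parent <- character(0)
  depth <- stats::setNames(0L, root)
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    frontier <- sort(frontier)
    nxt <- character(0)
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (is.na(depth[w])) {
          depth[w] <- d + 1L
          parent[w] <- u
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  nodes <- names(depth)
  weight <- stats::setNames(integer(length(nodes)), nodes)
  for (w in nodes[order(depth[nodes], decreasing = TRUE)]) {
    if (w == root) next
    p <- parent[[w]]
    weight[p] <- weight[p] + weight[w] + 1L
  }
  structure(list(root = root, parent = parent, depth = depth,
                 subtree_weight = weight, n_tree = length(nodes)),
            class = "sp_tree")
}

#' @export
print.sp_tree <- function(x, ...) {
  cat("Shortest-path tree rooted at", x$root, "-", x$n_tree, "nodes, depth",
      max(x$depth), "\n")
  invisible(x)
}

# Assemble a ranked score table: descending score, ties broken by ascending
# node id. `secondary` optionally breaks ties before the id (used by DSS).
hub_score_table <- function(scores, method, secondary = NULL) {
  nodes <- names(scores)
  if (is.null(secondary)) {
    ord <- order(-scores, nodes)
  } else {
    ord <- order(-scores, -secondary, nodes)
  }
  out <- data.frame(rank = seq_along(nodes), node = nodes[ord],
                    score = unname(scores[ord]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, method = method,
            class = c("hub_score_table", "data.frame"))
}

#' @export
print.hub_score_table <- function(x, n = 10, ...) {
  cat("Hub scores (", attr(x, "method"), "), ", nrow(x), " nodes\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Bottleneck (BN) scores
#'
#' For every node \eqn{v}, the shortest-path tree \eqn{T_v} rooted at
#' \eqn{v} is built (see [build_sp_tree()]). A non-root node \eqn{w} is a
#' bottleneck in \eqn{T_v} when its strict descendant count is no less than
#' \eqn{n/4}, where \eqn{n} is the number of nodes in \eqn{T_v} (the
#' threshold is the real value \eqn{n/4}, compared with \eqn{\ge}). The BN
#' score of \eqn{w} is the number of roots \eqn{v} for which \eqn{w} is a
#' bottleneck. The root itself is never counted as a bottleneck of its own
#' tree: its descendant count \eqn{n-1} would qualify trivially. Trees are
#' per connected component; cross-component pairs contribute nothing. Nodes
#' with high BN sit at the intersections between clusters: removing them
#' partitions the network.
#'
#' @param net An [interaction_network()].
#' @return A `hub_score_table` (data frame with `rank`, `node`, `score`).
#' @examples
#' p3 <- interaction_network(relations = data.frame(
#'   source = c("a", "b"), target = c("b", "c")))
#' bn_scores(p3)  # b scores 2
#' @export
bn_scores <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  adj <- adjacency_list(net)
  score <- stats::setNames(numeric(length(adj)), names(adj))
  for (v in names(adj)) {
    tr <- .sp_tree(adj, v)
    if (tr$n_tree < 2) next
    thr <- tr$n_tree / 4
    w <- names(tr$subtree_weight)
    hits <- w[w != v & tr$subtree_weight >= thr]
    score[hits] <- score[hits] + 1
  }
  hub_score_table(score, "bn")
}

# Largest connected component of the subgraph induced by v's open
# neighborhood; returns c(n_nodes, n_edges) of that component (0, 0 when
# the neighborhood is empty).
.mnc_component <- function(g, v) {
  nb <- igraph::neighbors(g, v)
  if (length(nb) == 0) return(c(0L, 0L))
  sub <- igraph::induced_subgraph(g, nb)
  comp <- igraph::components(sub)
  big <- which.max(comp$csize)
  vs <- igraph::V(sub)[comp$membership == big]
  mc <- igraph::induced_subgraph(sub, vs)
  c(igraph::vcount(mc), igraph::ecount(mc))
}

#' Maximum Neighborhood Component (MNC) scores
#'
#' MNC of a node \eqn{v} is the number of nodes in the largest connected
#' component of the subgraph induced by \eqn{v}'s open neighborhood
#' (\eqn{v} itself excluded). An isolated node scores 0. MNC never exceeds
#' the degree.
#'
#' @param net An [interaction_network()].
#' @return A `hub_score_table`.
#' @export
mnc_scores <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  g <- as_igraph(net)
  ids <- igraph::V(g)$name
  score <- stats::setNames(
    vapply(ids, function(v) .mnc_component(g, v)[1], 0), ids)
  hub_score_table(score, "mnc")
}

#' Density of Maximum Neighborhood Component (DMNC) scores
#'
#' DMNC of a node is \eqn{E / V^{\epsilon}} where \eqn{V} and \eqn{E} are
#' the node and edge counts of its maximum neighborhood component (see
#' [mnc_scores()]). A component with at most one node scores 0, so DMNC is
#' zero exactly when the neighborhood component contains no edge. The
#' exponent defaults to 1.7, the value of the original density-style
#' normalization; it is exposed because the method family treats it as a
#' tunable.
#'
#' @param net An [interaction_network()].
#' @param epsilon Positive exponent (default 1.7).
#' @return A `hub_score_table`.
#' @export
dmnc_scores <- function(net, epsilon = 1.7) {
  stopifnot(inherits(net, "interaction_network"), epsilon > 0)
  g <- as_igraph(net)
  ids <- igraph::V(g)$name
  score <- stats::setNames(vapply(ids, function(v) {
    ve <- .mnc_component(g, v)
    if (ve[1] <= 1) 0 else ve[2] / ve[1]^epsilon
  }, 0), ids)
  hub_score_table(score, "dmnc")
}

#' Degree scores
#'
#' Distinct-neighbor count on the simple undirected topology.
#'
#' @param net An [interaction_network()].
#' @return A `hub_score_table`.
#' @export
degree_scores <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  score <- lengths(adjacency_list(net))
  hub_score_table(as.numeric(score) |> stats::setNames(names(score)),
                  "degree")
}

#' Double screening scheme (DSS) ranking
#'
#' Two-stage hub shortlist: stage 1 selects the \eqn{2n} top-ranked nodes
#' by DMNC (an empirical pool factor); stage 2 re-ranks that pool by MNC
#' and returns the top \eqn{n}. Combining the two neighborhood statistics
#' captures a mixed characteristic of essential proteins that either alone
#' misses. The returned table carries the stage-2 MNC values as scores;
#' stage-1 pool ties and stage-2 ties are broken by ascending node id.
#'
#' @param net An [interaction_network()] with at least one node.
#' @param n_out Number of output hubs \eqn{n} (default 30, the usual
#'   top-30 report size).
#' @param screen_factor Pool multiplier for stage 1 (default 2, the
#'   empirical value).
#' @param epsilon DMNC exponent, passed to [dmnc_scores()].
#' @return A `hub_score_table` of at most `n_out` rows with attribute
#'   `pool` (the stage-1 node ids).
#' @export
dss_rank <- function(net, n_out = 30, screen_factor = 2, epsilon = 1.7) {
  stopifnot(inherits(net, "interaction_network"), n_out >= 1,
            nrow(net$nodes) >= 1)
  dm <- dmnc_scores(net, epsilon = epsilon)
  pool_size <- min(screen_factor * n_out, nrow(dm))
  pool <- dm$node[seq_len(pool_size)]
  mn <- mnc_scores(net)
  mnc_pool <- stats::setNames(mn$score, mn$node)[pool]
  ord <- order(-mnc_pool, pool)
  k <- min(n_out, pool_size)
  sel <- pool[ord][seq_len(k)]
  out <- data.frame(rank = seq_len(k), node = sel,
                    score = unname(mnc_pool[sel]), stringsAsFactors = FALSE)
  structure(out, method = "dss", pool = pool,
            class = c("hub_score_table", "data.frame"))
}

#' Top-k nodes of a ranked score table
#'
#' @param table A `hub_score_table`.
#' @param k Number of nodes to return (`k >= 1`). When `k` exceeds the
#'   table size, all nodes are returned with a warning.
#' @return Character vector of node ids in rank order.
#' @export
top_k <- function(table, k) {
  stopifnot(inherits(table, "hub_score_table"), k >= 1)
  if (k > nrow(table)) {
    warning("k = ", k, " exceeds table size ", nrow(table),
            "; returning all nodes", call. = FALSE)
    k <- nrow(table)
  }
  table$node[seq_len(k)]
}

#' Score a network with a named hub method
#'
#' Dispatch helper used by the pipeline driver.
#'
#' @param net An [interaction_network()].
#' @param method One of `"degree"`, `"bn"`, `"mnc"`, `"dmnc"`, `"dss"`.
#' @param ... Passed to the method (`n_out`, `epsilon`, ...).
#' @return A `hub_score_table`.
#' @export
hub_scores <- function(net, method = c("degree", "bn", "mnc", "dmnc", "dss"),
                       ...) {
  method <- match.arg(method)
  switch(method,
         degree = degree_scores(net),
         bn = bn_scores(net),
         mnc = mnc_scores(net),
         dmnc = dmnc_scores(net, ...),
         dss = dss_rank(net, ...))
}
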