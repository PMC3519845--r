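# Small graph builders used across the suite.

net_from_pairs <- function(a, b, rel_type = "binding", ...) {
  interaction_network(relations = data.frame(source = a, target = b,
                                             rel_type = rel_type, ...))
}

path_net <- function(ids) net_from_pairs(ids[-length(ids)], ids[-1])

star_net <- function(m, center = "hub") {
  leaves <- sprintf("leaf%02d", seq_len(m))
  net_from_pairs(rep(center, m), leaves)
}

clique_net <- function(ids) {
  pr <- t(utils::combn(ids, 2))
  net_from_pairs(pr[, 1], pr[, 2])
}

# Random connected Erdos-Renyi network on n nodes (regenerates until the
# graph is connected).
random_connected_net <- function(n, p = 0.35) {
  ids <- sprintf("n%02d", seq_len(n))
  pr <- t(utils::combn(ids, 2))
  repeat {
    keep <- stats::runif(nrow(pr)) < p
    if (!any(keep)) next
    net <- net_from_pairs(pr[keep, 1], pr[keep, 2])
    if (nrow(net$nodes) == n &&
        igraph::is_connected(as_igraph(net))) return(net)
  }
}

# Random (possibly disconnected) network: every node present, random edges.
random_net <- function(n, p = 0.3) {
  ids <- sprintf("n%02d", seq_len(n))
  pr <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pr)) < p
  rel <- data.frame(source = pr[keep, 1], target = pr[keep, 2],
                    rel_type = "binding", stringsAsFactors = FALSE)
  interaction_network(ids, rel)
}
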