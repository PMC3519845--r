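# Synthetic study generator: heavy-tailed interactomes, planted
# bottleneck/cluster structure, expression tables with planted effects, and
# annotation sets with a planted enriched term. Every generator is
# bit-reproducible from cfg$rng_seed: each reseeds at entry with the config
# seed plus a fixed stage offset (interactome/bottlenecks +0, expression +1,
# annotations +2), so standalone calls and pipeline runs agree.

#' Configuration for the synthetic-study generators
#'
#' Defaults define the simulated study conditions: a 500-node
#' preferential-attachment interactome (2 edges per new node), 10% of
#' protein nodes differentially expressed with fold changes 2.0 (up) and
#' 0.5 (down) and p-values below 0.01 — effects that straddle the 1.5 /
#' 0.66 / 0.05 screening thresholds with a strict margin — null fold
#' changes log-uniform in [0.8, 1.25], and 50 annotation terms with one
#' planted term fully overlapping its target set.
#'
#' @param n_nodes Number of interactome nodes.
#' @param attach_m Edges added per new node in preferential attachment.
#' @param n_clusters,cluster_size,n_connectors Planted bottleneck structure
#'   (used by [plant_bottlenecks()]): number and size of dense clusters and
#'   the number of connector nodes joining them.
#' @param de_fraction Fraction of protein nodes that are differentially
#'   expressed.
#' @param up_effect Planted upregulation fold change (> 1.5).
#' @param down_effect Planted downregulation fold change (in (0, 0.66)).
#' @param de_p_max Upper bound of planted p-values (< 0.05).
#' @param n_terms Number of annotation terms (including the planted one).
#' @param planted_term_overlap Fraction of the target set contained in the
#'   planted term, in (0, 1].
#' @param rng_seed Integer seed; all generators are deterministic given it.
#' @param kind_props,rel_props Named numeric vectors of node-kind and
#'   relation-type proportions for [simulate_interactome()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 500, attach_m = 2, n_clusters = 0,
                       cluster_size = 0, n_connectors = 0,
                       de_fraction = 0.1, up_effect = 2.0,
                       down_effect = 0.5, de_p_max = 0.01, n_terms = 50,
                       planted_term_overlap = 1.0, rng_seed = 1L,
                       kind_props = c(protein = 0.85, small_molecule = 0.06,
                                      functional_class = 0.04,
                                      complex = 0.03, cell_process = 0.02),
                       rel_props = c(binding = 0.45, regulation = 0.20,
                                     expression = 0.10,
                                     protein_modification = 0.10,
                                     direct_regulation = 0.08,
                                     promoter_binding = 0.07)) {
  cfg <- list(n_nodes = as.integer(n_nodes), attach_m = as.integer(attach_m),
              n_clusters = as.integer(n_clusters),
              cluster_size = as.integer(cluster_size),
              n_connectors = as.integer(n_connectors),
              de_fraction = de_fraction, up_effect = up_effect,
              down_effect = down_effect, de_p_max = de_p_max,
              n_terms = as.integer(n_terms),
              planted_term_overlap = planted_term_overlap,
              rng_seed = as.integer(rng_seed),
              kind_props = kind_props, rel_props = rel_props)
  if (cfg$n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  if (cfg$attach_m < 1) stop("attach_m must be >= 1", call. = FALSE)
  if (cfg$attach_m >= cfg$n_nodes)
    stop("attach_m must be smaller than n_nodes", call. = FALSE)
  if (cfg$de_fraction <= 0 || cfg$de_fraction >= 1)
    stop("de_fraction must be in (0, 1)", call. = FALSE)
  if (cfg$up_effect <= 1.5)
    stop("up_effect must exceed the 1.5 screen", call. = FALSE)
  if (cfg$down_effect <= 0 || cfg$down_effect >= 0.66)
    stop("down_effect must lie in (0, 0.66)", call. = FALSE)
  if (cfg$de_p_max >= 0.05 || cfg$de_p_max <= 0)
    stop("de_p_max must lie in (0, 0.05)", call. = FALSE)
  if (cfg$planted_term_overlap <= 0 || cfg$planted_term_overlap > 1)
    stop("planted_term_overlap must be in (0, 1]", call. = FALSE)
  if (cfg$n_clusters > 0 || cfg$n_connectors > 0) {
    if (cfg$n_clusters * cfg$cluster_size + cfg$n_connectors > cfg$n_nodes)
      stop("planted clusters + connectors exceed n_nodes", call. = FALSE)
  }
  if (!isTRUE(all.equal(sum(cfg$kind_props), 1)) ||
      !all(names(cfg$kind_props) %in% node_kinds()))
    stop("kind_props must be named by node kinds and sum to 1", call. = FALSE)
  if (!isTRUE(all.equal(sum(cfg$rel_props), 1)) ||
      !all(names(cfg$rel_props) %in% relation_types()))
    stop("rel_props must be named by relation types and sum to 1",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Draw a relation-attribute frame for a set of node pairs. binding stays
# undirected; directed types point source -> target as generated.
.draw_relations <- function(pairs, rel_props) {
  n <- nrow(pairs)
  types <- sample(names(rel_props), n, replace = TRUE, prob = rel_props)
  effects <- sample(relation_effects(), n, replace = TRUE,
                    prob = c(0.45, 0.35, 0.20))
  data.frame(source = pairs[[1]], target = pairs[[2]], rel_type = types,
             effect = effects,
             directed = unname(.default_directed[types]),
             references = "", stringsAsFactors = FALSE)
}

#' Simulate a heavy-tailed interactome
#'
#' Preferential-attachment (Barabasi-Albert style) backbone: the generator
#' starts from a clique on `attach_m + 1` nodes; each subsequent node
#' attaches to `attach_m` distinct existing nodes sampled with probability
#' proportional to their current degree. The edge count is therefore
#' exactly \deqn{\binom{m+1}{2} + m\,(n - m - 1)} for `n = n_nodes`,
#' `m = attach_m` — the closed form tested in the suite. Node kinds and
#' relation types/effects are drawn from the configured proportions; the
#' result is deterministic given `rng_seed`.
#'
#' @param cfg A [sim_config()].
#' @return An [interaction_network()] named `"synthetic"`.
#' @export
simulate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  n <- cfg$n_nodes
  m <- cfg$attach_m
  ids <- sprintf("G%0*d", nchar(n), seq_len(n))
  deg <- integer(n)
  seed_n <- m + 1L
  src <- integer(0); tgt <- integer(0)
  for (i in seq_len(seed_n - 1L))
    for (j in seq(i + 1L, seed_n)) {
      src <- c(src, i); tgt <- c(tgt, j)
    }
  deg[seq_len(seed_n)] <- seed_n - 1L
  for (v in seq(seed_n + 1L, n)) {
    existing <- seq_len(v - 1L)
    tg <- sample(existing, m, prob = deg[existing])
    src <- c(src, rep(v, m)); tgt <- c(tgt, tg)
    deg[v] <- deg[v] + m
    deg[tg] <- deg[tg] + 1L
  }
  pairs <- data.frame(a = ids[pmin(src, tgt)], b = ids[pmax(src, tgt)],
                      stringsAsFactors = FALSE)
  rel <- .draw_relations(pairs, cfg$rel_props)
  kinds <- sample(names(cfg$kind_props), n, replace = TRUE,
                  prob = cfg$kind_props)
  nodes <- data.frame(id = ids, kind = kinds, stringsAsFactors = FALSE)
  interaction_network(nodes, rel, name = "synthetic")
}

#' Closed-form edge count of the simulated interactome
#'
#' @param cfg A [sim_config()].
#' @return `choose(m+1, 2) + m * (n - m - 1)` with `n = n_nodes`,
#'   `m = attach_m`.
#' @export
expected_interactome_edges <- function(cfg) {
  choose(cfg$attach_m + 1, 2) + cfg$attach_m * (cfg$n_nodes - cfg$attach_m - 1)
}

#' Plant bottleneck connectors between dense clusters
#'
#' Generates `n_clusters` dense random clusters (Erdos-Renyi with edge
#' probability 0.6 plus a connecting cycle, so each cluster is connected)
#' joined *only* through `n_connectors` connector nodes, each wired to two
#' random members of every cluster. Removing all connectors disconnects the
#' graph — asserted on every instance; this realizes the defining property
#' of bottleneck nodes, whose removal partitions a network. All relations
#' are undirected binding; all nodes protein.
#'
#' @param cfg A [sim_config()] with `n_clusters >= 2`, `cluster_size >= 3`
#'   and `n_connectors >= 1`.
#' @return A list with `network` (an [interaction_network()]) and `truth`
#'   (character vector of connector ids).
#' @export
plant_bottlenecks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_clusters < 2) stop("n_clusters must be >= 2", call. = FALSE)
  if (cfg$n_connectors < 1) stop("n_connectors must be >= 1", call. = FALSE)
  if (cfg$cluster_size < 3) stop("cluster_size must be >= 3", call. = FALSE)
  set.seed(cfg$rng_seed)
  pairs <- NULL
  cluster_ids <- list()
  for (k in seq_len(cfg$n_clusters)) {
    idk <- sprintf("C%d_%02d", k, seq_len(cfg$cluster_size))
    cluster_ids[[k]] <- idk
    s <- cfg$cluster_size
    # connecting cycle guarantees a connected cluster
    cyc <- cbind(idk, idk[c(2:s, 1)])
    er <- t(utils::combn(idk, 2))
    er <- er[stats::runif(nrow(er)) < 0.6, , drop = FALSE]
    pairs <- rbind(pairs, cyc, er)
  }
  conn <- sprintf("X%02d", seq_len(cfg$n_connectors))
  for (x in conn)
    for (k in seq_len(cfg$n_clusters)) {
      anchors <- sample(cluster_ids[[k]], min(2L, cfg$cluster_size))
      pairs <- rbind(pairs, cbind(x, anchors))
    }
  a <- pmin(pairs[, 1], pairs[, 2]); b <- pmax(pairs[, 1], pairs[, 2])
  keep <- !duplicated(paste(a, b))
  rel <- data.frame(source = a[keep], target = b[keep], rel_type = "binding",
                    effect = "unknown", directed = FALSE, references = "",
                    stringsAsFactors = FALSE)
  net <- interaction_network(c(unlist(cluster_ids), conn), rel,
                             name = "planted_bottlenecks")
  g <- as_igraph(net)
  resid <- igraph::delete_vertices(g, conn)
  if (igraph::components(resid)$no < 2)
    stop("internal error: connector removal failed to disconnect",
         call. = FALSE)
  list(network = net, truth = conn)
}

#' Simulate an expression table with planted effects
#'
#' A fraction `de_fraction` of the network's protein nodes is split evenly
#' into truth-up and truth-down sets. Planted genes receive fold change
#' exactly `up_effect` / `down_effect` and p-values uniform on
#' (0, `de_p_max`); null genes receive fold changes log-uniform on
#' [0.8, 1.25] — strictly inside the no-call band — and p-values uniform on
#' (0, 1). With the default effects the threshold screen separates planted
#' from null genes deterministically, so truth recovery is exact.
#'
#' @param net An [interaction_network()].
#' @param cfg A [sim_config()].
#' @return A list with `records` (data frame: `gene_id`, `fold_change`,
#'   `p_value`), `truth_up` and `truth_down` (character vectors).
#' @export
simulate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "interaction_network"), inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed + 1L)
  genes <- net$nodes$id[net$nodes$kind == "protein"]
  n_de <- floor(cfg$de_fraction * length(genes))
  if (n_de < 2)
    stop("de_fraction * protein-node count must be >= 2", call. = FALSE)
  de <- sample(genes, n_de)
  truth_up <- sort(de[seq_len(ceiling(n_de / 2))])
  truth_down <- sort(setdiff(de, truth_up))
  fc <- stats::setNames(exp(stats::runif(length(genes), log(0.8),
                                         log(1.25))), genes)
  p <- stats::setNames(stats::runif(length(genes)), genes)
  fc[truth_up] <- cfg$up_effect
  fc[truth_down] <- cfg$down_effect
  p[de] <- stats::runif(length(de), 0, cfg$de_p_max)
  list(records = data.frame(gene_id = genes, fold_change = unname(fc),
                            p_value = unname(p), stringsAsFactors = FALSE),
       truth_up = truth_up, truth_down = truth_down)
}

#' Simulate an annotation set with one planted enriched term
#'
#' Builds `n_terms` flat gene sets over the background of all protein-node
#' ids. The planted term (id `"T_planted"`) contains a fraction
#' `planted_term_overlap` of `target_genes`, padded with random non-target
#' genes to the target-set size; the remaining terms sample genes uniformly
#' from the background. With full overlap the planted term attains the
#' minimal hypergeometric p-value on `target_genes` by construction.
#'
#' @param net An [interaction_network()].
#' @param cfg A [sim_config()].
#' @param target_genes Non-empty character vector of protein-node ids.
#' @return An [annotation_set()]; the planted term id is in attribute
#'   `"planted_term"`.
#' @export
simulate_annotations <- function(net, cfg, target_genes) {
  stopifnot(inherits(net, "interaction_network"), inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed + 2L)
  background <- net$nodes$id[net$nodes$kind == "protein"]
  target_genes <- unique(as.character(target_genes))
  if (!length(target_genes))
    stop("target_genes must be non-empty", call. = FALSE)
  if (!all(target_genes %in% background))
    stop("target_genes must be protein nodes of the network", call. = FALSE)
  size <- length(target_genes)
  n_in <- round(cfg$planted_term_overlap * size)
  if (n_in < 1)
    stop("planted_term_overlap infeasible for this target set", call. = FALSE)
  pool <- setdiff(background, target_genes)
  if (size - n_in > length(pool))
    stop("not enough non-target genes to pad the planted term",
         call. = FALSE)
  planted <- c(sample(target_genes, n_in),
               if (size - n_in > 0) sample(pool, size - n_in))
  terms <- list(T_planted = list(description = "planted enriched term",
                                 genes = sort(planted)))
  if (cfg$n_terms > 1)
    for (i in seq_len(cfg$n_terms - 1L))
      terms[[sprintf("T%03d", i)]] <-
        list(description = sprintf("null term %d", i),
             genes = sort(sample(background, min(size, length(background)))))
  ann <- annotation_set(terms, background = background)
  attr(ann, "planted_term") <- "T_planted"
  ann
}

#' Simulate a complete synthetic study
#'
#' Runs the generators in their documented order (interactome, expression,
#' annotations) and returns all pieces plus the ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A list: `network`, `expression` (records), `annotations`,
#'   `truth` (list with `truth_up`, `truth_down`, `planted_term`, and
#'   `connectors` when cluster planting is configured).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  connectors <- character(0)
  if (cfg$n_clusters >= 2 && cfg$n_connectors >= 1) {
    pb <- plant_bottlenecks(cfg)
    net <- pb$network
    connectors <- pb$truth
  } else {
    net <- simulate_interactome(cfg)
  }
  expr <- simulate_expression(net, cfg)
  target <- union(expr$truth_up, expr$truth_down)
  ann <- simulate_annotations(net, cfg, target)
  list(network = net, expression = expr$records, annotations = ann,
       truth = list(truth_up = expr$truth_up, truth_down = expr$truth_down,
                    planted_term = attr(ann, "planted_term"),
                    connectors = connectors))
}
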