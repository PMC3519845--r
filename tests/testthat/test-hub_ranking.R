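# Topological essentiality scores: shortest-path trees, BN, MNC, DMNC,
# degree, DSS, top-k.

test_that("shortest-path trees use the lexicographic parent tie-break", {
  chain <- path_net(c("a", "b", "c"))
  tr <- build_sp_tree(chain, "a")
  expect_equal(tr$parent[["b"]], "a")
  expect_equal(tr$parent[["c"]], "b")
  expect_equal(unname(tr$subtree_weight[c("a", "b", "c")]), c(2, 1, 0))
  expect_equal(tr$n_tree, 3)

  # square a-b, b-c, a-d, d-c: c reachable through b or d at depth 2
  sq <- net_from_pairs(c("a", "b", "a", "d"), c("b", "c", "d", "c"))
  tsq <- build_sp_tree(sq, "a")
  expect_equal(tsq$parent[["c"]], "b")
  expect_equal(unname(tsq$subtree_weight[c("b", "d")]), c(1, 0))

  iso <- interaction_network(c("solo", "x", "y"),
                             data.frame(source = "x", target = "y"))
  tiso <- build_sp_tree(iso, "solo")
  expect_equal(tiso$n_tree, 1)
  expect_length(tiso$parent, 0)
  expect_error(build_sp_tree(chain, "zz"), "unknown root")

  # tree structure invariants on a random graph
  withr::local_seed(3)
  net <- random_connected_net(10)
  tr <- build_sp_tree(net, net$nodes$id[1])
  for (w in names(tr$parent))
    expect_equal(tr$depth[[tr$parent[[w]]]], tr$depth[[w]] - 1L)
  kids <- names(tr$parent)[tr$parent == tr$root]
  expect_equal(sum(tr$subtree_weight[kids] + 1L), tr$n_tree - 1L)
})

test_that("BN closed forms: path, star, edgeless graph", {
  p3 <- path_net(c("a", "b", "c"))
  bn <- bn_scores(p3)
  got <- stats::setNames(bn$score, bn$node)
  expect_equal(unname(got[c("a", "b", "c")]), c(0, 2, 0))

  for (m in c(2, 5, 9)) {
    star <- star_net(m, center = "ctr")
    bns <- bn_scores(star)
    sc <- stats::setNames(bns$score, bns$node)
    expect_equal(unname(sc["ctr"]), m)
    expect_true(all(sc[names(sc) != "ctr"] == 0))
  }

  lone <- interaction_network(c("u", "v", "w"), NULL)
  expect_true(all(bn_scores(lone)$score == 0))
})

test_that("BN matches the brute-force tree oracle on random graphs", {
  withr::local_seed(101)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    net <- random_connected_net(n, p = stats::runif(1, 0.25, 0.6))
    got <- bn_scores(net)
    want <- oracle_bn(net)
    expect_identical(stats::setNames(got$score, got$node)[names(want)],
                     want)
  }
})

test_that("BN treats components separately and never counts the root", {
  two <- interaction_network(relations = data.frame(
    source = c("a", "b", "x", "y"), target = c("b", "c", "y", "z")))
  bn <- bn_scores(two)
  sc <- stats::setNames(bn$score, bn$node)
  expect_equal(unname(sc[c("b", "y")]), c(2, 2))
  expect_equal(unname(sc[c("a", "c", "x", "z")]), rep(0, 4))
  # K2: each root's tree has its neighbor as a leaf with weight 0
  k2 <- net_from_pairs("p", "q")
  expect_true(all(bn_scores(k2)$score == 0))
})

test_that("MNC and DMNC closed forms", {
  k4 <- clique_net(c("a", "b", "c", "d"))
  expect_true(all(mnc_scores(k4)$score == 3))
  expect_equal(dmnc_scores(k4)$score, rep(3 / 3^1.7, 4), tolerance = 1e-12)

  star <- star_net(5)
  mn <- mnc_scores(star)
  sc <- stats::setNames(mn$score, mn$node)
  expect_equal(unname(sc["hub"]), 1)  # neighbors pairwise non-adjacent
  dm <- dmnc_scores(star)
  expect_equal(unname(stats::setNames(dm$score, dm$node)["hub"]), 0)

  # triangle plus pendant: the pendant's only neighbor forms a 1-node MNC
  tp <- net_from_pairs(c("a", "a", "b", "c"), c("b", "c", "c", "p"))
  dmp <- dmnc_scores(tp)
  expect_equal(unname(stats::setNames(dmp$score, dmp$node)["p"]), 0)

  solo <- interaction_network("only", NULL)
  expect_equal(mnc_scores(solo)$score, 0)
  # custom exponent
  expect_equal(dmnc_scores(k4, epsilon = 1)$score, rep(1, 4))
})

test_that("degree counts distinct neighbors; a planted 117-neighbor hub
           scores 117", {
  tri <- clique_net(c("a", "b", "c"))
  expect_true(all(degree_scores(tri)$score == 2))
  big <- star_net(117, center = "CYP74A_like")
  dg <- degree_scores(big)
  expect_equal(dg$node[1], "CYP74A_like")
  expect_equal(dg$score[1], 117)
  # parallel relations collapse: degree is topological
  multi <- interaction_network(relations = data.frame(
    source = c("a", "a"), target = c("b", "b"),
    rel_type = c("binding", "regulation")))
  expect_true(all(degree_scores(multi)$score == 1))
})

test_that("MNC is bounded by degree and DMNC vanishes iff the neighborhood
           component is edgeless", {
  withr::local_seed(55)
  for (i in 1:25) {
    net <- random_net(sample(6:14, 1), p = stats::runif(1, 0.15, 0.5))
    deg <- stats::setNames(degree_scores(net)$score, degree_scores(net)$node)
    mn <- mnc_scores(net); mnv <- stats::setNames(mn$score, mn$node)
    dm <- dmnc_scores(net); dmv <- stats::setNames(dm$score, dm$node)
    expect_true(all(mnv <= deg[names(mnv)]))
    g <- as_igraph(net)
    for (v in names(dmv)) {
      nb <- igraph::neighbors(g, v)
      has_edge <- length(nb) >= 2 &&
        igraph::ecount(igraph::induced_subgraph(g, nb)) > 0
      expect_equal(dmv[[v]] > 0, has_edge)
    }
  }
})

test_that("DSS selects from the 2n DMNC pool and re-ranks by MNC", {
  withr::local_seed(66)
  for (i in 1:15) {
    net <- random_net(sample(8:16, 1), p = 0.35)
    n_out <- sample(2:5, 1)
    out <- dss_rank(net, n_out = n_out)
    pool <- attr(out, "pool")
    expect_lte(length(pool), 2 * n_out)
    expect_true(all(out$node %in% pool))
    expect_equal(nrow(out), min(n_out, length(pool)))
    # output ordered by MNC (descending), ties by id
    mn <- mnc_scores(net); mnv <- stats::setNames(mn$score, mn$node)
    expect_true(all(diff(mnv[out$node]) <= 0))
    expect_equal(out$score, unname(mnv[out$node]))
  }
  # degenerate pool: n_out >= |V| returns all nodes ranked by MNC
  tri <- clique_net(c("a", "b", "c"))
  all_out <- dss_rank(tri, n_out = 10)
  expect_equal(nrow(all_out), 3)
})

test_that("a node at the bottom of the DMNC pool but with maximal MNC
           reaches the DSS output", {
  # hub adjacent to every node of the path p1-..-p6: its neighborhood is one
  # sparse connected component (MNC 6, maximal; DMNC 5/6^1.7, minimal);
  # q1..q4 form a K4 with the densest neighborhoods (DMNC 3/3^1.7, MNC 3).
  path6 <- paste0("p", 1:6)
  pr <- rbind(t(utils::combn(paste0("q", 1:4), 2)),
              cbind(path6[-6], path6[-1]),
              cbind("hub", path6))
  net <- net_from_pairs(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  dm <- dmnc_scores(net)
  expect_equal(dm$node[nrow(dm)], "hub")  # bottom of the DMNC ranking
  out <- dss_rank(net, n_out = 6)
  expect_true("hub" %in% attr(out, "pool"))
  expect_equal(out$node[1], "hub")
  expect_equal(out$score[1], 6)
})

test_that("scores are equivariant under node relabeling", {
  withr::local_seed(77)
  relabel_net <- function(net, relab) {
    rel2 <- net$relations
    rel2$source <- unname(relab[rel2$source])
    rel2$target <- unname(relab[rel2$target])
    interaction_network(unname(relab), rel2)
  }
  net <- random_connected_net(10)
  ids <- net$nodes$id
  # arbitrary relabeling: neighborhood statistics are tie-break-free
  relab <- stats::setNames(sprintf("z%02d", sample(10)), ids)
  net2 <- relabel_net(net, relab)
  for (fn in list(mnc_scores, dmnc_scores, degree_scores)) {
    s1 <- fn(net); v1 <- stats::setNames(s1$score, s1$node)
    s2 <- fn(net2); v2 <- stats::setNames(s2$score, s2$node)
    expect_equal(unname(v2[unname(relab[ids])]), unname(v1[ids]))
  }
  # BN's lexicographic parent tie-break depends on the id order, so
  # equivariance is guaranteed for order-preserving relabelings
  mono <- stats::setNames(sprintf("w%02d", seq_along(ids)), sort(ids))
  net3 <- relabel_net(net, mono)
  b1 <- bn_scores(net); v1 <- stats::setNames(b1$score, b1$node)
  b3 <- bn_scores(net3); v3 <- stats::setNames(b3$score, b3$node)
  expect_equal(unname(v3[unname(mono[ids])]), unname(v1[ids]))
  d1 <- dss_rank(net, n_out = 4)
  d3 <- dss_rank(net3, n_out = 4)
  expect_equal(d3$node, unname(mono[d1$node]))
})

test_that("top_k respects rank order, id tie-breaks, and over-length k", {
  tab <- fgnet:::hub_score_table(c(C = 1, A = 3, B = 3), "degree")
  expect_equal(top_k(tab, 2), c("A", "B"))
  expect_warning(allk <- top_k(tab, 10), "exceeds")
  expect_equal(allk, c("A", "B", "C"))
  star <- star_net(6)
  expect_equal(top_k(degree_scores(star), 1), "hub")
  expect_equal(top_k(bn_scores(star), 1), "hub")
})

test_that("planted connectors are recovered as top BN nodes and their
           removal partitions the network", {
  for (seed in 1:30) {
    cfg <- sim_config(n_clusters = 2, cluster_size = 15, n_connectors = 1,
                      rng_seed = seed)
    pb <- plant_bottlenecks(cfg)
    bn <- bn_scores(pb$network)
    expect_equal(bn$node[1], pb$truth)
    g <- as_igraph(pb$network)
    expect_gte(igraph::components(
      igraph::delete_vertices(g, bn$node[1]))$no, 2)
  }
})
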