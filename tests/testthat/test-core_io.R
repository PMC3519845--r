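# Domain types and file formats: validation, canonicalization, round trips.

test_that("network construction validates and canonicalizes", {
  net <- net_from_pairs(c("B", "C"), c("A", "B"), rel_type = "binding")
  # undirected pairs stored smaller-id first
  expect_equal(net$relations$source, c("A", "B"))
  expect_equal(net$relations$target, c("B", "C"))

  expect_error(net_from_pairs("A", "A"), "self-loop")
  expect_error(interaction_network(relations = data.frame(
    source = c("A", "B"), target = c("B", "A"), rel_type = "binding")),
    "duplicate relation")
  expect_error(interaction_network(relations = data.frame(
    source = "A", target = "B", rel_type = "binding", directed = TRUE)),
    "undirected")
  expect_error(interaction_network(relations = data.frame(
    source = "A", target = "B", rel_type = "expression", directed = FALSE)),
    "directed")
  expect_error(interaction_network(nodes = c("A", "A"), relations = NULL),
               "duplicate node")
  expect_error(interaction_network(nodes = "A", relations = data.frame(
    source = "A", target = "Z")), "not in node table")
  # directed antiparallel pairs of the same type are distinct relations
  anti <- interaction_network(relations = data.frame(
    source = c("A", "B"), target = c("B", "A"), rel_type = "regulation",
    directed = TRUE))
  expect_equal(nrow(anti$relations), 2)
  expect_equal(nrow(edge_pairs(anti)), 1)
})

test_that("SIF reading matches the three-field format", {
  f <- withr::local_tempfile(lines = c("A binding B",
                                       "B regulation C",
                                       "C binding A"))
  net <- read_network(f, "sif")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$relations), 3)
  expect_true(all(net$nodes$kind == "protein"))

  f2 <- withr::local_tempfile(lines = c("A binding B", "B odd_rel C"))
  expect_warning(net2 <- read_network(f2, "sif"), "unknown relation")
  expect_equal(sort(net2$relations$rel_type), c("binding", "unknown"))

  f3 <- withr::local_tempfile(lines = "A binding")
  expect_error(read_network(f3, "sif"), "line 1")
  f4 <- withr::local_tempfile(lines = "A binding A")
  expect_error(read_network(f4, "sif"), "self-loop")
})

test_that("TSV dialect reads attributed edge lists", {
  f <- withr::local_tempfile(lines = c(
    "source\trel_type\teffect\tdirected\ttarget\treferences",
    "A\texpression\tpositive\tTRUE\tB\tpmid:1|pmid:2"))
  net <- read_network(f, "tsv")
  expect_equal(nrow(net$nodes), 2)
  expect_equal(net$relations$effect, "positive")
  expect_equal(net$relations$references, "pmid:1|pmid:2")

  f2 <- withr::local_tempfile(lines = c("source\ttarget", "A\tB"))
  expect_error(read_network(f2, "tsv"), "header")
})

test_that("network round trip is the identity for both dialects", {
  withr::local_seed(11)
  for (i in 1:5) {
    net <- random_net(8, p = 0.4)
    net$nodes$kind[1] <- "small_molecule"
    net$nodes$de_status[2] <- "up"
    for (dia in c("sif", "tsv")) {
      f <- tempfile(); nf <- tempfile()
      write_network(net, f, dia, nodes_path = nf)
      back <- read_network(f, dia, nodes_path = nf, name = net$name)
      if (dia == "tsv") {
        expect_identical(back$relations, net$relations)
      } else {
        expect_identical(back$relations[c("source", "target", "rel_type")],
                         net$relations[c("source", "target", "rel_type")])
      }
      expect_identical(back$nodes, net$nodes)
      # idempotence: writing the reloaded network reproduces the bytes
      f2 <- tempfile()
      write_network(back, f2, dia)
      expect_identical(readLines(f2), readLines(f))
      unlink(c(f, nf, f2))
    }
  }
})

test_that("round trip preserves unicode ids and empty networks", {
  net <- net_from_pairs("αβ-1", "Ωgene")
  f <- tempfile(); nf <- tempfile()
  write_network(net, f, "tsv", nodes_path = nf)
  back <- read_network(f, "tsv", nodes_path = nf)
  expect_identical(back$nodes$id, net$nodes$id)

  empty <- interaction_network()
  write_network(empty, f, "tsv")
  back <- read_network(f, "tsv")
  expect_equal(nrow(back$nodes), 0)
  expect_equal(nrow(back$relations), 0)
  unlink(c(f, nf))
})

test_that("expression tables parse, reject bad rows, enforce invariants", {
  f <- withr::local_tempfile(lines = c(
    "gene_id\tfold_change\tp_value",
    "AT3G04720\t2.1\t0.003",
    "BAD\tNA\t0.5",
    "OK2\t0.9\t0.7"))
  expect_warning(rec <- read_expression_table(f), "line\\(s\\) 3")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$fold_change[rec$gene_id == "AT3G04720"], 2.1)

  f2 <- withr::local_tempfile(lines = c("gene_id\tfold_change\tp_value",
                                        "A\t2.0\t1.2"))
  expect_error(read_expression_table(f2), "p_value outside")
  f3 <- withr::local_tempfile(lines = c("gene_id\tfold_change\tp_value",
                                        "A\t-1\t0.2"))
  expect_error(read_expression_table(f3), "fold_change")
  f4 <- withr::local_tempfile(lines = c("gene_id\tfc\tp_value", "A\t1\t0.2"))
  expect_error(read_expression_table(f4), "columns")
  # round trip
  f5 <- tempfile()
  write_expression_table(rec, f5)
  expect_equal(read_expression_table(f5), rec)
  unlink(f5)
})

test_that("GMT annotation sets load with background rules", {
  f <- withr::local_tempfile(lines = c("T1\tdesc one\tg1\tg2\tg3",
                                       "T2\tdesc two\tg3\tg4"))
  ann <- read_annotations(f)
  expect_equal(length(ann$terms), 2)
  expect_equal(ann$background, c("g1", "g2", "g3", "g4"))

  ann2 <- read_annotations(f, background = paste0("g", 1:10))
  expect_equal(length(ann2$background), 10)
  expect_error(read_annotations(f, background = c("g1", "g2")),
               "missing from background")

  fdup <- withr::local_tempfile(lines = c("T1\td\tg1", "T1\td\tg2"))
  expect_error(read_annotations(fdup), "duplicate term")
  fempty <- withr::local_tempfile(lines = c("T1\tdesc"))
  expect_error(read_annotations(fempty), "zero genes")
  # round trip
  fo <- tempfile()
  write_annotations(ann, fo)
  expect_equal(read_annotations(fo)$terms, ann$terms)
  unlink(fo)
})
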