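# End-to-end pipeline driver: chains simulate/select-de/build/subtract/
# summarize/rank/enrich from one structured config, writing all
# intermediates plus a reproducible run manifest.

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (optional), DE selection,
#' shortest-path network construction, subtraction, summary, hub ranking
#' (each requested method), enrichment — writing every intermediate file to
#' the run directory, and returns a run manifest (also written as
#' `manifest.json`) with the config snapshot, seed, per-stage counts and
#' per-file MD5 digests. Re-running with the same config and seed
#' reproduces identical digests.
#'
#' The config is a YAML file or an equivalent named list with either a
#' `simulate` block ([sim_config()] fields) or an `inputs` block (paths
#' `network`, optional `nodes`, `expression`, `gmt`, optional `groups` TSV
#' with columns `group_name`, `member_id`), never both. Optional blocks
#' `de` (`up_fc`, `down_fc`, `alpha`, `extra_up`, `extra_down`), `build`
#' (`max_len`), `rank` (`methods`, `top_k`, `dss_n`, `epsilon`) and
#' `enrich` (`alpha`, `correction`) override stage defaults. In simulate
#' mode the annotation terms double as the biological groups for network
#' construction; the study set for enrichment is the node set of the
#' subtracted network.
#'
#' @param config Path to a YAML config file, or a named list.
#' @param out_dir Run directory; defaults to `run-seed<seed>` under the
#'   current directory.
#' @param seed Integer seed overriding the config's `seed` entry.
#' @return The run manifest (list of class `run_manifest`), invisibly the
#'   same object written to `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML path or a list", call. = FALSE)
  has_sim <- !is.null(cfg$simulate)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim == has_inp)
    stop("config must contain exactly one of 'simulate' or 'inputs'",
         call. = FALSE)
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(seed)) stop("no seed in config or arguments", call. = FALSE)
  seed <- as.integer(seed)
  if (is.null(out_dir)) out_dir <- sprintf("run-seed%d", seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  counts <- list()

  # --- stage: inputs -------------------------------------------------------
  groups <- NULL
  if (has_sim) {
    sc <- do.call(sim_config, c(cfg$simulate, list(rng_seed = seed)))
    study_sim <- simulate_study(sc)
    net <- study_sim$network
    records <- study_sim$expression
    ann <- study_sim$annotations
    write_network(net, pth("interactome.tsv"), "tsv",
                  nodes_path = pth("interactome.nodes.tsv"))
    write_expression_table(records, pth("expression.tsv"))
    write_annotations(ann, pth("annotations.gmt"))
    jsonlite::write_json(study_sim$truth, pth("truth.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    .stage_log("simulate", nrow(net$nodes), " nodes, ",
               nrow(net$relations), " relations")
  } else {
    inp <- cfg$inputs
    for (need in c("network", "expression", "gmt"))
      if (is.null(inp[[need]]))
        stop("inputs block missing '", need, "'", call. = FALSE)
    dialect <- if (grepl("\\.sif$", inp$network)) "sif" else "tsv"
    net <- read_network(inp$network, dialect, nodes_path = inp$nodes)
    records <- read_expression_table(inp$expression)
    ann <- read_annotations(inp$gmt)
    if (!is.null(inp$groups)) {
      gt <- utils::read.delim(inp$groups, stringsAsFactors = FALSE,
                              colClasses = "character")
      if (!all(c("group_name", "member_id") %in% names(gt)))
        stop("groups file needs columns group_name, member_id", call. = FALSE)
      groups <- lapply(split(gt$member_id, gt$group_name), function(m)
        group_spec(name = "", members = m))
      groups <- Map(function(g, nm) { g$name <- nm; g },
                    groups, names(groups))
    }
    .stage_log("inputs", "loaded ", nrow(net$nodes), " nodes, ",
               nrow(records), " expression records")
  }
  counts$interactome <- list(nodes = nrow(net$nodes),
                             relations = nrow(net$relations))
  counts$expression <- list(records = nrow(records))

  # --- stage: select-de ----------------------------------------------------
  de_args <- cfg$de
  deset <- select_de_genes(records,
                           up_fc = de_args$up_fc %||% 1.5,
                           down_fc = de_args$down_fc %||% 0.66,
                           alpha = de_args$alpha %||% 0.05)
  if (!is.null(de_args$extra_up) || !is.null(de_args$extra_down))
    deset <- merge_curated_genes(deset,
                                 extra_up = de_args$extra_up %||% character(),
                                 extra_down = de_args$extra_down %||% character())
  de_tab <- data.frame(
    gene_id = c(deset$up, deset$down),
    direction = c(rep("up", length(deset$up)),
                  rep("down", length(deset$down))))
  utils::write.table(de_tab, pth("de_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$de <- list(up = length(deset$up), down = length(deset$down))
  .stage_log("select-de", length(deset$up), " up, ",
             length(deset$down), " down")

  # --- stage: build --------------------------------------------------------
  if (is.null(groups)) {
    # annotation terms double as biological groups
    groups <- Map(function(id, t)
      group_spec(id, intersect(t$genes, net$nodes$id)),
      names(ann$terms), ann$terms)
    groups <- Filter(function(g) length(g$members) > 0, groups)
  }
  seeds <- intersect(de_genes(deset), net$nodes$id)
  if (!length(seeds)) stop("no DE gene present in the interactome",
                           call. = FALSE)
  max_len <- cfg$build$max_len %||% 4
  primary <- shortest_path_network(net, seeds, groups, max_len = max_len)
  write_network(primary, pth("primary_network.tsv"), "tsv",
                nodes_path = pth("primary_network.nodes.tsv"))
  counts$primary <- list(nodes = nrow(primary$nodes),
                         edges = nrow(edge_pairs(primary)))
  .stage_log("build", counts$primary$nodes, " nodes, ",
             counts$primary$edges, " edges (max_len = ", max_len, ")")

  # --- stage: subtract + summarize ----------------------------------------
  sub <- subtract_network(primary, deset)
  write_network(sub, pth("subtracted_network.tsv"), "tsv",
                nodes_path = pth("subtracted_network.nodes.tsv"))
  summ <- summarize_network(sub, deset)
  jsonlite::write_json(unclass(summ)[c("n_nodes", "n_edges", "avg_degree",
                                       "avg_degree_int", "n_up", "n_down")],
                       pth("summary.json"), auto_unbox = TRUE, digits = NA)
  counts$subtracted <- list(nodes = summ$n_nodes, edges = summ$n_edges,
                            up = summ$n_up, down = summ$n_down)
  .stage_log("subtract", summ$n_nodes, " nodes, ", summ$n_edges,
             " edges; avg degree ", sprintf("%.2f", summ$avg_degree))

  # --- stage: rank ---------------------------------------------------------
  rk <- cfg$rank
  methods <- rk$methods %||% c("bn", "dss")
  top_n <- rk$top_k %||% 30
  rank_files <- character(0)
  for (m in methods) {
    tab <- if (m == "dss")
      dss_rank(sub, n_out = rk$dss_n %||% top_n,
               epsilon = rk$epsilon %||% 1.7)
    else if (m == "dmnc") dmnc_scores(sub, epsilon = rk$epsilon %||% 1.7)
    else hub_scores(sub, m)
    f <- pth(sprintf("hubs_%s.tsv", m))
    write_hub_table(tab, f)
    rank_files <- c(rank_files, f)
    counts[[paste0("rank_", m)]] <- list(scored = nrow(tab))
    .stage_log("rank", m, ": top node ",
               if (nrow(tab)) tab$node[1] else "<none>")
  }

  # --- stage: enrich -------------------------------------------------------
  study <- intersect(sub$nodes$id, ann$background)
  enr <- if (length(study)) fisher_enrichment(study, ann,
                                              correction = cfg$enrich$correction %||% "bh")
  else structure(data.frame(), class = c("enrichment_result", "data.frame"))
  enr_sig <- if (nrow(enr)) filter_significant(enr,
                                               cfg$enrich$alpha %||% 0.05)
  else enr
  write_enrichment(enr, pth("enrichment.tsv"))
  counts$enrichment <- list(tested = nrow(enr), significant = nrow(enr_sig))
  .stage_log("enrich", nrow(enr), " terms tested, ", nrow(enr_sig),
             " significant")

  # --- manifest ------------------------------------------------------------
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  digests <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(digests) <- outputs
  cfg_snapshot <- cfg
  cfg_snapshot$seed <- seed
  manifest <- structure(list(
    tool = "fgnet",
    version = as.character(utils::packageVersion("fgnet")),
    seed = seed,
    config = cfg_snapshot,
    counts = counts,
    digests = digests), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest (fgnet", x$version, ") seed", x$seed, "\n")
  for (nm in names(x$counts))
    cat("  ", nm, ": ",
        paste(names(x$counts[[nm]]), unlist(x$counts[[nm]]), sep = "=",
              collapse = ", "), "\n", sep = "")
  cat("  ", length(x$digests), " output files\n", sep = "")
  invisible(x)
}

#' Partition a reference gene list by network membership
#'
#' Utility for checking how much of an externally identified gene list is
#' captured by a constructed network.
#'
#' @param net An [interaction_network()].
#' @param reference Non-empty character vector of gene ids.
#' @return A list with `present` and `absent` (character vectors);
#'   `length(present) + length(absent) == length(unique(reference))`.
#' @export
compare_gene_lists <- function(net, reference) {
  stopifnot(inherits(net, "interaction_network"))
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("reference must be non-empty", call. = FALSE)
  inside <- reference %in% net$nodes$id
  list(present = sort(reference[inside]), absent = sort(reference[!inside]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
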