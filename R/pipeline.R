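# End-to-end orchestration: DEG prefilter -> seed list -> network ->
# centrality -> composite score -> communities -> mixture clustering ->
# enrichment. Each stage writes its outputs before the next starts and the
# run manifest records the headline counts. Per-stage seeds are derived
# from the master seed by fixed offsets so any stage can be rerun in
# isolation: EPC +1, clustering +2, DEG +3, synthetic network +4,
# synthetic gene sets +5, synthetic expression +6.

.stage_seed <- function(config, offset) as.integer(config$seed) + offset

#' Assemble a pipeline configuration
#'
#' All thresholds default to the standard analysis settings: DEG adjusted-p
#' cutoff 0.05 and fold change 2, clique percolation k = 3, EPC with 1000
#' iterations at retain probability 0.5, EASE enrichment over the annotated
#' universe, mixture components searched over 1..9.
#'
#' @param seed master seed (required; all stochastic stages derive their
#'   seeds from it).
#' @param out_dir output directory (created if missing).
#' @param network list describing the network input: either
#'   `list(edgelist = path)` / `list(sif = path)` (plus optional
#'   `isoform_map = path`), or `list(synthetic = list(...))` with
#'   [generate_network()] arguments.
#' @param expression optional list of experiments, each
#'   `list(matrix = path, groups = path)`, or `list(synthetic = list(...))`
#'   with [generate_expression()] arguments.
#' @param gene_lists optional character vector of ranked gene-list files
#'   merged into the seed set (see [merge_gene_lists()]).
#' @param seeds_file optional path to a fixed seed gene list (one symbol
#'   per line); used instead of the DEG stage output if given.
#' @param gmt optional GMT path, or `list(synthetic = list(...))` with
#'   [generate_gene_sets()] arguments; `NULL` skips enrichment.
#' @param alpha,fc_threshold,deg_B,deg_method DEG-stage settings.
#' @param top_k_per_list head size per external gene list.
#' @param epc_iterations,epc_retain EPC settings.
#' @param cpm_k clique-percolation k.
#' @param g_range,gmm_models mixture-model search space.
#' @param enrich_method,universe_mode enrichment settings.
#' @param top_k number of top genes reported.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed, out_dir, network,
                            expression = NULL, gene_lists = character(0),
                            seeds_file = NULL, gmt = NULL,
                            alpha = 0.05, fc_threshold = 2.0,
                            deg_B = NULL, deg_method = "permutation",
                            top_k_per_list = 20,
                            epc_iterations = 1000, epc_retain = 0.5,
                            cpm_k = 3, g_range = 1:9,
                            gmm_models = c("EII", "VVI", "EEE", "VVV"),
                            enrich_method = "ease",
                            universe_mode = "annotated", top_k = 50) {
  if (missing(seed)) stop("pipeline_config requires a master seed")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 network = network, expression = expression,
                 gene_lists = gene_lists, seeds_file = seeds_file,
                 gmt = gmt, alpha = alpha, fc_threshold = fc_threshold,
                 deg_B = deg_B, deg_method = deg_method,
                 top_k_per_list = top_k_per_list,
                 epc_iterations = epc_iterations, epc_retain = epc_retain,
                 cpm_k = cpm_k, g_range = g_range,
                 gmm_models = gmm_models, enrich_method = enrich_method,
                 universe_mode = universe_mode, top_k = top_k),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  if (!is.null(args$g_range) && length(args$g_range) == 2 &&
      !is.null(raw$g_range_is_span) && isTRUE(raw$g_range_is_span)) {
    args$g_range <- seq(args$g_range[[1]], args$g_range[[2]])
  }
  do.call(pipeline_config, args)
}

.run_stage <- function(name, manifest_env, fun) {
  res <- tryCatch(fun(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest_env$stages <- c(manifest_env$stages, name)
  res
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: the DEG prefilter on every expression experiment
#' (if configured) and seed-list assembly; network construction (from
#' files or the synthetic generator); the ten-index centrality table; the
#' composite score and top-gene ranking; k-clique-percolation communities;
#' BIC-selected mixture clustering of the normalized centrality profiles;
#' and gene-set enrichment of the top genes. Every stage's outputs are
#' written to `config$out_dir` as TSV before the next stage starts, and a
#' JSON manifest summarizes the run. Reruns with the same configuration
#' are byte-identical.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(); env$stages <- character(0)
  manifest <- list(seed = config$seed)

  ## stage 1: DEG prefilter + seed list ------------------------------------
  seed_genes <- NULL
  deg_counts <- list()
  if (!is.null(config$expression)) {
    degs <- .run_stage("deg", env, function() {
      exps <- config$expression
      if (!is.null(exps$synthetic)) exps <- list(exps)
      lapply(seq_along(exps), function(i) {
        ex <- exps[[i]]
        expr <- if (!is.null(ex$synthetic)) {
          args <- ex$synthetic
          args$seed <- .stage_seed(config, 6) + i
          # a synthetic experiment maps onto the synthetic network's gene
          # namespace, so downstream seed coverage is meaningful
          nw <- config$network
          if (is.null(args$genes) && !is.null(nw$synthetic)) {
            ns <- nw$synthetic$n_nodes
            if (!is.null(ns) && !is.null(args$n_genes) &&
                args$n_genes <= ns) {
              args$genes <- withr::with_seed(
                args$seed + 1, sample(sprintf("G%04d", seq_len(ns)),
                                      args$n_genes))
            }
          }
          do.call(generate_expression, args)$expr
        } else {
          read_expression_matrix(ex$matrix, ex$groups)
        }
        res <- select_degs(expr, alpha = config$alpha,
                           fc_threshold = config$fc_threshold,
                           B = config$deg_B,
                           seed = .stage_seed(config, 3) + i,
                           method = config$deg_method)
        utils::write.table(res, file.path(out, sprintf("deg_%02d.tsv", i)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res
      })
    })
    deg_counts <- lapply(degs, function(d) list(
      n_genes = nrow(d),
      n_raw_significant = attr(d, "n_raw_significant"),
      n_adjusted_significant = attr(d, "n_adjusted_significant"),
      n_selected = sum(d$selected)))
    pooled <- do.call(rbind, degs)
    pooled <- pooled[!duplicated(pooled$gene) | pooled$selected, ]
    merged <- merge_gene_lists(pooled, config$gene_lists,
                               top_k_per_list = config$top_k_per_list)
    seed_genes <- merged$gene
    utils::write.table(merged, file.path(out, "seed_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (length(config$gene_lists)) {
    merged <- merge_gene_lists(NULL, config$gene_lists,
                               top_k_per_list = config$top_k_per_list)
    seed_genes <- merged$gene
    utils::write.table(merged, file.path(out, "seed_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$seeds_file)) {
    seed_genes <- toupper(trimws(readLines(config$seeds_file, warn = FALSE)))
    seed_genes <- seed_genes[nzchar(seed_genes)]
  }
  manifest$deg <- deg_counts
  manifest$n_seed_genes <- length(seed_genes)

  ## stage 2: network -------------------------------------------------------
  g <- .run_stage("network", env, function() {
    nw <- config$network
    if (!is.null(nw$synthetic)) {
      args <- nw$synthetic
      args$seed <- .stage_seed(config, 4)
      gen <- do.call(generate_network, args)
      jsonlite::write_json(gen$truth, file.path(out, "network_truth.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      gen$graph
    } else {
      imap <- if (!is.null(nw$isoform_map)) read_isoform_map(nw$isoform_map)
      recs <- if (!is.null(nw$edgelist)) {
        parse_interactions(nw$edgelist, "edgelist")
      } else if (!is.null(nw$sif)) {
        parse_interactions(nw$sif, "sif")
      } else stop("network config needs 'edgelist', 'sif' or 'synthetic'")
      build_network(recs, imap)
    }
  })
  export_network(g, file.path(out, "network.tsv"), "edgelist")
  manifest$network <- list(n_nodes = igraph::vcount(g),
                           n_edges = igraph::ecount(g))
  if (!is.null(seed_genes) && length(seed_genes)) {
    cov <- seed_coverage(g, seed_genes)
    manifest$seed_coverage <- cov[c("n_seeds", "n_present", "fraction")]
  }

  ## stage 3: centrality -----------------------------------------------------
  ct <- .run_stage("centrality", env, function() {
    compute_all_centralities(g, epc_iterations = config$epc_iterations,
                             epc_retain = config$epc_retain,
                             epc_seed = .stage_seed(config, 1))
  })
  write_centrality_table(ct, file.path(out, "centrality.tsv"))

  ## stage 4: composite score ------------------------------------------------
  sc <- .run_stage("score", env, function() score_i(ct))
  write_score_table(sc, file.path(out, "scores.tsv"))
  tg <- top_genes(sc, config$top_k, restrict_to = seed_genes)
  utils::write.table(tg, file.path(out, "top_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  outside <- attr(tg, "outside_restrict")
  if (!is.null(outside)) {
    utils::write.table(outside, file.path(out, "top_genes_outside_seeds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$top_genes <- utils::head(tg$gene, 10)

  ## stage 5: communities ----------------------------------------------------
  cs <- .run_stage("communities", env, function()
    k_clique_communities(g, k = config$cpm_k))
  write_communities(cs, file.path(out, "communities.tsv"),
                    file.path(out, "community_overlap.tsv"))
  manifest$communities <- list(k = cs$k,
                               n_communities = length(cs$communities),
                               n_covered = length(cs$covered),
                               n_overlap_nodes = length(cs$overlap))

  ## stage 6: mixture clustering ----------------------------------------------
  clus <- .run_stage("clustering", env, function() {
    feats <- as.matrix(sc[centrality_indexes()])
    rownames(feats) <- sc$node
    g_range <- config$g_range[config$g_range < nrow(feats)]
    if (!length(g_range)) stop("no feasible component count for n nodes")
    select_model(feats, G_range = g_range, models = config$gmm_models,
                 seed = .stage_seed(config, 2))
  })
  utils::write.table(clus$bic_table, file.path(out, "bic_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summarize_clusters(clus$best, sc)
  utils::write.table(summ, file.path(out, "cluster_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assign_df <- data.frame(node = names(clus$best$assignments),
                          cluster = unname(clus$best$assignments),
                          stringsAsFactors = FALSE)
  utils::write.table(assign_df, file.path(out, "cluster_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$clustering <- list(G = clus$best$G, model = clus$best$model,
                              bic = clus$best$bic)

  ## stage 7: enrichment -------------------------------------------------------
  if (!is.null(config$gmt)) {
    enr <- .run_stage("enrichment", env, function() {
      universe <- igraph::V(g)$name
      if (is.list(config$gmt) && !is.null(config$gmt$synthetic)) {
        args <- config$gmt$synthetic
        args$universe <- universe
        args$seed <- .stage_seed(config, 5)
        gen <- do.call(generate_gene_sets, args)
        coll <- gen$collection
        write_gmt(coll, file.path(out, "gene_sets.gmt"))
      } else {
        if (!file.exists(config$gmt)) {
          stop("GMT file not found: ", config$gmt)
        }
        coll <- read_gmt(config$gmt)
      }
      query <- tg$gene
      enrich(query, coll, universe, method = config$enrich_method,
             universe_mode = config$universe_mode)
    })
    utils::write.table(enr$sets, file.path(out, "enrichment_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr$classes, file.path(out, "enrichment_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$enrichment <- list(coverage = enr$coverage,
                                universe_size = enr$universe_size,
                                n_significant_sets =
                                  sum(enr$sets$adjusted_p <= 0.05))
  }

  manifest$stages_complete <- env$stages
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
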