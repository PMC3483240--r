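# Synthetic inputs with the statistical structure the pipeline assumes:
# a scale-free (preferential-attachment) PPI backbone with optional planted
# hubs and cliques, gene-set collections with one planted over-represented
# set, and two-group expression matrices with spiked fold changes.
# Every generator is deterministic given its seed and returns the ground
# truth alongside the data.

#' Generate a synthetic PPI network
#'
#' The default backbone is a Barabasi-Albert preferential-attachment graph:
#' starting from `attachment_m` isolated nodes, every new node attaches
#' `attachment_m` edges to distinct existing nodes chosen with probability
#' proportional to their current degree (uniformly while all degrees are
#' zero, so the first arrival connects to the whole seed set). This yields
#' `attachment_m * (n_nodes - attachment_m)` edges and a power-law-like
#' degree distribution, the hallmark topology of PPI networks. An
#' Erdos-Renyi backbone (`backbone = "er"`) is available for experiments
#' needing a homogeneous sparse background.
#'
#' Planted structure: each planted hub is an extra node wired to
#' `hub_fraction` of the backbone nodes chosen uniformly; each planted
#' clique makes a fresh uniform sample of `clique_size` backbone nodes
#' (disjoint across cliques) pairwise adjacent. Hub nodes draw their gene
#' symbols from random positions of the shared `G<number>` namespace, so a
#' planted hub is label-exchangeable with backbone nodes: several indexes
#' break ties by lexicographic node order, and a systematically first- or
#' last-sorting hub label would bias them.
#'
#' @param n_nodes number of backbone nodes.
#' @param attachment_m edges attached per new node (at least 1 and less
#'   than `n_nodes`); only for the `"pa"` backbone.
#' @param backbone `"pa"` (preferential attachment, default) or `"er"`.
#' @param er_p edge probability for the `"er"` backbone.
#' @param n_hubs number of planted hub nodes (default 0).
#' @param hub_fraction fraction of backbone nodes each hub wires to.
#' @param n_cliques number of planted cliques (default 0).
#' @param clique_size size of each planted clique (>= 3).
#' @param seed integer seed (required).
#' @return list with `graph` (igraph network, gene symbols `G0001`, ...)
#'   and `truth` (list with `hubs` and `cliques`).
#' @export
generate_network <- function(n_nodes = 2000, attachment_m = 2,
                             backbone = c("pa", "er"), er_p = 0.01,
                             n_hubs = 0, hub_fraction = 0.2,
                             n_cliques = 0, clique_size = 6, seed) {
  backbone <- match.arg(backbone)
  if (missing(seed)) stop("generate_network requires an explicit seed")
  stopifnot(n_nodes > attachment_m, attachment_m >= 1)
  if (n_cliques > 0) {
    stopifnot(clique_size >= 3)
    if (n_cliques * clique_size > n_nodes) {
      stop("cannot plant ", n_cliques, " disjoint cliques of size ",
           clique_size, " in ", n_nodes, " nodes")
    }
  }
  all_names <- sprintf("G%04d", seq_len(n_nodes + n_hubs))
  withr::with_seed(as.integer(seed), {
    hub_names <- if (n_hubs > 0) sort(sample(all_names, n_hubs)) else character(0)
    node_names <- setdiff(all_names, hub_names)
    if (backbone == "pa") {
      m <- as.integer(attachment_m)
      deg <- integer(n_nodes)
      from <- integer(0); to <- integer(0)
      for (i in (m + 1):n_nodes) {
        cand <- seq_len(i - 1)
        w <- deg[cand]
        if (sum(w) == 0) w <- rep(1, length(cand))
        targets <- if (length(cand) <= m) cand else
          sample(cand, m, prob = w)
        from <- c(from, rep(i, length(targets)))
        to <- c(to, targets)
        deg[targets] <- deg[targets] + 1L
        deg[i] <- deg[i] + length(targets)
      }
      edges <- cbind(from, to)
    } else {
      g0 <- igraph::sample_gnp(n_nodes, er_p)
      edges <- igraph::as_edgelist(g0, names = FALSE)
    }
    el <- cbind(node_names[edges[, 1]], node_names[edges[, 2]])
    src <- rep(if (backbone == "pa") "synthetic_pa" else "synthetic_er",
               nrow(el))

    truth <- list(hubs = character(0), cliques = list())
    if (n_hubs > 0) {
      n_wire <- max(1L, round(hub_fraction * n_nodes))
      for (h in seq_len(n_hubs)) {
        hub <- hub_names[h]
        targets <- sample(node_names, n_wire)
        el <- rbind(el, cbind(rep(hub, n_wire), targets))
        src <- c(src, rep("synthetic_hub", n_wire))
        truth$hubs <- c(truth$hubs, hub)
      }
    }
    if (n_cliques > 0) {
      pool <- sample(node_names, n_cliques * clique_size)
      for (ci in seq_len(n_cliques)) {
        members <- sort(pool[((ci - 1) * clique_size + 1):(ci * clique_size)])
        pairs <- utils::combn(members, 2)
        el <- rbind(el, t(pairs))
        src <- c(src, rep("synthetic_clique", ncol(pairs)))
        truth$cliques[[ci]] <- members
      }
    }
  })
  records <- data.frame(a = el[, 1], b = el[, 2], source = src,
                        stringsAsFactors = FALSE)
  g <- build_network(records)
  # backbone nodes that stayed isolated (possible under "er") are kept
  miss <- setdiff(node_names, igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
  list(graph = g, truth = truth)
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Sets are uniform samples from the universe. The designated query draws
#' `enriched_fraction` of its genes from one target set (the planted
#' signal) and the rest uniformly from the remaining universe; an
#' `enriched_fraction` equal to the query's base rate yields a null
#' collection.
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of gene sets (default 50).
#' @param set_size_range inclusive range of set sizes (default c(10, 50)).
#' @param query_size size of the designated query (default 40).
#' @param enriched_fraction fraction of the query drawn from the target
#'   set (default 0.8).
#' @param n_classes number of class labels cycled over the sets.
#' @param seed integer seed (required).
#' @return list with `collection` (a `gene_set_collection`), `query`
#'   (character vector) and `truth` (list with `enriched_set`).
#' @export
generate_gene_sets <- function(universe, n_sets = 50,
                               set_size_range = c(10, 50), query_size = 40,
                               enriched_fraction = 0.8, n_classes = 4,
                               seed) {
  if (missing(seed)) stop("generate_gene_sets requires an explicit seed")
  universe <- unique(toupper(universe))
  if (max(set_size_range) > length(universe) ||
      query_size > length(universe)) {
    stop("set or query sizes infeasible for this universe")
  }
  withr::with_seed(as.integer(seed), {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    # the designated enriched set gets the top of the size range, so the
    # requested planted fraction is always achievable
    sizes[1] <- set_size_range[2]
    sets <- lapply(sizes, function(s) sample(universe, s))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    classes <- sprintf("class%d", rep_len(seq_len(n_classes), n_sets))
    names(classes) <- names(sets)
    target <- names(sets)[1]
    n_in <- round(enriched_fraction * query_size)
    n_in <- min(n_in, length(sets[[target]]))
    q_in <- sample(sets[[target]], n_in)
    q_out <- sample(setdiff(universe, q_in), query_size - n_in)
    query <- sort(c(q_in, q_out))
  })
  list(collection = gene_set_collection(sets, classes),
       query = query,
       truth = list(enriched_set = target))
}

#' Generate a two-group expression matrix with spiked fold changes
#'
#' Baseline (control) means are log-normally distributed across genes;
#' every measurement is its group mean times multiplicative log-normal
#' noise with coefficient of variation `noise_cv`. The first `n_de` genes
#' are differentially expressed with a true case/control mean ratio of
#' `true_fc`, alternating up- and down-regulation (both directions occur in
#' real case/control comparisons).
#'
#' @param n_genes number of genes (default 1000).
#' @param n_case,n_control samples per group (default 10 each, a common
#'   case/control microarray design; both >= 2).
#' @param n_de number of spiked genes (default 50).
#' @param true_fc true fold change of spiked genes (>= 1; default 4).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0.1).
#' @param genes optional character vector of `n_genes` gene symbols (e.g.
#'   nodes of a network the experiment should map onto); defaults to
#'   `GENE0001`, `GENE0002`, ...
#' @param seed integer seed (required).
#' @return list with `expr` (list of `values`, `groups`, consumable by
#'   [select_degs()]) and `truth` (data.frame `gene`, `direction` of the
#'   spiked genes).
#' @export
generate_expression <- function(n_genes = 1000, n_case = 10, n_control = 10,
                                n_de = 50, true_fc = 4, noise_cv = 0.1,
                                genes = NULL, seed) {
  if (missing(seed)) stop("generate_expression requires an explicit seed")
  stopifnot(n_de <= n_genes, n_case >= 2, n_control >= 2, true_fc >= 1,
            noise_cv > 0)
  if (is.null(genes)) {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
  } else {
    stopifnot(length(genes) == n_genes, !anyDuplicated(genes))
    genes <- toupper(genes)
  }
  samples <- c(sprintf("CASE%02d", seq_len(n_case)),
               sprintf("CTRL%02d", seq_len(n_control)))
  groups <- c(rep("case", n_case), rep("control", n_control))
  names(groups) <- samples
  sdlog <- sqrt(log(1 + noise_cv^2))
  withr::with_seed(as.integer(seed), {
    base <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    direction <- rep(0L, n_genes)
    if (n_de > 0) direction[seq_len(n_de)] <- rep_len(c(1L, -1L), n_de)
    case_mean <- base * true_fc^direction
    noise <- function(n) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    vals <- matrix(0, n_genes, n_case + n_control,
                   dimnames = list(genes, samples))
    for (j in seq_len(n_case)) vals[, j] <- case_mean * noise(n_genes)
    for (j in seq_len(n_control)) {
      vals[, n_case + j] <- base * noise(n_genes)
    }
  })
  truth <- data.frame(gene = genes[direction != 0],
                      direction = ifelse(direction[direction != 0] > 0,
                                         "up", "down"),
                      stringsAsFactors = FALSE)
  list(expr = list(values = vals, groups = groups), truth = truth)
}

#' Write an expression matrix and its groups file to TSV
#' @param expr list with `values` and `groups`.
#' @param path expression TSV path.
#' @param groups_path groups TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, groups_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(expr$groups), group = unname(expr$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}
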