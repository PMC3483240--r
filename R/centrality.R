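# Ten node-centrality indexes for hub detection in PPI networks.
# All indexes are defined on simple undirected unweighted graphs; shortest
# paths are unweighted, unordered pairs are counted once, and pair-based
# sums range over within-component pairs only.

#' Names of the ten centrality indexes, in table column order
#'
#' @return character vector of the index labels used by
#'   [compute_all_centralities()], in their fixed column order.
#' @export
centrality_indexes <- function() {
  c("degree", "betweenness", "stress", "eccentricity", "radiality",
    "bottleneck", "mnc", "dmnc", "mcc", "epc")
}

.named <- function(x, g) {
  names(x) <- igraph::V(g)$name
  x
}

# adjacency list as integer indices, one entry per vertex
.adj_list <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

#' Node degree
#' @param network an igraph PPI network.
#' @return named numeric vector, one value per node.
#' @export
degree_centrality <- function(network) {
  .named(as.numeric(igraph::degree(network)), network)
}

#' Betweenness centrality (unnormalized)
#'
#' Sum over unordered node pairs `{s,t}` (both different from `v`) of the
#' fraction of shortest `s`-`t` paths passing through `v`.
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(network) {
  .named(as.numeric(igraph::betweenness(network, directed = FALSE)), network)
}

# counts of shortest paths between all pairs, by breadth-first dynamic
# programming over distance levels (sigma[s,t] = number of shortest s-t paths)
.shortest_path_counts <- function(g, D = NULL) {
  n <- igraph::vcount(g)
  if (is.null(D)) D <- igraph::distances(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  sigma <- diag(1, n)
  finite <- D[is.finite(D)]
  maxd <- if (length(finite)) max(finite) else 0
  if (maxd >= 1) {
    for (l in seq_len(maxd)) {
      contrib <- (sigma * (D == (l - 1))) %*% A
      at <- D == l
      sigma[at] <- contrib[at]
    }
  }
  sigma
}

#' Stress centrality
#'
#' Number of shortest paths between other node pairs that pass through each
#' node. Unordered pairs counted once; equals betweenness whenever every
#' pair has a unique shortest path.
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
stress_centrality <- function(network) {
  # Level-wise dynamic program on the shortest-path DAG of every source s:
  # sigma[s,v] counts shortest s-v paths (forward over distance levels);
  # psi[s,v] counts shortest paths from v to all nodes strictly below v in
  # s's DAG (backward over levels). Every shortest v-t path with
  # d(s,v)+d(v,t)=d(s,t) lies inside the DAG, so the number of shortest
  # paths through v from source s is sigma[s,v]*psi[s,v]; each unordered
  # pair {s,t} is seen from both endpoints, hence the half.
  n <- igraph::vcount(network)
  if (n < 3 || igraph::ecount(network) == 0) {
    return(.named(numeric(n), network))
  }
  D <- igraph::distances(network)
  A <- as.matrix(igraph::as_adjacency_matrix(network, sparse = TRUE))
  sigma <- .shortest_path_counts(network, D)
  psi <- matrix(0, n, n)
  finite <- D[is.finite(D)]
  maxd <- max(finite)
  if (maxd >= 1) {
    for (l in seq(maxd - 1, 0)) {
      contrib <- ((1 + psi) * (D == (l + 1))) %*% A
      at <- D == l
      psi[at] <- contrib[at]
    }
  }
  prod <- sigma * psi
  diag(prod) <- 0
  .named(colSums(prod) / 2, network)
}

#' Eccentricity score
#'
#' Reciprocal of the graph-theoretic eccentricity (the maximum distance from
#' the node to any node of its connected component), so that larger values
#' mean more central. Isolated nodes score 1 by convention.
#' @inheritParams degree_centrality
#' @return named numeric vector with values in (0, 1].
#' @export
eccentricity_score <- function(network) {
  D <- igraph::distances(network)
  ecc <- apply(D, 1, function(d) {
    d <- d[is.finite(d)]
    max(d)  # includes d(v,v)=0, so isolated nodes get 0
  })
  .named(ifelse(ecc == 0, 1, 1 / ecc), network)
}

#' Radiality
#'
#' For node `v` in a component of size `n_c` and diameter `Delta`:
#' `sum_w (Delta + 1 - d(v, w)) / (n_c - 1)` over the other nodes `w` of the
#' component. Isolated nodes score 0 by convention.
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
radiality_centrality <- function(network) {
  n <- igraph::vcount(network)
  D <- igraph::distances(network)
  comp <- igraph::components(network)
  out <- numeric(n)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    nc <- length(members)
    if (nc < 2) next
    sub <- D[members, members, drop = FALSE]
    delta <- max(sub)
    out[members] <- (nc * (delta + 1) - (delta + 1) - rowSums(sub)) / (nc - 1)
  }
  .named(out, network)
}

#' Bottleneck centrality
#'
#' For every root `s` of `v`'s component, a shortest-path tree is grown from
#' `s` (each node's parent is its lexicographically smallest neighbor one
#' step closer to the root). `v` scores one point for each root whose tree
#' routes more than `n_c / 4` nodes through `v` (`v`'s subtree, `v`
#' included; `n_c` = component size).
#' @inheritParams degree_centrality
#' @return named numeric vector of non-negative counts.
#' @export
bottleneck_centrality <- function(network) {
  n <- igraph::vcount(network)
  out <- numeric(n)
  if (n == 0) return(.named(out, network))
  D <- igraph::distances(network)
  adj <- .adj_list(network)
  lexrank <- rank(igraph::V(network)$name, ties.method = "first")
  comp <- igraph::components(network)
  for (s in seq_len(n)) {
    members <- which(comp$membership == comp$membership[s])
    nc <- length(members)
    if (nc < 2) next
    dvec <- D[s, ]
    cnt <- rep(1, n)
    parent <- integer(n)
    ord <- members[order(dvec[members], decreasing = TRUE)]
    for (w in ord) {
      if (w == s) next
      cands <- adj[[w]]
      cands <- cands[dvec[cands] == dvec[w] - 1]
      parent[w] <- cands[which.min(lexrank[cands])]
    }
    for (w in ord) {
      if (w == s) next
      cnt[parent[w]] <- cnt[parent[w]] + cnt[w]
    }
    scored <- members[members != s & cnt[members] > nc / 4]
    out[scored] <- out[scored] + 1
  }
  .named(out, network)
}

# largest connected component of the open neighborhood of each vertex;
# returns list(size=, edges=) per vertex, breaking size ties by edge count
.max_neighborhood_component <- function(g) {
  n <- igraph::vcount(g)
  sizes <- numeric(n)
  edges <- numeric(n)
  for (v in seq_len(n)) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(g, nb)
    cl <- igraph::components(sub)
    best_size <- max(cl$csize)
    cand <- which(cl$csize == best_size)
    best_edges <- max(vapply(cand, function(ci) {
      igraph::ecount(igraph::induced_subgraph(sub, which(cl$membership == ci)))
    }, 0))
    sizes[v] <- best_size
    edges[v] <- best_edges
  }
  list(size = sizes, edges = edges)
}

#' Maximum neighborhood component (MNC)
#'
#' Size of the largest connected component of the subgraph induced by the
#' node's neighbors (the node itself excluded). 0 for isolated nodes.
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
mnc_centrality <- function(network) {
  .named(.max_neighborhood_component(network)$size, network)
}

#' Density of maximum neighborhood component (DMNC)
#'
#' `|E(N_v)| / |V(N_v)|^epsilon` for the largest neighborhood component
#' `N_v` of [mnc_centrality()] (ties in size broken toward the component
#' with most edges). 0 when the component has no edges.
#' @inheritParams degree_centrality
#' @param epsilon positive exponent applied to the component size
#'   (default 1.7).
#' @return named numeric vector.
#' @export
dmnc_centrality <- function(network, epsilon = 1.7) {
  stopifnot(is.numeric(epsilon), epsilon > 0)
  mn <- .max_neighborhood_component(network)
  out <- ifelse(mn$size > 0, mn$edges / mn$size^epsilon, 0)
  .named(out, network)
}

#' Maximal clique centrality (MCC)
#'
#' Sum of `(|C| - 1)!` over the maximal cliques `C` (of size at least 2)
#' containing the node. For a node whose neighbors share no edges this
#' reduces to its degree; isolated nodes score 0.
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
mcc_centrality <- function(network) {
  n <- igraph::vcount(network)
  out <- numeric(n)
  if (igraph::ecount(network) > 0) {
    cliques <- igraph::max_cliques(network, min = 2)
    for (cl in cliques) {
      idx <- as.integer(cl)
      out[idx] <- out[idx] + factorial(length(idx) - 1)
    }
  }
  .named(out, network)
}

#' Edge percolation component (EPC)
#'
#' Monte-Carlo estimate of the expected size of the node's connected
#' component when every edge is retained independently with probability
#' `retain_probability`. Averaged over `n_iterations` percolated copies;
#' values lie in `[1, n]` and are reproducible for a fixed `seed`.
#' @inheritParams degree_centrality
#' @param n_iterations number of percolation replicates (default 1000).
#' @param retain_probability edge retention probability in `[0, 1]`.
#' @param seed integer seed for the percolation draws (required).
#' @return named numeric vector.
#' @export
epc_centrality <- function(network, n_iterations = 1000,
                           retain_probability = 0.5, seed) {
  stopifnot(n_iterations >= 1,
            retain_probability >= 0, retain_probability <= 1)
  if (missing(seed)) stop("epc_centrality requires an explicit seed")
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  if (m == 0 || retain_probability == 0) {
    return(.named(rep(1, n), network))
  }
  tot <- numeric(n)
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(n_iterations)) {
      keep <- which(stats::runif(m) < retain_probability)
      sg <- igraph::subgraph_from_edges(network, keep, delete.vertices = FALSE)
      cl <- igraph::components(sg)
      tot <- tot + cl$csize[cl$membership]
    }
  })
  .named(tot / n_iterations, network)
}

#' Compute all ten centrality indexes
#'
#' Evaluates degree, betweenness, stress, eccentricity score, radiality,
#' bottleneck, MNC, DMNC, MCC and EPC for every node, in that fixed column
#' order (see [centrality_indexes()]).
#'
#' @inheritParams degree_centrality
#' @param epc_iterations,epc_retain,epc_seed parameters forwarded to
#'   [epc_centrality()]; the seed is required.
#' @param dmnc_epsilon exponent forwarded to [dmnc_centrality()].
#' @return data.frame with column `node` followed by the ten index columns,
#'   one row per network node.
#' @export
compute_all_centralities <- function(network, epc_iterations = 1000,
                                     epc_retain = 0.5, epc_seed,
                                     dmnc_epsilon = 1.7) {
  if (igraph::vcount(network) < 2) {
    stop("centrality table requires a network with at least 2 nodes")
  }
  if (missing(epc_seed)) stop("compute_all_centralities requires epc_seed")
  tab <- data.frame(
    node = igraph::V(network)$name,
    degree = unname(degree_centrality(network)),
    betweenness = unname(betweenness_centrality(network)),
    stress = unname(stress_centrality(network)),
    eccentricity = unname(eccentricity_score(network)),
    radiality = unname(radiality_centrality(network)),
    bottleneck = unname(bottleneck_centrality(network)),
    mnc = unname(mnc_centrality(network)),
    dmnc = unname(dmnc_centrality(network, epsilon = dmnc_epsilon)),
    mcc = unname(mcc_centrality(network)),
    epc = unname(epc_centrality(network, n_iterations = epc_iterations,
                                retain_probability = epc_retain,
                                seed = epc_seed)),
    stringsAsFactors = FALSE
  )
  stopifnot(identical(names(tab)[-1], centrality_indexes()))
  tab
}

#' Write a centrality table to TSV
#' @param table data.frame from [compute_all_centralities()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
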