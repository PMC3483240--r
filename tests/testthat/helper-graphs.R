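# Graph fixtures built in code: named toy graphs and seeded random graphs.

# graph from a character vector of edges, c("A","B", "B","C", ...)
toy_graph <- function(..., isolated = character(0)) {
  ends <- c(...)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unique(c(ends, isolated)))
  if (length(ends)) g <- igraph::add_edges(g, ends)
  g
}

path3 <- function() toy_graph("A", "B", "B", "C")
star3 <- function() toy_graph("C", "L1", "C", "L2", "C", "L3")
k3 <- function() toy_graph("A", "B", "B", "C", "A", "C")
k4 <- function() {
  toy_graph("A", "B", "A", "C", "A", "D", "B", "C", "B", "D", "C", "D")
}
c4 <- function() toy_graph("A", "B", "B", "C", "C", "D", "D", "A")
# two triangles sharing the edge B-C
bowtie_edge <- function() {
  toy_graph("A", "B", "A", "C", "B", "C", "B", "D", "C", "D")
}
# two triangles sharing only the vertex V
bowtie_vertex <- function() {
  toy_graph("A", "B", "A", "V", "B", "V", "C", "D", "C", "V", "D", "V")
}

# Erdos-Renyi G(n, p) with shuffled node names, so that vertex order and
# lexicographic name order disagree (exercises deterministic tie-breaking)
rand_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    nms <- sample(sprintf("N%02d", seq_len(n)))
  })
  dimnames(A) <- list(nms, nms)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

rand_connected_graph <- function(n, p, seed) {
  for (try in 0:199) {
    g <- rand_graph(n, p, seed + 7919 * try)
    if (igraph::is_connected(g)) return(g)
  }
  stop("no connected draw found")
}

# all labelled graphs on n nodes (n <= 4 in practice)
all_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  nms <- LETTERS[seq_len(n)]
  lapply(seq_len(2^m) - 1L, function(code) {
    keep <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    A <- matrix(0, n, n, dimnames = list(nms, nms))
    for (e in keep) {
      A[pairs[1, e], pairs[2, e]] <- 1
      A[pairs[2, e], pairs[1, e]] <- 1
    }
    igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  })
}

expect_named_equal <- function(actual, expected, tol = 1e-9) {
  expect_equal(actual[sort(names(actual))],
               expected[sort(names(expected))], tolerance = tol)
}

# all ten indexes vs their oracles on one graph
expect_matches_oracles <- function(g, tol = 1e-9) {
  pc <- o_paths_centrality(g)
  expect_named_equal(betweenness_centrality(g), pc$betweenness, tol)
  expect_named_equal(stress_centrality(g), pc$stress, tol)
  expect_named_equal(eccentricity_score(g), o_eccentricity_score(g), tol)
  expect_named_equal(radiality_centrality(g), o_radiality(g), tol)
  expect_named_equal(bottleneck_centrality(g), o_bottleneck(g), tol)
  md <- o_mnc_dmnc(g)
  expect_named_equal(mnc_centrality(g), md$mnc, tol)
  expect_named_equal(dmnc_centrality(g), md$dmnc, tol)
  expect_named_equal(mcc_centrality(g), o_mcc(g), tol)
  A <- o_adj(g)
  expect_named_equal(degree_centrality(g),
                     stats::setNames(rowSums(A), rownames(A)), tol)
  # EPC at the two deterministic retention probabilities
  comp_sizes <- {
    D <- o_dist(A)
    stats::setNames(apply(D, 1, function(d) sum(is.finite(d))), rownames(A))
  }
  expect_named_equal(epc_centrality(g, 10, 1, seed = 1), comp_sizes, tol)
  expect_named_equal(epc_centrality(g, 10, 0, seed = 1),
                     stats::setNames(rep(1, nrow(A)), rownames(A)), tol)
}
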