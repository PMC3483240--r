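# Toy-graph values below were computed with the brute-force oracles in
# helper-oracles.R (path enumeration, subset clique checks, explicit
# shortest-path trees) and frozen.

test_that("degree, betweenness and stress match hand-checkable toy graphs", {
  expect_named_equal(degree_centrality(path3()), c(A = 1, B = 2, C = 1))
  expect_named_equal(degree_centrality(star3()),
                     c(C = 3, L1 = 1, L2 = 1, L3 = 1))
  expect_named_equal(degree_centrality(k3()), c(A = 2, B = 2, C = 2))

  expect_named_equal(betweenness_centrality(path3()), c(A = 0, B = 1, C = 0))
  expect_named_equal(betweenness_centrality(star3()),
                     c(C = 3, L1 = 0, L2 = 0, L3 = 0))
  expect_named_equal(betweenness_centrality(k3()), c(A = 0, B = 0, C = 0))

  expect_named_equal(stress_centrality(path3()), c(A = 0, B = 1, C = 0))
  # C4: the opposite pair has two shortest paths, one through each interior node
  expect_named_equal(stress_centrality(c4()), c(A = 1, B = 1, C = 1, D = 1))
  expect_named_equal(stress_centrality(k3()), c(A = 0, B = 0, C = 0))
})

test_that("eccentricity score and radiality match their formulas on toys", {
  expect_named_equal(eccentricity_score(path3()), c(A = 0.5, B = 1, C = 0.5))
  expect_named_equal(eccentricity_score(k4()), c(A = 1, B = 1, C = 1, D = 1))
  expect_named_equal(eccentricity_score(star3()),
                     c(C = 1, L1 = 0.5, L2 = 0.5, L3 = 0.5))

  expect_named_equal(radiality_centrality(path3()),
                     c(A = 1.5, B = 2, C = 1.5))
  expect_named_equal(radiality_centrality(star3()),
                     c(C = 2, L1 = 4 / 3, L2 = 4 / 3, L3 = 4 / 3))
  expect_named_equal(radiality_centrality(k3()), c(A = 1, B = 1, C = 1))
})

test_that("bottleneck counts roots routing over a quarter of the component", {
  # n_c = 3 makes every subtree exceed n_c/4, so each node scores n-1
  expect_named_equal(bottleneck_centrality(path3()), c(A = 2, B = 2, C = 2))
  bn <- bottleneck_centrality(star3())
  expect_equal(unname(bn["C"]), 3)
  expect_named_equal(bottleneck_centrality(toy_graph("A", "B")),
                     c(A = 1, B = 1))
})

test_that("bottleneck resolves shortest-path-tree ties lexicographically", {
  # two equal-length routes from D to A, via B and via C: the tree must
  # route through B (lexicographically first), never C
  g <- toy_graph("A", "B", "A", "C", "B", "D", "C", "D")
  expect_named_equal(bottleneck_centrality(g), o_bottleneck(g))
  g2 <- rand_connected_graph(9, 0.3, seed = 42)
  expect_named_equal(bottleneck_centrality(g2), o_bottleneck(g2))
})

test_that("neighborhood-component indexes match definitions on toys", {
  expect_named_equal(mnc_centrality(star3()),
                     c(C = 1, L1 = 1, L2 = 1, L3 = 1))
  expect_named_equal(mnc_centrality(k3()), c(A = 2, B = 2, C = 2))
  expect_equal(unname(mnc_centrality(path3())["B"]), 1)

  expect_equal(unname(dmnc_centrality(path3())["B"]), 0)
  expect_equal(unname(dmnc_centrality(k3())["A"]), 1 / 2^1.7)
  expect_equal(unname(dmnc_centrality(k4())["A"]), 3 / 3^1.7)

  expect_named_equal(mcc_centrality(star3()),
                     c(C = 3, L1 = 1, L2 = 1, L3 = 1))
  expect_named_equal(mcc_centrality(k3()), c(A = 2, B = 2, C = 2))
  expect_equal(unname(mcc_centrality(path3())["B"]), 2)
})

test_that("EPC is exact at retention 0/1, reproducible, and unbiased on K2", {
  expect_named_equal(epc_centrality(k3(), 50, 1, seed = 1),
                     c(A = 3, B = 3, C = 3))
  expect_named_equal(epc_centrality(k3(), 50, 0, seed = 1),
                     c(A = 1, B = 1, C = 1))
  e1 <- epc_centrality(k3(), 200, 0.5, seed = 9)
  e2 <- epc_centrality(k3(), 200, 0.5, seed = 9)
  expect_identical(e1, e2)
  # exact expectation on K2 is 1 + p (enumeration over the two outcomes)
  k2 <- toy_graph("A", "B")
  expect_named_equal(o_epc_exact(k2, 0.5), c(A = 1.5, B = 1.5), tol = 1e-12)
  e <- epc_centrality(k2, 10000, 0.5, seed = 3)
  expect_lt(max(abs(e - 1.5)), 0.02)
})

test_that("Monte-Carlo EPC converges to the exact subset-enumeration expectation", {
  for (g in list(path3(), k3(), c4())) {
    exact <- o_epc_exact(g, 0.6)
    est <- epc_centrality(g, 20000, 0.6, seed = 17)
    expect_named_equal(est, exact, tol = 0.03)
  }
})

test_that("all indexes agree with brute-force oracles on random graphs", {
  seeds <- 1:12
  for (s in seeds) {
    n <- sample(4:7, 1)
    expect_matches_oracles(rand_connected_graph(n, 0.45, seed = 100 + s))
  }
  # disconnected graphs exercise the per-component conventions
  for (s in 1:6) {
    expect_matches_oracles(rand_graph(7, 0.22, seed = 300 + s))
  }
})

test_that("per-component conventions handle isolated nodes and split graphs", {
  g <- toy_graph("A", "B", "C", "D", isolated = "Z")
  expect_equal(unname(eccentricity_score(g)["Z"]), 1)
  expect_equal(unname(radiality_centrality(g)["Z"]), 0)
  expect_equal(unname(mcc_centrality(g)["Z"]), 0)
  expect_equal(unname(mnc_centrality(g)["Z"]), 0)
  expect_equal(unname(bottleneck_centrality(g)["Z"]), 0)
  expect_equal(unname(epc_centrality(g, 50, 0.5, seed = 1)["Z"]), 1)
  tab <- compute_all_centralities(g, epc_iterations = 50, epc_seed = 1)
  expect_true(all(vapply(tab[-1], function(x) all(is.finite(x)), TRUE)))
})

test_that("structural invariants hold on random graphs", {
  for (s in 1:8) {
    g <- rand_graph(8, 0.35, seed = 500 + s)
    expect_equal(sum(degree_centrality(g)), 2 * igraph::ecount(g))
    es <- eccentricity_score(g)
    expect_true(all(es > 0 & es <= 1))
    expect_true(all(mnc_centrality(g) <= degree_centrality(g)))
    expect_true(all(stress_centrality(g) >= betweenness_centrality(g) - 1e-9))
  }
  kc <- igraph::make_full_graph(5)
  igraph::V(kc)$name <- LETTERS[1:5]
  expect_true(all(betweenness_centrality(kc) == 0))
  expect_true(all(stress_centrality(kc) == 0))
})

test_that("vertex-transitive graphs give identical values at every node", {
  # odd ring: shortest paths are unique, so even the lexicographic
  # tie-break of the bottleneck trees cannot break node symmetry
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- LETTERS[1:5]
  kc <- igraph::make_full_graph(4)
  igraph::V(kc)$name <- LETTERS[1:4]
  for (g in list(ring, kc)) {
    tab <- compute_all_centralities(g, epc_iterations = 10, epc_retain = 1,
                                    epc_seed = 1)
    for (col in centrality_indexes()) {
      expect_lt(diff(range(tab[[col]])), 1e-9)
    }
  }
})

test_that("the centrality table has the ten documented columns in order", {
  tab <- compute_all_centralities(path3(), epc_iterations = 50, epc_seed = 2)
  expect_identical(names(tab), c("node", centrality_indexes()))
  expect_equal(ncol(tab) - 1, 10)
  # the middle node of a path dominates the leaves in every index
  b <- tab[tab$node == "B", -1]
  a <- tab[tab$node == "A", -1]
  expect_true(all(as.numeric(b) >= as.numeric(a)))
  expect_error(compute_all_centralities(toy_graph(isolated = "A"),
                                        epc_seed = 1), "at least 2")
})
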