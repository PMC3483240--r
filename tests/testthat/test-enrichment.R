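test_that("GMT parsing extracts sets and class labels", {
  f <- withr::local_tempfile(lines = c("S1\tCancer\tA\tB\tC",
                                       "S2\t.\tD\tE"))
  coll <- read_gmt(f)
  expect_equal(coll$sets$S1, c("A", "B", "C"))
  expect_equal(unname(coll$classes["S1"]), "Cancer")
  expect_equal(unname(coll$classes["S2"]), "unclassified")

  dup <- withr::local_tempfile(lines = c("S1\tx\tA", "S1\ty\tB"))
  expect_error(read_gmt(dup), "duplicate")
  empty <- withr::local_tempfile(lines = c("S1\tx\tA", "S2\t.\t"))
  expect_warning(coll2 <- read_gmt(empty), "no genes")
  expect_equal(names(coll2$sets), "S1")
})

test_that("GMT round-trips through write_gmt", {
  coll <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("C")),
                              classes = c(S1 = "Cancer"))
  f <- withr::local_tempfile()
  write_gmt(coll, f)
  back <- read_gmt(f)
  expect_equal(back$sets, coll$sets)
  expect_equal(back$classes, coll$classes)
})

test_that("hypergeometric and EASE p-values match frozen oracle values", {
  # values computed with the explicit combinatorial sum o_hyper_tail
  expect_equal(set_pvalue(5, 5, 5, 20, "hypergeometric"), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(set_pvalue(5, 5, 5, 20, "ease"), (5 * 15 + 1) / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(set_pvalue(0, 5, 5, 20, "hypergeometric"), 1)
  expect_equal(set_pvalue(0, 5, 5, 20, "ease"), 1)
  expect_equal(set_pvalue(1, 5, 5, 20, "ease"), 1)
  expect_error(set_pvalue(6, 5, 5, 20, "ease"), "inconsistent")
})

test_that("p-values agree with the combinatorial oracle on all small tables", {
  for (N in c(5, 12, 20, 30)) {
    for (K in seq_len(N)) {
      for (n in seq_len(N)) {
        ks <- 0:min(K, n)
        hyper <- vapply(ks, set_pvalue, 0, n = n, K = K, N = N,
                        method = "hypergeometric")
        want <- vapply(ks, o_hyper_tail, 0, n = n, K = K, N = N)
        expect_equal(hyper, want, tolerance = 1e-9)
        ease <- vapply(ks, set_pvalue, 0, n = n, K = K, N = N,
                       method = "ease")
        want_e <- vapply(pmax(ks - 1, 0), o_hyper_tail, 0, n = n, K = K, N = N)
        expect_equal(ease, want_e, tolerance = 1e-9)
        expect_true(all(ease >= hyper - 1e-12))
      }
    }
  }
})

test_that("BH adjustment matches the hand-evaluated step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  # order preserved, adjusted >= raw
  p <- c(0.04, 0.001, 0.9, 0.02)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(adj, stats::p.adjust(p, "BH"))
})

test_that("enrich finds a planted set, aggregates classes, reports coverage", {
  universe <- sprintf("G%03d", 1:200)
  gen <- generate_gene_sets(universe, n_sets = 20, set_size_range = c(10, 30),
                            query_size = 30, enriched_fraction = 0.8,
                            seed = 77)
  res <- enrich(gen$query, gen$collection, universe,
                method = "hypergeometric", universe_mode = "all")
  expect_equal(res$sets$name[1], gen$truth$enriched_set)
  expect_true(all(res$sets$adjusted_p >= res$sets$p_value - 1e-12))
  expect_true(all(res$sets$overlap <=
                    pmin(res$sets$set_size, res$sets$query_size)))
  # class rows aggregate unions of member sets
  cls <- unname(gen$collection$classes[gen$truth$enriched_set])
  expect_true(cls %in% res$classes$class)
  expect_true(res$coverage > 0 && res$coverage <= 1)
  expect_error(enrich(c("NOT_IN"), gen$collection, universe), "universe")
})

test_that("annotated-universe mode restricts background to annotated genes", {
  universe <- c("A", "B", "C", "D", "E", "F")
  coll <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("C")))
  res <- enrich(c("A", "D"), coll, universe, universe_mode = "annotated")
  expect_equal(res$universe_size, 3)  # A, B, C annotated
  expect_equal(res$query_size, 1)     # D dropped with the universe
  expect_equal(res$coverage, 0.5)
  res_all <- enrich(c("A", "D"), coll, universe, universe_mode = "all")
  expect_equal(res_all$universe_size, 6)
})

test_that("a query disjoint from all sets yields empty set rows but coverage", {
  universe <- c("A", "B", "C", "D")
  coll <- gene_set_collection(list(S1 = c("A", "B")))
  res <- enrich("D", coll, universe, universe_mode = "all")
  expect_equal(nrow(res$sets), 0)
  expect_equal(res$coverage, 0.5)
})

test_that("null queries produce approximately uniform raw p-values", {
  universe <- sprintf("G%04d", 1:400)
  sets <- withr::with_seed(101, {
    lapply(1:40, function(i) sample(universe, 60))
  })
  names(sets) <- sprintf("S%02d", 1:40)
  coll <- gene_set_collection(sets)
  n_rep <- 60
  hits <- 0; total <- 0
  for (r in seq_len(n_rep)) {
    query <- withr::with_seed(5000 + r, sample(universe, 50))
    res <- enrich(query, coll, universe, method = "hypergeometric",
                  universe_mode = "all")
    hits <- hits + sum(res$sets$p_value <= 0.05)
    total <- total + 40
  }
  rate <- hits / total
  # binomial 3-sigma band around the nominal level (discreteness makes the
  # test slightly conservative, so the band is one-sided generous below)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
  expect_gt(rate, 0.02)
})
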