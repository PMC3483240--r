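test_that("a single-Gaussian fit recovers the closed-form MLE and BIC", {
  x <- matrix(withr::with_seed(7, stats::rnorm(80, 5, 2)), ncol = 1,
              dimnames = list(sprintf("O%02d", 1:80), "f"))
  fit <- fit_mixture(x, G = 1, model = "EII", seed = 1)
  n <- nrow(x)
  expect_equal(fit$means[[1]], c(f = mean(x)), tolerance = 1e-6)
  expect_equal(fit$covariances[[1]][1], mean((x - mean(x))^2),
               tolerance = 1e-4)
  # m = 2 free parameters in 1-D: one mean, one variance
  expect_equal(fit$n_params, 2)
  expect_equal(fit$bic, 2 * fit$log_likelihood - 2 * log(n), tolerance = 1e-9)
  expect_error(fit_mixture(x[1:3, , drop = FALSE], G = 5, seed = 1),
               "n > G")
})

test_that("EM recovers the means of two well-separated clusters", {
  x <- sim_mixture(100, rbind(-10, 10), sd = 1, seed = 2)
  fit <- fit_mixture(x, G = 2, model = "VVV", seed = 3)
  mu <- sort(vapply(fit$means, `[[`, 0, 1))
  expect_lt(abs(mu[1] + 10), 0.5)
  expect_lt(abs(mu[2] - 10), 0.5)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone non-decreasing at every iteration", {
  for (model in c("EII", "VVI", "EEE", "VVV")) {
    x <- sim_mixture(60, rbind(c(0, 0), c(4, 4), c(-4, 4)), sd = 1.5,
                     seed = 11)
    fit <- fit_mixture(x, G = 3, model = model, seed = 12)
    expect_false(fit$failed)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8),
                info = model)
  }
})

test_that("fits are deterministic given the seed", {
  x <- sim_mixture(50, rbind(c(0, 0), c(6, 0)), seed = 21)
  f1 <- fit_mixture(x, G = 2, seed = 5)
  f2 <- fit_mixture(x, G = 2, seed = 5)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_identical(f1$assignments, f2$assignments)
})

test_that("assignments are invariant under feature-order permutation", {
  x <- sim_mixture(40, rbind(c(0, 0, 0), c(5, 5, 5)), seed = 31)
  f1 <- fit_mixture(x, G = 2, model = "VVI", seed = 6)
  f2 <- fit_mixture(x[, c(3, 1, 2)], G = 2, model = "VVI", seed = 6)
  # cluster labels may swap; compare the induced partitions
  expect_equal(unname(f1$assignments == f1$assignments[1]),
               unname(f2$assignments == f2$assignments[1]))
})

test_that("BIC selects the true number of well-separated components", {
  wins2 <- 0; wins3 <- 0
  for (r in 1:6) {
    x2 <- sim_mixture(80, rbind(c(-8, 0), c(8, 0)), sd = 1, seed = 100 + r)
    sel2 <- select_model(x2, G_range = 1:4, models = c("EII", "VVV"),
                         seed = 200 + r)
    if (sel2$best$G == 2) wins2 <- wins2 + 1
    x3 <- sim_mixture(60, rbind(c(0, 0), c(10, 0), c(0, 10)), sd = 1,
                      seed = 300 + r)
    sel3 <- select_model(x3, G_range = 1:5, models = c("EII", "VVV"),
                         seed = 400 + r)
    if (sel3$best$G == 3) wins3 <- wins3 + 1
  }
  expect_gte(wins2, 5)
  expect_gte(wins3, 5)
})

test_that("single-Gaussian data selects G = 1 and beats overfit models", {
  wins <- 0
  for (r in 1:6) {
    x <- sim_mixture(120, rbind(c(0, 0)), sd = 1, seed = 500 + r)
    sel <- select_model(x, G_range = 1:3, models = "EII", seed = 600 + r)
    if (sel$best$G == 1) wins <- wins + 1
    bt <- sel$bic_table
    expect_true(all(bt$bic[bt$G == 1] >= bt$bic[bt$G == 3] - 1e-9) ||
                  any(bt$failed))
  }
  expect_gte(wins, 5)
  expect_error(select_model(sim_mixture(10, rbind(0), seed = 1),
                            G_range = integer(0), seed = 1), "non-empty")
})

test_that("BIC and classification agree with the mclust reference", {
  # mclust model names coincide with the package's covariance families
  mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller
  x <- sim_mixture(70, rbind(c(0, 0), c(7, 7)), sd = 1, seed = 41)
  fit <- fit_mixture(x, G = 2, model = "VVI", seed = 7, tol = 1e-8)
  ref <- mclust::Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  # same optimum found: log-likelihood and BIC match closely
  expect_equal(fit$log_likelihood, ref$loglik, tolerance = 1e-3)
  expect_equal(fit$n_params, mclust::nMclustParams("VVI", d = 2, G = 2))
  expect_equal(fit$bic, as.numeric(ref$bic), tolerance = 1e-2)
  agree <- mean((fit$assignments == fit$assignments[1]) ==
                  (ref$classification == ref$classification[1]))
  expect_gte(max(agree, 1 - agree), 0.99)
})

test_that("cluster summaries order clusters by mean composite score", {
  sc <- data.frame(node = c("A", "B", "C"), score_i = c(1, 2, 10))
  fit <- structure(list(G = 2, failed = FALSE,
                        assignments = c(A = 1L, B = 1L, C = 2L)),
                   class = "mixture_fit")
  summ <- summarize_clusters(fit, sc)
  expect_equal(summ$cluster, c("C1", "C2"))
  expect_equal(summ$mean_score, c(1.5, 10))
  expect_equal(sum(summ$size), 3)
  bad <- data.frame(node = c("A", "B"), score_i = c(1, 2))
  expect_error(summarize_clusters(fit, bad), "same node set")
})

test_that("planted hubs end up in the top-scoring cluster", {
  gen <- generate_network(n_nodes = 150, attachment_m = 2, n_hubs = 2,
                          hub_fraction = 0.25, seed = 71)
  ct <- compute_all_centralities(gen$graph, epc_iterations = 100,
                                 epc_seed = 72)
  sc <- score_i(ct)
  feats <- as.matrix(sc[centrality_indexes()])
  rownames(feats) <- sc$node
  sel <- select_model(feats, G_range = 2:4, models = c("EII", "VVV"),
                      seed = 73)
  summ <- summarize_clusters(sel$best, sc)
  top_cluster <- summ$cluster[which.max(summ$mean_score)]
  members <- strsplit(summ$members[summ$cluster == top_cluster], ",")[[1]]
  expect_true(all(gen$truth$hubs %in% members))
})
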