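# Model-based clustering of nodes by their normalized centrality profiles.
# Gaussian mixtures are fitted by EM under four covariance families and the
# number of components is selected by BIC = 2*logL - m*log(n) (higher is
# better, the mclust sign convention). Supported families:
#   "EII"  spherical, one variance shared by all components and features
#   "VVI"  diagonal, per-component per-feature variances
#   "EEE"  one full covariance matrix shared by all components
#   "VVV"  full covariance per component (ellipsoidal, fully variable)

.gmm_models <- c("EII", "VVI", "EEE", "VVV")

# log-densities of multivariate normals, one column per component
.gmm_logdens <- function(x, means, covs, model) {
  n <- nrow(x); d <- ncol(x); G <- length(means)
  out <- matrix(NA_real_, n, G)
  for (g in seq_len(G)) {
    ctr <- sweep(x, 2, means[[g]])
    if (model %in% c("EII", "VVI")) {
      v <- covs[[g]]  # length-d vector of variances
      out[, g] <- -0.5 * (d * log(2 * pi) + sum(log(v)) +
                            rowSums(sweep(ctr^2, 2, v, "/")))
    } else {
      R <- chol(covs[[g]])
      z <- ctr %*% backsolve(R, diag(d))
      out[, g] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) +
                            rowSums(z^2))
    }
  }
  out
}

# free-parameter count: weights + means + covariance parameters
.gmm_nparams <- function(G, d, model) {
  cov_p <- switch(model,
                  EII = 1,
                  VVI = G * d,
                  EEE = d * (d + 1) / 2,
                  VVV = G * d * (d + 1) / 2)
  (G - 1) + G * d + cov_p
}

.gmm_mstep_cov <- function(x, resp, means, model, ridge) {
  n <- nrow(x); d <- ncol(x); G <- ncol(resp)
  nk <- colSums(resp)
  if (model == "EII") {
    ss <- 0
    for (g in seq_len(G)) {
      ctr <- sweep(x, 2, means[[g]])
      ss <- ss + sum(resp[, g] * rowSums(ctr^2))
    }
    v <- ss / (n * d) + ridge
    return(rep(list(rep(v, d)), G))
  }
  if (model == "VVI") {
    return(lapply(seq_len(G), function(g) {
      ctr <- sweep(x, 2, means[[g]])
      colSums(resp[, g] * ctr^2) / nk[g] + ridge
    }))
  }
  if (model == "EEE") {
    S <- matrix(0, d, d)
    for (g in seq_len(G)) {
      ctr <- sweep(x, 2, means[[g]])
      S <- S + crossprod(ctr * sqrt(resp[, g]))
    }
    S <- S / n + diag(ridge, d)
    return(rep(list(S), G))
  }
  lapply(seq_len(G), function(g) {
    ctr <- sweep(x, 2, means[[g]])
    crossprod(ctr * sqrt(resp[, g])) / nk[g] + diag(ridge, d)
  })
}

#' Fit a Gaussian mixture by EM
#'
#' Seeded k-means initialization, EM iterated until the log-likelihood
#' increase falls below `tol` (or `max_iter`), with a small ridge added to
#' every covariance estimate for numerical stability. The per-iteration
#' log-likelihood trace is returned so monotonicity can be verified.
#'
#' @param data numeric matrix (observations x features), e.g. the
#'   normalized centrality columns of a [score_i()] table. Row names label
#'   the observations.
#' @param G number of mixture components (`1 <= G < n`).
#' @param model covariance family: `"EII"`, `"VVI"`, `"EEE"` or `"VVV"`
#'   (default; full covariance per component).
#' @param seed integer seed for the k-means initialization (required).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param ridge covariance regularization added to diagonals (default 1e-6).
#' @return object of class `mixture_fit`: list with `G`, `model`, `weights`,
#'   `means` (list of vectors), `covariances` (list), `log_likelihood`,
#'   `loglik_trace`, `bic` (`2*logL - m*log(n)`, higher is better),
#'   `n_params`, `assignments` (named integer vector, max posterior),
#'   `responsibilities`, `converged`, `failed`.
#' @export
fit_mixture <- function(data, G, model = "VVV", seed, tol = 1e-6,
                        max_iter = 500, ridge = 1e-6) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (!all(is.finite(x))) stop("features must be finite")
  if (G < 1 || G >= n) stop("need n > G >= 1")
  if (!model %in% .gmm_models) {
    stop("unknown covariance model: ", model, " (supported: ",
         paste(.gmm_models, collapse = ", "), ")")
  }
  if (missing(seed)) stop("fit_mixture requires an explicit seed")

  fail <- function(msg) {
    structure(list(G = G, model = model, failed = TRUE, message = msg,
                   bic = -Inf), class = "mixture_fit")
  }
  # k-means initialization (seeded); degenerate data falls back to a
  # quantile-spread assignment
  init <- withr::with_seed(as.integer(seed), {
    if (G == 1) {
      rep(1L, n)
    } else {
      km <- tryCatch(
        stats::kmeans(x, centers = G, nstart = 5, iter.max = 50),
        error = function(e) NULL)
      if (is.null(km)) {
        as.integer(cut(rank(x[, 1], ties.method = "first"), G, labels = FALSE))
      } else km$cluster
    }
  })
  resp <- matrix(0, n, G)
  resp[cbind(seq_len(n), init)] <- 1

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # M step
    nk <- colSums(resp)
    if (any(nk < .Machine$double.eps)) return(fail("empty component"))
    weights <- nk / n
    means <- lapply(seq_len(G), function(g) colSums(resp[, g] * x) / nk[g])
    covs <- .gmm_mstep_cov(x, resp, means, model, ridge)
    # E step (log-sum-exp)
    ld <- tryCatch(.gmm_logdens(x, means, covs, model),
                   error = function(e) NULL)
    if (is.null(ld) || !all(is.finite(ld))) {
      return(fail("singular covariance"))
    }
    lw <- sweep(ld, 2, log(weights), "+")
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(lw - lse)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  m <- .gmm_nparams(G, d, model)
  assignments <- max.col(resp, ties.method = "first")
  names(assignments) <- rownames(x)
  structure(list(G = G, model = model, weights = weights, means = means,
                 covariances = covs, log_likelihood = ll,
                 loglik_trace = loglik_trace,
                 bic = 2 * ll - m * log(n), n_params = m,
                 assignments = assignments, responsibilities = resp,
                 converged = converged, failed = FALSE),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("mixture fit (G = %d, %s): FAILED (%s)\n",
                x$G, x$model, x$message))
  } else {
    cat(sprintf("mixture fit: G = %d, model %s, logL = %.3f, BIC = %.3f\n",
                x$G, x$model, x$log_likelihood, x$bic))
  }
  invisible(x)
}

#' Select a mixture model by BIC
#'
#' Fits every (G, model) combination and returns the fit maximizing BIC,
#' together with the full BIC table. Failed fits (singular or emptied
#' components) are recorded in the table and excluded from selection.
#'
#' @inheritParams fit_mixture
#' @param G_range integer vector of component counts to try (default 1:9).
#' @param models character vector of covariance families (default all
#'   four).
#' @return list with `best` (a `mixture_fit`), `bic_table` (data.frame
#'   `G`, `model`, `bic`, `converged`, `failed`) and `fits` (all fits).
#' @export
select_model <- function(data, G_range = 1:9, models = .gmm_models, seed,
                         tol = 1e-6, max_iter = 500, ridge = 1e-6) {
  if (!length(G_range)) stop("G_range must be non-empty")
  if (missing(seed)) stop("select_model requires an explicit seed")
  grid <- expand.grid(G = G_range, model = models,
                      stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch(
      fit_mixture(data, G = grid$G[i], model = grid$model[i],
                  seed = as.integer(seed) + grid$G[i], tol = tol,
                  max_iter = max_iter, ridge = ridge),
      error = function(e) structure(
        list(G = grid$G[i], model = grid$model[i], failed = TRUE,
             message = conditionMessage(e), bic = -Inf),
        class = "mixture_fit"))
  })
  bic_table <- data.frame(
    G = grid$G, model = grid$model,
    bic = vapply(fits, function(f) f$bic, 0),
    converged = vapply(fits, function(f) isTRUE(f$converged), TRUE),
    failed = vapply(fits, function(f) isTRUE(f$failed), TRUE),
    stringsAsFactors = FALSE
  )
  ok <- which(!bic_table$failed)
  if (!length(ok)) stop("all mixture fits failed")
  best <- fits[[ok[which.max(bic_table$bic[ok])]]]
  list(best = best, bic_table = bic_table, fits = fits)
}

#' Per-cluster composite-score summary
#'
#' Labels clusters C1..CG in order of increasing mean composite score, so
#' the highest-scoring (most hub-like) cluster always gets the highest
#' label, and reports size, mean score and members per cluster.
#'
#' @param fit a converged `mixture_fit` whose assignment names are gene
#'   symbols.
#' @param scores data.frame from [score_i()] covering exactly the same
#'   genes.
#' @return data.frame with columns `cluster`, `size`, `mean_score`,
#'   `members` (comma-separated), ordered C1..CG.
#' @export
summarize_clusters <- function(fit, scores) {
  stopifnot(inherits(fit, "mixture_fit"), !isTRUE(fit$failed))
  genes <- names(fit$assignments)
  if (is.null(genes) || !setequal(genes, scores$node)) {
    stop("fit and score table must cover the same node set")
  }
  sc <- scores$score_i
  names(sc) <- scores$node
  comp <- sort(unique(fit$assignments))
  means <- vapply(comp, function(g)
    mean(sc[genes[fit$assignments == g]]), 0)
  ord <- comp[order(means)]
  out <- do.call(rbind, lapply(seq_along(ord), function(i) {
    members <- sort(genes[fit$assignments == ord[i]])
    data.frame(cluster = paste0("C", i), size = length(members),
               mean_score = mean(sc[members]),
               members = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
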