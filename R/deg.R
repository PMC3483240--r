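# Two-group differential-expression prefilter: per-gene resampling p-value
# on the difference of log2 group means, fold-change filter on linear-scale
# group means, Benjamini-Hochberg correction across genes, and merging of
# the selected genes with externally supplied ranked gene lists.

#' Read a two-group expression matrix
#'
#' Expression TSV: first column gene symbols, remaining columns one sample
#' each (header = sample ids), linear-scale positive values. The groups
#' file assigns `case` or `control` to every sample
#' (`sample <TAB> case|control`).
#'
#' @param path expression matrix TSV.
#' @param groups_path two-column TSV mapping sample to group.
#' @return list with `values` (numeric matrix, genes x samples) and
#'   `groups` (named character vector of `"case"`/`"control"`).
#' @export
read_expression_matrix <- function(path, groups_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- toupper(df[[1]])
  if (anyNA(vals)) stop("expression matrix contains missing values")
  gr <- utils::read.delim(groups_path, header = FALSE,
                          stringsAsFactors = FALSE)
  groups <- gr[[2]]
  names(groups) <- gr[[1]]
  if (!all(colnames(vals) %in% names(groups))) {
    stop("groups file does not cover all samples")
  }
  groups <- groups[colnames(vals)]
  if (!all(groups %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'")
  }
  if (!any(groups == "case") || !any(groups == "control")) {
    stop("both groups must be non-empty")
  }
  list(values = vals, groups = groups)
}

#' Resampling p-value for a two-group comparison of one gene
#'
#' The test statistic is the difference of group means of log2 expression.
#' Under `method = "permutation"` (default) group labels are permuted;
#' under `method = "bootstrap"` both groups are redrawn with replacement
#' from the pooled values. The two-sided p-value is
#' `(1 + #(|T*| >= |T|)) / (B + 1)`. A gene with identical values in all
#' samples returns p = 1.
#'
#' @param case,control numeric vectors of linear-scale expression values
#'   (each group needs >= 2 samples).
#' @param B number of resampling iterations (>= 100).
#' @param seed integer seed (required).
#' @param method `"permutation"` or `"bootstrap"`.
#' @return two-sided p-value.
#' @export
resampling_pvalue <- function(case, control, B = 1000, seed,
                              method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (length(case) < 2 || length(control) < 2) {
    stop("each group needs at least 2 samples")
  }
  if (B < 100) stop("B must be >= 100")
  if (missing(seed)) stop("resampling_pvalue requires an explicit seed")
  x <- log2(c(case, control))
  n1 <- length(case)
  n <- length(x)
  if (max(x) - min(x) < .Machine$double.eps^0.5) return(1)
  tobs <- mean(x[seq_len(n1)]) - mean(x[-seq_len(n1)])
  tot <- sum(x)
  withr::with_seed(as.integer(seed), {
    if (method == "permutation") {
      picks <- replicate(B, sample.int(n, n1))
    } else {
      picks <- NULL
      boot1 <- matrix(sample.int(n, n1 * B, replace = TRUE), nrow = n1)
      boot2 <- matrix(sample.int(n, (n - n1) * B, replace = TRUE),
                      nrow = n - n1)
    }
  })
  if (method == "permutation") {
    cs <- colSums(matrix(x[picks], nrow = n1))
    tstar <- cs / n1 - (tot - cs) / (n - n1)
  } else {
    # both groups redrawn from the pooled values, so the bootstrap
    # distribution is already centered on the null
    tstar <- colMeans(matrix(x[boot1], nrow = n1)) -
      colMeans(matrix(x[boot2], nrow = n - n1))
  }
  (1 + sum(abs(tstar) >= abs(tobs) - 1e-12)) / (B + 1)
}

#' Select differentially expressed genes
#'
#' Per-gene resampling p-values (see [resampling_pvalue()]), BH adjustment
#' across all genes, and selection of genes with adjusted p <= `alpha` and
#' a symmetric fold change of at least `fc_threshold` (a gene at half the
#' control level counts as 2-fold). Fold change is the ratio of
#' linear-scale group means (case / control).
#'
#' @param expr list with `values` (genes x samples matrix) and `groups`
#'   (per-sample `"case"`/`"control"`), as from [read_expression_matrix()].
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param fc_threshold symmetric fold-change cutoff (default 2).
#' @param B resampling iterations; `NULL` picks 10000 when the experiment
#'   has >= 20 samples and 1000 otherwise.
#' @param seed integer master seed; per-gene seeds are derived from it.
#' @param method resampling scheme, see [resampling_pvalue()].
#' @return data.frame (one row per gene): `gene`, `fold_change`, `raw_p`,
#'   `adjusted_p`, `selected`; attributes `n_raw_significant` (raw p <=
#'   alpha) and `n_adjusted_significant` (adjusted p <= alpha).
#' @export
select_degs <- function(expr, alpha = 0.05, fc_threshold = 2.0, B = NULL,
                        seed, method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (missing(seed)) stop("select_degs requires an explicit seed")
  vals <- expr$values
  groups <- expr$groups
  stopifnot(is.matrix(vals), all(vals > 0),
            all(groups %in% c("case", "control")))
  n_samples <- ncol(vals)
  if (is.null(B)) B <- if (n_samples >= 20) 10000 else 1000
  case_idx <- which(groups == "case")
  ctrl_idx <- which(groups == "control")
  genes <- rownames(vals)
  raw_p <- vapply(seq_len(nrow(vals)), function(i) {
    resampling_pvalue(vals[i, case_idx], vals[i, ctrl_idx], B = B,
                      seed = as.integer(seed) + i, method = method)
  }, 0)
  fc <- rowMeans(vals[, case_idx, drop = FALSE]) /
    rowMeans(vals[, ctrl_idx, drop = FALSE])
  adj_p <- bh_adjust(raw_p)
  selected <- adj_p <= alpha & pmax(fc, 1 / fc) >= fc_threshold
  out <- data.frame(gene = genes, fold_change = unname(fc), raw_p = raw_p,
                    adjusted_p = adj_p, selected = selected,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_raw_significant") <- sum(raw_p <= alpha)
  attr(out, "n_adjusted_significant") <- sum(adj_p <= alpha)
  out
}

#' Merge selected DEGs with external ranked gene lists
#'
#' Takes the union of the selected genes of a DEG result and the top
#' `top_k_per_list` entries of each extra list (one ranked symbol per line,
#' e.g. the output of text-mining prioritization tools), collapsing
#' duplicates and recording per-gene provenance.
#'
#' @param deg data.frame from [select_degs()], or `NULL`.
#' @param extra_lists character vector of gene-list file paths (may be
#'   empty).
#' @param top_k_per_list how many genes to take from the head of each list
#'   (default 20).
#' @return data.frame with columns `gene` and `provenance`
#'   (semicolon-separated origins), sorted by gene symbol.
#' @export
merge_gene_lists <- function(deg = NULL, extra_lists = character(0),
                             top_k_per_list = 20) {
  prov <- list()
  add <- function(genes, tag) {
    for (g in genes) prov[[g]] <<- union(prov[[g]], tag)
  }
  if (!is.null(deg) && nrow(deg)) {
    add(toupper(deg$gene[deg$selected]), "deg")
  }
  for (path in extra_lists) {
    if (!file.exists(path)) stop("gene list file not found: ", path)
    genes <- readLines(path, warn = FALSE)
    genes <- toupper(trimws(genes))
    genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
    add(utils::head(unique(genes), top_k_per_list), basename(path))
  }
  genes <- sort(names(prov))
  data.frame(gene = genes,
             provenance = vapply(prov[genes], function(p)
               paste(sort(p), collapse = ";"), ""),
             stringsAsFactors = FALSE)
}
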