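# Composite hub score: each centrality index is min-max normalized to a
# percentage across all network nodes, and the per-node percentages are
# summed over the Nc indexes. With Nc indexes the score is bounded by
# 100 * Nc (1000 for the standard ten-index table).

#' Min-max normalize one centrality index to percentages
#'
#' Maps the minimum to 0 and the maximum to 100, linearly in between. A
#' constant column (max = min) carries no ranking information and maps to
#' all zeros.
#'
#' @param values numeric vector (optionally named), all finite.
#' @return numeric vector of percentages in `[0, 100]`, names preserved.
#' @export
normalize_index <- function(values) {
  if (!length(values)) stop("cannot normalize an empty index column")
  if (!all(is.finite(values))) stop("index values must be finite")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    out <- rep(0, length(values))
    names(out) <- names(values)
    return(out)
  }
  (values - rng[1]) / (rng[2] - rng[1]) * 100
}

#' Composite hub score from a centrality table
#'
#' Normalizes every index column with [normalize_index()] (over all network
#' nodes) and sums the per-node percentages into the composite score. The
#' score is invariant under column permutation and under strictly
#' increasing affine rescaling of any single raw column, and is bounded by
#' `100 * Nc`.
#'
#' @param table data.frame from [compute_all_centralities()]: column `node`
#'   followed by one numeric column per index.
#' @return data.frame with column `node`, the normalized percentage columns
#'   (same names as the input indexes), and `score_i`.
#' @export
score_i <- function(table) {
  stopifnot(is.data.frame(table), "node" %in% names(table), ncol(table) >= 2)
  idx_cols <- setdiff(names(table), "node")
  vals <- as.matrix(table[idx_cols])
  if (!all(is.finite(vals))) stop("centrality table contains non-finite values")
  norm <- apply(vals, 2, normalize_index)
  if (nrow(table) == 1) norm <- matrix(norm, nrow = 1, dimnames = list(NULL, idx_cols))
  out <- data.frame(node = table$node, norm, stringsAsFactors = FALSE)
  out$score_i <- rowSums(norm)
  out
}

#' Rank genes by composite score
#'
#' Sorts descending by `score_i` with lexicographic tie-breaking on the
#' gene symbol. When `restrict_to` is given only members of that set are
#' ranked, and the top-scoring genes *outside* the set are reported in the
#' `"outside_restrict"` attribute (high-scoring network genes absent from
#' the seed list are often of interest in their own right).
#'
#' @param scores data.frame from [score_i()].
#' @param k number of genes to return (all available if fewer).
#' @param restrict_to optional character vector of gene symbols.
#' @return data.frame with columns `gene`, `score`; when `restrict_to` is
#'   supplied, attribute `outside_restrict` holds the analogous top-`k`
#'   table for genes not in the set.
#' @export
top_genes <- function(scores, k, restrict_to = NULL) {
  stopifnot(k >= 1)
  ranked <- data.frame(gene = scores$node, score = scores$score_i,
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$score, ranked$gene), , drop = FALSE]
  rownames(ranked) <- NULL
  if (is.null(restrict_to)) {
    return(utils::head(ranked, k))
  }
  restrict_to <- unique(toupper(restrict_to))
  inside <- ranked[ranked$gene %in% restrict_to, , drop = FALSE]
  outside <- ranked[!ranked$gene %in% restrict_to, , drop = FALSE]
  res <- utils::head(inside, k)
  rownames(res) <- NULL
  out_top <- utils::head(outside, k)
  rownames(out_top) <- NULL
  attr(res, "outside_restrict") <- out_top
  res
}

#' Write a score table to TSV
#' @param scores data.frame from [score_i()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
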