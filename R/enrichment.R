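# Gene-set over-representation analysis. For a query of n genes drawn from
# a universe of N genes, K of which belong to a given set, the overlap k is
# scored with the hypergeometric upper tail P(X >= k) or with the more
# conservative EASE variant (the same tail recomputed with one overlapping
# gene removed). Benjamini-Hochberg correction is applied across sets.

#' Read a GMT gene-set collection
#'
#' GMT lines are `name <TAB> description <TAB> gene1 <TAB> gene2 ...`. The
#' description column is used as an optional class label (e.g. a disease
#' class grouping several disease sets); `.` or an empty description means
#' unclassified. Lines without genes are skipped with a warning; duplicate
#' set names are an error. Gene symbols are uppercased.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors) and `classes` (named character vector of
#'   class labels, `"unclassified"` when absent).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  classes <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3) {
      warning(sprintf("GMT line %d ('%s') has no genes; skipped", i,
                      if (length(f)) f[1] else ""))
      next
    }
    name <- f[1]
    if (name %in% names(sets)) stop("duplicate gene-set name: ", name)
    desc <- trimws(f[2])
    genes <- unique(toupper(f[-(1:2)]))
    sets[[name]] <- genes
    classes[name] <- if (desc == "" || desc == ".") "unclassified" else desc
  }
  structure(list(sets = sets, classes = classes),
            class = "gene_set_collection")
}

#' Construct a gene-set collection in memory
#' @param sets named list of character vectors of gene symbols.
#' @param classes optional named character vector of class labels (names =
#'   set names); missing entries become `"unclassified"`.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, classes = NULL) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets),
            !anyDuplicated(names(sets)), all(lengths(sets) > 0))
  sets <- lapply(sets, function(g) unique(toupper(g)))
  cl <- rep("unclassified", length(sets))
  names(cl) <- names(sets)
  if (!is.null(classes)) cl[names(classes)] <- classes
  structure(list(sets = sets, classes = cl), class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$classes[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation p-value for one gene set
#'
#' @param k overlap between query and set.
#' @param n query size.
#' @param K set size (within the universe).
#' @param N universe size.
#' @param method `"hypergeometric"` for the upper tail `P(X >= k)`;
#'   `"ease"` for the EASE score, the same tail computed with overlap
#'   `k - 1` (an overlap of 0 or 1 then gives p = 1), which penalizes
#'   single-gene overlaps.
#' @return p-value in `[0, 1]`.
#' @export
set_pvalue <- function(k, n, K, N, method = c("ease", "hypergeometric")) {
  method <- match.arg(method)
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > min(n, K) || n > N || K > N) {
    stop("inconsistent contingency counts")
  }
  if (method == "ease") k <- k - 1
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (with the usual monotonicity
#' enforcement), preserving input order. Thin wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Scores every set with at least one query gene, and additionally every
#' set *class* (the union of its member sets), against the chosen universe.
#' By default the universe is restricted to annotated genes (those present
#' in at least one set of the collection) and the query is restricted
#' accordingly; `universe_mode = "all"` keeps the full supplied universe.
#'
#' @param query character vector of gene symbols; must be contained in
#'   `universe`.
#' @param collection a `gene_set_collection`.
#' @param universe character vector of background gene symbols (e.g. all
#'   network genes).
#' @param method p-value method, see [set_pvalue()].
#' @param universe_mode `"annotated"` (default) or `"all"`.
#' @return list with `sets` and `classes` data.frames (columns `name`,
#'   `class`, `overlap`, `set_size`, `query_size`, `universe_size`,
#'   `p_value`, `adjusted_p`, `genes`), `coverage` (fraction of the
#'   supplied universe present in >= 1 set), `universe_size` and
#'   `query_size` actually used.
#' @export
enrich <- function(query, collection, universe,
                   method = c("ease", "hypergeometric"),
                   universe_mode = c("annotated", "all")) {
  method <- match.arg(method)
  universe_mode <- match.arg(universe_mode)
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(toupper(query))
  if (!all(query %in% universe)) {
    stop("query genes must be contained in the universe")
  }
  annotated <- unique(unlist(collection$sets))
  coverage <- length(intersect(universe, annotated)) / length(universe)
  if (universe_mode == "annotated") {
    universe <- intersect(universe, annotated)
    query <- intersect(query, universe)
  }
  N <- length(universe)
  if (!N) stop("universe is empty after restriction to annotated genes")
  n <- length(query)

  score_sets <- function(sets, classes) {
    rows <- lapply(names(sets), function(nm) {
      members <- intersect(sets[[nm]], universe)
      ov <- intersect(query, members)
      if (!length(ov) || !length(members)) return(NULL)
      p <- set_pvalue(length(ov), n, length(members), N, method = method)
      data.frame(name = nm, class = classes[[nm]], overlap = length(ov),
                 set_size = length(members), query_size = n,
                 universe_size = N, p_value = p, adjusted_p = NA_real_,
                 genes = paste(sort(ov), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) {
      return(data.frame(name = character(0), class = character(0),
                        overlap = integer(0), set_size = integer(0),
                        query_size = integer(0), universe_size = integer(0),
                        p_value = numeric(0), adjusted_p = numeric(0),
                        genes = character(0), stringsAsFactors = FALSE))
    }
    df <- do.call(rbind, rows)
    df$adjusted_p <- bh_adjust(df$p_value)
    df <- df[order(df$p_value, df$name), , drop = FALSE]
    rownames(df) <- NULL
    df
  }

  set_df <- score_sets(collection$sets, collection$classes)
  cls <- unique(unname(collection$classes))
  class_sets <- lapply(cls, function(cl) {
    unique(unlist(collection$sets[collection$classes == cl]))
  })
  names(class_sets) <- cls
  class_labels <- cls
  names(class_labels) <- cls
  class_df <- score_sets(class_sets, class_labels)

  list(sets = set_df, classes = class_df, coverage = coverage,
       universe_size = N, query_size = n, method = method)
}
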