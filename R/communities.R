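# Clique-percolation (CPM) community detection. A k-clique community is the
# union of all k-cliques reachable from one another through "adjacent"
# k-cliques, i.e. k-cliques sharing k-1 nodes. Communities may overlap: a
# node can sit in several communities, and overlap nodes are of particular
# biological interest.

#' Maximal cliques of a network
#'
#' @param network an igraph PPI network.
#' @param min minimum clique size reported (default 2).
#' @return list of character vectors (each sorted), one per maximal clique,
#'   sorted by decreasing size then lexicographically.
#' @export
maximal_cliques <- function(network, min = 2) {
  cl <- igraph::max_cliques(network, min = min)
  out <- lapply(cl, function(x) sort(igraph::V(network)$name[as.integer(x)]))
  keys <- vapply(out, paste, "", collapse = ",")
  out[order(-lengths(out), keys)]
}

# all k-cliques, enumerated as k-subsets of maximal cliques (deduplicated);
# returns a list of sorted integer vectors of vertex indices
.k_cliques <- function(g, k) {
  maxc <- igraph::max_cliques(g, min = k)
  if (!length(maxc)) return(list())
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", 0)
  for (cl in maxc) {
    idx <- sort(as.integer(cl))
    subs <- utils::combn(idx, k, simplify = FALSE)
    for (s in subs) {
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- s
      }
    }
  }
  out
}

#' k-clique-percolation communities
#'
#' Enumerates all k-cliques and merges those sharing k-1 nodes into
#' communities (unions of the member cliques' node sets). Communities are
#' reported as lexicographically sorted node sets, ordered by decreasing
#' size then lexicographically.
#'
#' @param network an igraph PPI network.
#' @param k clique size, an integer >= 2 (default 3, the smallest size
#'   giving non-trivial overlapping modules).
#' @return object of class `community_set`: a list with elements `k`,
#'   `communities` (list of character vectors), `overlap` (named integer
#'   vector of community counts for nodes in >= 2 communities) and
#'   `covered` (character vector of all community members).
#' @export
k_clique_communities <- function(network, k = 3) {
  if (!is.numeric(k) || k < 2) stop("k must be an integer >= 2")
  k <- as.integer(k)
  cliques <- .k_cliques(network, k)
  nm <- igraph::V(network)$name
  ncl <- length(cliques)
  comms <- list()
  if (ncl) {
    # union-find over cliques; two k-cliques sharing k-1 nodes share a
    # (k-1)-subset, so hash every (k-1)-subset to its first owner
    parent <- seq_len(ncl)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    owner <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(ncl)) {
      for (drop in seq_len(k)) {
        key <- paste(cliques[[i]][-drop], collapse = ",")
        j <- owner[[key]]
        if (is.null(j)) {
          owner[[key]] <- i
        } else {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_len(ncl), find, 0L)
    groups <- split(seq_len(ncl), roots)
    comms <- lapply(groups, function(is) {
      sort(nm[sort(unique(unlist(cliques[is])))])
    })
    comms <- unname(comms[!duplicated(vapply(comms, paste, "", collapse = ","))])
    keys <- vapply(comms, paste, "", collapse = ",")
    comms <- comms[order(-lengths(comms), keys)]
  }
  members <- unlist(comms)
  counts <- table(members)
  overlap <- sort(counts[counts >= 2], decreasing = TRUE)
  overlap_v <- as.integer(overlap)
  names(overlap_v) <- names(overlap)
  structure(list(k = k,
                 communities = comms,
                 overlap = overlap_v,
                 covered = sort(unique(members))),
            class = "community_set")
}

#' @export
print.community_set <- function(x, ...) {
  cat(sprintf("k-clique community set (k = %d): %d communities covering %d nodes\n",
              x$k, length(x$communities), length(x$covered)))
  if (length(x$overlap)) {
    cat(sprintf("  %d node(s) in >= 2 communities\n", length(x$overlap)))
  }
  invisible(x)
}

#' Community-overlap report
#'
#' @param cs a `community_set` from [k_clique_communities()].
#' @return data.frame with columns `node`, `count` for nodes belonging to
#'   two or more communities, sorted by decreasing count then node symbol.
#' @export
overlap_report <- function(cs) {
  stopifnot(inherits(cs, "community_set"))
  if (!length(cs$overlap)) {
    return(data.frame(node = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(node = names(cs$overlap), count = as.integer(cs$overlap),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write communities and overlap tables to TSV
#' @param cs a `community_set`.
#' @param path output path for the community table
#'   (`community_id`, `size`, `members`).
#' @param overlap_path optional output path for the overlap table.
#' @return `path`, invisibly.
#' @export
write_communities <- function(cs, path, overlap_path = NULL) {
  df <- data.frame(
    community_id = sprintf("M%03d", seq_along(cs$communities)),
    size = lengths(cs$communities),
    members = vapply(cs$communities, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(overlap_path)) {
    utils::write.table(overlap_report(cs), overlap_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
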