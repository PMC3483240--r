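#' Canonicalize gene identifiers
#'
#' Maps raw identifiers through an optional isoform map and uppercases the
#' result, yielding one canonical symbol per gene. Canonicalization is
#' idempotent: applying it twice gives the same symbols. Identifiers absent
#' from the map pass through unchanged (a single warning reports how many).
#'
#' @param ids character vector of raw identifiers.
#' @param isoform_map named character vector (`names` = raw identifier,
#'   values = canonical symbol) or `NULL`. See [read_isoform_map()].
#' @param warn_unmapped warn when a non-`NULL` map does not cover all ids.
#' @return character vector of canonical (uppercase) gene symbols.
#' @export
canonical_gene_id <- function(ids, isoform_map = NULL, warn_unmapped = TRUE) {
  ids <- as.character(ids)
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop("gene identifiers must be non-empty")
  }
  if (any(grepl("\\s", ids))) {
    stop("gene identifiers must not contain whitespace")
  }
  if (!is.null(isoform_map) && length(isoform_map)) {
    hit <- ids %in% names(isoform_map)
    if (warn_unmapped && !all(hit)) {
      n_un <- length(unique(ids[!hit]))
      warning(sprintf("%d identifier(s) not in isoform map; passed through unchanged", n_un))
    }
    ids[hit] <- unname(isoform_map[ids[hit]])
  }
  toupper(ids)
}

#' Read an isoform-to-gene mapping table
#'
#' Two-column TSV, `raw_id <TAB> symbol`, `#` comments allowed. Mapped-to
#' symbols are uppercased so that the map is idempotent on canonical symbols.
#'
#' @param path file path.
#' @return named character vector mapping raw identifier to canonical symbol.
#' @export
read_isoform_map <- function(path) {
  if (!file.exists(path)) stop("isoform map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) stop("malformed isoform map line ", bad[1])
  map <- toupper(vapply(parts, `[[`, "", 2L))
  names(map) <- vapply(parts, `[[`, "", 1L)
  map
}

#' Parse interaction records from an edge-list or SIF file
#'
#' Edge-list files are whitespace/tab separated with columns
#' `gene_a gene_b [source]`; a header naming the first two columns
#' `gene_a`/`gene_b` is recognised and skipped. SIF lines are
#' `A <relation> B [C ...]`, producing one record per target. Lines starting
#' with `#` are skipped in both dialects.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"sif"`.
#' @param source source tag recorded per record; defaults to the file name.
#' @return data.frame with columns `a`, `b`, `source`, one row per
#'   interaction record in file order.
#' @export
parse_interactions <- function(path, format = c("edgelist", "sif"),
                               source = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("interaction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (!length(idx)) {
    warning("no interaction records in ", path)
    return(data.frame(a = character(0), b = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines[idx]), "[\t ]+")
  if (format == "edgelist") {
    first <- tolower(parts[[1]])
    if (length(first) >= 2 && first[1] == "gene_a" && first[2] == "gene_b") {
      parts <- parts[-1]
      idx <- idx[-1]
    }
    if (!length(parts)) {
      warning("no interaction records in ", path)
      return(data.frame(a = character(0), b = character(0),
                        source = character(0), stringsAsFactors = FALSE))
    }
    nf <- vapply(parts, length, 0L)
    bad <- which(nf < 2L)
    if (length(bad)) {
      stop(sprintf("malformed interaction line %d in %s: expected >= 2 columns",
                   idx[bad[1]], path))
    }
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    src <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else source, "")
    data.frame(a = a, b = b, source = src, stringsAsFactors = FALSE)
  } else {
    nf <- vapply(parts, length, 0L)
    bad <- which(nf < 3L)
    if (length(bad)) {
      stop(sprintf("malformed SIF line %d in %s: expected 'A <relation> B ...'",
                   idx[bad[1]], path))
    }
    recs <- lapply(parts, function(p) {
      data.frame(a = p[[1]], b = p[-(1:2)], source = source,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  }
}

#' Build a simple undirected PPI network from interaction records
#'
#' Identifiers are canonicalized (isoform map, then uppercase), self-loops
#' dropped, and duplicate edges (in either orientation) collapsed with their
#' source tags unioned into the `sources` edge attribute
#' (semicolon-separated). Nodes that only appeared in self-loops are retained
#' as isolated vertices.
#'
#' @param records data.frame with columns `a`, `b` and optionally `source`,
#'   as returned by [parse_interactions()].
#' @param isoform_map optional named character vector, see
#'   [read_isoform_map()].
#' @return an undirected simple [igraph::graph] with vertex attribute `name`
#'   (gene symbol) and edge attribute `sources`.
#' @export
build_network <- function(records, isoform_map = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (!is.null(isoform_map) && length(isoform_map)) {
    raw <- unique(c(records$a, records$b))
    n_un <- sum(!raw %in% names(isoform_map))
    if (n_un) {
      warning(sprintf("%d identifier(s) not in isoform map; passed through unchanged", n_un))
    }
  }
  a <- canonical_gene_id(records$a, isoform_map, warn_unmapped = FALSE)
  b <- canonical_gene_id(records$b, isoform_map, warn_unmapped = FALSE)
  src <- if (!is.null(records$source)) as.character(records$source) else
    rep("unknown", length(a))
  nodes <- sort(unique(c(a, b)))
  keep <- a != b
  a <- a[keep]; b <- b[keep]; src <- src[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  srcs <- vapply(split(src, key), function(s)
    paste(sort(unique(s)), collapse = ";"), "")
  ukey <- names(srcs)
  ends <- strsplit(ukey, "\r", fixed = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = vapply(ends, `[[`, "", 1L),
               to = vapply(ends, `[[`, "", 2L),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  igraph::E(g)$sources <- unname(srcs)
  g
}

#' Seed-list coverage of a network
#'
#' Reports how many of an externally curated seed gene list are present as
#' network nodes, mirroring the usual loss when mapping a literature-derived
#' gene set onto an interaction index.
#'
#' @param network an igraph PPI network.
#' @param seeds character vector of seed gene symbols (canonicalized
#'   internally; duplicates collapse).
#' @return list with `n_seeds`, `n_present`, `fraction` and the character
#'   vectors `present` and `missing`.
#' @export
seed_coverage <- function(network, seeds) {
  seeds <- unique(canonical_gene_id(seeds, warn_unmapped = FALSE))
  if (!length(seeds)) stop("seed set must be non-empty")
  nodes <- igraph::V(network)$name
  present <- intersect(seeds, nodes)
  list(n_seeds = length(seeds),
       n_present = length(present),
       fraction = length(present) / length(seeds),
       present = sort(present),
       missing = sort(setdiff(seeds, present)))
}

#' Export a PPI network
#'
#' Writes the network to SIF (`A pp B`, isolated nodes as single-token
#' lines), GraphML, or a headered TSV edge list with the `sources` column.
#' All three round-trip: re-importing reproduces the node and edge sets.
#'
#' @param network an igraph PPI network; must be non-empty.
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "edgelist")) {
  format <- match.arg(format)
  if (igraph::vcount(network) == 0) stop("cannot export an empty network")
  el <- igraph::as_edgelist(network)
  if (format == "sif") {
    lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2], sep = "\t") else character(0)
    iso <- igraph::V(network)$name[igraph::degree(network) == 0]
    writeLines(c(lines, iso), path)
  } else if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    src <- if ("sources" %in% igraph::edge_attr_names(network))
      igraph::E(network)$sources else rep("unknown", nrow(el))
    df <- data.frame(gene_a = el[, 1], gene_b = el[, 2], source = src,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a previously exported network
#'
#' @param path file path.
#' @param format one of `"sif"`, `"graphml"`, `"edgelist"`.
#' @return an undirected simple igraph network.
#' @export
import_network <- function(path, format = c("sif", "graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    return(igraph::simplify(g))
  }
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[\t ]+")
    nf <- vapply(parts, length, 0L)
    iso <- toupper(vapply(parts[nf == 1L], `[[`, "", 1L))
    edge_parts <- parts[nf >= 3L]
    recs <- if (length(edge_parts)) {
      do.call(rbind, lapply(edge_parts, function(p)
        data.frame(a = p[[1]], b = p[-(1:2)], source = basename(path),
                   stringsAsFactors = FALSE)))
    } else {
      data.frame(a = character(0), b = character(0), source = character(0))
    }
    g <- build_network(recs)
    add <- setdiff(iso, igraph::V(g)$name)
    if (length(add)) g <- igraph::add_vertices(g, length(add), name = add)
    return(g)
  }
  build_network(parse_interactions(path, format = "edgelist"))
}
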