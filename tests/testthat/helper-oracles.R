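# Brute-force reference implementations ("oracles") used to verify the
# package's centrality, clique-percolation and enrichment code. They work
# on plain adjacency matrices with explicit enumeration (Floyd-Warshall
# distances, recursive shortest-path listing, subset clique checks), never
# sharing code paths with the implementations they check.

# named adjacency matrix of an igraph object
o_adj <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(A) <- list(igraph::V(g)$name, igraph::V(g)$name)
  A
}

# all-pairs distances by Floyd-Warshall
o_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# list of all shortest s-t paths (vertex index sequences), by recursion
# along distance-decreasing neighbors
o_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  nbrs <- which(A[s, ] > 0 & D[, t] == D[s, t] - 1)
  out <- list()
  for (u in nbrs) {
    for (tail in o_shortest_paths(A, D, u, t)) {
      out[[length(out) + 1L]] <- c(s, tail)
    }
  }
  out
}

# betweenness and stress from explicit path enumeration over unordered pairs
o_paths_centrality <- function(g) {
  A <- o_adj(g)
  D <- o_dist(A)
  n <- nrow(A)
  btw <- stats::setNames(numeric(n), rownames(A))
  str <- stats::setNames(numeric(n), rownames(A))
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        paths <- o_shortest_paths(A, D, s, t)
        np <- length(paths)
        if (np == 0) next
        for (p in paths) {
          interior <- setdiff(p, c(s, t))
          btw[interior] <- btw[interior] + 1 / np
          str[interior] <- str[interior] + 1
        }
      }
    }
  }
  list(betweenness = btw, stress = str)
}

o_eccentricity_score <- function(g) {
  D <- o_dist(o_adj(g))
  ecc <- apply(D, 1, function(d) max(d[is.finite(d)]))
  stats::setNames(ifelse(ecc == 0, 1, 1 / ecc), rownames(D))
}

o_radiality <- function(g) {
  D <- o_dist(o_adj(g))
  n <- nrow(D)
  out <- stats::setNames(numeric(n), rownames(D))
  for (v in seq_len(n)) {
    comp <- which(is.finite(D[v, ]))
    if (length(comp) < 2) next
    delta <- max(D[comp, comp])
    others <- setdiff(comp, v)
    out[v] <- sum(delta + 1 - D[v, others]) / (length(comp) - 1)
  }
  out
}

# bottleneck: shortest-path tree per root with lexicographically-first
# parents; subtree membership determined by walking parent chains
o_bottleneck <- function(g) {
  A <- o_adj(g)
  D <- o_dist(A)
  n <- nrow(A)
  nms <- rownames(A)
  out <- stats::setNames(numeric(n), nms)
  for (s in seq_len(n)) {
    comp <- which(is.finite(D[s, ]))
    nc <- length(comp)
    if (nc < 2) next
    parent <- rep(NA_integer_, n)
    for (w in setdiff(comp, s)) {
      cand <- which(A[w, ] > 0 & D[s, ] == D[s, w] - 1)
      parent[w] <- cand[order(nms[cand])][1]
    }
    for (v in setdiff(comp, s)) {
      in_subtree <- vapply(comp, function(u) {
        while (!is.na(parent[u])) {
          if (u == v) return(TRUE)
          u <- parent[u]
        }
        u == v
      }, TRUE)
      if (sum(in_subtree) > nc / 4) out[v] <- out[v] + 1
    }
  }
  out
}

# all cliques / maximal cliques by exhaustive subset enumeration (n <= ~14)
o_all_cliques <- function(A, min_size = 1) {
  n <- nrow(A)
  out <- list()
  for (code in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < min_size) next
    if (length(members) < 2 ||
        all(A[members, members][upper.tri(diag(length(members)))] > 0)) {
      out[[length(out) + 1L]] <- members
    }
  }
  out
}

o_maximal_cliques <- function(g, min_size = 2) {
  A <- o_adj(g)
  cl <- o_all_cliques(A, min_size)
  is_max <- vapply(cl, function(c1) {
    !any(vapply(cl, function(c2)
      length(c2) > length(c1) && all(c1 %in% c2), TRUE))
  }, TRUE)
  lapply(cl[is_max], function(idx) sort(rownames(A)[idx]))
}

o_mcc <- function(g) {
  A <- o_adj(g)
  maxcl <- o_maximal_cliques(g, 2)
  out <- stats::setNames(numeric(nrow(A)), rownames(A))
  for (cl in maxcl) out[cl] <- out[cl] + factorial(length(cl) - 1)
  out
}

# largest component of each node's neighborhood, by reachability closure
o_mnc_dmnc <- function(g, epsilon = 1.7) {
  A <- o_adj(g)
  n <- nrow(A)
  mnc <- stats::setNames(numeric(n), rownames(A))
  dmnc <- stats::setNames(numeric(n), rownames(A))
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (!length(nb)) next
    S <- A[nb, nb, drop = FALSE]
    R <- S + diag(length(nb))
    for (i in seq_len(length(nb))) R <- (R %*% R > 0) * 1  # transitive closure
    seen <- rep(FALSE, length(nb))
    best_size <- 0; best_edges <- 0
    for (i in seq_len(length(nb))) {
      if (seen[i]) next
      members <- which(R[i, ] > 0)
      seen[members] <- TRUE
      sz <- length(members)
      ed <- sum(S[members, members]) / 2
      if (sz > best_size || (sz == best_size && ed > best_edges)) {
        best_size <- sz; best_edges <- ed
      }
    }
    mnc[v] <- best_size
    dmnc[v] <- if (best_size > 0) best_edges / best_size^epsilon else 0
  }
  list(mnc = mnc, dmnc = dmnc)
}

# exact EPC expectation by enumerating all edge subsets (small graphs only)
o_epc_exact <- function(g, p) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  n <- igraph::vcount(g)
  stopifnot(m <= 16)
  out <- stats::setNames(numeric(n), igraph::V(g)$name)
  for (code in seq_len(2^m) - 1L) {
    keep <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    prob <- p^length(keep) * (1 - p)^(m - length(keep))
    # component sizes by label propagation
    lab <- seq_len(n)
    repeat {
      changed <- FALSE
      for (e in keep) {
        a <- el[e, 1]; b <- el[e, 2]
        l <- min(lab[a], lab[b])
        if (lab[a] != l || lab[b] != l) {
          lab[lab == max(lab[a], lab[b])] <- l
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    sizes <- table(lab)
    out <- out + prob * as.numeric(sizes[as.character(lab)])
  }
  out
}

# clique-percolation communities by exhaustive k-subset enumeration and
# breadth-first search over the "share k-1 nodes" relation
o_cpm <- function(g, k) {
  A <- o_adj(g)
  n <- nrow(A)
  if (n < k) return(list())
  subs <- utils::combn(n, k, simplify = FALSE)
  kcl <- Filter(function(s)
    all(A[s, s][upper.tri(diag(k))] > 0), subs)
  if (!length(kcl)) return(list())
  nc <- length(kcl)
  adj <- matrix(FALSE, nc, nc)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i != j && length(intersect(kcl[[i]], kcl[[j]])) == k - 1) {
        adj[i, j] <- TRUE
      }
    }
  }
  unvisited <- rep(TRUE, nc)
  comms <- list()
  for (i in seq_len(nc)) {
    if (!unvisited[i]) next
    queue <- i; group <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!unvisited[cur]) next
      unvisited[cur] <- FALSE
      group <- c(group, cur)
      queue <- c(queue, which(adj[cur, ] & unvisited))
    }
    comms[[length(comms) + 1L]] <- sort(rownames(A)[
      sort(unique(unlist(kcl[group])))])
  }
  keys <- vapply(comms, paste, "", collapse = ",")
  comms[order(-lengths(comms), keys)]
}

# hypergeometric upper tail by explicit combinatorial summation
o_hyper_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
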