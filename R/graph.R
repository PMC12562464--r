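# Internal graph primitives on dense distance matrices. Node order is
# assumed canonical by the caller; all tie-breaks are "first index wins",
# which with canonical ordering is the lexicographic rule.

# total length of a minimum spanning tree (Prim)
mst_total <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best <- D[1L, ]
  best[1L] <- Inf
  total <- 0
  for (k in seq_len(n - 1L)) {
    j <- which.min(best)
    total <- total + best[j]
    in_tree[j] <- TRUE
    dj <- D[, j]
    lt <- dj < best
    best[lt] <- dj[lt]
    best[in_tree] <- Inf
  }
  unname(total)
}

# minimum spanning tree edge list (Kruskal, deterministic: sorted by
# (length, i, j) with i < j); returns two-column index matrix
mst_edges_kruskal <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(matrix(integer(), 0, 2))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(idx))
  got <- 0L
  for (e in seq_len(nrow(idx))) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      keep[e] <- TRUE
      got <- got + 1L
      if (got == n - 1L) break
    }
  }
  idx[keep, , drop = FALSE]
}

# connection levels (minimax path distances) via single-linkage clustering
connection_levels <- function(D) {
  n <- nrow(D)
  if (n == 2L) return(D)
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  as.matrix(stats::cophenetic(hc))
}

# epsilon-relaxed minimum spanning network: all pairs whose distance is
# within eps of the level at which they first become connected. With eps = 0
# this is the union of all minimum spanning trees.
msn_edges <- function(D, eps = 0) {
  n <- nrow(D)
  if (n < 2L) return(matrix(integer(), 0, 2))
  conn <- connection_levels(D)
  sel <- which(upper.tri(D) & D <= conn + eps + 1e-9, arr.ind = TRUE)
  sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
}
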