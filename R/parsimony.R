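#' Resolve a median-joining network into a most-parsimonious tree
#'
#' Reticulations in a median-joining network arise where alternative minimal
#' connections are equally acceptable. For the rho clock a single rooted
#' tree is needed, so the network is resolved into a spanning tree of
#' minimum total weighted length over the network's own edges — the
#' exact minimiser over all spanning-tree resolutions, found by a
#' deterministic greedy (Kruskal) pass ordered by (length, node label);
#' ties are therefore always broken lexicographically and the result is
#' invariant under permutation of the input samples. Median nodes left as
#' leaves carry no samples and are pruned. The tree is rooted at `root` and
#' every edge is annotated with its mutation (step) count.
#'
#' @param net An [mj_network] (must be connected).
#' @param root Root (founder) node: a node id, a node state label, or a
#'   sample id contained in an observed node.
#' @return Object of class `parsimony_tree`: `states`, `labels`, `parent`
#'   (index of each node's parent, `NA` at the root), `edge_steps`
#'   (mutations on the edge to the parent), `multiplicity`, `samples`,
#'   `type`, `root`, `panel`, `total_steps`, `total_length`.
#' @export
extract_parsimony_tree <- function(net, root) {
  stopifnot(inherits(net, "mj_network"))
  n <- nrow(net$nodes)
  root <- resolve_node(net, root)

  # minimum spanning tree over the network's edges, deterministic order
  eo <- order(net$edges$length,
              net$nodes$label[net$edges$from],
              net$nodes$label[net$edges$to])
  parent_uf <- seq_len(n)
  find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  keep <- integer(0)
  for (e in eo) {
    a <- find(net$edges$from[e]); b <- find(net$edges$to[e])
    if (a != b) {
      parent_uf[a] <- b
      keep <- c(keep, e)
      if (length(keep) == n - 1L) break
    }
  }
  if (length(keep) < n - 1L) stop("network is not connected")
  ef <- net$edges$from[keep]; et <- net$edges$to[keep]
  est <- net$edges$steps[keep]; elen <- net$edges$length[keep]

  # prune median leaves (they carry no samples and only lengthen the tree)
  alive <- rep(TRUE, n)
  repeat {
    deg <- tabulate(c(ef, et), nbins = n)
    drop <- which(alive & deg == 1L & net$nodes$type == "median" &
                    seq_len(n) != root)
    # root median with a single child stays: it is the inferred founder
    if (!length(drop)) break
    alive[drop] <- FALSE
    ok <- !(ef %in% drop) & !(et %in% drop)
    ef <- ef[ok]; et <- et[ok]; est <- est[ok]; elen <- elen[ok]
  }

  # orient from the root
  adj <- vector("list", n)
  for (k in seq_along(ef)) {
    adj[[ef[k]]] <- rbind(adj[[ef[k]]], c(et[k], est[k], elen[k]))
    adj[[et[k]]] <- rbind(adj[[et[k]]], c(ef[k], est[k], elen[k]))
  }
  parent <- rep(NA_integer_, n)
  p_steps <- rep(NA_real_, n)
  p_len <- rep(NA_real_, n)
  visited <- !alive
  queue <- root
  visited[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (r in seq_len(NROW(adj[[v]]))) {
      if (is.null(adj[[v]])) break
      u <- adj[[v]][r, 1]
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        p_steps[u] <- adj[[v]][r, 2]
        p_len[u] <- adj[[v]][r, 3]
        queue <- c(queue, u)
      }
    }
  }
  if (!all(visited)) stop("network is not connected")

  idx <- which(alive)
  remap <- match(seq_len(n), idx)
  structure(list(
    states = net$states[idx, , drop = FALSE],
    labels = net$nodes$label[idx],
    parent = remap[parent[idx]],
    edge_steps = p_steps[idx],
    edge_length = p_len[idx],
    multiplicity = net$nodes$multiplicity[idx],
    samples = net$nodes$samples[idx],
    type = net$nodes$type[idx],
    populations = net$nodes$populations[idx],
    root = remap[root],
    panel = net$panel,
    total_steps = sum(p_steps[idx], na.rm = TRUE),
    total_length = sum(p_len[idx], na.rm = TRUE)),
    class = "parsimony_tree")
}

resolve_node <- function(net, root) {
  if (is.numeric(root)) {
    root <- as.integer(root)
    if (root < 1L || root > nrow(net$nodes)) stop("root id out of range")
    return(root)
  }
  hit <- which(net$nodes$label == root)
  if (length(hit) == 1L) return(hit)
  hit <- which(vapply(net$nodes$samples, function(s) root %in% s, logical(1)))
  if (length(hit) == 1L) return(hit)
  stop("root not found in network: ", root)
}

#' @export
print.parsimony_tree <- function(x, ...) {
  cat(sprintf("<parsimony_tree> %d nodes, root %s, total %d mutations\n",
              length(x$labels), x$labels[x$root], as.integer(x$total_steps)))
  invisible(x)
}

# mutations on the path from the root to every node
root_path_steps <- function(tree) {
  n <- length(tree$labels)
  out <- rep(NA_real_, n)
  out[tree$root] <- 0
  # parents always appear before children if we iterate in BFS order; do a
  # simple fixed-point pass instead (n is small)
  repeat {
    todo <- which(is.na(out))
    if (!length(todo)) break
    prog <- FALSE
    for (v in todo) {
      p <- tree$parent[v]
      if (!is.na(p) && !is.na(out[p])) {
        out[v] <- out[p] + tree$edge_steps[v]
        prog <- TRUE
      }
    }
    if (!prog) stop("tree is not rooted/connected")
  }
  out
}

#' Infer a cluster's founder node
#'
#' Returns the network node minimising the multiplicity-weighted sum of
#' weighted step distances to the cluster's observed members — the centre
#' of gravity of the cluster and the reference point of both clocks. When
#' ancient anchor nodes are supplied and the best anchor comes within one
#' mutation step (one unit of weight) of the minimum, the anchor is
#' preferred: a sampled ancient chromosome close to the optimum is better
#' direct evidence of the ancestral state than an unobserved median.
#' Remaining ties go to the lexicographically smallest node label.
#'
#' @param net An [mj_network].
#' @param cluster_nodes Node ids of the cluster's observed members
#'   (default: all observed nodes).
#' @param anchors Optional node ids of ancient samples.
#' @return The founder node id.
#' @export
infer_founder <- function(net, cluster_nodes = NULL, anchors = NULL) {
  stopifnot(inherits(net, "mj_network"))
  if (is.null(cluster_nodes))
    cluster_nodes <- net$nodes$id[net$nodes$type == "observed"]
  cluster_nodes <- as.integer(cluster_nodes)
  if (!length(cluster_nodes)) stop("cluster is empty")
  w <- expand_weight(net$params, net$panel)
  D <- state_dist(net$states, w, net$states[cluster_nodes, , drop = FALSE])
  mult <- net$nodes$multiplicity[cluster_nodes]
  score <- as.numeric(D %*% mult)
  best <- min(score)
  if (!is.null(anchors) && length(anchors)) {
    anchors <- as.integer(anchors)
    step_w <- mean(w)
    a_ok <- anchors[score[anchors] <= best + step_w + 1e-9]
    if (length(a_ok)) return(a_ok[which.min(score[a_ok])])
  }
  which.min(score)  # first minimum = lexicographically smallest label
}
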