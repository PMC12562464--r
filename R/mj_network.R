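#' Build a median-joining network of Y-STR haplotypes
#'
#' Implements the median-joining heuristic for intraspecific phylogenies:
#' identical haplotypes are collapsed into nodes carrying their sample
#' multiplicity and population composition; an epsilon-relaxed minimum
#' spanning network (MSN) is built over the current states; for triplets of
#' states connected in the MSN, per-locus median (consensus) states are
#' generated and those whose insertion shortens the minimal network — within
#' the epsilon tolerance among improving candidates — are added; the cycle
#' repeats until no median improves the network, after which obsolete median
#' nodes (degree <= 1 in the final MSN, i.e. unused by any minimal
#' connection) are removed. Median generation is restricted to
#' MSN-connected triplets, the feasibility rule of the published algorithm;
#' the full quasi-median closure is deliberately not computed.
#'
#' All orderings and tie-breaks are canonical (states sorted
#' lexicographically), so the result is invariant under permutation of the
#' input samples.
#'
#' @param x A [haplotype_set], or an integer state matrix with columns =
#'   panel loci (then `panel` is required and every row has multiplicity 1).
#' @param params [mj_params]: epsilon (default 0) and per-locus weight
#'   (default 10), the published defaults for this analysis.
#' @param panel [locus_panel]; taken from `x` when `x` is a haplotype set.
#' @param max_rounds Safety cap on median-insertion rounds.
#' @return Object of class `mj_network`: `states` (node state matrix in
#'   canonical order), `nodes` (tibble: id, label, type observed/median,
#'   multiplicity, samples, populations), `edges` (tibble: from, to, steps,
#'   length, changed loci), `resolved_length` (length of a minimal spanning
#'   resolution of the final states), `panel`, `params`.
#' @export
build_mj_network <- function(x, params = mj_params(), panel = NULL,
                             max_rounds = 100L) {
  if (inherits(x, "haplotype_set")) {
    panel <- x$panel
    states0 <- x$repeats
    pops <- x$meta$population
    ids <- x$meta$sample_id
  } else {
    if (is.null(panel)) stop("panel is required when x is a state matrix")
    states0 <- as.matrix(x)
    if (is.null(colnames(states0))) colnames(states0) <- panel$loci
    storage.mode(states0) <- "integer"
    ids <- rownames(states0)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(states0)))
    pops <- rep("", nrow(states0))
  }
  states0 <- normalize_states(states0[, panel$loci, drop = FALSE], panel)
  w <- expand_weight(params, panel)
  eps <- params$epsilon

  # collapse identical states
  lab <- state_label(states0)
  first <- !duplicated(lab)
  S <- states0[first, , drop = FALSE]
  grp <- match(lab, lab[first])
  if (nrow(S) < 2L) stop("median-joining needs at least 2 distinct haplotype states")
  mult <- as.integer(tabulate(grp, nbins = nrow(S)))
  samples <- split(ids, grp)
  pops_by <- split(pops, grp)
  observed <- rep(TRUE, nrow(S))

  D <- state_dist(S, w)
  seen <- new.env(hash = TRUE)
  for (l in state_label(S)) assign(l, TRUE, envir = seen)

  for (round in seq_len(max_rounds)) {
    cand <- median_candidates(S, D, eps, seen)
    if (is.null(cand) || nrow(cand) == 0L) break
    base_len <- mst_total(D)
    Dc <- state_dist(cand, w, S)
    new_len <- vapply(seq_len(nrow(cand)), function(i) {
      mst_total(rbind(cbind(D, Dc[i, ]), c(Dc[i, ], 0)))
    }, numeric(1))
    improving <- new_len < base_len - 1e-9
    if (!any(improving)) break
    thr <- min(new_len[improving]) + eps + 1e-9
    add <- which(improving & new_len <= thr)
    for (i in add) assign(state_label(cand[i, , drop = FALSE]), TRUE, envir = seen)
    Snew <- cand[add, , drop = FALSE]
    Dnew <- Dc[add, , drop = FALSE]
    D <- rbind(cbind(D, t(Dnew)), cbind(Dnew, state_dist(Snew, w)))
    S <- rbind(S, Snew)
    observed <- c(observed, rep(FALSE, length(add)))
    mult <- c(mult, rep(0L, length(add)))
    samples <- c(samples, rep(list(character()), length(add)))
    pops_by <- c(pops_by, rep(list(character()), length(add)))
    if (round == max_rounds)
      warning("median insertion stopped at the round cap; network may be incomplete")
  }

  # obsolete-median removal: medians unused by any minimal connection
  repeat {
    em <- msn_edges(D, eps)
    deg <- tabulate(c(em[, 1], em[, 2]), nbins = nrow(S))
    drop <- which(!observed & deg <= 1L)
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(S)), drop)
    S <- S[keep, , drop = FALSE]; D <- D[keep, keep, drop = FALSE]
    observed <- observed[keep]; mult <- mult[keep]
    samples <- samples[keep]; pops_by <- pops_by[keep]
  }

  # canonical node order
  ord <- do.call(order, as.data.frame(S))
  S <- S[ord, , drop = FALSE]
  D <- D[ord, ord, drop = FALSE]
  observed <- observed[ord]; mult <- mult[ord]
  samples <- samples[ord]; pops_by <- pops_by[ord]

  em <- msn_edges(D, eps)
  steps_m <- state_steps(S)
  changed <- vapply(seq_len(nrow(em)), function(e) {
    a <- S[em[e, 1], ]; b <- S[em[e, 2], ]
    ok <- !is.na(a) & !is.na(b) & a != b
    paste(sprintf("%s:%+d", colnames(S)[ok], (b - a)[ok]), collapse = ",")
  }, character(1))
  nodes <- tibble::tibble(
    id = seq_len(nrow(S)),
    label = state_label(S),
    type = ifelse(observed, "observed", "median"),
    multiplicity = mult,
    samples = samples,
    populations = lapply(pops_by, function(p) table(p[nzchar(p)])))
  edges <- tibble::tibble(
    from = em[, 1], to = em[, 2],
    steps = steps_m[em],
    length = D[em],
    changed = changed)
  structure(list(states = S, nodes = nodes, edges = edges,
                 panel = panel, params = params,
                 resolved_length = mst_total(D),
                 total_length = sum(edges$length)),
            class = "mj_network")
}

# median states of MSN-connected triplets (centre node + two neighbours)
median_candidates <- function(S, D, eps, seen) {
  em <- msn_edges(D, eps)
  if (nrow(em) == 0L) return(NULL)
  nbr <- vector("list", nrow(S))
  for (e in seq_len(nrow(em))) {
    nbr[[em[e, 1]]] <- c(nbr[[em[e, 1]]], em[e, 2])
    nbr[[em[e, 2]]] <- c(nbr[[em[e, 2]]], em[e, 1])
  }
  trips <- lapply(seq_len(nrow(S)), function(c0) {
    nb <- nbr[[c0]]
    if (length(nb) < 2L) return(NULL)
    prs <- utils::combn(sort(nb), 2L)
    cbind(c0, prs[1, ], prs[2, ])
  })
  trips <- do.call(rbind, trips)
  if (is.null(trips) || nrow(trips) == 0L) return(NULL)
  A <- S[trips[, 1], , drop = FALSE]
  B <- S[trips[, 2], , drop = FALSE]
  C <- S[trips[, 3], , drop = FALSE]
  # median of three = sum - min - max; with missing values fall back to the
  # smaller of two, the single value, or NA
  med <- A + B + C - pmin(A, B, C) - pmax(A, B, C)
  if (anyNA(med)) {
    two <- pmin(A, B, C, na.rm = TRUE)  # lower of the non-missing values
    nna <- (!is.na(A)) + (!is.na(B)) + (!is.na(C))
    med[is.na(med) & nna > 0L] <- two[is.na(med) & nna > 0L]
  }
  storage.mode(med) <- "integer"
  cand <- med[!duplicated(state_label(med)), , drop = FALSE]
  colnames(cand) <- colnames(S)
  labs <- state_label(cand)
  new <- !vapply(labs, exists, logical(1), envir = seen, inherits = FALSE,
                 USE.NAMES = FALSE)
  cand[new, , drop = FALSE]
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("<mj_network> %d nodes (%d observed, %d median), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "observed"),
              sum(x$nodes$type == "median"), nrow(x$edges)))
  cat(sprintf("  resolved length %.1f (weight %s, epsilon %g)\n",
              x$resolved_length, paste(unique(x$params$weight), collapse = "/"),
              x$params$epsilon))
  invisible(x)
}

#' Export a network as plain tables or DOT
#'
#' `network_tables()` flattens an [mj_network] into a node table and an
#' edge table suitable for TSV export; `write_network()` writes them to
#' `<prefix>_nodes.tsv` / `<prefix>_edges.tsv`; `write_dot()` writes a
#' Graphviz DOT file.
#'
#' @param net An [mj_network].
#' @return `network_tables()`: list of two tibbles.
#' @export
network_tables <- function(net) {
  pops <- vapply(net$nodes$populations, function(tb) {
    if (!length(tb)) "" else paste(sprintf("%s:%d", names(tb), tb), collapse = ",")
  }, character(1))
  list(
    nodes = tibble::tibble(
      id = net$nodes$id, label = net$nodes$label, type = net$nodes$type,
      multiplicity = net$nodes$multiplicity,
      samples = vapply(net$nodes$samples, paste, character(1), collapse = ","),
      populations = pops),
    edges = tibble::tibble(
      from = net$nodes$label[net$edges$from],
      to = net$nodes$label[net$edges$to],
      steps = net$edges$steps, length = net$edges$length,
      changed = net$edges$changed))
}

#' @rdname network_tables
#' @param prefix Output path prefix.
#' @export
write_network <- function(net, prefix) {
  tb <- network_tables(net)
  utils::write.table(tb$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tb$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname network_tables
#' @param path Output DOT file path.
#' @export
write_dot <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph mjn {", con)
  for (i in net$nodes$id) {
    shape <- if (net$nodes$type[i] == "observed") "circle" else "point"
    writeLines(sprintf('  n%d [label="%s" shape=%s];', i,
                       if (shape == "circle") sprintf("%d", net$nodes$multiplicity[i]) else "",
                       shape), con)
  }
  for (e in seq_len(nrow(net$edges)))
    writeLines(sprintf('  n%d -- n%d [label="%d"];',
                       net$edges$from[e], net$edges$to[e], net$edges$steps[e]), con)
  writeLines("}", con)
  invisible(path)
}
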