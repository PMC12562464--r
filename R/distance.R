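#' Median-joining network parameters
#'
#' @param epsilon Non-negative relaxation parameter: how much longer than the
#'   minimal connection an edge (or a median insertion) may be and still be
#'   retained. `0` keeps only minimal connections.
#' @param weight Positive per-locus weight multiplying step counts in all
#'   distances; a single value (default 10, applied uniformly) or a vector
#'   named by panel marker.
#' @return Object of class `mj_params`.
#' @export
mj_params <- function(epsilon = 0, weight = 10) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0)
    stop("epsilon must be a single non-negative number")
  if (any(is.na(weight)) || any(weight <= 0))
    stop("all weights must be positive")
  structure(list(epsilon = as.numeric(epsilon), weight = weight),
            class = "mj_params")
}

# per expanded locus weight vector
expand_weight <- function(params, panel) {
  w <- params$weight
  if (length(w) == 1L)
    return(stats::setNames(rep(as.numeric(w), panel$L), panel$loci))
  if (is.null(names(w))) stop("a weight vector must be named by marker")
  cols <- column_of_locus(panel$loci, panel$columns, panel$multicopy)
  if (!all(cols %in% names(w))) stop("weights must cover every panel marker")
  stats::setNames(as.numeric(w[cols]), panel$loci)
}

# sort multicopy pairs so that 1-D min-cost assignment = aligned difference
normalize_states <- function(states, panel) {
  for (m in panel$multicopy) {
    ab <- paste0(m, c("a", "b"))
    a <- states[, ab[1]]; b <- states[, ab[2]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    swap <- !is.na(a) & !is.na(b)
    states[swap, ab[1]] <- lo[swap]
    states[swap, ab[2]] <- hi[swap]
  }
  states
}

#' Weighted single-step distance between two Y-STR haplotypes
#'
#' The step metric of the median-joining algorithm: the weighted sum of
#' absolute repeat-count differences over the loci typed in both
#' haplotypes. Multi-copy markers are compared by the minimum-cost
#' assignment between their two repeat multisets, which for an absolute
#' difference cost equals the sorted (copy-aligned) comparison. Loci missing
#' in either haplotype are skipped; it is an error if no locus is shared.
#'
#' @param a,b Integer repeat vectors named by (expanded) panel locus, or
#'   single-row matrices.
#' @param panel A [locus_panel].
#' @param params [mj_params] supplying the per-locus weights.
#' @return Weighted step count (0 iff the states agree on every compared
#'   locus; symmetric in `a` and `b`).
#' @export
str_distance <- function(a, b, panel = default_panel(), params = mj_params()) {
  a <- as_state(a, panel); b <- as_state(b, panel)
  w <- expand_weight(params, panel)
  st <- matrix(c(a, b), 2, panel$L, byrow = TRUE,
               dimnames = list(NULL, panel$loci))
  st <- normalize_states(st, panel)
  ok <- !is.na(st[1, ]) & !is.na(st[2, ])
  if (!any(ok)) stop("haplotypes share no typed locus")
  sum(w[ok] * abs(st[1, ok] - st[2, ok]))
}

as_state <- function(x, panel) {
  x <- drop(as.matrix(x))
  if (!is.null(names(x))) {
    if (all(panel$loci %in% names(x))) return(as.integer(x[panel$loci]))
    stop("state vector names do not cover the panel loci")
  }
  if (length(x) != panel$L) stop("state vector length does not match panel")
  as.integer(x)
}

# weighted L1 distance matrix between rows of two state matrices
# (missing loci skipped pairwise, no rescaling: graph distances)
state_dist <- function(states, w, states2 = NULL) {
  A <- states
  B <- if (is.null(states2)) states else states2
  n <- nrow(A); m <- nrow(B)
  D <- matrix(0, n, m)
  for (l in seq_len(ncol(A))) {
    d <- abs(outer(A[, l], B[, l], "-")) * w[l]
    d[is.na(d)] <- 0
    D <- D + d
  }
  D
}

# unweighted step count matrix (mutations)
state_steps <- function(states, states2 = NULL) {
  state_dist(states, rep(1, ncol(states)), states2)
}

state_label <- function(states) {
  do.call(paste, c(as.data.frame(states), sep = "."))
}
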