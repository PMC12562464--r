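#' Molecular-clock parameters
#'
#' @param panel [locus_panel] carrying the per-locus mutation rates
#'   (default: the 37-locus panel at a uniform 0.0039 mutations/locus/
#'   generation).
#' @param generation_years Calendar years per generation (default 31.5).
#' @return Object of class `clock_params`.
#' @export
clock_params <- function(panel = default_panel(), generation_years = 31.5) {
  stopifnot(inherits(panel, "locus_panel"))
  if (generation_years <= 0) stop("generation interval must be positive")
  structure(list(panel = panel, generation_years = generation_years),
            class = "clock_params")
}

tmrca_estimate <- function(method, t_gen, gen_years, se_years, n, rho = NA_real_) {
  structure(list(method = method,
                 t_generations = t_gen,
                 t_years = t_gen * gen_years,
                 se_years = se_years,
                 n = n, rho = rho),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("<tmrca %s> %.0f +/- %.0f YBP (%.1f generations, n = %d)\n",
              x$method, x$t_years, x$se_years, x$t_generations, x$n))
  invisible(x)
}

#' ASD clock: TMRCA from the average squared distance to the founder
#'
#' Under the symmetric single-step mutation model the expected squared
#' repeat-count difference between a descendant and the founder after t
#' generations is exactly mu * t per locus, so
#' `ASD = mean over loci of mean over members of (repeat - founder)^2`
#' divided by the mean per-locus rate is an unbiased estimate of t. Loci
#' untyped in the founder or in a member are skipped and the locus average
#' runs over the compared loci only. The standard error is obtained by a
#' seeded bootstrap over loci, which captures locus-to-locus variance in
#' accumulated mutations. The `pairwise` reference instead halves the mean
#' pairwise ASD between members, for comparison with founder-free dating.
#'
#' @param members A [haplotype_set] (the cluster's members) or an integer
#'   state matrix with columns = panel loci.
#' @param founder Founder haplotype state (named integer vector); required
#'   unless `reference = "pairwise"`.
#' @param clock [clock_params].
#' @param n_boot Bootstrap resamples for the SE (default 1000).
#' @param seed Seed for the bootstrap (recorded in the estimate).
#' @param reference `"founder"` (default) or `"pairwise"`.
#' @return A `tmrca_estimate` with method `"ASD"`.
#' @export
asd_tmrca <- function(members, founder = NULL, clock = clock_params(),
                      n_boot = 1000L, seed = 1L,
                      reference = c("founder", "pairwise")) {
  reference <- match.arg(reference)
  panel <- clock$panel
  M <- if (inherits(members, "haplotype_set")) members$repeats else as.matrix(members)
  M <- normalize_states(M[, panel$loci, drop = FALSE], panel)
  if (nrow(M) == 0L) stop("no cluster members")
  if (reference == "founder") {
    if (is.null(founder)) stop("founder state is required")
    f <- as_state(founder, panel)
    f <- drop(normalize_states(matrix(f, 1, dimnames = list(NULL, panel$loci)), panel))
    used <- which(!is.na(f) & colSums(!is.na(M)) > 0L)
    if (!length(used)) stop("founder is missing at all compared loci")
    sq <- sweep(M[, used, drop = FALSE], 2L, f[used], "-")^2
    per_locus <- colMeans(sq, na.rm = TRUE)
  } else {
    used <- which(colSums(!is.na(M)) > 0L)
    per_locus <- vapply(used, function(l) {
      v <- M[!is.na(M[, l]), l]
      if (length(v) < 2L) return(0)
      mean(as.numeric(stats::dist(v))^2) / 2
    }, numeric(1))
  }
  mu <- panel$mu[used]
  t_gen <- mean(per_locus) / mean(mu)
  # bootstrap over loci
  Lc <- length(used)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(Lc, Lc, replace = TRUE)
    mean(per_locus[idx]) / mean(mu[idx])
  }, numeric(1))
  est <- tmrca_estimate("ASD", t_gen, clock$generation_years,
                        stats::sd(boot) * clock$generation_years, nrow(M))
  est$bootstrap_seed <- as.integer(seed)
  est$n_boot <- as.integer(n_boot)
  est$reference <- reference
  est
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Rho clock: TMRCA from the mean mutational distance to the root
#'
#' The rho statistic is the multiplicity-weighted mean number of mutations
#' on the tree path from the root (founder) to each sampled haplotype.
#' Divided by the total per-haplotype mutation rate `L * mean(mu)` it gives
#' the age in generations. The standard error follows the genealogy-based
#' estimator computed on the resolved tree:
#' `sigma_rho^2 = (1/n^2) * sum over branches of m_b * n_b^2`, with `m_b`
#' the mutations on branch b and `n_b` the samples below it.
#'
#' Because the statistic counts *net* repeat changes on a most-parsimonious
#' tree, back- and parallel mutations are invisible to it; for old clusters
#' this makes rho systematically younger than the ASD clock (which is exact
#' under the model). Both are reported so the divergence is visible.
#'
#' @param tree A [extract_parsimony_tree()] result rooted at the founder.
#' @param clock [clock_params].
#' @return A `tmrca_estimate` with method `"rho"` and the `rho` value filled.
#' @export
rho_tmrca <- function(tree, clock = clock_params()) {
  if (!inherits(tree, "parsimony_tree") || is.na(tree$root))
    stop("rho requires a tree rooted at the founder")
  steps <- root_path_steps(tree)
  mult <- tree$multiplicity
  n <- sum(mult)
  if (n == 0L) stop("tree has no sampled haplotypes")
  rho <- sum(mult * steps) / n
  # samples below each branch (branch = edge from node v to its parent)
  depth <- steps_depth(tree)
  sub <- as.numeric(mult)
  for (v in order(depth, decreasing = TRUE)) {
    p <- tree$parent[v]
    if (!is.na(p)) sub[p] <- sub[p] + sub[v]
  }
  nonroot <- which(!is.na(tree$parent))
  sigma2 <- sum(tree$edge_steps[nonroot] * sub[nonroot]^2) / n^2
  rate <- clock$panel$L * mean(clock$panel$mu)
  est <- tmrca_estimate("rho", rho / rate, clock$generation_years,
                        sqrt(sigma2) / rate * clock$generation_years,
                        as.integer(n), rho = rho)
  est$sigma_rho <- sqrt(sigma2)
  est
}

# topological depth (edge count from root)
steps_depth <- function(tree) {
  n <- length(tree$labels)
  d <- rep(NA_integer_, n)
  d[tree$root] <- 0L
  repeat {
    todo <- which(is.na(d))
    if (!length(todo)) break
    for (v in todo) {
      p <- tree$parent[v]
      if (!is.na(p) && !is.na(d[p])) d[v] <- d[p] + 1L
    }
  }
  d
}

#' Date a haplotype cluster with both clocks
#'
#' Convenience wrapper running the full dating workflow for one cluster:
#' build a median-joining network of the member haplotypes (plus the
#' founder state, when supplied), infer the founder node if not given
#' (preferring ancient members as anchors), resolve the network into a
#' most-parsimonious tree rooted at the founder, and return both the ASD
#' and the rho estimate.
#'
#' @param members [haplotype_set] of cluster members.
#' @param founder Optional founder state (named integer vector). When
#'   `NULL` the founder node is inferred from the network.
#' @param clock [clock_params].
#' @param params [mj_params].
#' @param n_boot,seed Bootstrap control for the ASD standard error.
#' @return List with elements `asd`, `rho` (both `tmrca_estimate`),
#'   `founder_state`, `network`, `tree`.
#' @export
date_cluster <- function(members, founder = NULL, clock = clock_params(),
                         params = mj_params(), n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(members, "haplotype_set"))
  panel <- clock$panel
  M <- normalize_states(members$repeats[, panel$loci, drop = FALSE], panel)
  n <- nrow(M)

  pseudo <- "\r__founder__"
  states <- M
  ids <- members$meta$sample_id
  pops <- members$meta$population
  if (!is.null(founder)) {
    f <- as_state(founder, panel)
    states <- rbind(states, f)
    ids <- c(ids, pseudo)
    pops <- c(pops, "")
  }
  labs <- state_label(normalize_states(states, panel))
  if (length(unique(labs)) < 2L) {
    # degenerate cluster: every member (and founder) shares one state
    f <- if (is.null(founder)) M[1, ] else as_state(founder, panel)
    asd <- asd_tmrca(M, f, clock, n_boot = n_boot, seed = seed)
    rho <- tmrca_estimate("rho", 0, clock$generation_years, 0, n, rho = 0)
    return(list(asd = asd, rho = rho, founder_state = f,
                network = NULL, tree = NULL))
  }

  anc <- members$meta$ancient
  if (!is.null(founder)) anc <- c(anc, FALSE)
  hs2 <- haplotype_set(states,
                       tibble::tibble(sample_id = ids, population = pops,
                                      ancient = anc),
                       panel)
  net <- build_mj_network(hs2, params)
  # the founder pseudo-sample must not count as a sampled haplotype
  if (!is.null(founder)) {
    fi <- which(vapply(net$nodes$samples, function(s) pseudo %in% s, logical(1)))
    net$nodes$multiplicity[fi] <- net$nodes$multiplicity[fi] - 1L
    net$nodes$samples[[fi]] <- setdiff(net$nodes$samples[[fi]], pseudo)
    if (net$nodes$multiplicity[fi] == 0L) net$nodes$type[fi] <- "median"
    root <- fi
  } else {
    anchors <- which(vapply(net$nodes$samples, function(s)
      any(members$meta$ancient[match(s, members$meta$sample_id)]), logical(1)))
    obs <- net$nodes$id[net$nodes$type == "observed"]
    root <- infer_founder(net, obs, anchors = if (length(anchors)) anchors)
  }
  f_state <- net$states[root, ]
  tree <- extract_parsimony_tree(net, root)
  asd <- asd_tmrca(M, f_state, clock, n_boot = n_boot, seed = seed)
  rho <- rho_tmrca(tree, clock)
  list(asd = asd, rho = rho, founder_state = f_state,
       network = net, tree = tree)
}
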