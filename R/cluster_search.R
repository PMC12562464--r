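#' Partition a haplotype set by Y-SNP search branch
#'
#' Splits a haplotype set into disjoint, exhaustive groups by the first
#' component of each sample's `snp_branch` label. Labels may be
#' hierarchical, `"<search branch>><terminal branch>"` (e.g.
#' `"CTS1211(xY35)>B07"`); the part before the first `>` names the search
#' group a separate phylogenetic network is built for, the full label names
#' the terminal cluster. The exclusion syntax `"A(xB)"` reads: derived at
#' A, ancestral at B. Samples with an empty `snp_branch` are collected into
#' an `"unassigned"` group with a warning.
#'
#' @param hs A [haplotype_set].
#' @return Named list of [haplotype_set]s, one per search branch.
#' @export
partition_by_snp <- function(hs) {
  stopifnot(inherits(hs, "haplotype_set"))
  lab <- search_branch(hs$meta$snp_branch)
  if (any(lab == "unassigned"))
    warning(sum(lab == "unassigned"),
            " sample(s) with empty snp_branch collected into 'unassigned'")
  idx <- split(seq_len(n_haplotypes(hs)), lab)
  lapply(idx, function(i) subset_haplotypes(hs, i))
}

search_branch <- function(snp_branch) {
  lab <- vapply(strsplit(snp_branch, ">", fixed = TRUE),
                function(p) if (length(p)) p[[1]] else "", character(1))
  ifelse(nzchar(trimws(lab)), trimws(lab), "unassigned")
}

#' Delimit haplotype clusters within a search group
#'
#' Two delimitation modes. `"snp"` (default): a cluster is the set of
#' samples sharing a terminal `snp_branch` label — the validated approach,
#' since identified Y-STR clusters correspond well to Y-SNP branches.
#' `"subtree"`: for data without fine SNP typing, the group's
#' median-joining network is resolved into a parsimony tree and cut into
#' maximal subtrees: median chains (inferred nodes carrying no samples) are
#' contracted, and any observed-to-observed tree path longer than
#' `cut_steps` mutation steps is severed; the resulting components are the
#' clusters. This label-free mode is this package's own addition; it
#' recovers planted clusters when founders are separated by clearly more
#' than `cut_steps` steps and within-cluster diversity stays below the
#' separation.
#'
#' @param hs_group A [haplotype_set] (one search group).
#' @param mode `"snp"` or `"subtree"`.
#' @param net Optional prebuilt [mj_network] for `"subtree"` mode.
#' @param params [mj_params] used if a network must be built.
#' @param cut_steps Subtree mode: sever observed-to-observed tree paths
#'   longer than this many steps (default 3).
#' @return List of cluster objects (class `str_cluster`): `label`,
#'   `sample_ids`, `populations`, `ages` (`NULL` until dated),
#'   `informative` (`NA` until screened).
#' @export
delimit_clusters <- function(hs_group, mode = c("snp", "subtree"),
                             net = NULL, params = mj_params(),
                             cut_steps = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(hs_group, "haplotype_set"))
  if (mode == "snp") {
    lab <- trimws(hs_group$meta$snp_branch)
    lab[!nzchar(lab)] <- "unassigned"
    idx <- split(seq_len(n_haplotypes(hs_group)), lab)
  } else {
    if (is.null(net)) net <- build_mj_network(hs_group, params)
    root <- infer_founder(net)
    tree <- extract_parsimony_tree(net, root)
    comp <- tree_cut_assignment(tree, cut_steps)
    node_of <- rep(NA_integer_, n_haplotypes(hs_group))
    for (v in seq_along(tree$samples)) {
      m <- match(tree$samples[[v]], hs_group$meta$sample_id)
      node_of[m[!is.na(m)]] <- v
    }
    idx <- split(seq_len(n_haplotypes(hs_group)), comp[node_of])
    names(idx) <- sprintf("subtree_%02d", seq_along(idx))
  }
  lapply(names(idx), function(lb) {
    i <- idx[[lb]]
    new_cluster(lb, hs_group$meta$sample_id[i], hs_group$meta$population[i])
  })
}

# component labels after contracting median chains and cutting long paths:
# two observed nodes stay together iff the tree path between them that runs
# only through median (sample-free) nodes totals at most cut_steps mutations
tree_cut_assignment <- function(tree, cut_steps) {
  n <- length(tree$labels)
  adj <- vector("list", n)
  for (v in seq_len(n)) {
    p <- tree$parent[v]
    if (!is.na(p)) {
      adj[[v]] <- rbind(adj[[v]], c(p, tree$edge_steps[v]))
      adj[[p]] <- rbind(adj[[p]], c(v, tree$edge_steps[v]))
    }
  }
  observed <- tree$multiplicity > 0L
  parent_uf <- seq_len(n)
  find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  for (v in which(observed)) {
    visited <- logical(n)
    visited[v] <- TRUE
    frontier <- cbind(adj[[v]][, 1], adj[[v]][, 2])
    while (NROW(frontier)) {
      u <- as.integer(frontier[1, 1]); d <- frontier[1, 2]
      frontier <- frontier[-1, , drop = FALSE]
      if (visited[u] || d > cut_steps) next
      visited[u] <- TRUE
      if (observed[u]) {
        parent_uf[find(v)] <- find(u)  # path through medians only
      } else if (d < cut_steps && !is.null(adj[[u]])) {
        frontier <- rbind(frontier,
                          cbind(adj[[u]][, 1], d + adj[[u]][, 2]))
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
  match(comp, unique(comp[observed]))
}

new_cluster <- function(label, sample_ids, populations) {
  structure(list(label = label, sample_ids = sample_ids,
                 populations = populations, founder = NULL,
                 ages = NULL, informative = NA, reason = ""),
            class = "str_cluster")
}

#' @export
print.str_cluster <- function(x, ...) {
  cat(sprintf("<cluster %s> n = %d", x$label, length(x$sample_ids)))
  if (!is.null(x$ages))
    cat(sprintf(", ASD %.0f, rho %.0f YBP",
                x$ages$asd$t_years, x$ages$rho$t_years))
  if (!is.na(x$informative))
    cat(sprintf(", %s", if (x$informative) "informative" else
      paste0("non-informative (", x$reason, ")")))
  cat("\n")
  invisible(x)
}

#' Screening criteria for informative clusters
#'
#' An informative cluster must (1) contain members of every required
#' population group and (2) predate a colonisation horizon. The default
#' horizon of 1000 years before present operationalises "before the Slavic
#' colonization (before the 10th century)".
#'
#' @param groups Named list mapping each required group label to the
#'   population labels it comprises, e.g.
#'   `list(Slavic = "Ryazan-Russian", Finnic = c("Erzya", "Moksha", "Shoksha"))`.
#'   At least two groups are required.
#' @param min_age_ybp Age threshold in years before present (default 1000).
#' @return Object of class `filter_criteria`.
#' @export
filter_criteria <- function(groups, min_age_ybp = 1000) {
  if (length(groups) < 2L || is.null(names(groups)))
    stop("at least two named population groups are required")
  if (min_age_ybp <= 0) stop("min_age_ybp must be positive")
  structure(list(groups = groups, min_age_ybp = as.numeric(min_age_ybp)),
            class = "filter_criteria")
}

group_of <- function(populations, criteria) {
  out <- rep(NA_character_, length(populations))
  for (g in names(criteria$groups))
    out[populations %in% criteria$groups[[g]]] <- g
  out
}

#' Flag informative clusters
#'
#' Applies the two-criterion screen to dated clusters: a cluster is
#' informative iff every required population group contributes at least one
#' member AND the minimum of the two clocks' point ages exceeds the age
#' threshold (both clocks must predate the horizon — the conservative
#' reading). Clusters failing a criterion get a reason string
#' (`"single-group"`, `"too young"`, or both). Lowering the age threshold
#' or dropping a required group can only enlarge the informative set.
#'
#' @param clusters List of dated `str_cluster` objects.
#' @param criteria A [filter_criteria].
#' @return The cluster list with `informative` and `reason` set.
#' @export
filter_informative <- function(clusters, criteria) {
  stopifnot(inherits(criteria, "filter_criteria"))
  lapply(clusters, function(cl) {
    if (is.null(cl$ages))
      stop("cluster ", cl$label, " has no TMRCA estimates; date it first")
    grp <- group_of(cl$populations, criteria)
    have <- vapply(names(criteria$groups), function(g) any(grp %in% g), logical(1))
    age <- min(cl$ages$asd$t_years, cl$ages$rho$t_years)
    reasons <- character()
    if (!all(have)) reasons <- c(reasons, "single-group")
    if (!(age > criteria$min_age_ybp)) reasons <- c(reasons, "too young")
    cl$informative <- length(reasons) == 0L
    cl$reason <- if (cl$informative) "ok" else paste(reasons, collapse = "+")
    cl
  })
}

#' Round a count to a printed percentage
#'
#' @param k,n Numerator and denominator.
#' @param digits Decimal places (default 0, the printed convention).
#' @return `100 * k / n` rounded; `NA` when `n == 0`.
#' @export
prop_pct <- function(k, n, digits = 0) {
  ifelse(n == 0, NA_real_, round(100 * k / n, digits))
}

#' Per-group membership summary of informative clusters
#'
#' For each population group: how many of its haplogroup carriers fall in
#' informative clusters, out of how many carriers in the analysed set, as a
#' percentage — and, when per-group haplogroup frequencies are supplied,
#' the population-level share, i.e. the in-cluster share among carriers
#' multiplied by the haplogroup frequency of the group.
#'
#' @param clusters Screened cluster list ([filter_informative()] output).
#' @param hs The full [haplotype_set] the clusters were drawn from.
#' @param criteria [filter_criteria] defining the groups.
#' @param haplogroup_freq Optional named numeric: haplogroup frequency (%)
#'   per group, to derive the population-level share.
#' @return Tibble: group, n_informative, n_total, pct (1 d.p.),
#'   pct_printed (0 d.p.), and population_share_pct when frequencies given.
#' @export
membership_summary <- function(clusters, hs, criteria, haplogroup_freq = NULL) {
  inf_ids <- unlist(lapply(clusters, function(cl)
    if (isTRUE(cl$informative)) cl$sample_ids else character()))
  grp <- group_of(hs$meta$population, criteria)
  out <- lapply(names(criteria$groups), function(g) {
    tot <- sum(grp %in% g, na.rm = TRUE)
    k <- sum(hs$meta$sample_id[grp %in% g] %in% inf_ids)
    tibble::tibble(group = g, n_informative = k, n_total = tot,
                   pct = prop_pct(k, tot, 1),
                   pct_printed = prop_pct(k, tot, 0))
  })
  out <- do.call(rbind, out)
  if (!is.null(haplogroup_freq)) {
    f <- haplogroup_freq[out$group]
    out$haplogroup_freq_pct <- as.numeric(f)
    out$population_share_pct <- round(out$pct * as.numeric(f) / 100, 1)
  }
  out
}

#' Flat table of screened clusters
#'
#' @param clusters Dated (and optionally screened) cluster list.
#' @param criteria Optional [filter_criteria] to add per-group counts.
#' @return Tibble, one row per cluster: branch, n, per-group counts, both
#'   ages with standard errors (years BP, rounded to 10 as printed),
#'   informative flag and reason.
#' @export
cluster_table <- function(clusters, criteria = NULL) {
  rows <- lapply(clusters, function(cl) {
    r <- tibble::tibble(branch = cl$label, n = length(cl$sample_ids))
    if (!is.null(criteria)) {
      grp <- group_of(cl$populations, criteria)
      for (g in names(criteria$groups))
        r[[paste0("n_", g)]] <- sum(grp %in% g, na.rm = TRUE)
    }
    if (!is.null(cl$ages)) {
      r$asd_ybp <- round(cl$ages$asd$t_years / 10) * 10
      r$asd_se <- round(cl$ages$asd$se_years / 10) * 10
      r$rho_ybp <- round(cl$ages$rho$t_years / 10) * 10
      r$rho_se <- round(cl$ages$rho$se_years / 10) * 10
    }
    r$informative <- cl$informative
    r$reason <- cl$reason
    r
  })
  do.call(rbind, rows)
}
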