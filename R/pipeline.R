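#' Run the full substrate-screening pipeline
#'
#' Executes the complete workflow on a haplotype set: partition into Y-SNP
#' search groups, delimit clusters within each group, infer each cluster's
#' founder, resolve its network into a parsimony tree, date it with both
#' clocks, apply the two-criterion informative-cluster screen, and
#' summarise per-group membership. Deterministic under a fixed seed and
#' configuration: reruns produce byte-identical cluster tables.
#'
#' @param hs A [haplotype_set]; must validate with zero errors.
#' @param criteria A [filter_criteria].
#' @param params [mj_params] for all network construction.
#' @param clock [clock_params].
#' @param seed Integer seed for the ASD bootstrap (each cluster's bootstrap
#'   seed is derived deterministically from it).
#' @param delimit_mode `"snp"` (default) or `"subtree"`, see
#'   [delimit_clusters()].
#' @param group_networks Build and retain the per-search-group
#'   median-joining networks (needed for `"subtree"` delimitation and for
#'   network export; the cluster-level dating always builds its own
#'   networks). Default `FALSE`.
#' @param haplogroup_freq Optional named per-group haplogroup frequencies
#'   (%) for the population-level share, see [membership_summary()].
#' @param n_boot ASD bootstrap resamples.
#' @param out_dir Optional output directory; when given, writes
#'   `clusters.tsv`, `summary.tsv`, `params.yaml` (the fully serialised
#'   configuration) and, with `group_networks = TRUE`,
#'   `network_<branch>_{nodes,edges}.tsv`.
#' @return Object of class `strclock_run`: `clusters` (screened cluster
#'   list), `cluster_table`, `summary`, `groups` (per-branch sizes),
#'   `networks` (if built), `config`.
#' @export
run_pipeline <- function(hs, criteria, params = mj_params(),
                         clock = clock_params(panel = hs$panel),
                         seed = 1L, delimit_mode = c("snp", "subtree"),
                         group_networks = FALSE, haplogroup_freq = NULL,
                         n_boot = 200L, out_dir = NULL) {
  delimit_mode <- match.arg(delimit_mode)
  stopifnot(inherits(hs, "haplotype_set"), inherits(criteria, "filter_criteria"))
  val <- validate_haplotypes(hs)
  if (val$n_errors > 0)
    stop("[validate] haplotype set has ", val$n_errors,
         " error(s); fix them before running the pipeline")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  groups <- stage("partition", partition_by_snp(hs))
  networks <- list()
  clusters <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    net <- NULL
    if (group_networks || delimit_mode == "subtree")
      net <- stage(paste0("network:", gname),
                   build_mj_network(g, params))
    if (group_networks) networks[[gname]] <- net
    cls <- stage(paste0("delimit:", gname),
                 delimit_clusters(g, mode = delimit_mode, net = net,
                                  params = params))
    for (cl in cls) {
      members <- subset_haplotypes(hs, cl$sample_ids)
      cl_seed <- (as.integer(seed) + 7919L * (length(clusters) + 1L)) %% 2147483647L
      dated <- stage(paste0("date:", cl$label),
                     date_cluster(members, clock = clock, params = params,
                                  n_boot = n_boot, seed = cl_seed))
      cl$ages <- dated[c("asd", "rho")]
      cl$founder <- dated$founder_state
      clusters[[length(clusters) + 1L]] <- cl
    }
  }
  ord <- order(vapply(clusters, function(cl) cl$label, character(1)))
  clusters <- clusters[ord]
  clusters <- stage("filter", filter_informative(clusters, criteria))
  tab <- cluster_table(clusters, criteria)
  summ <- stage("summary",
                membership_summary(clusters, hs, criteria, haplogroup_freq))
  config <- list(seed = as.integer(seed), delimit_mode = delimit_mode,
                 epsilon = params$epsilon, weight = params$weight,
                 generation_years = clock$generation_years,
                 mean_mu = mean(clock$panel$mu), L = clock$panel$L,
                 min_age_ybp = criteria$min_age_ybp,
                 groups = criteria$groups, n_boot = as.integer(n_boot),
                 n_samples = n_haplotypes(hs))
  run <- structure(list(clusters = clusters, cluster_table = tab,
                        summary = summ,
                        groups = vapply(groups, n_haplotypes, integer(1)),
                        networks = networks, config = config),
                   class = "strclock_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "params.yaml"))
    for (gname in names(networks))
      write_network(networks[[gname]],
                    file.path(out_dir, paste0("network_", gsub("[^A-Za-z0-9]", "_", gname))))
  }
  run
}

#' @export
print.strclock_run <- function(x, ...) {
  n_inf <- sum(vapply(x$clusters, function(cl) isTRUE(cl$informative), logical(1)))
  cat(sprintf("<strclock_run> %d samples, %d search group(s), %d cluster(s), %d informative\n",
              x$config$n_samples, length(x$groups), length(x$clusters), n_inf))
  print(x$summary)
  invisible(x)
}

#' Date every terminal SNP branch of a haplotype table
#'
#' Reads a haplotype table, groups samples by terminal `snp_branch` label
#' and dates each group with both clocks from its inferred founder —
#' producing a branch/n/ASD/rho age table in the shape used to report
#' cluster ages. Intended for re-dating published haplotype appendices.
#'
#' @param path Haplotype table (see [read_haplotypes()]).
#' @param panel [locus_panel].
#' @param clock [clock_params].
#' @param params [mj_params].
#' @param min_n Smallest branch worth dating (default 2).
#' @param seed Bootstrap seed.
#' @return Tibble: branch, n, asd_ybp, asd_se, rho_ybp, rho_se.
#' @export
branch_age_table <- function(path, panel = default_panel(),
                             clock = clock_params(panel = panel),
                             params = mj_params(), min_n = 2L, seed = 1L) {
  hs <- read_haplotypes(path, panel)
  lab <- trimws(hs$meta$snp_branch)
  lab[!nzchar(lab)] <- "unassigned"
  idx <- split(seq_len(n_haplotypes(hs)), lab)
  idx <- idx[vapply(idx, length, integer(1)) >= min_n]
  rows <- lapply(names(idx), function(lb) {
    d <- date_cluster(subset_haplotypes(hs, idx[[lb]]), clock = clock,
                      params = params, seed = seed)
    tibble::tibble(branch = lb, n = length(idx[[lb]]),
                   asd_ybp = round(d$asd$t_years / 10) * 10,
                   asd_se = round(d$asd$se_years / 10) * 10,
                   rho_ybp = round(d$rho$t_years / 10) * 10,
                   rho_se = round(d$rho$se_years / 10) * 10)
  })
  do.call(rbind, rows)
}
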