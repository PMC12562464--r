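#' Simulation configuration
#'
#' Study conditions for the stepwise-mutation-model (SMM) generator: each
#' locus mutates by +1 or -1 repeat with equal probability, at its panel
#' rate, on a star or coalescent genealogy. By default the number of
#' mutations per lineage and locus is drawn Poisson(mu * t) with a signed
#' random walk of steps — equivalent to per-generation simulation for
#' mu * t << 1 and much faster; the exact per-generation mode is kept
#' behind `mode = "generation"`.
#'
#' @param n Number of sampled lineages (>= 2).
#' @param T_years True TMRCA in years (star genealogy).
#' @param Ne Male effective population size in individuals (coalescent
#'   genealogy; time unit 2\*Ne generations, so E\[TMRCA\] = 2\*Ne
#'   generations at n = 2).
#' @param genealogy `"star"` or `"coalescent"`.
#' @param panel [locus_panel] (default: the 37-locus panel).
#' @param founder Founder state (default: a fixed reference haplotype).
#' @param generation_years Years per generation (default 31.5).
#' @param seed Integer seed; recorded in the output provenance.
#' @param mode `"poisson"` (default) or `"generation"`.
#' @param population Population label given to the simulated samples.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n, T_years = NULL, Ne = NULL,
                       genealogy = c("star", "coalescent"),
                       panel = default_panel(), founder = NULL,
                       generation_years = 31.5, seed = 1L,
                       mode = c("poisson", "generation"),
                       population = "SimPop") {
  genealogy <- match.arg(genealogy)
  mode <- match.arg(mode)
  if (n < 2L) stop("n must be at least 2")
  if (genealogy == "star") {
    if (is.null(T_years) || T_years < 0) stop("star genealogy needs T_years >= 0")
  } else if (is.null(Ne) || Ne <= 0) stop("coalescent genealogy needs Ne > 0")
  if (is.null(founder)) founder <- default_founder(panel)
  structure(list(n = as.integer(n), T_years = T_years, Ne = Ne,
                 genealogy = genealogy, panel = panel,
                 founder = as_state(founder, panel),
                 generation_years = generation_years,
                 seed = as.integer(seed), mode = mode,
                 population = population),
            class = "sim_config")
}

#' Fixed reference founder haplotype for a panel
#'
#' A deterministic, plausibly-sized repeat state (values cycling through
#' 11-25) used as the default simulation founder; far enough from zero
#' that SMM walks never leave the positive range at realistic time depths.
#'
#' @param panel A [locus_panel].
#' @export
default_founder <- function(panel) {
  v <- rep(c(14L, 13L, 16L, 23L, 11L, 17L, 25L, 12L, 19L, 15L),
           length.out = panel$L)
  names(v) <- panel$loci
  drop(normalize_states(matrix(v, 1, dimnames = list(NULL, panel$loci)), panel))
}

# net SMM displacement for each (lineage, locus) over t generations
smm_steps <- function(n, panel, t_gen, mode) {
  L <- panel$L
  if (mode == "poisson") {
    k <- stats::rpois(n * L, rep(panel$mu, each = n) * t_gen)
    net <- 2L * stats::rbinom(n * L, k, 0.5) - k
  } else {
    net <- integer(n * L)
    mu <- rep(panel$mu, each = n)
    for (g in seq_len(round(t_gen))) {
      hit <- stats::rbinom(n * L, 1L, mu)
      net <- net + hit * (2L * stats::rbinom(n * L, 1L, 0.5) - 1L)
    }
  }
  matrix(as.integer(net), n, L, dimnames = list(NULL, panel$loci))
}

#' Simulate haplotypes on a star genealogy
#'
#' Each of n lineages descends independently from the founder for
#' `round(T_years / generation_years)` generations under the symmetric
#' single-step SMM. The scenario under which both clocks are calibrated:
#' the expected per-locus squared displacement after t generations is
#' exactly mu * t.
#'
#' @param cfg A [sim_config] with `genealogy = "star"`.
#' @return List: `haplotypes` (a [haplotype_set]) and `truth` (founder
#'   state, true TMRCA in years and generations, seed).
#' @export
simulate_star <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$genealogy != "star") stop("cfg$genealogy must be 'star'")
  if (cfg$T_years < 0) stop("T_years must be non-negative")
  set.seed(cfg$seed)
  g <- round(cfg$T_years / cfg$generation_years)
  net <- smm_steps(cfg$n, cfg$panel, g, cfg$mode)
  reps <- sweep(net, 2L, cfg$founder, "+")
  reps <- normalize_states(reps, cfg$panel)
  meta <- tibble::tibble(sample_id = sprintf("S%04d", seq_len(cfg$n)),
                         population = cfg$population)
  hs <- haplotype_set(reps, meta, cfg$panel,
                      provenance = sprintf("simulate_star seed=%d", cfg$seed))
  list(haplotypes = hs,
       truth = list(founder = cfg$founder, T_years = cfg$T_years,
                    generations = g, seed = cfg$seed))
}

#' Simulate haplotypes on a Kingman coalescent genealogy
#'
#' Draws a neutral coalescent tree on n tips (exponential waiting times at
#' rate k(k-1)/2 in units of 2*Ne generations), then drops SMM mutations on
#' every branch as a Poisson process at the panel rates. Used as the
#' robustness check for star-assumption bias: coalescent genealogies share
#' internal branches, so cluster members are correlated.
#'
#' @param cfg A [sim_config] with `genealogy = "coalescent"`.
#' @return List: `haplotypes`, `tree` (an `ape::phylo` with branch lengths
#'   in generations), `truth` (founder, true TMRCA in generations/years,
#'   total branch length, mutation count, seed).
#' @export
simulate_coalescent <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$genealogy != "coalescent") stop("cfg$genealogy must be 'coalescent'")
  if (cfg$n < 2L) stop("n must be at least 2")
  set.seed(cfg$seed)
  tree <- ape::rcoal(cfg$n, tip.label = sprintf("S%04d", seq_len(cfg$n)))
  tree$edge.length <- tree$edge.length * 2 * cfg$Ne  # generations
  L <- cfg$panel$L
  n_edge <- nrow(tree$edge)
  k <- stats::rpois(n_edge * L,
                    rep(cfg$panel$mu, each = n_edge) * tree$edge.length)
  net <- matrix(2L * stats::rbinom(n_edge * L, k, 0.5) - k, n_edge, L)
  # accumulate states from the root down
  n_node <- cfg$n + tree$Nnode
  states <- matrix(NA_integer_, n_node, L)
  root <- cfg$n + 1L
  states[root, ] <- cfg$founder
  for (e in order(tree$edge[, 1])) {  # parents precede children in rcoal
    states[tree$edge[e, 2], ] <- states[tree$edge[e, 1], ] + net[e, ]
  }
  reps <- states[seq_len(cfg$n), , drop = FALSE]
  colnames(reps) <- cfg$panel$loci
  reps <- normalize_states(reps, cfg$panel)
  meta <- tibble::tibble(sample_id = tree$tip.label, population = cfg$population)
  hs <- haplotype_set(reps, meta, cfg$panel,
                      provenance = sprintf("simulate_coalescent seed=%d", cfg$seed))
  depths <- ape::node.depth.edgelength(tree)
  list(haplotypes = hs, tree = tree,
       truth = list(founder = cfg$founder,
                    tmrca_generations = max(depths),
                    tmrca_years = max(depths) * cfg$generation_years,
                    total_branch_generations = sum(tree$edge.length),
                    n_mutations = sum(abs(k)), seed = cfg$seed))
}

#' Simulate a full two-population regional scenario with known truth
#'
#' Emulates the structure of a regional Y-chromosome survey: ~400
#' haplotypes in one Slavic-labelled population (Ryazan-Russian) and three
#' Finnic-labelled populations (Erzya, Moksha, Shoksha), organised into
#' \itemize{
#'   \item `n_informative` old mixed-population clusters (true TMRCA drawn
#'     from `age_range_ybp`, default 1600-2900 y) — the planted pre-Slavic
#'     substrate lineages a correct screen must flag;
#'   \item `n_decoy_young` young mixed clusters (default ages 300-600 y) —
#'     must be rejected as too recent;
#'   \item `n_decoy_old` old single-population clusters — must be rejected
#'     as single-group.
#' }
#' Every cluster descends from its own founder haplotype (pairwise
#' separation at least `min_founder_sep` steps; an error if founders cannot
#' be placed) by star-genealogy SMM evolution, carries a hierarchical
#' `snp_branch` label `"<search branch>><cluster>"` over five search
#' branches, and is recorded in the returned truth tables.
#'
#' @param n_informative,n_decoy_young,n_decoy_old Cluster counts (at least
#'   one informative and one decoy in total).
#' @param age_range_ybp True TMRCA range of old clusters (years).
#' @param young_age_range_ybp True TMRCA range of young decoys.
#' @param informative_size,decoy_size Cluster size ranges (samples).
#' @param slavic_frac Probability a mixed-cluster member is Russian.
#' @param min_founder_sep Minimum founder separation in mutation steps.
#' @param panel [locus_panel].
#' @param generation_years Years per generation.
#' @param seed Integer seed.
#' @return List: `haplotypes` (a [haplotype_set]) and `truth` (list with
#'   `clusters` and `samples` tibbles, plus the generator settings).
#' @export
simulate_region_scenario <- function(n_informative = 10L,
                                     n_decoy_young = 2L,
                                     n_decoy_old = 2L,
                                     age_range_ybp = c(1600, 2900),
                                     young_age_range_ybp = c(300, 600),
                                     informative_size = c(10L, 45L),
                                     decoy_size = c(20L, 35L),
                                     slavic_frac = 0.45,
                                     min_founder_sep = 8L,
                                     panel = default_panel(),
                                     generation_years = 31.5,
                                     seed = 1L) {
  if (n_informative < 1L) stop("at least one informative cluster is required")
  if (n_decoy_young + n_decoy_old < 1L) stop("at least one decoy cluster is required")
  set.seed(as.integer(seed))
  slavic_pop <- "Ryazan-Russian"
  finnic_pops <- c("Erzya", "Moksha", "Shoksha")
  finnic_w <- c(0.5, 0.35, 0.15)
  ryazan_districts <- c("Kadomsky", "Kasimovsky", "Mikhaylovsky", "Sapozhkovsky",
                        "Saraevsky", "Shilovsky", "Spassky")
  mordovia_districts <- c("Ardatovsky", "Chamzinsky", "Ichalkovsky", "Insarsky",
                          "Krasnoslobodsky", "Ruzaevsky", "Tengushevsky",
                          "Torbeyevsky")
  search_branches <- c("Y3910", "Y33(xY1390)", "Y35(xY33)", "CTS1211(xY35)", "Z92")

  k <- n_informative + n_decoy_young + n_decoy_old
  type <- c(rep("informative", n_informative),
            rep("young_mixed", n_decoy_young),
            rep("old_single", n_decoy_old))
  ages <- numeric(k)
  old <- type != "young_mixed"
  ages[old] <- stats::runif(sum(old), age_range_ybp[1], age_range_ybp[2])
  ages[!old] <- stats::runif(sum(!old), young_age_range_ybp[1], young_age_range_ybp[2])
  sizes <- integer(k)
  sizes[type == "informative"] <-
    sample(informative_size[1]:informative_size[2], n_informative, replace = TRUE)
  sizes[type != "informative"] <-
    sample(decoy_size[1]:decoy_size[2], k - n_informative, replace = TRUE)

  founders <- place_founders(k, panel, min_founder_sep)
  branch <- sample(rep_len(search_branches, k))
  label <- sprintf("%s>B%02d", branch, seq_len(k))

  pops <- vector("list", k)
  for (i in seq_len(k)) {
    if (type[i] == "old_single") {
      pops[[i]] <- rep(sample(c(slavic_pop, finnic_pops[1:2]), 1L), sizes[i])
    } else {
      p <- ifelse(stats::runif(sizes[i]) < slavic_frac, slavic_pop,
                  sample(finnic_pops, sizes[i], replace = TRUE, prob = finnic_w))
      p[1] <- slavic_pop                       # guarantee the mix
      p[2] <- sample(finnic_pops, 1L, prob = finnic_w)
      pops[[i]] <- p
    }
  }

  reps <- vector("list", k)
  for (i in seq_len(k)) {
    g <- round(ages[i] / generation_years)
    net <- smm_steps(sizes[i], panel, g, "poisson")
    reps[[i]] <- normalize_states(sweep(net, 2L, founders[i, ], "+"), panel)
  }

  n_tot <- sum(sizes)
  all_pops <- unlist(pops)
  meta <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n_tot)),
    population = all_pops,
    district = ifelse(all_pops == slavic_pop,
                      sample(ryazan_districts, n_tot, replace = TRUE),
                      sample(mordovia_districts, n_tot, replace = TRUE)),
    ancient = FALSE, ancient_date = "",
    snp_branch = rep(label, sizes))
  hs <- haplotype_set(do.call(rbind, reps), meta, panel,
                      provenance = sprintf("simulate_region_scenario seed=%d", seed))
  truth <- list(
    clusters = tibble::tibble(
      label = label, type = type, informative = type == "informative",
      age_ybp = ages, n = sizes, search_branch = branch,
      founder = lapply(seq_len(k), function(i) founders[i, ])),
    samples = tibble::tibble(sample_id = meta$sample_id,
                             cluster = rep(label, sizes)),
    settings = list(seed = as.integer(seed), min_founder_sep = min_founder_sep,
                    generation_years = generation_years,
                    slavic_frac = slavic_frac))
  list(haplotypes = hs, truth = truth)
}

# draw k founder states pairwise >= min_sep mutation steps apart
place_founders <- function(k, panel, min_sep, max_try = 500L) {
  base <- default_founder(panel)
  out <- matrix(NA_integer_, k, panel$L, dimnames = list(NULL, panel$loci))
  n_pert <- min_sep + 4L
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      loci <- sample.int(panel$L, n_pert, replace = TRUE)
      steps <- tabulate(loci, panel$L) * sample(c(-1L, 1L), panel$L, replace = TRUE)
      cand <- pmax(base + steps, 1L)
      if (i == 1L || all(rowSums(abs(sweep(out[seq_len(i - 1L), , drop = FALSE],
                                           2L, cand, "-"))) >= min_sep)) {
        out[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", k, " cluster founders at separation >= ",
           min_sep, " on this panel")
  }
  normalize_states(out, panel)
}

#' Write scenario truth to a YAML file
#'
#' @param truth The `truth` element of [simulate_region_scenario()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  cl <- truth$clusters
  yaml::write_yaml(list(
    settings = truth$settings,
    clusters = lapply(seq_len(nrow(cl)), function(i) list(
      label = cl$label[i], type = cl$type[i],
      informative = cl$informative[i],
      age_ybp = round(cl$age_ybp[i], 1), n = cl$n[i],
      founder = as.integer(cl$founder[[i]]))),
    samples = stats::setNames(as.list(truth$samples$cluster),
                              truth$samples$sample_id)), path)
  invisible(path)
}
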