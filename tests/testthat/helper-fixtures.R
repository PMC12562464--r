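# shared fixtures, built in code

tiny_panel <- function(k = 3, mu = 0.0039, multicopy = character()) {
  locus_panel(sprintf("L%02d", seq_len(k)), mu = mu, multicopy = multicopy)
}

# haplotype set from a plain state matrix
make_hs <- function(states, panel, pops = NULL, ids = NULL, snp = NULL,
                    ancient = NULL) {
  states <- as.matrix(states)
  colnames(states) <- panel$loci
  n <- nrow(states)
  meta <- tibble::tibble(
    sample_id = if (is.null(ids)) sprintf("S%03d", seq_len(n)) else ids,
    population = if (is.null(pops)) "Pop" else pops,
    snp_branch = if (is.null(snp)) "" else snp,
    ancient = if (is.null(ancient)) FALSE else ancient)
  haplotype_set(states, meta, panel)
}

rand_states <- function(n, L, lo = 10L, hi = 20L) {
  matrix(sample(lo:hi, n * L, replace = TRUE), n, L)
}

# greedy best-matching membership agreement between two labelings
membership_agreement <- function(truth, pred) {
  tab <- table(truth, pred)
  matched <- 0
  while (length(tab) && nrow(tab) && ncol(tab)) {
    i <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    matched <- matched + tab[i[1], i[2]]
    tab <- tab[-i[1], -i[2], drop = FALSE]
  }
  matched / length(truth)
}

# standard screening criteria for the regional scenario
scenario_criteria <- function(min_age_ybp = 1000) {
  filter_criteria(list(Slavic = "Ryazan-Russian",
                       Finnic = c("Erzya", "Moksha", "Shoksha")),
                  min_age_ybp = min_age_ybp)
}

# fabricate a dated cluster for screen-level tests
fake_cluster <- function(label, pops, asd_ybp, rho_ybp = asd_ybp) {
  cl <- strclock:::new_cluster(label, sprintf("%s_%03d", label, seq_along(pops)), pops)
  cl$ages <- list(asd = list(t_years = asd_ybp), rho = list(t_years = rho_ybp))
  cl
}
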