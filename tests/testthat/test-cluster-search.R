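test_that("partition by search branch splits and bins correctly", {
  p <- tiny_panel(2)
  hs <- make_hs(rand_states(5, 2), p,
                snp = c("Z92", "Z92", "Z92", "CTS1211(xY35)", "CTS1211(xY35)"))
  gr <- partition_by_snp(hs)
  expect_setequal(names(gr), c("Z92", "CTS1211(xY35)"))
  expect_equal(n_haplotypes(gr$Z92), 3)
  expect_equal(n_haplotypes(gr$`CTS1211(xY35)`), 2)

  # one label -> identity partition
  hs1 <- make_hs(rand_states(4, 2), p, snp = "Y3910")
  gr1 <- partition_by_snp(hs1)
  expect_equal(names(gr1), "Y3910")
  expect_equal(n_haplotypes(gr1$Y3910), 4)

  # hierarchical labels partition on the search component
  hs2 <- make_hs(rand_states(3, 2), p,
                 snp = c("Z92>B01", "Z92>B02", "Y3910>B03"))
  gr2 <- partition_by_snp(hs2)
  expect_setequal(names(gr2), c("Z92", "Y3910"))

  # empty labels are binned with a warning
  hs3 <- make_hs(rand_states(3, 2), p, snp = c("Z92", "", "Z92"))
  expect_warning(gr3 <- partition_by_snp(hs3), "unassigned")
  expect_equal(n_haplotypes(gr3$unassigned), 1)
})

test_that("scenario partition matches the generator's bookkeeping", {
  sc <- simulate_region_scenario(seed = 14)
  gr <- partition_by_snp(sc$haplotypes)
  truth_sizes <- tapply(sc$truth$clusters$n, sc$truth$clusters$search_branch, sum)
  expect_setequal(names(gr), names(truth_sizes))
  for (b in names(gr))
    expect_equal(n_haplotypes(gr[[b]]), unname(truth_sizes[b]))
})

test_that("snp-mode delimitation follows terminal labels", {
  p <- tiny_panel(2)
  hs <- make_hs(rand_states(5, 2), p,
                snp = c("Z92>B01", "Z92>B01", "Z92>B02", "Z92>B02", "Z92>B02"))
  cls <- delimit_clusters(hs, mode = "snp")
  expect_equal(length(cls), 2)
  expect_setequal(vapply(cls, function(cl) length(cl$sample_ids), integer(1)),
                  c(2L, 3L))
  # single label -> one cluster with everything
  hs1 <- make_hs(rand_states(4, 2), p, snp = "Z92>B01")
  cls1 <- delimit_clusters(hs1)
  expect_equal(length(cls1), 1)
  expect_equal(length(cls1[[1]]$sample_ids), 4)
})

test_that("subtree-mode delimitation recovers planted clusters from the network alone", {
  # 3 planted star clusters + 1 young decoy, founders >= 6 steps apart and
  # within-cluster diversity well below the separation; SNP labels hidden
  accs <- vapply(1:20, function(s) {
    sc <- simulate_region_scenario(
      n_informative = 3, n_decoy_young = 1, n_decoy_old = 0,
      age_range_ybp = c(150, 350), young_age_range_ybp = c(150, 250),
      informative_size = c(8L, 12L), decoy_size = c(8L, 12L),
      min_founder_sep = 6L, seed = s)
    hs <- sc$haplotypes
    hs$meta$snp_branch <- "ALL"
    cls <- delimit_clusters(hs, mode = "subtree")
    pred <- rep(NA_character_, n_haplotypes(hs))
    for (cl in cls) pred[match(cl$sample_ids, hs$meta$sample_id)] <- cl$label
    membership_agreement(sc$truth$samples$cluster, pred)
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})

test_that("the two-criterion screen matches the stated examples", {
  crit <- scenario_criteria()
  cls <- list(
    fake_cluster("mix_old", c("Ryazan-Russian", "Erzya", "Moksha"), 1500),
    fake_cluster("rus_old", rep("Ryazan-Russian", 4), 2000),
    fake_cluster("mix_young", c("Ryazan-Russian", "Erzya"), 800),
    fake_cluster("rus_young", rep("Ryazan-Russian", 3), 700))
  out <- filter_informative(cls, crit)
  expect_true(out[[1]]$informative)
  expect_false(out[[2]]$informative); expect_equal(out[[2]]$reason, "single-group")
  expect_false(out[[3]]$informative); expect_equal(out[[3]]$reason, "too young")
  expect_equal(out[[4]]$reason, "single-group+too young")

  # the conservative rule: BOTH clocks must predate the horizon
  border <- fake_cluster("mix", c("Ryazan-Russian", "Erzya"), 1500, rho_ybp = 900)
  expect_false(filter_informative(list(border), crit)[[1]]$informative)

  undated <- strclock:::new_cluster("x", "s1", "Erzya")
  expect_error(filter_informative(list(undated), crit), "no TMRCA")
})

test_that("the screen is monotone in its criteria", {
  set.seed(55)
  crit_hi <- scenario_criteria(min_age_ybp = 1500)
  crit_lo <- scenario_criteria(min_age_ybp = 800)
  for (i in 1:30) {
    pops <- sample(c("Ryazan-Russian", "Erzya", "Moksha", "Shoksha"),
                   sample(2:8, 1), replace = TRUE)
    cl <- fake_cluster("c", pops, runif(1, 300, 3000), runif(1, 300, 3000))
    hi <- filter_informative(list(cl), crit_hi)[[1]]$informative
    lo <- filter_informative(list(cl), crit_lo)[[1]]$informative
    if (hi) expect_true(lo)     # lowering the threshold never drops a cluster
    # dropping a required group never drops a cluster either
    one <- filter_criteria(list(Any = c("Ryazan-Russian", "Erzya", "Moksha",
                                        "Shoksha"), Extra = "nobody"),
                           min_age_ybp = 800)
    # (two groups minimum; 'Extra' unmatchable makes everything single-group)
    ex <- filter_informative(list(cl), one)[[1]]$informative
    if (ex) expect_true(lo)
  }
})

test_that("membership arithmetic reproduces the printed percentages", {
  p <- tiny_panel(2)
  crit <- scenario_criteria()
  # 154 Russian carriers, 74 of them inside informative clusters
  pops <- rep(c("Ryazan-Russian", "Erzya"), c(154, 93))
  hs <- make_hs(rand_states(247, 2), p, pops = pops)
  in_ids <- c(hs$meta$sample_id[1:74],                     # 74 of 154 Russians
              hs$meta$sample_id[155:247])                  # all 93 Finnic
  cl <- strclock:::new_cluster("B01", in_ids,
                               hs$meta$population[match(in_ids, hs$meta$sample_id)])
  cl$ages <- list(asd = list(t_years = 2000), rho = list(t_years = 1800))
  out <- filter_informative(list(cl), crit)
  s <- membership_summary(out, hs, crit,
                          haplogroup_freq = c(Slavic = 56.4, Finnic = 44.1))
  slav <- s[s$group == "Slavic", ]
  expect_equal(slav$n_informative, 74L)
  expect_equal(slav$n_total, 154L)
  expect_equal(slav$pct, 48.1)
  expect_equal(slav$pct_printed, 48)
  # 48.05% of carriers x 56.4% haplogroup frequency -> 27.1% of the population
  expect_equal(slav$population_share_pct, 27.1)

  # zero membership and empty groups
  cl0 <- strclock:::new_cluster("B02", character(), character())
  cl0$ages <- list(asd = list(t_years = 2000), rho = list(t_years = 2000))
  cl0$informative <- FALSE; cl0$reason <- "single-group"
  s0 <- membership_summary(list(cl0), hs, crit)
  expect_equal(s0$pct_printed[s0$group == "Slavic"], 0)
  hs_no_f <- make_hs(rand_states(3, 2), p, pops = "Ryazan-Russian")
  s1 <- membership_summary(list(cl0), hs_no_f, crit)
  expect_true(is.na(s1$pct[s1$group == "Finnic"]))
})
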