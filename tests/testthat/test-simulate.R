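test_that("star simulation honours T = 0, determinism and preconditions", {
  cfg <- sim_config(n = 6, T_years = 0, seed = 4)
  sim <- simulate_star(cfg)
  expect_true(all(apply(sim$haplotypes$repeats, 1,
                        function(r) all(r == cfg$founder))))
  s1 <- simulate_star(sim_config(n = 10, T_years = 2000, seed = 11))
  s2 <- simulate_star(sim_config(n = 10, T_years = 2000, seed = 11))
  expect_identical(s1$haplotypes$repeats, s2$haplotypes$repeats)
  s3 <- simulate_star(sim_config(n = 10, T_years = 2000, seed = 12))
  expect_false(identical(s1$haplotypes$repeats, s3$haplotypes$repeats))
  expect_error(sim_config(n = 1, T_years = 100), "at least 2")
  expect_error(sim_config(n = 5, T_years = -10), "T_years")
})

test_that("per-locus displacement has mean 0 and variance mu*t", {
  # the identity underwriting the ASD clock: at T = 2000 y (63 generations),
  # E[(X - founder)^2] = 0.0039 * 63 = 0.2457 per locus
  reps <- 200
  m1 <- m2 <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_star(sim_config(n = 25, T_years = 2000, seed = 20000 + r))
    d <- sweep(sim$haplotypes$repeats, 2, sim$truth$founder, "-")
    m1[r] <- mean(d)
    m2[r] <- mean(d^2)
  }
  mu_t <- 0.0039 * round(2000 / 31.5)
  expect_lt(abs(mean(m2) - mu_t), 3 * sd(m2) / sqrt(reps))
  expect_lt(abs(mean(m1)), 3 * sd(m1) / sqrt(reps))
})

test_that("the exact per-generation mode agrees with the Poisson shortcut", {
  p <- tiny_panel(10, mu = 0.02)   # inflated rate so the test sees mutations
  reps <- 80
  v_pois <- v_gen <- numeric(reps)
  for (r in seq_len(reps)) {
    cp <- sim_config(n = 10, T_years = 630, seed = 300 + r, panel = p)
    cg <- sim_config(n = 10, T_years = 630, seed = 300 + r, panel = p,
                     mode = "generation")
    v_pois[r] <- mean(sweep(simulate_star(cp)$haplotypes$repeats, 2, cp$founder)^2)
    v_gen[r] <- mean(sweep(simulate_star(cg)$haplotypes$repeats, 2, cg$founder)^2)
  }
  # both must estimate mu*g = 0.02 * 20 = 0.4 (binomial vs Poisson counts)
  expect_equal(mean(v_pois), 0.4, tolerance = 0.1)
  expect_equal(mean(v_gen), 0.4, tolerance = 0.1)
})

test_that("coalescent TMRCA matches theory at n = 2 and is reproducible", {
  p <- tiny_panel(2)
  t2 <- vapply(1:2000, function(s)
    simulate_coalescent(sim_config(n = 2, Ne = 500, genealogy = "coalescent",
                                   seed = s, panel = p))$truth$tmrca_generations,
    numeric(1))
  # E[TMRCA] = 2 * Ne generations under the haploid 2Ne-unit convention
  expect_equal(mean(t2), 1000, tolerance = 0.05)
  c1 <- simulate_coalescent(sim_config(n = 5, Ne = 300, genealogy = "coalescent",
                                       seed = 9, panel = p))
  c2 <- simulate_coalescent(sim_config(n = 5, Ne = 300, genealogy = "coalescent",
                                       seed = 9, panel = p))
  expect_identical(c1$haplotypes$repeats, c2$haplotypes$repeats)
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(c2$tree))
})

test_that("mutation counts on the coalescent tree are Poisson-thinned", {
  # conditional on each tree, the total mutation count is Poisson with mean
  # L * mu * (total branch length); compare the pooled distribution of
  # counts against the exact Poisson mixture over the simulated trees
  p <- tiny_panel(4, mu = 0.0039)
  reps <- 1000
  counts <- lam <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_coalescent(sim_config(n = 2, Ne = 200,
                                          genealogy = "coalescent",
                                          seed = 40000 + r, panel = p))
    counts[r] <- sim$truth$n_mutations
    lam[r] <- 4 * 0.0039 * sim$truth$total_branch_generations
  }
  kmax <- max(counts)
  expected <- vapply(0:kmax, function(k) sum(stats::dpois(k, lam)), numeric(1))
  expected[kmax + 1] <- expected[kmax + 1] + sum(1 - stats::ppois(kmax, lam))
  observed <- tabulate(counts + 1L, nbins = kmax + 1L)
  keep <- expected >= 5
  other_o <- sum(observed[!keep]); other_e <- sum(expected[!keep])
  o <- c(observed[keep], other_o); e <- c(expected[keep], other_e)
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1
  expect_gt(stats::pchisq(stat, df, lower.tail = FALSE), 0.01)
})

test_that("the regional scenario has the documented structure and is consistent", {
  sc <- simulate_region_scenario(seed = 31)
  cl <- sc$truth$clusters
  expect_equal(sum(cl$type == "informative"), 10)
  expect_equal(sum(cl$type != "informative"), 4)
  expect_equal(n_haplotypes(sc$haplotypes), sum(cl$n))
  expect_gt(n_haplotypes(sc$haplotypes), 300)  # ~400 samples
  expect_lt(n_haplotypes(sc$haplotypes), 550)
  pops <- unique(sc$haplotypes$meta$population)
  expect_setequal(intersect(pops, "Ryazan-Russian"), "Ryazan-Russian")
  expect_true(all(setdiff(pops, "Ryazan-Russian") %in%
                    c("Erzya", "Moksha", "Shoksha")))
  # truth and table are mutually consistent
  expect_setequal(sc$truth$samples$sample_id, sc$haplotypes$meta$sample_id)
  expect_identical(sc$truth$samples$cluster, sc$haplotypes$meta$snp_branch)
  # informative clusters predate the horizon, young decoys do not
  expect_true(all(cl$age_ybp[cl$type == "informative"] >= 1600))
  expect_true(all(cl$age_ybp[cl$type == "young_mixed"] <= 600))
  # founders are separated and each sample lies nearest its own founder on average
  F <- do.call(rbind, cl$founder)
  DF <- as.matrix(dist(F, method = "manhattan"))
  expect_gte(min(DF[upper.tri(DF)]), 8)
  idx <- match(sc$truth$samples$cluster, cl$label)
  d_own <- rowSums(abs(sc$haplotypes$repeats - F[idx, ]))
  expect_lt(mean(d_own), mean(DF[upper.tri(DF)]) / 2)
  # mixed clusters really are mixed
  for (i in which(cl$type != "old_single")) {
    members <- sc$truth$samples$sample_id[sc$truth$samples$cluster == cl$label[i]]
    pp <- sc$haplotypes$meta$population[match(members, sc$haplotypes$meta$sample_id)]
    expect_true("Ryazan-Russian" %in% pp && any(pp != "Ryazan-Russian"))
  }
  for (i in which(cl$type == "old_single")) {
    members <- sc$truth$samples$sample_id[sc$truth$samples$cluster == cl$label[i]]
    pp <- sc$haplotypes$meta$population[match(members, sc$haplotypes$meta$sample_id)]
    expect_equal(length(unique(pp)), 1)
  }
})

test_that("scenario preconditions and infeasible founder placement error out", {
  expect_error(simulate_region_scenario(n_informative = 0), "informative")
  expect_error(simulate_region_scenario(n_decoy_young = 0, n_decoy_old = 0),
               "decoy")
  # a 1-locus panel offers only two states at a fixed perturbation size:
  # a third founder can never reach the required separation
  p1 <- locus_panel("A", mu = 0.0039)
  expect_error(simulate_region_scenario(n_informative = 2, n_decoy_young = 1,
                                        n_decoy_old = 0, panel = p1,
                                        min_founder_sep = 10L, seed = 2),
               "could not place")
})

test_that("scenario truth serialises to YAML", {
  sc <- simulate_region_scenario(n_informative = 2, n_decoy_young = 1,
                                 n_decoy_old = 1, seed = 8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_truth(sc$truth, f)
  y <- yaml::read_yaml(f)
  expect_equal(length(y$clusters), 4)
  expect_equal(y$settings$seed, 8)
})
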