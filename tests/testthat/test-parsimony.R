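# exhaustive spanning-tree oracle: minimum total length over all spanning
# trees of the network graph (subsets of edges, connectivity via union-find)
spanning_tree_oracle <- function(net) {
  n <- nrow(net$nodes)
  m <- nrow(net$edges)
  best <- Inf
  for (cols in utils::combn(m, n - 1, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in cols) {
      a <- find(net$edges$from[e]); b <- find(net$edges$to[e])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(net$edges$length[cols]))
  }
  best
}

test_that("a network that is already a tree is returned unchanged", {
  p <- tiny_panel(3)
  S <- rbind(c(13L, 14L, 15L), c(13L, 14L, 16L), c(13L, 14L, 17L))
  net <- build_mj_network(S, panel = p)
  expect_equal(nrow(net$edges), nrow(net$nodes) - 1)
  tree <- extract_parsimony_tree(net, root = "13.14.15")
  expect_equal(tree$total_length, net$resolved_length)
  expect_equal(sum(!is.na(tree$parent)), length(tree$labels) - 1)
  # same edges as the network
  te <- sort(paste(pmin(tree$labels[!is.na(tree$parent)],
                        tree$labels[tree$parent[!is.na(tree$parent)]]),
                   pmax(tree$labels[!is.na(tree$parent)],
                        tree$labels[tree$parent[!is.na(tree$parent)]])))
  ne <- sort(paste(pmin(net$nodes$label[net$edges$from], net$nodes$label[net$edges$to]),
                   pmax(net$nodes$label[net$edges$from], net$nodes$label[net$edges$to])))
  expect_identical(te, ne)
})

test_that("equal-length reticulations resolve deterministically", {
  # a 4-cycle of equal edge lengths: 2 spanning trees tie; the lexicographic
  # rule must pick the same one on every run
  p <- tiny_panel(2)
  S <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  net <- build_mj_network(S, mj_params(weight = 1), panel = p)
  trees <- replicate(5, extract_parsimony_tree(net, root = "0.0"),
                     simplify = FALSE)
  for (t2 in trees[-1]) {
    expect_identical(t2$parent, trees[[1]]$parent)
    expect_identical(t2$labels, trees[[1]]$labels)
  }
  expect_equal(trees[[1]]$total_steps, 3)    # one cycle edge removed
})

test_that("resolution attains the exhaustive minimum on small reticulated networks", {
  p <- tiny_panel(3)
  set.seed(17)
  reticulated <- 0
  for (i in 1:60) {
    S <- unique(rand_states(5, 3, lo = 13L, hi = 15L))
    if (nrow(S) < 3) next
    net <- build_mj_network(S, panel = p)
    if (nrow(net$nodes) > 8 || nrow(net$edges) < nrow(net$nodes)) next
    reticulated <- reticulated + 1
    tree <- extract_parsimony_tree(net, root = 1)
    # prune-free comparison: oracle spans all nodes, ours prunes median
    # leaves afterwards, so ours can only be shorter or equal
    expect_lte(tree$total_length, spanning_tree_oracle(net) + 1e-9)
    # and over observed nodes it must span everything
    expect_setequal(tree$labels[tree$multiplicity > 0],
                    net$nodes$label[net$nodes$type == "observed"])
  }
  expect_gte(reticulated, 5)
})

test_that("tree extraction is invariant under input sample permutation", {
  p <- tiny_panel(4)
  set.seed(3)
  S <- rand_states(7, 4, lo = 12L, hi = 15L)
  hs <- make_hs(S, p)
  net1 <- build_mj_network(hs)
  t1 <- extract_parsimony_tree(net1, root = 1)
  hs2 <- subset_haplotypes(hs, sample(7))
  net2 <- build_mj_network(hs2)
  t2 <- extract_parsimony_tree(net2, root = 1)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$parent, t2$parent)
  expect_identical(t1$edge_steps, t2$edge_steps)
})

test_that("founder inference matches hand-checked star cases", {
  p <- tiny_panel(3)
  # five identical haplotypes: the shared state is the founder
  S <- matrix(rep(c(13L, 14L, 15L), each = 5), 5, 3)
  S2 <- rbind(S, c(13L, 14L, 18L))           # plus one outlier to have 2 states
  net <- build_mj_network(S2, panel = p)
  f <- infer_founder(net)
  expect_equal(net$nodes$label[f], "13.14.15")

  # perfect star: centre state minimises total distance
  centre <- c(13L, 14L, 15L)
  tips <- t(sapply(1:3, function(i) { v <- centre; v[i] <- v[i] + 2L; v }))
  net2 <- build_mj_network(rbind(centre, tips), panel = p)
  f2 <- infer_founder(net2)
  expect_equal(net2$nodes$label[f2], "13.14.15")
})

test_that("founder inference agrees with the brute-force minimiser", {
  p <- tiny_panel(4)
  set.seed(29)
  for (i in 1:15) {
    S <- rand_states(10, 4, lo = 12L, hi = 16L)
    net <- build_mj_network(S, panel = p)
    f <- infer_founder(net)
    w <- strclock:::expand_weight(net$params, p)
    D <- strclock:::state_dist(net$states, w)
    obs <- net$nodes$id[net$nodes$type == "observed"]
    score <- D[, obs, drop = FALSE] %*% net$nodes$multiplicity[obs]
    expect_equal(score[f], min(score))
  }
  # empty cluster is an error
  S <- rand_states(4, 4)
  net <- build_mj_network(S, panel = p)
  expect_error(infer_founder(net, integer(0)), "empty")
})

test_that("an ancient anchor near the optimum is preferred as founder", {
  # scores by hand (weight 10): c = 10+10+70 = 90, t1 = 10+20+60 = 90,
  # t2 = 10+20+80 = 110, u = 70+60+80 = 210; minimum 90
  p <- tiny_panel(3)
  S <- rbind(c = c(13L, 14L, 15L), t1 = c(14L, 14L, 15L),
             t2 = c(13L, 15L, 15L), u = c(20L, 14L, 15L))
  net <- build_mj_network(S, panel = p)
  t1 <- which(net$nodes$label == "14.14.15")
  u <- which(net$nodes$label == "20.14.15")
  # without anchors the tie at 90 goes to the lexicographically smaller label
  expect_equal(net$nodes$label[infer_founder(net)], "13.14.15")
  # t1 attains the minimum within one weighted step -> preferred
  expect_equal(infer_founder(net, anchors = t1), t1)
  # u is far above the minimum -> ignored
  expect_false(infer_founder(net, anchors = u) == u)
})
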