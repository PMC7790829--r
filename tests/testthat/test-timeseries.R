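toy3 <- function() {
  tree <- dated_tree(ape::read.tree(text = "((A:10,B:10):10,C:20);"),
                     root_age = 40)
  occ <- data.frame(taxon = c("A", "B", "C"),
                    fad_ma = c(18, 20, 35), lad_ma = c(10, 15, 30))
  x <- c(A = 1, B = 3, C = 5)
  bins <- data.frame(old_ma = c(40, 30, 20), young_ma = c(30, 20, 10),
                     label = c("b1", "b2", "b3"))
  list(tree = tree, occ = occ, x = x, bins = bins)
}

test_that("ancestral states reduce to the weighted-average closed forms", {
  tr <- dated_tree(ape::read.tree(text = "(A:2,B:4);"))
  anc <- ancestral_states(tr, c(A = 1, B = 4))
  expect_equal(anc$value, (1 / 2 + 4 / 4) / (1 / 2 + 1 / 4))

  tr2 <- dated_tree(ape::read.tree(text = "(A:3,B:3);"))
  expect_equal(ancestral_states(tr2, c(A = 0, B = 2))$value, 1)
})

test_that("ancestral states match rerooted GLS and ape::ace", {
  set.seed(19)
  tr <- rand_tree(6)
  x <- rand_trait(tr)
  anc <- ancestral_states(tr, x)
  for (r in seq_len(nrow(anc))) {
    if (anc$node[r] == ape::Ntip(tr$phy) + 1) {
      C <- dense_C(tr)
      Ci1 <- solve(C, rep(1, 6))
      expect_equal(anc$value[r], sum(Ci1 * x[rownames(C)]) / sum(Ci1),
                   tolerance = 1e-8)
    } else {
      expect_equal(anc$value[r], reroot_gls_state(tr, x, anc$node[r]),
                   tolerance = 1e-8)
    }
  }
  ace <- ape::ace(x[tr$phy$tip.label], tr$phy, method = "REML")$ace
  expect_equal(anc$value, unname(ace[as.character(anc$node)]),
               tolerance = 1e-4)
  expect_error(ancestral_states(tr, x[-1]), tr$phy$tip.label[1])
})

test_that("hand-enumerated toy series match under all three methods", {
  t3 <- toy3()
  emp <- build_series(t3$tree, t3$occ, t3$x, t3$bins, "empirical", "mean")
  expect_equal(emp$n, c(1L, 1L, 2L))
  expect_equal(emp$value, c(5, 5, 2))

  gho <- build_series(t3$tree, t3$occ, t3$x, t3$bins, "ghost", "mean")
  expect_equal(gho$n, c(1L, 3L, 2L))
  expect_equal(gho$value, c(5, 3, 2))

  anc <- ancestral_states(t3$tree, t3$x)
  root_val <- anc$value[anc$age_ma == 40]
  ab_val <- anc$value[anc$age_ma == 30]
  ga <- build_series(t3$tree, t3$occ, t3$x, t3$bins, "ghost+ancestors",
                     "mean")
  expect_equal(ga$n, c(2L, 4L, 2L))
  expect_equal(ga$value,
               c(mean(c(5, root_val)), mean(c(1, 3, 5, ab_val)), 2))
})

test_that("variance series are zero for identical traits, NA when n < 2", {
  t3 <- toy3()
  x0 <- setNames(rep(2.5, 3), names(t3$x))
  v <- build_series(t3$tree, t3$occ, x0, t3$bins, "ghost", "variance")
  expect_equal(v$value, c(NA, 0, 0))   # first bin has a single member
})

test_that("ghost counts dominate empirical counts in every bin", {
  sim <- quick_sim(50, seed = 13)
  cfg <- sim_config(n_tips = 50, seed = 13)
  tv <- sim_trait(sim$tree, cfg)
  bins <- myr_bins(ceiling(sim$tree$root_age), 0, width = 2)
  emp <- build_series(sim$tree, sim$occ, tv$tip_values, bins, "empirical",
                      "mean")
  gho <- build_series(sim$tree, sim$occ, tv$tip_values, bins, "ghost",
                      "mean")
  expect_true(all(gho$n >= emp$n))
})

test_that("series counts equal brute-force membership enumeration", {
  sim <- quick_sim(40, seed = 17)
  cfg <- sim_config(n_tips = 40, seed = 17)
  tv <- sim_trait(sim$tree, cfg)
  bins <- myr_bins(ceiling(sim$tree$root_age), 0, width = 3)
  occ <- sim$occ
  phy <- sim$tree$phy
  i <- match(phy$tip.label, occ$taxon)
  parent_age <- sim$tree$node_age[phy$edge[, 1]][match(seq_len(40),
                                                       phy$edge[, 2])]
  emp <- build_series(sim$tree, occ, tv$tip_values, bins, "empirical",
                      "mean")
  gho <- build_series(sim$tree, occ, tv$tip_values, bins, "ghost", "mean")
  bm_emp <- brute_members(occ$fad_ma[i], occ$lad_ma[i], bins)
  bm_gho <- brute_members(pmax(occ$fad_ma[i], parent_age), occ$lad_ma[i],
                          bins)
  expect_equal(emp$n, lengths(bm_emp))
  expect_equal(gho$n, lengths(bm_gho))
})

test_that("ancestors enter one bin as points, more bins as branch spans", {
  t3 <- toy3()
  pt <- build_series(t3$tree, t3$occ, t3$x, t3$bins, "ghost+ancestors",
                     "mean", ancestor_span = "point")
  br <- build_series(t3$tree, t3$occ, t3$x, t3$bins, "ghost+ancestors",
                     "mean", ancestor_span = "branch")
  expect_true(sum(br$n) >= sum(pt$n))
})

test_that("rate series average scalars over intersecting branches", {
  sim <- quick_sim(30, seed = 23)
  set.seed(3)
  sc <- runif(nrow(sim$tree$phy$edge), 0.2, 4)
  bins <- myr_bins(ceiling(sim$tree$root_age), 0, width = 4)
  sr <- build_series(sim$tree, sim$occ, NULL, bins, "ghost", "mean_rate",
                     rate_scalars = sc)
  page <- sim$tree$node_age[sim$tree$phy$edge[, 1]]
  cage <- sim$tree$node_age[sim$tree$phy$edge[, 2]]
  for (i in seq_len(nrow(bins))) {
    e <- which(page > bins$young_ma[i] & cage <= bins$old_ma[i])
    expect_equal(sr$n[i], length(e))
    if (length(e)) expect_equal(sr$value[i], mean(sc[e]))
  }
  # taxon-presence mode runs and uses terminal-branch scalars
  st <- build_series(sim$tree, sim$occ, NULL, bins, "ghost", "mean_rate",
                     rate_scalars = sc, rate_membership = "taxa")
  expect_true(all(st$n <= ape::Ntip(sim$tree$phy)))
})

test_that("bootstrap envelopes behave at the edges and under a seed", {
  t3 <- toy3()
  full <- bootstrap_envelope(t3$tree, t3$occ, t3$x, t3$bins, "ghost",
                             "mean", fraction = 1, n_iter = 20, seed = 1)
  expect_equal(full$q25, full$q75)
  expect_equal(full$min, full$max)
  expect_equal(full$value, c(5, 3, 2))

  # a 2-member bin at 50% resamples single members only
  bins1 <- data.frame(old_ma = 20, young_ma = 10, label = "b")
  xb <- c(A = 0, B = 10, C = 5)
  bs <- bootstrap_envelope(t3$tree, t3$occ, xb, bins1, "empirical",
                           "mean", fraction = 0.5, n_iter = 200, seed = 2)
  expect_equal(bs$min, 0)
  expect_equal(bs$max, 10)

  b1 <- bootstrap_envelope(t3$tree, t3$occ, t3$x, t3$bins, "ghost",
                           "mean", 0.5, 50, seed = 7)
  b2 <- bootstrap_envelope(t3$tree, t3$occ, t3$x, t3$bins, "ghost",
                           "mean", 0.5, 50, seed = 7)
  expect_identical(b1, b2)
})

test_that("envelope width shrinks as the subsample fraction grows", {
  sim <- quick_sim(60, seed = 29)
  cfg <- sim_config(n_tips = 60, seed = 29)
  tv <- sim_trait(sim$tree, cfg)
  bins <- myr_bins(ceiling(sim$tree$root_age), 0, width = 5)
  width <- vapply(c(0.5, 0.8, 1.0), function(f) {
    b <- bootstrap_envelope(sim$tree, sim$occ, tv$tip_values, bins,
                            "ghost", "mean", f, 60, seed = 11)
    mean(b$max - b$min, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(width) <= 1e-9))
})

test_that("dense fossil sampling closes the gap between methods", {
  cfg <- sim_config(n_tips = 50, seed = 37, sampling_rate = 20)
  sim <- sim_tree_and_ranges(cfg)
  tv <- sim_trait(sim$tree, cfg)
  bins <- myr_bins(ceiling(sim$tree$root_age), 0, width = 2)
  emp <- build_series(sim$tree, sim$occurrences, tv$tip_values, bins,
                      "empirical", "mean")
  gho <- build_series(sim$tree, sim$occurrences, tv$tip_values, bins,
                      "ghost", "mean")
  # with near-complete sampling ghost ranges add almost nothing
  expect_gt(mean(gho$n == emp$n), 0.8)
})
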