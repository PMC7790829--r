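test_that("generators are reproducible under a fixed seed", {
  cfg <- sim_config(n_tips = 30, seed = 5)
  a <- sim_tree_and_ranges(cfg)
  b <- sim_tree_and_ranges(cfg)
  expect_equal(a$tree$node_age, b$tree$node_age)
  expect_identical(ape::write.tree(a$tree$phy), ape::write.tree(b$tree$phy))
  expect_equal(a$occurrences, b$occurrences)
  expect_equal(sim_trait(a$tree, cfg)$tip_values,
               sim_trait(b$tree, cfg)$tip_values)
  tv <- sim_trait(a$tree, cfg)
  latent <- tv$tip_values - min(tv$tip_values) + 5
  expect_identical(sim_measurements(latent, cfg),
                   sim_measurements(latent, cfg))
  expect_equal(sim_temperature(c(100, 0), cfg),
               sim_temperature(c(100, 0), cfg))
})

test_that("dense sampling pins first appearances to branch origins", {
  cfg <- sim_config(n_tips = 25, seed = 9, death = 0, sampling_rate = 50)
  sim <- sim_tree_and_ranges(cfg)
  phy <- sim$tree$phy
  parent_age <- sim$tree$node_age[phy$edge[, 1]][match(
    seq_len(ape::Ntip(phy)), phy$edge[, 2])]
  fad <- sim$occurrences$fad_ma[match(phy$tip.label,
                                      sim$occurrences$taxon)]
  expect_true(all(fad <= parent_age + 1e-9))
  expect_lt(mean(parent_age - fad), 0.5)   # ~1/(2*rate) per branch end
})

test_that("pure-birth waiting times match the analytic expectation", {
  b <- 0.1; n <- 8
  root_ages <- vapply(1:400, function(s) {
    cfg <- sim_config(n_tips = n, seed = s, birth = b, death = 0,
                      sampling_rate = 1)
    sim_tree_and_ranges(cfg)$tree$root_age
  }, 0)
  # root age = (time of n-th birth - time of 1st birth) + one extra
  # exponential gap before the present is declared
  expected <- sum(1 / (b * (2:(n - 1)))) + 1 / (b * n)
  expect_lt(abs(mean(root_ages) / expected - 1), 0.1)
})

test_that("trait simulation honours its closed-form moments", {
  cfg <- sim_config(n_tips = 20, seed = 13,
                    trait = list(kind = "random_walk", sigma2 = 0,
                                 alpha = 2.5))
  sim <- sim_tree_and_ranges(cfg)
  tv <- sim_trait(sim$tree, cfg)
  expect_true(all(tv$tip_values == 2.5))

  # variance over a single branch of length t is sigma2 * t
  tr <- dated_tree(ape::read.tree(text = "(A:4,B:4);"))
  set.seed(31)
  reps <- vapply(1:8000, function(i)
    sim_trait(tr, list(kind = "random_walk", sigma2 = 1.5, alpha = 0,
                       shifts = list()))$tip_values[["A"]], 0)
  expect_lt(abs(var(reps) / 6 - 1), 0.05)
})

test_that("planted rate shifts inflate contrast variance inside the clade", {
  cfg0 <- sim_config(n_tips = 80, seed = 17)
  sim <- sim_tree_and_ranges(cfg0)
  phy <- sim$tree$phy
  n_tip <- ape::Ntip(phy)
  sizes <- vapply((n_tip + 2):(n_tip + phy$Nnode), function(n)
    length(ape::extract.clade(phy, n)$tip.label), 0)
  node <- ((n_tip + 2):(n_tip + phy$Nnode))[which.min(abs(sizes - 10))]
  cfg <- sim_config(n_tips = 80, seed = 17,
                    trait = list(kind = "variable_rates", sigma2 = 1,
                                 alpha = 0,
                                 shifts = list(list(node = node,
                                                    scalar = 50))))
  tv <- sim_trait(sim$tree, cfg)
  pic <- ape::pic(tv$tip_values[phy$tip.label], phy)
  planted_edges <- which(tv$edge_rates > 1)
  inside <- unique(phy$edge[planted_edges, 1] - n_tip)
  inside <- inside[inside > 0]
  ratio <- var(pic[inside]) / var(pic[-inside])
  expect_gt(ratio, 5)
})

test_that("measurement matrices are rank one without noise or gaps", {
  sizes <- setNames(seq(2, 30, length.out = 15), sprintf("t%02d", 1:15))
  M <- sim_measurements(sizes, list(n_characters = 6, slopes = NULL,
                                    noise_sd = 0, missingness = 0,
                                    size_biased = FALSE))
  sv <- svd(sweep(M, 2, colMeans(M)))$d
  expect_lt(sv[2] / sv[1], 1e-10)
  expect_error(sim_measurements(c(a = -1, b = 2), list(
    n_characters = 3, slopes = NULL, noise_sd = 0, missingness = 0,
    size_biased = FALSE)), "positive")
})

test_that("temperature curves honour their configuration", {
  cfg <- sim_config(n_tips = 10, seed = 23,
                    temperature = list(walk_sd = 0, coupling = 0))
  temp <- sim_temperature(c(50, 0), cfg)
  expect_equal(length(unique(temp$d18o)), 1L)
  expect_equal(nrow(temp), 51L)
  expect_error(sim_temperature(c(5, 0), cfg), "10 Myr")
  cfg2 <- sim_config(n_tips = 10, seed = 23,
                     temperature = list(walk_sd = 0.1, coupling = -2))
  expect_error(sim_temperature(c(50, 0), cfg2), "rate_series")
})

test_that("simulated bundles satisfy every downstream precondition", {
  for (seed in c(1, 2, 3, 4, 5)) {
    out <- simulate_dataset(sim_config(n_tips = 40, seed = seed))
    expect_true(all(branch_durations(out$tree) > 0))
    expect_s3_class(out$tree, "dated_tree")
    expect_silent(as_occurrences(out$occurrences))
    expect_silent(as_measurements(out$measurements))
    expect_silent(as_temperature(out$temperature))
    expect_equal(sort(names(out$trait$tip_values)),
                 sort(out$tree$phy$tip.label))
    # the bundle redates cleanly from its own occurrence table
    redated <- equal_dating(out$tree$phy, out$occurrences, 5)
    expect_true(all(branch_durations(redated) > 0))
  }
})

test_that("bundles export as plain-text files", {
  dir <- withr::local_tempdir()
  simulate_dataset(sim_config(n_tips = 15, seed = 3), out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("tree.nex", "ranges.csv", "measurements.csv",
           "temperature.csv", "truth.json")))))
  M <- read_measurements(file.path(dir, "measurements.csv"))
  expect_equal(nrow(M), 15)
})
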