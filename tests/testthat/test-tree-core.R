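test_that("tree I/O round-trips topology, labels and branch lengths", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", p)
  tr <- read_tree(p)
  expect_s3_class(tr, "dated_tree")
  expect_equal(sort(tr$phy$tip.label), c("A", "B", "C"))
  expect_equal(sort(branch_durations(tr)), c(1, 1, 1, 2))

  sim <- quick_sim(120, seed = 5)
  for (fmt in c("newick", "nexus")) {
    f <- withr::local_tempfile(fileext = if (fmt == "nexus") ".nex" else ".nwk")
    write_tree(sim$tree, f, fmt)
    back <- read_tree(f, fmt)
    expect_equal(ape::dist.topo(ape::unroot(back$phy),
                                ape::unroot(sim$tree$phy))[[1]], 0)
    expect_lt(max(abs(sort(back$phy$edge.length) -
                      sort(sim$tree$phy$edge.length))), 1e-6)
  }
})

test_that("parser failures and degenerate inputs raise informative errors", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1:1,C:2;", p)
  expect_error(read_tree(p))
  writeLines("((A:1,A:1):1,C:2);", p)
  expect_error(read_tree(p), "duplicate")
  writeLines("((A,B),C);", p)
  topo <- read_tree(p)              # no branch lengths: undated topology
  expect_s3_class(topo, "phylo")
  expect_false(is_dated_tree(topo))
})

test_that("equal dating follows the 4-step rule on worked examples", {
  phy <- ape::read.tree(text = "((A,B),C);")
  occ <- data.frame(taxon = c("A", "B", "C"), fad_ma = c(100, 100, 150),
                    lad_ma = c(95, 90, 140))
  tr <- equal_dating(phy, occ, root_buffer_myr = 10)
  expect_equal(tr$root_age, 160)
  ages <- tr$node_age
  n_ab <- ape::getMRCA(tr$phy, c("A", "B"))
  expect_equal(ages[n_ab], 130)     # 60-Myr span split 30 + 30
  expect_equal(unname(tip_ages(tr)[c("A", "B", "C")]), c(100, 100, 150))
  expect_true(all(branch_durations(tr) > 0))

  cherry <- ape::read.tree(text = "(A,B);")
  occ2 <- data.frame(taxon = c("A", "B"), fad_ma = c(50, 50),
                     lad_ma = c(40, 45))
  tr2 <- equal_dating(cherry, occ2, 10)
  expect_equal(tr2$root_age, 60)
  expect_equal(unname(branch_durations(tr2)), c(10, 10))

  # distinct FADs: the oldest descendant still pins a zero branch, which
  # the rule resolves by halving the 35-Myr span above the AB node
  phy3 <- ape::read.tree(text = "((A,B),C);")
  occ3 <- data.frame(taxon = c("A", "B", "C"), fad_ma = c(80, 120, 150),
                     lad_ma = c(70, 110, 140))
  tr3 <- equal_dating(phy3, occ3, 5)
  expect_equal(tr3$root_age, 155)
  expect_equal(tr3$node_age[ape::getMRCA(tr3$phy, c("A", "B"))], 137.5)
  expect_true(all(branch_durations(tr3) > 0))
})

test_that("equal dating errors on missing taxa and bad buffers", {
  phy <- ape::read.tree(text = "((A,B),C);")
  occ <- data.frame(taxon = c("A", "B"), fad_ma = c(1, 2), lad_ma = c(0, 0))
  expect_error(equal_dating(phy, occ, 5), "C")
  occ$taxon <- c("A", "B")
  expect_error(equal_dating(phy, rbind(occ, data.frame(
    taxon = "C", fad_ma = 3, lad_ma = 0)), 0), "positive")
})

test_that("dating is order-independent and path sums are consistent", {
  sim <- quick_sim(40, seed = 9)
  occ <- sim$occ
  t1 <- equal_dating(sim$tree$phy, occ, 5)
  set.seed(1)
  t2 <- equal_dating(sim$tree$phy, occ[sample(nrow(occ)), ], 5)
  expect_equal(t1$node_age, t2$node_age, tolerance = 1e-12)

  # sum of branch durations along any root-to-tip path = root - tip age
  depths <- t1$root_age - t1$node_age[seq_len(ape::Ntip(t1$phy))]
  pd <- ape::node.depth.edgelength(t1$phy)[seq_len(ape::Ntip(t1$phy))]
  expect_lt(max(abs(depths - pd)), 1e-9)
})

test_that("trimming preserves ages and sums suppressed branches", {
  tr <- dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"),
                   root_age = 10)
  sub <- trim_to(tr, c("A", "B"))
  expect_equal(sort(sub$phy$tip.label), c("A", "B"))
  expect_equal(sub$root_age, 9)     # the AB node's original age

  sim <- quick_sim(100, seed = 3)
  set.seed(4)
  keep <- sample(sim$tree$phy$tip.label, 40)
  sub2 <- trim_to(sim$tree, keep)
  expect_equal(tip_ages(sub2)[sort(keep)], tip_ages(sim$tree)[sort(keep)])
  expect_identical(trim_to(sim$tree, sim$tree$phy$tip.label), sim$tree)
  expect_error(trim_to(sim$tree, character(0)), "non-empty")
})

test_that("bin membership matches interval logic in all three modes", {
  phy <- ape::read.tree(text = "((A:20,B:30):10,C:45);")
  tr <- dated_tree(phy, root_age = 150)
  # ages: C tip 105, A tip 120, B tip 110, AB node 140, root 150
  occ <- data.frame(taxon = c("A", "B", "C"),
                    fad_ma = c(100, 100, 100), lad_ma = c(95, 96, 99))
  expect_setequal(lineages_in_bin(tr, occ, c(97, 96), "empirical"),
                  c("A", "B"))
  # ghost mode reaches back to the parent node age
  expect_true("A" %in% lineages_in_bin(tr, occ, c(130, 129), "ghost"))
  expect_false("A" %in% lineages_in_bin(tr, occ, c(130, 129), "empirical"))

  # branch mode equals a brute-force interval sweep
  bins <- myr_bins(160, 90)
  page <- tr$node_age[tr$phy$edge[, 1]]
  cage <- tr$node_age[tr$phy$edge[, 2]]
  for (i in seq_len(nrow(bins))) {
    got <- lineages_in_bin(tr, bin = c(bins$old_ma[i], bins$young_ma[i]),
                           mode = "branches")
    want <- which(page > bins$young_ma[i] & cage <= bins$old_ma[i])
    expect_identical(got, want)
  }
  # out-of-span bin is empty, not an error
  expect_length(lineages_in_bin(tr, occ, c(500, 499), "empirical"), 0)
})

test_that("ghost membership always contains empirical membership", {
  sim <- quick_sim(60, seed = 11)
  bins <- myr_bins(ceiling(sim$tree$root_age), 0, width = 5)
  for (i in seq_len(nrow(bins))) {
    b <- c(bins$old_ma[i], bins$young_ma[i])
    emp <- lineages_in_bin(sim$tree, sim$occ, b, "empirical")
    gho <- lineages_in_bin(sim$tree, sim$occ, b, "ghost")
    expect_true(all(emp %in% gho))
  }
})

test_that("stage table is a contiguous half-open partition of time", {
  st <- stage_bins()
  expect_true(all(st$old_ma > st$young_ma))
  expect_equal(st$old_ma[-1], st$young_ma[-nrow(st)])
  expect_gt(nrow(stage_bins(201.3, 66)), 20)  # Jurassic + Cretaceous stages
})
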