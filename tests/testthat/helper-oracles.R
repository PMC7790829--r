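# Independent dense oracles and small fixture builders. Everything here
# works from explicit covariance matrices (ape::vcv + matrix algebra),
# never through the package's pruning/transform code paths.

dense_mvn_ll <- function(x, mean, V) {
  R <- chol(V)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# BM covariance (shared path lengths) in a fixed tip order
dense_C <- function(tree) {
  C <- ape::vcv.phylo(tree$phy)
  C[tree$phy$tip.label, tree$phy$tip.label]
}

# Pagel-transformed covariances built directly from C
dense_C_kappa <- function(tree, kappa) {
  phy <- tree$phy
  phy$edge.length <- phy$edge.length^kappa
  ape::vcv.phylo(phy)[tree$phy$tip.label, tree$phy$tip.label]
}
dense_C_delta <- function(tree, delta) dense_C(tree)^delta
dense_C_lambda <- function(tree, lambda) {
  C <- dense_C(tree)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}
dense_V_ou <- function(tree, sigma2, a) {
  C <- dense_C(tree)
  ti <- diag(C)
  sigma2 / (2 * a) * exp(-a * (outer(ti, ti, `+`) - 2 * C)) *
    (1 - exp(-2 * a * C))
}

# random non-ultrametric dated tree
rand_tree <- function(n, min_len = 0.2, max_len = 3) {
  phy <- ape::rtree(n, br = NULL)
  phy$edge.length <- runif(nrow(phy$edge), min_len, max_len)
  dated_tree(phy)
}

rand_trait <- function(tree) {
  setNames(rnorm(ape::Ntip(tree$phy), 0, 2), tree$phy$tip.label)
}

# rerooted-GLS ancestral state at one internal node (oracle for the
# belief-propagation estimator)
reroot_gls_state <- function(tree, x, node) {
  phy <- tree$phy
  r <- ape::root(phy, node = node, resolve.root = FALSE)
  C <- ape::vcv.phylo(r)[names(x), names(x)]
  Ci1 <- solve(C, rep(1, length(x)))
  sum(Ci1 * x) / sum(Ci1)
}

# brute-force per-bin interval-overlap membership
brute_members <- function(starts, ends, bins) {
  lapply(seq_len(nrow(bins)), function(i)
    which(starts > bins$young_ma[i] & ends <= bins$old_ma[i]))
}

# plant rate-shift clades (size 5-30 tips) spread across the tree's span,
# so every era carries rate variation for the coupling-recovery checks
spread_shifts <- function(tree, scalar = 20,
                          quantiles = c(0.15, 0.4, 0.65, 0.9)) {
  phy <- tree$phy
  n_tip <- ape::Ntip(phy)
  nn <- (n_tip + 2):(n_tip + phy$Nnode)
  sizes <- vapply(nn, function(n)
    length(ape::extract.clade(phy, n)$tip.label), 0)
  ages <- tree$node_age[nn]
  cand <- sizes >= 5 & sizes <= 30
  lapply(quantiles, function(q) {
    nd <- nn[cand][which.min(abs(ages[cand] - q * tree$root_age))]
    list(node = nd, scalar = scalar)
  })
}

# planted-coupling recovery rates: how often era-partitioned OLS finds the
# planted negative rate-temperature association over `n_seeds` replicate
# temperature curves
coupling_recovery <- function(base_seed, n_tips = 120, coupling = -2,
                              n_seeds = 100) {
  cfg0 <- sim_config(n_tips = n_tips, seed = base_seed)
  sim <- sim_tree_and_ranges(cfg0)
  cfg <- sim_config(n_tips = n_tips, seed = base_seed,
                    trait = list(kind = "variable_rates", sigma2 = 1,
                                 alpha = 0,
                                 shifts = spread_shifts(sim$tree)))
  tv <- sim_trait(sim$tree, cfg)
  bins <- myr_bins(ceiling(sim$tree$root_age), 0)
  sr <- build_series(sim$tree, sim$occurrences, NULL, bins, "ghost",
                     "mean_rate", rate_scalars = tv$edge_rates)
  rate_series <- data.frame(age_ma = bin_midpoints(bins), value = sr$value)
  rate_series <- rate_series[!is.na(rate_series$value), ]
  hits <- c(all = 0L, mesozoic = 0L, cenozoic = 0L)
  for (s in seq_len(n_seeds)) {
    cfg_t <- sim_config(n_tips = n_tips, seed = base_seed * 1000 + s,
                        temperature = list(walk_sd = 0.15,
                                           coupling = coupling))
    temp <- sim_temperature(c(sim$tree$root_age, 0), cfg_t, rate_series)
    for (era in names(hits)) {
      r <- suppressWarnings(regress_on_temperature(sr, temp, era))
      hits[era] <- hits[era] + (r$slope < 0 && r$p_value < 0.05)
    }
  }
  hits
}

quick_sim <- function(n_tips = 60, seed = 1, ...) {
  cfg <- sim_config(n_tips = n_tips, seed = seed, ...)
  sim <- sim_tree_and_ranges(cfg)
  list(cfg = cfg, tree = sim$tree, occ = sim$occurrences)
}
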