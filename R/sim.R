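#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with a mandatory seed. The default
#' preset mirrors the dimensions of a large fossil-archosaur dataset: a
#' birth-death tree conditioned on 280 tips whose expected span is on the
#' order of 250 Myr, up to 21 linear characters driven by a latent size
#' factor with 60% of cells missing, and a 1-Myr-step random-walk
#' oxygen-isotope curve.
#'
#' @param n_tips total number of tips (extinct + extant) to condition on.
#' @param birth,death speciation and extinction rates (/Myr/lineage).
#' @param sampling_rate Poisson fossil-sampling rate along terminal
#'   branches (/Myr).
#' @param trait list: `kind` (any [model_spec()] kind), `sigma2`, `alpha`,
#'   `param` (transform parameter where relevant), `shifts` (for
#'   `variable_rates`: list of `list(tips = c(...), scalar = s)` planted
#'   clade rate shifts).
#' @param measurement list: `n_characters`, `slopes` (per-character
#'   allometric slopes; default 1 for the skull-width character and
#'   spread over `[0.3, 2]` otherwise), `noise_sd` (cm), `missingness`
#'   fraction in `[0, 1)`, `size_biased` (smaller taxa more often
#'   missing).
#' @param temperature list: `walk_sd` (permil per Myr step), `coupling`
#'   (linear coefficient on the standardized rate series; negative values
#'   plant the warm-high-rate association).
#' @param seed RNG seed (mandatory).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 280, birth = 0.035, death = 0.015,
                       sampling_rate = 0.1,
                       trait = list(), measurement = list(),
                       temperature = list(), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (n_tips < 3) stop("`n_tips` must be >= 3")
  if (birth <= 0 || death < 0 || sampling_rate < 0)
    stop("rates must be non-negative (birth positive)")
  shifts <- trait$shifts %||% list()
  trait$shifts <- NULL
  trait <- utils::modifyList(
    list(kind = "random_walk", sigma2 = 1, alpha = 0, param = NULL),
    trait)
  trait$shifts <- shifts
  measurement <- utils::modifyList(
    list(n_characters = 21, slopes = NULL, noise_sd = 0.5,
         missingness = 0.6, size_biased = FALSE), measurement)
  if (measurement$missingness < 0 || measurement$missingness >= 1)
    stop("missingness must be in [0, 1)")
  temperature <- utils::modifyList(list(walk_sd = 0.15, coupling = 0),
                                   temperature)
  structure(list(n_tips = n_tips, birth = birth, death = death,
                 sampling_rate = sampling_rate, trait = trait,
                 measurement = measurement, temperature = temperature,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a birth-death tree with fossil occurrence ranges
#'
#' Forward (Gillespie) birth-death simulation from a single lineage,
#' conditioned on reaching `n_tips` total tips; the present is placed at
#' the first event after the last birth, so all terminal branches are
#' positive. Each tip's first/last appearance is drawn by Poisson
#' sampling at `sampling_rate` along its terminal branch; unsampled tips
#' collapse to a point occurrence at their endpoint, and extant tips have
#' a last appearance of 0 Ma.
#'
#' @param config a [sim_config()].
#' @param max_retry attempts before giving up when the clade dies out.
#' @return list with `tree` (a [dated_tree] with true ages) and
#'   `occurrences` (taxon/fad_ma/lad_ma data frame).
#' @export
sim_tree_and_ranges <- function(config, max_retry = 100) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  for (try in seq_len(max_retry)) {
    lin <- sim_bd_forward(config$n_tips, config$birth, config$death)
    if (!is.null(lin)) break
    lin <- NULL
  }
  if (is.null(lin))
    stop("clade went extinct before reaching ", config$n_tips,
         " tips in ", max_retry, " attempts")
  phy <- ape::read.tree(text = lineages_to_newick(lin$tab, lin$present))
  tree <- dated_tree(phy, root_age = lin$present - lin$first_split)

  # fossil sampling along terminal branches
  tab <- lin$tab
  term_start <- vapply(seq_len(nrow(tab)), function(i) {
    kids <- tab$t_birth[tab$parent == tab$id[i]]
    max(c(tab$t_birth[i], kids))
  }, 0)
  t_end <- ifelse(is.na(tab$t_death), lin$present, tab$t_death)
  occ <- data.frame(taxon = tab$name, fad_ma = NA_real_, lad_ma = NA_real_)
  for (i in seq_len(nrow(tab))) {
    dur <- t_end[i] - term_start[i]
    k <- rpois(1, config$sampling_rate * dur)
    if (k > 0) {
      tt <- runif(k, term_start[i], t_end[i])
      occ$fad_ma[i] <- lin$present - min(tt)
      occ$lad_ma[i] <- lin$present - max(tt)
    } else {
      occ$fad_ma[i] <- occ$lad_ma[i] <- lin$present - t_end[i]
    }
  }
  occ$lad_ma[abs(occ$lad_ma) < 1e-9] <- 0
  list(tree = tree, occurrences = as_occurrences(occ))
}

# Gillespie forward simulation; returns NULL on extinction before n_tips.
sim_bd_forward <- function(n_tips, birth, death) {
  tab <- data.frame(id = 1L, parent = 0L, t_birth = 0, t_death = NA_real_)
  alive <- 1L
  t <- 0
  repeat {
    n <- length(alive)
    if (n == 0L) return(NULL)
    t <- t + rexp(1, n * (birth + death))
    if (nrow(tab) == n_tips) break       # present = first post-birth event
    if (runif(1) < birth / (birth + death)) {
      par <- alive[sample.int(n, 1L)]
      id <- nrow(tab) + 1L
      tab <- rbind(tab, data.frame(id = id, parent = par, t_birth = t,
                                   t_death = NA_real_))
      alive <- c(alive, id)
    } else {
      vic <- sample.int(n, 1L)
      tab$t_death[alive[vic]] <- t
      alive <- alive[-vic]
    }
  }
  first_split <- min(tab$t_birth[tab$parent == 1L])
  tab$name <- sprintf("t%03d", tab$id)
  list(tab = tab, present = t, first_split = first_split)
}

# Budding genealogy -> Newick with branch durations.
lineages_to_newick <- function(tab, present) {
  t_end <- ifelse(is.na(tab$t_death), present, tab$t_death)
  kids <- split(tab[-1L, c("id", "t_birth")], tab$parent[-1L])
  build <- function(i, from) {
    ev <- kids[[as.character(tab$id[i])]]
    ev <- ev[ev$t_birth > from, , drop = FALSE]
    if (is.null(ev) || nrow(ev) == 0L)
      return(sprintf("%s:%.10f", tab$name[i], t_end[i] - from))
    j <- which.min(ev$t_birth)
    s <- ev$t_birth[j]
    child <- match(ev$id[j], tab$id)
    sprintf("(%s,%s):%.10f", build(i, s), build(child, s), s - from)
  }
  # drop the root edge: the tree starts at the first split
  paste0(sub(":[0-9.]+$", "", build(1L, 0)), ";")
}

#' Simulate a continuous trait on a dated tree
#'
#' Recursive root-to-tip simulation under any of the package's models:
#' Brownian increments `N(0, sigma2 * b)` on (possibly Pagel-transformed)
#' branch durations; `trend` adds `beta * b` to each increment's mean;
#' `ou` uses the exact Ornstein-Uhlenbeck transition law toward the root
#' state; `variable_rates` multiplies `sigma2` by planted clade scalars.
#' True internal-node values are returned for validating ancestral-state
#' estimation.
#'
#' @param tree a [dated_tree].
#' @param config a [sim_config()] (its `trait` entry is used), or a bare
#'   list with the same fields.
#' @return list with `tip_values` (named), `node_values` (all nodes,
#'   ape numbering) and `edge_rates` (true per-edge rate scalars in
#'   `tree$phy$edge` order).
#' @export
sim_trait <- function(tree, config) {
  stopifnot(is_dated_tree(tree))
  tr <- if (inherits(config, "sim_config")) config$trait else config
  if (inherits(config, "sim_config")) set.seed(config$seed + 1L)
  kind <- tr$kind
  sigma2 <- tr$sigma2; alpha <- tr$alpha
  phy <- tree$phy
  sim_tree <- tree
  if (kind %in% c("lambda", "delta", "kappa"))
    sim_tree <- transform_tree(tree, kind, tr$param)

  n_tip <- ape::Ntip(phy)
  n_all <- n_tip + phy$Nnode
  edge <- sim_tree$phy$edge
  len <- sim_tree$phy$edge.length

  rates <- rep(1, nrow(edge))
  if (kind == "variable_rates" && length(tr$shifts)) {
    for (sh in tr$shifts) {
      node <- if (!is.null(sh$node)) sh$node
              else ape::getMRCA(phy, sh$tips)
      ed <- clade_edges(phy, node)
      rates[ed] <- rates[ed] * sh$scalar
    }
  }

  x <- numeric(n_all)
  root <- n_tip + 1L
  x[root] <- alpha
  pre <- order(node_depths(phy)[edge[, 2L]])  # parents before children
  for (e in pre) {
    par <- edge[e, 1L]; chi <- edge[e, 2L]; b <- len[e]
    if (kind == "ou" && tr$param > 0) {
      a <- tr$param
      m <- alpha + (x[par] - alpha) * exp(-a * b)
      v <- sigma2 / (2 * a) * (1 - exp(-2 * a * b))
      x[chi] <- rnorm(1, m, sqrt(v))
    } else {
      drift <- if (kind == "trend") tr$param * b else 0
      x[chi] <- rnorm(1, x[par] + drift, sqrt(sigma2 * rates[e] * b))
    }
  }
  list(tip_values = setNames(x[seq_len(n_tip)], phy$tip.label),
       node_values = x, edge_rates = rates)
}

# Edge indices (phy$edge order) of the clade rooted at `node`, stem
# included.
clade_edges <- function(phy, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    e <- which(phy$edge[, 2L] == v)
    out <- c(out, e)
    stack <- c(stack, phy$edge[phy$edge[, 1L] == v, 2L])
  }
  sort(out)
}

#' Simulate a sparse measurement matrix from latent sizes
#'
#' Each character is an allometric multiple of the latent size plus
#' Gaussian noise, truncated positive; cells are then deleted at random
#' (completely at random by default, or with smaller taxa more likely
#' missing when `size_biased`), always leaving at least one observation
#' per row and per column. The first character is named `skull_width`
#' with slope 1, so the PC-1/skull-width back-transform applies.
#'
#' @param sizes named positive latent sizes (cm scale), one per taxon.
#' @param config a [sim_config()] (its `measurement` entry is used).
#' @return a measurement matrix (see [as_measurements()]).
#' @export
sim_measurements <- function(sizes, config) {
  me <- if (inherits(config, "sim_config")) config$measurement else config
  if (inherits(config, "sim_config")) set.seed(config$seed + 2L)
  if (any(sizes <= 0)) stop("latent sizes must be positive")
  p <- me$n_characters
  if (p < 2) stop("need >= 2 characters")
  slopes <- me$slopes %||% c(1, seq(0.3, 2, length.out = p - 1L))
  if (length(slopes) != p) stop("need one slope per character")
  n <- length(sizes)
  X <- outer(sizes, slopes) + matrix(rnorm(n * p, 0, me$noise_sd), n, p)
  X <- pmax(X, 0.01)
  dimnames(X) <- list(names(sizes),
                      c("skull_width", sprintf("char_%02d", seq_len(p - 1L))))

  if (me$missingness > 0) {
    pmiss <- matrix(me$missingness, n, p)
    if (isTRUE(me$size_biased)) {
      z <- as.numeric(scale(sizes))
      pmiss <- pmin(0.95, me$missingness * 2 * stats::plogis(-z))
    }
    drop <- matrix(runif(n * p) < pmiss, n, p)
    # keep at least one observation in every row and column
    for (i in which(rowSums(!drop) == 0))
      drop[i, sample.int(p, 1L)] <- FALSE
    for (j in which(colSums(!drop) == 0))
      drop[sample.int(n, 1L), j] <- FALSE
    X[drop] <- NA_real_
  }
  as_measurements(X)
}

#' Simulate an oxygen-isotope temperature curve
#'
#' Gaussian random walk in delta-18-O at 1-Myr steps over a time span.
#' With a nonzero `coupling` coefficient and a supplied rate series, a
#' linear component proportional to the standardized rate is added
#' (negative coupling plants the warmer-temperature/higher-rate
#' association, since the proxy scales inversely with temperature).
#'
#' @param span `c(old_ma, young_ma)` (or a single old age, to 0), at
#'   least 10 Myr.
#' @param config a [sim_config()] (its `temperature` entry is used).
#' @param rate_series optional data frame `age_ma`, `value` to couple to.
#' @return a temperature data frame (`age_ma`, `d18o`).
#' @export
sim_temperature <- function(span, config, rate_series = NULL) {
  te <- if (inherits(config, "sim_config")) config$temperature else config
  if (inherits(config, "sim_config")) set.seed(config$seed + 3L)
  if (length(span) == 1L) span <- c(span, 0)
  if (span[1L] - span[2L] < 10) stop("span must cover >= 10 Myr")
  ages <- seq(span[1L], span[2L], by = -1)
  d18o <- cumsum(rnorm(length(ages), 0, te$walk_sd))
  if (te$coupling != 0) {
    if (is.null(rate_series))
      stop("coupling requires a `rate_series`")
    r <- approx(rate_series$age_ma, rate_series$value, xout = ages,
                rule = 2)$y
    d18o <- d18o + te$coupling * as.numeric(scale(r))
  }
  as_temperature(data.frame(age_ma = ages, d18o = d18o))
}

#' Simulate a complete analysis bundle
#'
#' Runs every generator with one configuration: tree + occurrence ranges,
#' trait values (with true ancestral states and rates), a latent-size
#' measurement matrix (latent size is the trait shifted to a positive cm
#' scale), and a temperature curve over the tree's span. Optionally
#' writes the bundle to a directory as `tree.nex`, `ranges.csv`,
#' `measurements.csv`, `temperature.csv` and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `tree`, `occurrences`, `trait` (the [sim_trait()]
#'   output), `latent_sizes`, `measurements`, `temperature`, `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tr <- sim_tree_and_ranges(config)
  trait <- sim_trait(tr$tree, config)
  latent <- trait$tip_values - min(trait$tip_values) + 5
  meas <- sim_measurements(latent, config)
  temp <- sim_temperature(c(tr$tree$root_age, 0), config)
  out <- list(tree = tr$tree, occurrences = tr$occurrences, trait = trait,
              latent_sizes = latent, measurements = meas,
              temperature = temp, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tree(tr$tree, file.path(out_dir, "tree.nex"), "nexus")
    write.csv(tr$occurrences, file.path(out_dir, "ranges.csv"),
              row.names = FALSE)
    mm <- data.frame(taxon = rownames(meas), meas, check.names = FALSE)
    write.csv(mm, file.path(out_dir, "measurements.csv"),
              row.names = FALSE)
    write.csv(temp, file.path(out_dir, "temperature.csv"),
              row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(
        list(seed = config$seed, trait = config$trait,
             tip_values = as.list(trait$tip_values)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
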