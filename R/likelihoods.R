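#' Brownian-motion log-likelihood by pruning
#'
#' Log density of tip values under a Brownian random walk with fixed root
#' state: a multivariate normal with mean `root_state` and covariance
#' `sigma2 * C`, where `C[i, j]` is the shared root-to-MRCA path length.
#' Computed by Felsenstein's pruning algorithm in O(tips) (C++ kernel), so
#' it never forms `C` explicitly.
#'
#' @param tree a [dated_tree] with positive branch durations.
#' @param trait_values named numeric vector with one value per tip.
#' @param sigma2 Brownian rate (trait^2/Myr), positive.
#' @param root_state trait value at the root.
#' @param rates optional per-edge rate scalars (background 1), in the
#'   tree's edge order; used by the variable-rates model.
#' @return the log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, trait_values, sigma2, root_state, rates = NULL) {
  pr <- bm_prune(tree, trait_values, sigma2, rates)
  pr$logf + dnorm(root_state, pr$mu_root, sqrt(sigma2 * pr$v_root), log = TRUE)
}

# Shared pruning pass. Returns logf (contrast terms), mu_root and v_root so
# the likelihood can be re-evaluated at any root state; mu_root is also the
# GLS (phylogenetic) mean of the data.
bm_prune <- function(tree, trait_values, sigma2, rates = NULL,
                     mean_offset = NULL) {
  stopifnot(is_dated_tree(tree))
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  phy <- tree$phy
  x <- match_tip_values(phy, trait_values)
  if (!is.null(mean_offset)) x <- x - mean_offset
  n_tip <- ape::Ntip(phy)
  if (n_tip == 1L) {
    t1 <- tree$root_age - tree$node_age[1L]
    return(list(logf = 0, mu_root = unname(x), v_root = t1))
  }
  eo <- reorder_edges(phy)
  if (is.null(rates)) rates <- rep(1, nrow(phy$edge))
  if (length(rates) != nrow(phy$edge))
    stop("`rates` must have one entry per edge")
  # rates are supplied in phy$edge order; re-order to postorder
  idx <- match(paste(eo$edge[, 1L], eo$edge[, 2L]),
               paste(phy$edge[, 1L], phy$edge[, 2L]))
  out <- bm_prune_cpp(eo$edge, eo$edge.length, rates[idx], n_tip,
                      x, sigma2, 0)
  list(logf = out[4L], mu_root = out[2L], v_root = out[3L])
}

match_tip_values <- function(phy, trait_values) {
  if (is.null(names(trait_values))) {
    if (length(trait_values) != ape::Ntip(phy))
      stop("trait vector length does not match the number of tips")
    return(as.numeric(trait_values))
  }
  missing <- setdiff(phy$tip.label, names(trait_values))
  if (length(missing))
    stop("missing trait values for tips: ", paste(missing, collapse = ", "))
  as.numeric(trait_values[phy$tip.label])
}

#' Pagel tree transformations
#'
#' Rescales a dated tree so that Brownian motion on the transformed tree
#' has the covariance of a Pagel model on the original:
#' * `kappa`: each branch duration raised to the power `param` (kappa 0 =
#'   every branch has length 1, pure punctuational change per split);
#' * `delta`: node depths from the root raised to the power `param`
#'   (delta < 1 concentrates change early in the tree);
#' * `lambda`: internal branches scaled by `param` with terminal branches
#'   adjusted to preserve root-to-tip path lengths (off-diagonal
#'   covariance entries multiplied by lambda).
#'
#' @param tree a [dated_tree].
#' @param kind one of `"kappa"`, `"delta"`, `"lambda"`.
#' @param param transformation parameter: kappa >= 0, delta > 0,
#'   lambda in `[0, 1]` (values > 1 are rejected if any terminal branch
#'   would become negative).
#' @return a [dated_tree] whose edge lengths carry the transformed
#'   covariance; node ages are re-anchored so the deepest tip sits at 0.
#' @export
transform_tree <- function(tree, kind = c("kappa", "delta", "lambda"),
                           param) {
  stopifnot(is_dated_tree(tree))
  kind <- match.arg(kind)
  phy <- tree$phy
  n_tip <- ape::Ntip(phy)
  if (kind == "kappa") {
    if (param < 0) stop("kappa must be >= 0")
    phy$edge.length <- phy$edge.length^param
  } else if (kind == "delta") {
    if (param <= 0) stop("delta must be > 0")
    depth <- tree$root_age - tree$node_age   # root-to-node path lengths
    phy$edge.length <- depth[phy$edge[, 2L]]^param -
      depth[phy$edge[, 1L]]^param
  } else {
    if (param < 0) stop("lambda must be >= 0")
    depth <- tree$root_age - tree$node_age
    tip_edge <- phy$edge[, 2L] <= n_tip
    len <- phy$edge.length * param
    len[tip_edge] <- depth[phy$edge[tip_edge, 2L]] -
      param * depth[phy$edge[tip_edge, 1L]]
    if (any(len < 0))
      stop("lambda = ", param, " yields negative terminal branches")
    phy$edge.length <- len
  }
  dated_tree(phy)
}

#' Ornstein-Uhlenbeck log-likelihood (fixed root)
#'
#' Single-optimum OU process started from a fixed root state equal to the
#' optimum, on a possibly non-ultrametric tree:
#' `V[i, j] = sigma2/(2a) * exp(-a (t_i + t_j - 2 t_ij)) *
#' (1 - exp(-2 a t_ij))` with `t_i` the root-to-tip time and `t_ij` the
#' root-to-MRCA time. The limit `a -> 0` recovers Brownian motion (used
#' directly for very small `a`).
#'
#' @inheritParams bm_loglik
#' @param a attraction strength (per Myr), `>= 0`.
#' @return the log-likelihood.
#' @export
ou_loglik <- function(tree, trait_values, sigma2, root_state, a) {
  stopifnot(is_dated_tree(tree))
  if (a < 0) stop("`a` must be >= 0")
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  if (a < 1e-10) return(bm_loglik(tree, trait_values, sigma2, root_state))
  x <- match_tip_values(tree$phy, trait_values)
  C <- dated_vcv(tree)
  ti <- diag(C)
  V <- sigma2 / (2 * a) * exp(-a * (outer(ti, ti, `+`) - 2 * C)) *
    (1 - exp(-2 * a * C))
  dmvnorm_chol(x, rep(root_state, length(x)), V)
}

#' Directional-trend log-likelihood
#'
#' Brownian motion with a drift: tip `i` has mean
#' `root_state + beta * T_i`, `T_i` its root-to-tip duration, with BM
#' covariance. On an ultrametric tree all `T_i` are equal and `beta` is
#' unidentifiable from the root state; a warning is raised and the
#' likelihood still returned.
#'
#' @inheritParams bm_loglik
#' @param beta drift in trait units per Myr.
#' @return the log-likelihood.
#' @export
trend_loglik <- function(tree, trait_values, sigma2, root_state, beta) {
  stopifnot(is_dated_tree(tree))
  Ti <- tip_durations(tree)
  if (diff(range(Ti)) < 1e-8 * max(Ti))
    warning("tree is ultrametric: trend beta is confounded with the root state")
  x <- match_tip_values(tree$phy, trait_values)
  pr <- bm_prune(tree, setNames(x, tree$phy$tip.label), sigma2,
                 mean_offset = beta * Ti)
  pr$logf + dnorm(root_state, pr$mu_root, sqrt(sigma2 * pr$v_root), log = TRUE)
}

# Root-to-tip durations in tip order.
tip_durations <- function(tree) {
  tree$root_age - tree$node_age[seq_len(ape::Ntip(tree$phy))]
}

# Phylogenetic covariance structure C (shared path lengths), tip order.
dated_vcv <- function(tree) {
  ape::vcv.phylo(tree$phy)[tree$phy$tip.label, tree$phy$tip.label]
}

# Multivariate normal log density via Cholesky.
dmvnorm_chol <- function(x, mean, V) {
  R <- chol(V)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}
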