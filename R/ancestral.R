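#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates the trait value at every internal node of a dated tree by
#' Gaussian belief propagation: an upward (pruning) pass collects each
#' subtree's information, a downward pass conditions each node on the rest
#' of the tree. The point estimates equal the rerooted GLS
#' (weighted-average) estimator, are independent of `sigma2`, and the root
#' estimate is the GLS generalized (phylogenetic) mean.
#'
#' @param tree a [dated_tree] with positive branch durations.
#' @param trait_values named numeric, one value per tip.
#' @return a data frame (one row per internal node) with columns `node`
#'   (ape node id), `value` (estimated trait) and `age_ma` (node age).
#' @export
ancestral_states <- function(tree, trait_values) {
  stopifnot(is_dated_tree(tree))
  phy <- tree$phy
  x <- match_tip_values(phy, trait_values)
  n_tip <- ape::Ntip(phy)
  n_all <- n_tip + phy$Nnode
  eo <- reorder_edges(phy)
  edge <- eo$edge; len <- eo$edge.length
  root <- edge[nrow(edge), 1L]

  # upward messages: distribution of each node's value given its subtree
  up_m <- numeric(n_all); up_v <- numeric(n_all)
  up_m[seq_len(n_tip)] <- x
  combine <- function(ms, vs) {
    w <- 1 / vs
    v <- 1 / sum(w)
    c(sum(ms * w) * v, v)
  }
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  up_at <- function(node) {
    ke <- kids[[as.character(node)]]
    cm <- combine(up_m[edge[ke, 2L]], up_v[edge[ke, 2L]] + len[ke])
    up_m[node] <<- cm[1L]; up_v[node] <<- cm[2L]
  }
  # postorder guarantees a node's subtree edges precede its stem edge
  for (e in seq_len(nrow(edge)))
    if (edge[e, 2L] > n_tip) up_at(edge[e, 2L])
  up_at(root)

  # downward messages: information from outside each node's subtree
  down_m <- rep(NA_real_, n_all); down_v <- rep(Inf, n_all)
  est <- numeric(n_all)
  est[root] <- up_m[root]
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    par <- edge[e, 1L]; chi <- edge[e, 2L]
    sibs <- setdiff(kids[[as.character(par)]], e)
    ms <- up_m[edge[sibs, 2L]]; vs <- up_v[edge[sibs, 2L]] + len[sibs]
    if (is.finite(down_v[par])) {
      ms <- c(ms, down_m[par]); vs <- c(vs, down_v[par])
    }
    cm <- combine(ms, vs)
    down_m[chi] <- cm[1L]; down_v[chi] <- cm[2L] + len[e]
    if (chi > n_tip) {
      ke <- kids[[as.character(chi)]]
      cm2 <- combine(c(up_m[edge[ke, 2L]], down_m[chi]),
                     c(up_v[edge[ke, 2L]] + len[ke], down_v[chi]))
      est[chi] <- cm2[1L]
    }
  }

  nodes <- (n_tip + 1L):n_all
  data.frame(node = nodes, value = est[nodes],
             age_ma = tree$node_age[nodes])
}
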