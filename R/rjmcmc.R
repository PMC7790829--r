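#' Reversible-jump MCMC for the variable-rates model
#'
#' Brownian motion whose rate is perturbed by a set of multiplicative
#' scalars, each attached to a branch or to a whole clade (stem branch
#' plus all descendant branches). The effective duration of a branch is
#' its true duration times the product of every scalar covering it. The
#' sampler jumps between numbers of scalars: the assignment count has a
#' Poisson prior (mean `spec$rj$poisson_mean`, truncated at the number of
#' assignable nodes), assigned nodes are uniform subsets, scopes are
#' branch/clade with equal probability, and each scalar is log-normal
#' (`sdlog = spec$rj$scalar_sdlog`). Birth/death proposals draw from the
#' prior, so acceptance ratios reduce to the likelihood ratio times the
#' Poisson count ratio; scalar updates are random walks on the log scale.
#'
#' @inheritParams mcmc_fit
#' @param spec a [model_spec()] with `kind = "variable_rates"`.
#' @return a list with elements `fit` (a `model_fit` for `sigma2`, `alpha`
#'   and `n_rates`) and `vr` (class `variable_rates`: `edge_mean_scalar`,
#'   posterior mean scalar per edge in `tree$phy$edge` order;
#'   `n_rates_mean`; `draws` of the assignment count).
#' @export
rjmcmc_variable_rates <- function(tree, trait_values, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$kind != "variable_rates")
    stop("spec$kind must be 'variable_rates'")
  set.seed(spec$seed)
  res <- run_rj_chain(tree, trait_values, spec, beta = 1)
  fit <- finish_fit(list(draws = res$draws, acceptance = res$acceptance),
                    tree, trait_values, spec)
  vr <- structure(list(edge_mean_scalar = res$edge_mean_scalar,
                       n_rates_mean = res$n_rates_mean,
                       draws = res$draws$n_rates),
                  class = "variable_rates")
  list(fit = fit, vr = vr)
}

#' @export
print.variable_rates <- function(x, ...) {
  cat(sprintf(
    "Variable-rates posterior: %.2f rate scalars on average; per-branch\n",
    x$n_rates_mean))
  cat(sprintf("  posterior mean scalars span [%.3g, %.3g]\n",
              min(x$edge_mean_scalar), max(x$edge_mean_scalar)))
  invisible(x)
}

# Core RJ kernel, shared with the stepping-stone sampler (beta tempers the
# likelihood). Returns thinned draws plus per-edge posterior mean scalars.
run_rj_chain <- function(tree, trait_values, spec, beta = 1,
                         iterations = spec$iterations,
                         burn_in = spec$burn_in,
                         thinning = spec$thinning,
                         init = NULL, collect_edges = TRUE) {
  phy <- tree$phy
  x <- match_tip_values(phy, trait_values)
  n_tip <- ape::Ntip(phy)
  eo <- reorder_edges(phy)
  L0 <- eo$edge.length
  n_edge <- length(L0)

  # edges covered by each assignable node (every node except the root):
  # branch scope = stem edge; clade scope = stem edge + subtree edges
  stem_of <- integer(n_tip + phy$Nnode)
  stem_of[eo$edge[, 2L]] <- seq_len(n_edge)
  below <- vector("list", n_tip + phy$Nnode)
  for (e in seq_len(n_edge)) {
    chi <- eo$edge[e, 2L]
    kids <- eo$edge[eo$edge[, 1L] == chi, 2L]
    below[[chi]] <- c(e, unlist(below[kids]))
  }
  nodes <- eo$edge[, 2L]            # one assignable node per edge
  N <- length(nodes)
  lam <- spec$rj$poisson_mean
  sdlog <- spec$rj$scalar_sdlog

  defs <- make_param_defs("random_walk", tree, trait_values, spec$priors,
                          spec$fixed)
  theta <- list(log_sigma2 = log(max(var(x) / max(tip_durations(tree)),
                                     1e-6)),
                alpha = mean(x))
  assign_node <- integer(0); assign_scope <- integer(0)
  assign_logr <- numeric(0)
  if (!is.null(init)) {
    theta <- init$theta
    assign_node <- init$assign_node; assign_scope <- init$assign_scope
    assign_logr <- init$assign_logr
  }

  edge_logr <- function(node, scope, logr) {
    lr <- numeric(n_edge)
    for (j in seq_along(node)) {
      ed <- if (scope[j] == 1L) stem_of[node[j]] else below[[node[j]]]
      lr[ed] <- lr[ed] + logr[j]
    }
    lr
  }
  ll_of <- function(theta, lr) {
    out <- bm_prune_cpp(eo$edge, L0, exp(lr), n_tip, x,
                        exp(theta$log_sigma2), 0)
    out[4L] + dnorm(theta$alpha, out[2L],
                    sqrt(exp(theta$log_sigma2) * out[3L]), log = TRUE)
  }

  lr <- edge_logr(assign_node, assign_scope, assign_logr)
  ll <- ll_of(theta, lr)
  sds <- c(log_sigma2 = 0.5, alpha = defs$alpha$sd, logr = 0.5)
  acc <- tries <- c(log_sigma2 = 0, alpha = 0, logr = 0,
                    birth = 0, death = 0)

  n_keep <- floor((iterations - burn_in) / thinning)
  draws <- matrix(NA_real_, n_keep, 4L,
                  dimnames = list(NULL, c("log_sigma2", "alpha", "n_rates",
                                          "loglik")))
  edge_sum <- numeric(n_edge); kept <- 0L

  for (it in seq_len(iterations)) {
    for (p in c("log_sigma2", "alpha")) {
      prop <- theta
      prop[[p]] <- theta[[p]] + rnorm(1, 0, sds[[p]])
      lp_new <- defs[[p]]$logdens(prop[[p]])
      lp_old <- defs[[p]]$logdens(theta[[p]])
      tries[[p]] <- tries[[p]] + 1
      if (is.finite(lp_new)) {
        ll_new <- ll_of(prop, lr)
        if (log(runif(1)) < beta * (ll_new - ll) + lp_new - lp_old) {
          theta <- prop; ll <- ll_new; acc[[p]] <- acc[[p]] + 1
        }
      }
    }
    k <- length(assign_node)
    u <- runif(1)
    if (u < 0.25) {                               # birth
      free <- setdiff(nodes, assign_node)
      if (length(free)) {
        nd <- free[sample.int(length(free), 1L)]
        sc <- sample.int(2L, 1L)
        r0 <- rnorm(1, 0, sdlog)
        lr_new <- lr
        ed <- if (sc == 1L) stem_of[nd] else below[[nd]]
        lr_new[ed] <- lr_new[ed] + r0
        ll_new <- ll_of(theta, lr_new)
        tries[["birth"]] <- tries[["birth"]] + 1
        if (log(runif(1)) < beta * (ll_new - ll) + log(lam) - log(k + 1)) {
          assign_node <- c(assign_node, nd)
          assign_scope <- c(assign_scope, sc)
          assign_logr <- c(assign_logr, r0)
          lr <- lr_new; ll <- ll_new; acc[["birth"]] <- acc[["birth"]] + 1
        }
      }
    } else if (u < 0.5) {                         # death
      if (k > 0) {
        j <- sample.int(k, 1L)
        lr_new <- lr
        ed <- if (assign_scope[j] == 1L) stem_of[assign_node[j]] else
          below[[assign_node[j]]]
        lr_new[ed] <- lr_new[ed] - assign_logr[j]
        ll_new <- ll_of(theta, lr_new)
        tries[["death"]] <- tries[["death"]] + 1
        if (log(runif(1)) < beta * (ll_new - ll) + log(k) - log(lam)) {
          assign_node <- assign_node[-j]
          assign_scope <- assign_scope[-j]
          assign_logr <- assign_logr[-j]
          lr <- lr_new; ll <- ll_new; acc[["death"]] <- acc[["death"]] + 1
        }
      }
    } else if (k > 0) {                           # modify a scalar
      j <- sample.int(k, 1L)
      d0 <- rnorm(1, 0, sds[["logr"]])
      lr_new <- lr
      ed <- if (assign_scope[j] == 1L) stem_of[assign_node[j]] else
        below[[assign_node[j]]]
      lr_new[ed] <- lr_new[ed] + d0
      ll_new <- ll_of(theta, lr_new)
      tries[["logr"]] <- tries[["logr"]] + 1
      pr_ratio <- dnorm(assign_logr[j] + d0, 0, sdlog, log = TRUE) -
        dnorm(assign_logr[j], 0, sdlog, log = TRUE)
      if (log(runif(1)) < beta * (ll_new - ll) + pr_ratio) {
        assign_logr[j] <- assign_logr[j] + d0
        lr <- lr_new; ll <- ll_new; acc[["logr"]] <- acc[["logr"]] + 1
      }
    }
    if (it <= burn_in && it %% 200 == 0) {
      nm3 <- c("log_sigma2", "alpha", "logr")
      rate <- acc[nm3] / pmax(tries[nm3], 1)
      sds <- sds * exp(pmin(pmax(rate - 0.3, -0.5), 0.5))
      acc[nm3] <- 0; tries[nm3] <- 0
    }
    if (it > burn_in && (it - burn_in) %% thinning == 0 && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- c(theta$log_sigma2, theta$alpha,
                         length(assign_node), ll)
      if (collect_edges) edge_sum <- edge_sum + exp(lr)
    }
  }

  # map postorder edge means back to the tree's native edge order
  idx <- match(paste(phy$edge[, 1L], phy$edge[, 2L]),
               paste(eo$edge[, 1L], eo$edge[, 2L]))
  d <- as.data.frame(draws[seq_len(kept), , drop = FALSE])
  list(draws = d, acceptance = acc / pmax(tries, 1),
       n_rates_mean = mean(d$n_rates),
       edge_mean_scalar = (edge_sum / max(kept, 1))[idx],
       final = list(theta = theta, assign_node = assign_node,
                    assign_scope = assign_scope, assign_logr = assign_logr))
}

#' Export a rate-scaled tree
#'
#' Writes the tree in Newick format with branch lengths replaced by the
#' posterior mean rate scalars from a variable-rates fit, the substrate of
#' rate-on-tree figures.
#'
#' @param tree a [dated_tree].
#' @param vr a `variable_rates` object from [rjmcmc_variable_rates()], or
#'   a numeric vector of per-edge scalars in `tree$phy$edge` order.
#' @param path output Newick file path.
#' @return invisibly, the rate-scaled `phylo`.
#' @export
export_rate_tree <- function(tree, vr, path) {
  stopifnot(is_dated_tree(tree))
  scal <- if (inherits(vr, "variable_rates")) vr$edge_mean_scalar else vr
  if (length(scal) != nrow(tree$phy$edge))
    stop("need one scalar per branch")
  phy <- tree$phy
  phy$edge.length <- as.numeric(scal)
  ape::write.tree(phy, file = path)
  invisible(phy)
}
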