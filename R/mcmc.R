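#' Specify a trait-evolution model and its MCMC settings
#'
#' Seven models of continuous trait evolution are supported: a Brownian
#' random walk (the null), Pagel's lambda, delta and kappa transformations,
#' a single-optimum Ornstein-Uhlenbeck process, a directional trend, and a
#' reversible-jump variable-rates model (see
#' [rjmcmc_variable_rates()]). Default chain settings are 2,000,000
#' iterations with the first 10,000 discarded as burn-in, thinning every
#' 1,000; all are configurable for desk-scale runs.
#'
#' Default priors: `log(sigma2) ~ U(-20, 20)`; root state `alpha ~ U(data
#' range +/- 3 SD)`; `lambda ~ U(0, 1)`; `delta, kappa ~ U(0, 3)`;
#' OU attraction `a ~ U(0, 5/tree depth)`; trend
#' `beta ~ U(+/- 10 SD / tree depth)`. Override any with `priors`
#' (uniform: `c(lo, hi)`; for `alpha` a `list(mean=, sd=)` normal prior is
#' also accepted). `fixed` pins parameters at given values (e.g.
#' `list(sigma2 = 1)`), removing them from the chain.
#'
#' @param kind one of `"random_walk"`, `"lambda"`, `"delta"`, `"kappa"`,
#'   `"ou"`, `"trend"`, `"variable_rates"`.
#' @param iterations,burn_in,thinning chain length, burn-in, thinning
#'   interval (`iterations > burn_in >= 0`).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param priors,fixed named lists; see Details.
#' @param rj for the variable-rates model: list with `poisson_mean`
#'   (prior mean number of rate-scalar assignments, default 2) and
#'   `scalar_sdlog` (log-normal sd of a scalar, default 1.5).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(kind = c("random_walk", "lambda", "delta", "kappa",
                                "ou", "trend", "variable_rates"),
                       iterations = 2e6, burn_in = 1e4, thinning = 1e3,
                       seed = 1, priors = list(), fixed = list(),
                       rj = list()) {
  kind <- match.arg(kind)
  if (iterations <= burn_in || burn_in < 0)
    stop("need iterations > burn_in >= 0")
  rj <- utils::modifyList(list(poisson_mean = 2, scalar_sdlog = 1.5), rj)
  structure(list(kind = kind, iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = seed,
                 priors = priors, fixed = fixed, rj = rj),
            class = "model_spec")
}

transform_param_name <- function(kind) {
  switch(kind, lambda = "lambda", delta = "delta", kappa = "kappa",
         ou = "a", trend = "beta", NULL)
}

# Fast likelihood closure: theta is a named vector with log_sigma2, alpha
# and (optionally) the transform parameter. All tree geometry is
# precomputed; each call is one C++ pruning pass (dense algebra for OU).
make_loglik <- function(tree, trait_values, kind) {
  phy <- tree$phy
  x <- match_tip_values(phy, trait_values)
  n_tip <- ape::Ntip(phy)
  eo <- reorder_edges(phy)
  L0 <- eo$edge.length
  ones <- rep(1, length(L0))
  depth <- tree$root_age - tree$node_age
  dpar <- depth[eo$edge[, 1L]]
  dchi <- depth[eo$edge[, 2L]]
  tip_edge <- eo$edge[, 2L] <= n_tip
  Ti <- tip_durations(tree)
  tp <- transform_param_name(kind)

  if (kind == "ou") {
    C <- dated_vcv(tree)
    ti <- diag(C)
    tsum <- outer(ti, ti, `+`)
    return(function(theta) {
      s2 <- exp(theta[["log_sigma2"]]); a <- theta[["a"]]
      if (a < 1e-10) {
        out <- bm_prune_cpp(eo$edge, L0, ones, n_tip, x, s2, 0)
        return(out[4L] + dnorm(theta[["alpha"]], out[2L],
                               sqrt(s2 * out[3L]), log = TRUE))
      }
      V <- s2 / (2 * a) * exp(-a * (tsum - 2 * C)) * (1 - exp(-2 * a * C))
      dmvnorm_chol(x, rep(theta[["alpha"]], n_tip), V)
    })
  }

  function(theta) {
    s2 <- exp(theta[["log_sigma2"]])
    len <- L0
    xx <- x
    if (!is.null(tp) && kind != "trend") {
      p <- theta[[tp]]
      len <- switch(kind,
        kappa  = L0^p,
        delta  = dchi^p - dpar^p,
        lambda = { l <- L0 * p; l[tip_edge] <- dchi[tip_edge] -
                     p * dpar[tip_edge]; l })
      if (any(len < 0)) return(-Inf)
    } else if (kind == "trend") {
      xx <- x - theta[["beta"]] * Ti
    }
    out <- bm_prune_cpp(eo$edge, len, ones, n_tip, xx, s2, 0)
    out[4L] + dnorm(theta[["alpha"]], out[2L], sqrt(s2 * out[3L]),
                    log = TRUE)
  }
}

# Parameter definitions: bounds, prior log-density and prior sampler.
make_param_defs <- function(kind, tree, trait_values, priors, fixed) {
  x <- match_tip_values(tree$phy, trait_values)
  sdx <- max(sd(x), 1e-8)
  depth <- max(tip_durations(tree))
  defs <- list()

  unif <- function(lo, hi) list(
    lower = lo, upper = hi,
    logdens = function(v) ifelse(v >= lo & v <= hi, -log(hi - lo), -Inf),
    sample = function() runif(1, lo, hi))

  if (is.null(fixed$sigma2)) {
    rng <- priors$log_sigma2 %||% c(-20, 20)
    defs$log_sigma2 <- c(unif(rng[1], rng[2]), list(init = NA, sd = 0.5))
  }
  if (is.null(fixed$alpha)) {
    ap <- priors$alpha
    if (is.list(ap)) {
      defs$alpha <- list(lower = -Inf, upper = Inf,
        logdens = function(v) dnorm(v, ap$mean, ap$sd, log = TRUE),
        sample = function() rnorm(1, ap$mean, ap$sd),
        init = ap$mean, sd = sdx / 2)
    } else {
      rng <- ap %||% c(min(x) - 3 * sdx, max(x) + 3 * sdx)
      defs$alpha <- c(unif(rng[1], rng[2]),
                      list(init = mean(x), sd = sdx / 2))
    }
  }
  tp <- transform_param_name(kind)
  if (!is.null(tp) && is.null(fixed[[tp]])) {
    rng <- priors[[tp]] %||% switch(kind,
      lambda = c(0, 1), delta = c(0, 3), kappa = c(0, 3),
      ou = c(0, 5 / depth),
      trend = c(-10 * sdx / depth, 10 * sdx / depth))
    init <- switch(kind, lambda = 0.5, delta = 1, kappa = 1,
                   ou = rng[2] / 10, trend = 0)
    defs[[tp]] <- c(unif(rng[1], rng[2]),
                    list(init = init, sd = diff(rng) / 20))
  }
  defs
}

# Generic component-wise Metropolis-Hastings on a tempered posterior
# (beta * loglik + logprior). Proposal scales adapt during burn-in toward
# ~30% acceptance. Returns thinned draws and diagnostics.
run_chain <- function(loglik_fn, defs, fixed_theta, iterations, burn_in,
                      thinning, beta = 1, adapt = TRUE) {
  nm <- names(defs)
  theta <- fixed_theta
  for (p in nm) theta[[p]] <- defs[[p]]$init
  if (!is.null(defs$log_sigma2) && is.na(theta[["log_sigma2"]]))
    theta[["log_sigma2"]] <- 0
  lp <- sum(vapply(nm, function(p) defs[[p]]$logdens(theta[[p]]), 0))
  if (!is.finite(lp)) {           # init outside prior support: resample
    for (p in nm) theta[[p]] <- defs[[p]]$sample()
    lp <- sum(vapply(nm, function(p) defs[[p]]$logdens(theta[[p]]), 0))
  }
  ll <- loglik_fn(theta)
  sds <- vapply(defs, `[[`, 0, "sd")
  acc <- tries <- setNames(numeric(length(nm)), nm)

  n_keep <- floor((iterations - burn_in) / thinning)
  draws <- matrix(NA_real_, n_keep, length(nm) + 1L,
                  dimnames = list(NULL, c(nm, "loglik")))
  kept <- 0L
  for (it in seq_len(iterations)) {
    for (p in nm) {
      prop <- theta
      prop[[p]] <- theta[[p]] + rnorm(1, 0, sds[[p]])
      lp_p <- defs[[p]]$logdens(prop[[p]])
      if (!is.finite(lp_p)) { tries[[p]] <- tries[[p]] + 1; next }
      lp_new <- lp - defs[[p]]$logdens(theta[[p]]) + lp_p
      ll_new <- loglik_fn(prop)
      tries[[p]] <- tries[[p]] + 1
      if (is.finite(ll_new) &&
          log(runif(1)) < beta * (ll_new - ll) + lp_new - lp) {
        theta <- prop; ll <- ll_new; lp <- lp_new
        acc[[p]] <- acc[[p]] + 1
      }
    }
    if (adapt && it <= burn_in && it %% 200 == 0) {
      rate <- acc / pmax(tries, 1)
      sds <- sds * exp(pmin(pmax(rate - 0.3, -0.5), 0.5))
      acc[] <- 0; tries[] <- 0
    }
    if (it > burn_in && (it - burn_in) %% thinning == 0 && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- c(unlist(theta[nm]), ll)
    }
  }
  list(draws = as.data.frame(draws[seq_len(kept), , drop = FALSE]),
       acceptance = acc / pmax(tries, 1), proposal_sd = sds,
       final = theta)
}

#' Fit a trait-evolution model by MCMC
#'
#' Metropolis-Hastings sampling of (`sigma2`, root state `alpha`, and the
#' model's transform parameter) under the priors in the [model_spec()].
#' Proposal scales adapt during burn-in. The retained log-likelihood trace
#' is summarized by a flatness diagnostic (first-half vs second-half mean,
#' in posterior-SD units) mirroring the practice of inspecting the
#' likelihood profile for a uniform band as a convergence check.
#'
#' @param tree a [dated_tree].
#' @param trait_values named numeric, one value per tip.
#' @param spec a [model_spec()] (not `variable_rates`; see
#'   [rjmcmc_variable_rates()]).
#' @return an object of class `model_fit`: posterior summary table
#'   (`summary`), thinned `draws`, `alpha_mle` (GLS phylogenetic mean at
#'   posterior-mean parameters), acceptance rates, warning flags, and
#'   `log_marginal_lik` (`NA` until [stepping_stone_logZ()] fills it).
#' @export
mcmc_fit <- function(tree, trait_values, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$kind == "variable_rates")
    stop("use rjmcmc_variable_rates() for the variable-rates model")
  set.seed(spec$seed)
  loglik <- make_loglik(tree, trait_values, spec$kind)
  defs <- make_param_defs(spec$kind, tree, trait_values, spec$priors,
                          spec$fixed)
  fixed_theta <- as.list(spec$fixed)
  if (!is.null(fixed_theta$sigma2)) {
    fixed_theta$log_sigma2 <- log(fixed_theta$sigma2)
    fixed_theta$sigma2 <- NULL
  }
  # data-informed init for log_sigma2 (contrast variance scale)
  if (!is.null(defs$log_sigma2)) {
    x <- match_tip_values(tree$phy, trait_values)
    defs$log_sigma2$init <-
      log(max(var(x) / max(tip_durations(tree)), 1e-6))
  }
  res <- run_chain(loglik, defs, fixed_theta, spec$iterations,
                   spec$burn_in, spec$thinning)
  finish_fit(res, tree, trait_values, spec)
}

finish_fit <- function(res, tree, trait_values, spec) {
  d <- res$draws
  if (!is.null(d$log_sigma2)) d$sigma2 <- exp(d$log_sigma2)
  pars <- setdiff(names(d), c("log_sigma2", "loglik"))
  summ <- do.call(rbind, lapply(pars, function(p) data.frame(
    parameter = p, mean = mean(d[[p]]), median = median(d[[p]]),
    q2.5 = quantile(d[[p]], 0.025), q97.5 = quantile(d[[p]], 0.975))))
  rownames(summ) <- NULL

  ll <- d$loglik
  half <- length(ll) %/% 2
  flat <- if (half >= 2)
    abs(mean(ll[seq_len(half)]) - mean(ll[-seq_len(half)])) /
      max(sd(ll), 1e-12) else NA_real_

  s2_hat <- if (!is.null(d$sigma2)) mean(d$sigma2) else spec$fixed$sigma2
  pr <- bm_prune(tree, trait_values, s2_hat)
  warn <- character()
  if (any(res$acceptance < 0.05 | res$acceptance > 0.95))
    warn <- c(warn, "extreme acceptance rate after adaptation")
  if (is.finite(flat) && flat > 1)
    warn <- c(warn, "log-likelihood trace not flat; inspect convergence")

  structure(list(kind = spec$kind, summary = summ, draws = d,
                 alpha_mle = pr$mu_root, acceptance = res$acceptance,
                 trace_flatness = flat, warnings = warn,
                 log_marginal_lik = NA_real_, spec = spec),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Trait-evolution model fit: %s (%d retained draws)\n",
              x$kind, nrow(x$draws)))
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.na(x$log_marginal_lik))
    cat(sprintf("log marginal likelihood: %.3f\n", x$log_marginal_lik))
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

fit_param_mean <- function(fit, name) {
  s <- fit$summary
  if (!name %in% s$parameter) return(NA_real_)
  s$mean[s$parameter == name]
}
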