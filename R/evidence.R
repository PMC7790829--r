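#' Stepping-stone marginal likelihood
#'
#' Estimates the log marginal likelihood (evidence) of a trait-evolution
#' model by path sampling from prior to posterior: inverse temperatures
#' `beta_j = (j/K)^(1/0.3)` (a schedule stretched toward the prior), a
#' short MCMC run per stone warm-started from the previous stone, and the
#' standard stepping-stone ratio estimator per interval. The Monte-Carlo
#' standard error is the delta-method combination of per-stone errors
#' (computed from the raw draws, so it understates error when stones mix
#' slowly; lengthen `per_stone_iters` for publication-grade runs).
#'
#' @inheritParams mcmc_fit
#' @param spec a [model_spec()] of any kind, including `variable_rates`.
#' @param n_stones number of stones `K` (at least 8).
#' @param per_stone_iters MCMC iterations retained per stone.
#' @return list with `logZ`, `se`, `betas` and per-stone log ratios
#'   (`log_ratios`).
#' @export
stepping_stone_logZ <- function(tree, trait_values, spec, n_stones = 48,
                                per_stone_iters = 1000) {
  stopifnot(inherits(spec, "model_spec"))
  if (n_stones < 8) stop("`n_stones` must be >= 8")
  set.seed(spec$seed)
  K <- n_stones
  betas <- (0:K / K)^(1 / 0.3)

  rj <- spec$kind == "variable_rates"
  defs <- NULL; loglik <- NULL; fixed_theta <- NULL
  if (!rj) {
    loglik <- make_loglik(tree, trait_values, spec$kind)
    defs <- make_param_defs(spec$kind, tree, trait_values, spec$priors,
                            spec$fixed)
    fixed_theta <- as.list(spec$fixed)
    if (!is.null(fixed_theta$sigma2)) {
      fixed_theta$log_sigma2 <- log(fixed_theta$sigma2)
      fixed_theta$sigma2 <- NULL
    }
  }

  log_ratios <- numeric(K); se2 <- numeric(K)
  state <- NULL
  for (j in seq_len(K)) {
    b_lo <- betas[j]; b_hi <- betas[j + 1L]
    if (!rj && b_lo == 0) {
      # exact independent sampling from the prior
      ll <- replicate(per_stone_iters, {
        th <- fixed_theta
        for (p in names(defs)) th[[p]] <- defs[[p]]$sample()
        loglik(th)
      })
    } else if (!rj) {
      burn <- max(100L, per_stone_iters %/% 5L)
      if (!is.null(state))
        for (p in names(defs)) defs[[p]]$init <- state[[p]]
      res <- run_chain(loglik, defs, fixed_theta,
                       iterations = per_stone_iters + burn,
                       burn_in = burn, thinning = 1L, beta = b_lo)
      state <- res$final
      ll <- res$draws$loglik
    } else {
      burn <- max(200L, per_stone_iters %/% 5L)
      res <- run_rj_chain(tree, trait_values, spec, beta = b_lo,
                          iterations = per_stone_iters + burn,
                          burn_in = burn, thinning = 1L, init = state,
                          collect_edges = FALSE)
      state <- res$final
      ll <- res$draws$loglik
    }
    w <- (b_hi - b_lo) * ll
    m <- max(w)
    a <- exp(w - m)
    r_hat <- mean(a)
    if (!is.finite(m) || !is.finite(r_hat) || r_hat <= 0)
      stop("non-finite stone average at stone ", j,
           " (beta = ", signif(b_lo, 4), ")")
    log_ratios[j] <- m + log(r_hat)
    se2[j] <- var(a) / (length(a) * r_hat^2)
  }
  list(logZ = sum(log_ratios), se = sqrt(sum(se2)), betas = betas,
       log_ratios = log_ratios)
}

#' Harmonic-mean marginal likelihood
#'
#' The harmonic-mean estimator computed from a fit's retained
#' log-likelihood trace. Provided for fidelity checks against legacy
#' workflows only: the estimator is notoriously unstable and
#' [stepping_stone_logZ()] should be preferred for inference.
#'
#' @param fit a `model_fit` (or any object with `draws$loglik`).
#' @return the harmonic-mean estimate of the log marginal likelihood.
#' @export
harmonic_mean_logZ <- function(fit) {
  ll <- fit$draws$loglik
  if (is.null(ll) || !length(ll)) stop("fit carries no log-likelihood draws")
  m <- max(-ll)
  -(m + log(mean(exp(-ll - m))))
}

#' Log Bayes factor between two fitted models
#'
#' `2 * (logZ_model - logZ_null)`, the scale on which a value above 2 is
#' conventionally read as significant support for the model over the
#' null.
#'
#' @param fit_model,fit_null `model_fit` objects whose `log_marginal_lik`
#'   has been filled in (see [stepping_stone_logZ()]), or bare numeric log
#'   marginal likelihoods.
#' @return the log Bayes factor (numeric scalar).
#' @seealso [compare_models()], [weighted_alpha()]
#' @export
log_bayes_factor <- function(fit_model, fit_null) {
  z <- function(f) {
    if (is.numeric(f)) return(f)
    if (is.na(f$log_marginal_lik))
      stop("fit has no log_marginal_lik; run stepping_stone_logZ() first")
    f$log_marginal_lik
  }
  2 * (z(fit_model) - z(fit_null))
}

#' Model comparison table
#'
#' Builds the per-model summary used for reporting: log Bayes factor
#' against the random-walk null, significance flag (log BF > `threshold`),
#' posterior mean `sigma2`, root state `alpha` and the model's transform
#' statistic.
#'
#' @param fits named list of `model_fit` objects with marginal
#'   likelihoods; names are used as model labels.
#' @param fit_null the random-walk `model_fit` (with marginal likelihood).
#' @param threshold significance threshold on the log-Bayes-factor scale.
#' @return data frame with columns `model`, `log_bf`, `significant`,
#'   `sigma2`, `alpha`, `statistic`.
#' @export
compare_models <- function(fits, fit_null, threshold = 2) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    stat_name <- transform_param_name(f$kind) %||%
      (if (f$kind == "variable_rates") "n_rates" else NA_character_)
    data.frame(model = nm,
               log_bf = log_bayes_factor(f, fit_null),
               sigma2 = fit_param_mean(f, "sigma2"),
               alpha = fit_param_mean(f, "alpha"),
               statistic = if (is.na(stat_name)) NA_real_
                           else fit_param_mean(f, stat_name))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$log_bf > threshold
  out[, c("model", "log_bf", "significant", "sigma2", "alpha", "statistic")]
}

#' Bayes-factor-weighted mean root state
#'
#' The phylogenetically adjusted mean trait value averaged over the models
#' that significantly outperform the random-walk null, each weighted by
#' its log Bayes factor: `sum(logBF_m * alpha_m) / sum(logBF_m)`.
#'
#' @param comparisons a data frame with columns `log_bf` and `alpha`
#'   (e.g. from [compare_models()]), or a `model_comparison`-like list.
#' @param threshold models with `log_bf > threshold` enter the average.
#' @return the weighted mean `alpha` (same scale as the trait, typically
#'   PC-1 units).
#' @export
#' @examples
#' tab <- data.frame(log_bf = c(22.200, 5.183, 169.658),
#'                   alpha  = c(-14.337, -11.823, -14.148))
#' weighted_alpha(tab)  # -14.108
weighted_alpha <- function(comparisons, threshold = 2) {
  if (!all(c("log_bf", "alpha") %in% names(comparisons)))
    stop("`comparisons` needs columns log_bf and alpha")
  keep <- comparisons$log_bf > threshold
  if (!any(keep))
    stop("no model significantly outperforms the null; ",
         "report the null model's alpha instead")
  w <- comparisons$log_bf[keep]
  a <- comparisons$alpha[keep]
  sum(w * a) / sum(w)
}
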