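#' Time series of body size, disparity and evolutionary rate
#'
#' Bins a trait (and optionally per-branch rate scalars) through time
#' under three reconstruction methods:
#' * `"empirical"`: a taxon contributes to every bin its observed
#'   `[FAD, LAD]` range intersects;
#' * `"ghost"`: ranges are extended back to the age of each tip's parent
#'   node on the dated tree (ghost ranges);
#' * `"ghost+ancestors"`: additionally, each internal node's estimated
#'   ancestral state (see [ancestral_states()]) contributes to the single
#'   bin containing its node age (or to every bin its stem branch spans,
#'   with `ancestor_span = "branch"`).
#'
#' Statistics: `"mean"`, `"variance"` (sample variance, n-1 denominator,
#' missing for bins with fewer than 2 items) and `"mean_rate"` (mean
#' posterior rate scalar over the branches intersecting the bin, or over
#' the terminal branches of the taxa present with
#' `rate_membership = "taxa"`).
#'
#' @param tree a [dated_tree].
#' @param occurrences occurrence table covering the tree's tips.
#' @param trait_values named numeric per-tip trait (PC-1 scores).
#' @param bins bin table from [myr_bins()] or [stage_bins()].
#' @param method reconstruction method (see Details).
#' @param statistic `"mean"`, `"variance"` or `"mean_rate"`.
#' @param rate_scalars per-edge scalars (`tree$phy$edge` order) or a
#'   `variable_rates` object; required for `"mean_rate"`.
#' @param ancestors optional precomputed [ancestral_states()] table.
#' @param ancestor_span `"point"` (default) or `"branch"`.
#' @param rate_membership `"branches"` (default) or `"taxa"`.
#' @return a `binned_series` data frame: `bin_old_ma`, `bin_young_ma`,
#'   `n`, `value`, `method`, `statistic`. Empty bins carry `NA`, never 0.
#' @export
build_series <- function(tree, occurrences, trait_values, bins,
                         method = c("empirical", "ghost",
                                    "ghost+ancestors"),
                         statistic = c("mean", "variance", "mean_rate"),
                         rate_scalars = NULL, ancestors = NULL,
                         ancestor_span = c("point", "branch"),
                         rate_membership = c("branches", "taxa")) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  vals <- bin_member_values(tree, occurrences, trait_values, bins, method,
                            statistic, rate_scalars, ancestors,
                            match.arg(ancestor_span),
                            match.arg(rate_membership))
  out <- data.frame(bin_old_ma = bins$old_ma, bin_young_ma = bins$young_ma,
                    n = vapply(vals, length, 0L),
                    value = vapply(vals, apply_statistic, 0,
                                   statistic = statistic),
                    method = method, statistic = statistic)
  class(out) <- c("binned_series", "data.frame")
  out
}

apply_statistic <- function(v, statistic) {
  if (statistic == "variance") {
    if (length(v) < 2) return(NA_real_)
    return(var(v))
  }
  if (!length(v)) return(NA_real_)
  mean(v)
}

# Per-bin member values for every method/statistic combination; the single
# source of truth used by build_series() and bootstrap_envelope().
bin_member_values <- function(tree, occurrences, trait_values, bins,
                              method, statistic, rate_scalars = NULL,
                              ancestors = NULL, ancestor_span = "point",
                              rate_membership = "branches") {
  stopifnot(is_dated_tree(tree))
  validate_bins(bins)
  if (inherits(rate_scalars, "variable_rates"))
    rate_scalars <- rate_scalars$edge_mean_scalar

  if (statistic == "mean_rate") {
    if (is.null(rate_scalars)) stop("mean_rate needs `rate_scalars`")
    if (length(rate_scalars) != nrow(tree$phy$edge))
      stop("need one rate scalar per branch")
    if (rate_membership == "branches") {
      return(lapply(seq_len(nrow(bins)), function(i) {
        e <- lineages_in_bin(tree, bin = c(bins$old_ma[i], bins$young_ma[i]),
                             mode = "branches")
        rate_scalars[e]
      }))
    }
    tip_edge <- match(seq_len(ape::Ntip(tree$phy)), tree$phy$edge[, 2L])
    tip_rate <- setNames(rate_scalars[tip_edge], tree$phy$tip.label)
    return(lapply(seq_len(nrow(bins)), function(i) {
      taxa <- lineages_in_bin(tree, occurrences,
                              c(bins$old_ma[i], bins$young_ma[i]), "ghost")
      tip_rate[taxa]
    }))
  }

  x <- setNames(match_tip_values(tree$phy, trait_values),
                tree$phy$tip.label)
  mode <- if (method == "empirical") "empirical" else "ghost"
  vals <- lapply(seq_len(nrow(bins)), function(i) {
    taxa <- lineages_in_bin(tree, occurrences,
                            c(bins$old_ma[i], bins$young_ma[i]), mode)
    x[taxa]
  })
  if (method == "ghost+ancestors") {
    anc <- ancestors %||% ancestral_states(tree, trait_values)
    if (ancestor_span == "point") {
      for (i in seq_len(nrow(bins))) {
        hit <- anc$age_ma <= bins$old_ma[i] & anc$age_ma > bins$young_ma[i]
        if (any(hit)) vals[[i]] <- c(vals[[i]], anc$value[hit])
      }
    } else {
      parent <- tree$phy$edge[, 1L][match(anc$node, tree$phy$edge[, 2L])]
      page <- ifelse(is.na(parent), anc$age_ma, tree$node_age[parent])
      for (i in seq_len(nrow(bins))) {
        hit <- page > bins$young_ma[i] & anc$age_ma <= bins$old_ma[i]
        if (any(hit)) vals[[i]] <- c(vals[[i]], anc$value[hit])
      }
    }
  }
  vals
}

#' Bootstrap envelopes for a binned time series
#'
#' Recomputes the per-bin statistic on random subsamples of each bin's
#' members (by default 50% of taxa, drawn without replacement, 100
#' iterations) and reports the replicate median as the point value with
#' interquartile and total-range envelopes. With `resample = "global"` a
#' single taxon subsample is drawn per iteration and applied to every bin
#' (branch-based rate series always resample within bins).
#'
#' @inheritParams build_series
#' @param fraction subsample fraction in (0, 1].
#' @param n_iter number of bootstrap iterations (>= 2).
#' @param seed RNG seed.
#' @param resample `"bin"` (independent per bin) or `"global"`.
#' @return a `binned_series` data frame with columns `bin_old_ma`,
#'   `bin_young_ma`, `n`, `value`, `q25`, `q75`, `min`, `max`, `method`,
#'   `statistic`.
#' @export
bootstrap_envelope <- function(tree, occurrences, trait_values, bins,
                               method = "ghost", statistic = "mean",
                               fraction = 0.5, n_iter = 100, seed = 1,
                               rate_scalars = NULL, ancestors = NULL,
                               ancestor_span = "point",
                               rate_membership = "branches",
                               resample = c("bin", "global")) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  if (n_iter < 2) stop("`n_iter` must be >= 2")
  resample <- match.arg(resample)
  vals <- bin_member_values(tree, occurrences, trait_values, bins, method,
                            statistic, rate_scalars, ancestors,
                            ancestor_span, rate_membership)
  set.seed(seed)
  reps <- matrix(NA_real_, n_iter, nrow(bins))
  all_taxa <- tree$phy$tip.label
  for (b in seq_len(n_iter)) {
    if (resample == "global") {
      keep <- sample(all_taxa, ceiling(fraction * length(all_taxa)))
      for (i in seq_len(nrow(bins))) {
        v <- vals[[i]]
        if (!length(v)) next
        sel <- is.na(match(names2(v), all_taxa)) | names2(v) %in% keep
        if (any(sel)) reps[b, i] <- apply_statistic(v[sel], statistic)
      }
    } else {
      for (i in seq_len(nrow(bins))) {
        v <- vals[[i]]
        if (!length(v)) next
        m <- ceiling(fraction * length(v))
        reps[b, i] <- apply_statistic(v[sample.int(length(v), m)], statistic)
      }
    }
  }
  env <- apply(reps, 2L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_))
    c(median(r), quantile(r, 0.25), quantile(r, 0.75), min(r), max(r))
  })
  out <- data.frame(bin_old_ma = bins$old_ma, bin_young_ma = bins$young_ma,
                    n = vapply(vals, length, 0L),
                    value = env[1L, ], q25 = env[2L, ], q75 = env[3L, ],
                    min = env[4L, ], max = env[5L, ],
                    method = method, statistic = statistic)
  class(out) <- c("binned_series", "data.frame")
  out
}

names2 <- function(v) if (is.null(names(v))) rep("", length(v)) else names(v)

#' @rdname bootstrap_envelope
#' @param series a `binned_series`.
#' @param path output CSV path.
#' @export
write_series <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}
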