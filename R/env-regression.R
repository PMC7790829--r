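#' Read a paleotemperature series
#'
#' Oxygen-isotope (delta-18-O, permil) series against age in Ma. The
#' proxy scales inversely with temperature: higher delta-18-O means
#' colder. CSV columns: `age_ma`, `d18o`.
#'
#' @param path CSV path.
#' @return data frame with columns `age_ma`, `d18o`, sorted old to young.
#' @export
read_temperature <- function(path) {
  as_temperature(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_temperature
#' @param x a data frame with columns `age_ma`, `d18o`.
#' @export
as_temperature <- function(x) {
  need <- c("age_ma", "d18o")
  if (!all(need %in% names(x)))
    stop("temperature series needs columns: ", paste(need, collapse = ", "))
  if (nrow(x) < 2) stop("temperature series needs >= 2 rows")
  x <- x[order(-x$age_ma), need]
  if (anyDuplicated(x$age_ma)) stop("duplicate ages in temperature series")
  rownames(x) <- NULL
  x
}

#' Interpolate a temperature series onto time bins
#'
#' Linear interpolation of delta-18-O at each bin midpoint; midpoints
#' outside the series' coverage are returned as `NA`.
#'
#' @param temperature a temperature series (see [as_temperature()]).
#' @param bins a bin table ([myr_bins()] / [stage_bins()]).
#' @return numeric vector of per-bin delta-18-O values.
#' @export
align_to_bins <- function(temperature, bins) {
  temperature <- as_temperature(temperature)
  validate_bins(bins)
  mid <- bin_midpoints(bins)
  covered <- mid <= max(temperature$age_ma) & mid >= min(temperature$age_ma)
  if (!any(covered)) stop("temperature series does not overlap the bins")
  if (mean(covered) < 0.5)
    warning("temperature series covers under half of the bins")
  approx(temperature$age_ma, temperature$d18o, xout = mid, rule = 1)$y
}

#' Era-partitioned regression of a binned series on temperature
#'
#' Ordinary least squares of a binned statistic (mean size, size
#' variance, or mean evolutionary rate) on the delta-18-O proxy, over the
#' bins falling in the requested era. The Mesozoic/Cenozoic boundary is
#' fixed at 66.0 Ma (the end-Cretaceous mass extinction); a bin belongs to
#' an era by its midpoint. A Durbin-Watson statistic is reported alongside
#' as an autocorrelation caveat; inference is plain OLS.
#'
#' @param series a `binned_series` (from [build_series()] or
#'   [bootstrap_envelope()]).
#' @param temperature a temperature series.
#' @param era `"mesozoic"`, `"cenozoic"` or `"all"`.
#' @param boundary_ma era boundary age (Ma).
#' @return a one-row data frame of class `regression_result`: `era`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n`, `durbin_watson`.
#' @export
regress_on_temperature <- function(series, temperature,
                                   era = c("all", "mesozoic", "cenozoic"),
                                   boundary_ma = 66) {
  era <- match.arg(era)
  bins <- data.frame(old_ma = series$bin_old_ma,
                     young_ma = series$bin_young_ma)
  d18o <- align_to_bins(temperature, bins)
  mid <- bin_midpoints(bins)
  keep <- switch(era, all = rep(TRUE, length(mid)),
                 mesozoic = mid > boundary_ma,
                 cenozoic = mid <= boundary_ma)
  ok <- keep & !is.na(d18o) & !is.na(series$value)
  if (sum(ok) < 3)
    stop("need >= 3 paired non-missing bins in era '", era, "'")
  df <- data.frame(x = d18o[ok], y = series$value[ok],
                   mid = mid[ok])
  df <- df[order(-df$mid), ]
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  dw <- unname(lmtest::dwtest(fit)$statistic)
  out <- data.frame(era = era, slope = coef(fit)[["x"]],
                    intercept = coef(fit)[["(Intercept)"]],
                    r_squared = sm$r.squared,
                    p_value = sm$coefficients["x", "Pr(>|t|)"],
                    n = nrow(df), durbin_watson = dw)
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Regression table across series and eras
#'
#' Convenience wrapper producing the standard report: one row per
#' (series, era) combination.
#'
#' @param series_list named list of `binned_series` objects (e.g. mean
#'   size, size variance, mean rate).
#' @inheritParams regress_on_temperature
#' @param eras eras to fit.
#' @return data frame with a `dependent` column plus the
#'   [regress_on_temperature()] columns.
#' @export
regression_table <- function(series_list, temperature,
                             eras = c("cenozoic", "mesozoic"),
                             boundary_ma = 66) {
  rows <- list()
  for (nm in names(series_list))
    for (era in eras) {
      r <- regress_on_temperature(series_list[[nm]], temperature, era,
                                  boundary_ma)
      rows[[length(rows) + 1L]] <- cbind(dependent = nm, r)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
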