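#' Time-bin specifications
#'
#' Bins are half-open intervals `[old, young)` in Ma, contiguous and
#' strictly decreasing in age, represented as a data frame with columns
#' `old_ma`, `young_ma` and `label`. `myr_bins()` builds equal-width bins
#' (1 Myr by default); `stage_bins()` returns the geological stage table
#' (ICS international stages, Induan through Holocene) shipped with the
#' package, optionally restricted to a time window.
#'
#' @param old_ma,young_ma time window bounds in Ma (`old_ma > young_ma`).
#' @param width bin width in Myr.
#' @return a data frame with columns `old_ma`, `young_ma`, `label`.
#' @export
#' @examples
#' head(myr_bins(250, 0))
#' head(stage_bins(201.3, 66))
myr_bins <- function(old_ma, young_ma = 0, width = 1) {
  if (old_ma <= young_ma) stop("`old_ma` must exceed `young_ma`")
  edges <- seq(old_ma, young_ma, by = -width)
  if (tail(edges, 1L) > young_ma) edges <- c(edges, young_ma)
  data.frame(old_ma = head(edges, -1L), young_ma = tail(edges, -1L),
             label = sprintf("%g-%g", head(edges, -1L), tail(edges, -1L)))
}

#' @rdname myr_bins
#' @export
stage_bins <- function(old_ma = Inf, young_ma = -Inf) {
  path <- system.file("extdata", "ics_stages.csv", package = "paleosize")
  st <- read.csv(path, stringsAsFactors = FALSE)
  st <- st[st$old_ma <= old_ma & st$young_ma >= young_ma, ]
  data.frame(old_ma = st$old_ma, young_ma = st$young_ma, label = st$stage)
}

#' @rdname myr_bins
#' @param bins a bin table.
#' @export
bin_midpoints <- function(bins) (bins$old_ma + bins$young_ma) / 2

validate_bins <- function(bins) {
  need <- c("old_ma", "young_ma")
  if (!all(need %in% names(bins))) stop("bins need columns old_ma, young_ma")
  if (any(bins$old_ma <= bins$young_ma))
    stop("each bin must have old_ma > young_ma")
  invisible(bins)
}
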