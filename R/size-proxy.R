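#' Measurement matrices
#'
#' The body-size proxy is built from a taxon-by-character matrix of linear
#' measurements in cm (up to 21 characters in typical use), with missing
#' values allowed. `as_measurements()` validates a numeric matrix (rows =
#' taxa, columns = named characters, `NA` = missing); `read_measurements()`
#' reads the CSV layout (`taxon` column plus one column per character,
#' empty cells = missing). Where a taxon appears in several rows
#' (multiple specimens), per-character medians are taken before analysis.
#'
#' @param path CSV path.
#' @return a numeric matrix with taxon rownames and character colnames.
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"taxon" %in% names(df)) stop("measurement CSV needs a 'taxon' column")
  vals <- as.matrix(df[, setdiff(names(df), "taxon"), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$taxon
  if (anyDuplicated(df$taxon)) vals <- aggregate_specimens(vals)
  as_measurements(vals)
}

#' @rdname read_measurements
#' @param x numeric matrix, taxa in rows, characters in columns.
#' @export
as_measurements <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("measurements must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("measurement matrix needs taxon rownames and character colnames")
  if (ncol(x) < 2) stop("need at least 2 measured characters")
  if (any(rowSums(!is.na(x)) == 0))
    stop("taxa with no observed measurements: ",
         paste(rownames(x)[rowSums(!is.na(x)) == 0], collapse = ", "))
  if (any(colSums(!is.na(x)) == 0))
    stop("characters with no observed values: ",
         paste(colnames(x)[colSums(!is.na(x)) == 0], collapse = ", "))
  obs <- x[!is.na(x)]
  if (any(!is.finite(obs)) || any(obs <= 0))
    stop("observed measurements must be finite and positive")
  x
}

#' @rdname read_measurements
#' @export
aggregate_specimens <- function(x) {
  taxa <- rownames(x)
  out <- do.call(rbind, lapply(split(seq_along(taxa), taxa), function(i)
    apply(x[i, , drop = FALSE], 2L, median, na.rm = TRUE)))
  out[is.nan(out)] <- NA_real_
  out
}

#' Spearman rank-correlation screen of measurement characters
#'
#' Tests every pair of characters for monotone association over the rows
#' where both are observed. A strong, uniformly positive correlation
#' structure is the signature of a latent size factor; pairs with
#' `rho <= 0` are flagged as candidate violations of the size signal.
#' Pairs with fewer than 4 jointly observed rows are reported untestable.
#'
#' @param x a measurement matrix (see [as_measurements()]).
#' @return a data frame with one row per unordered character pair:
#'   `char1`, `char2`, `n`, `rho`, `p`, `nonpositive`, `untestable`.
#' @export
spearman_screen <- function(x) {
  x <- as_measurements(x)
  cn <- colnames(x)
  pairs <- utils::combn(length(cn), 2L)
  res <- apply(pairs, 2L, function(ij) {
    xi <- x[, ij[1L]]; xj <- x[, ij[2L]]
    ok <- !is.na(xi) & !is.na(xj)
    n <- sum(ok)
    if (n < 4) return(c(n, NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(xi[ok], xj[ok], method = "spearman",
                                    exact = FALSE))
    c(n, unname(ct$estimate), ct$p.value)
  })
  data.frame(char1 = cn[pairs[1L, ]], char2 = cn[pairs[2L, ]],
             n = as.integer(res[1L, ]), rho = res[2L, ], p = res[3L, ],
             nonpositive = !is.na(res[2L, ]) & res[2L, ] <= 0,
             untestable = is.na(res[2L, ]))
}

#' Iterative-imputation principal components analysis
#'
#' PCA of the raw (not log-transformed) measurement covariance matrix with
#' iterative imputation of missing cells: (1) missing cells start at column
#' means; (2) the column-centred covariance matrix is eigen-decomposed;
#' (3) missing cells are re-estimated from the rank-`n_components`
#' reconstruction; (4) steps 2-3 repeat until the largest absolute change
#' in any imputed cell falls below `tol` (cm) or `max_iter` is reached.
#' PC-1 of the final decomposition is the relative body-size score.
#'
#' The PC-1 sign is fixed so that the loading of `sign_character` (by
#' default a column named `"skull_width"`, else the character with the
#' largest absolute loading) is positive: larger animals score higher.
#'
#' @param x measurement matrix (taxa x characters, cm, `NA` = missing).
#' @param n_components rank of the reconstruction used for imputation.
#' @param tol convergence tolerance on imputed cells, in cm.
#' @param max_iter iteration cap; non-convergence sets a warning flag.
#' @param sign_character character (column name) whose PC-1 loading is
#'   forced positive, or `NULL` for the default rule.
#' @return an object of class `size_scores`: list with `scores` (per-taxon
#'   PC-1), `all_scores` (all components), `loadings` (characters x
#'   components, unit columns), `eigenvalues` (non-increasing),
#'   `iterations`, `converged`, `completed` (the imputed matrix) and
#'   `center` (column means of the completed matrix).
#' @export
iterative_pca <- function(x, n_components = 3, tol = 1e-6, max_iter = 500,
                          sign_character = NULL) {
  x <- as_measurements(x)
  if (n_components < 1) stop("`n_components` must be >= 1")
  k <- min(n_components, ncol(x) - 1L, nrow(x) - 1L)
  miss <- is.na(x)
  filled <- x
  cm <- colMeans(x, na.rm = TRUE)
  filled[miss] <- cm[col(x)[miss]]

  iterations <- 0L
  converged <- !any(miss)
  repeat {
    dec <- eigen(stats::cov(filled), symmetric = TRUE)
    if (converged || iterations >= max_iter) break
    iterations <- iterations + 1L
    ctr <- colMeans(filled)
    centred <- sweep(filled, 2L, ctr)
    V <- dec$vectors[, seq_len(k), drop = FALSE]
    recon <- sweep(centred %*% V %*% t(V), 2L, ctr, `+`)
    delta <- max(abs(recon[miss] - filled[miss]))
    filled[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE }
  }
  if (!converged)
    warning("iterative PCA did not converge in ", max_iter, " iterations")

  ctr <- colMeans(filled)
  scores <- sweep(filled, 2L, ctr) %*% dec$vectors
  loadings <- dec$vectors
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(x))))
  colnames(scores) <- colnames(loadings)

  sc <- sign_character %||%
    (if ("skull_width" %in% colnames(x)) "skull_width" else
       colnames(x)[which.max(abs(loadings[, 1L]))])
  if (!sc %in% colnames(x)) stop("unknown sign_character: ", sc)
  if (loadings[sc, 1L] < 0) {
    loadings[, 1L] <- -loadings[, 1L]
    scores[, 1L] <- -scores[, 1L]
  }

  structure(list(scores = setNames(scores[, 1L], rownames(x)),
                 all_scores = scores, loadings = loadings,
                 eigenvalues = pmax(dec$values, 0),
                 iterations = iterations, converged = converged,
                 completed = filled, center = ctr),
            class = "size_scores")
}

#' @export
print.size_scores <- function(x, ...) {
  pve <- 100 * x$eigenvalues[1L] / sum(x$eigenvalues)
  cat(sprintf(
    "Iterative-imputation PCA size scores: %d taxa, %d characters\n",
    length(x$scores), nrow(x$loadings)))
  cat(sprintf("  PC-1 explains %.1f%% of variance; %d imputation iteration(s)%s\n",
              pve, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Back-transform PC-1 scores to skull width
#'
#' Calibrates an ordinary least-squares line of observed skull width (cm)
#' on PC-1 score over the taxa with skull width measured, and predicts the
#' skull width corresponding to a given PC-1 value. Used to express
#' dimensionless size scores (e.g. a phylogenetically adjusted mean) on an
#' interpretable anatomical scale.
#'
#' @param scores a `size_scores` object or named numeric vector of PC-1
#'   scores.
#' @param x the measurement matrix holding the skull-width column.
#' @param pc1_value PC-1 value(s) at which to predict.
#' @param skull_column name of the skull-width character.
#' @return predicted skull width(s) in cm.
#' @export
pc1_to_skull_width <- function(scores, x, pc1_value,
                               skull_column = "skull_width") {
  s <- if (inherits(scores, "size_scores")) scores$scores else scores
  if (!skull_column %in% colnames(x))
    stop("no '", skull_column, "' column in the measurement matrix")
  w <- x[, skull_column]
  taxa <- intersect(names(s), rownames(x)[!is.na(w)])
  if (length(taxa) < 3)
    stop("need >= 3 taxa with observed skull width for calibration")
  xx <- s[taxa]
  if (var(xx) == 0) stop("degenerate calibration: PC-1 has zero variance")
  fit <- lm(y ~ x, data = data.frame(x = xx, y = w[taxa]))
  unname(predict(fit, newdata = data.frame(x = pc1_value)))
}

#' Summary statistics of size scores
#'
#' Arithmetic mean and sample variance of the PC-1 scores (the raw-data
#' counterpart of a phylogenetically adjusted mean).
#'
#' @param scores a `size_scores` object or numeric vector.
#' @return list with `mean` and `variance` (sample variance; `NA` for a
#'   single score).
#' @export
summarize_scores <- function(scores) {
  s <- if (inherits(scores, "size_scores")) scores$scores else scores
  if (length(s) < 1) stop("need at least one score")
  list(mean = mean(s), variance = if (length(s) > 1) var(s) else NA_real_)
}

#' Export size scores
#'
#' Writes per-taxon scores as CSV (`taxon, pc1, n_observed`) and the
#' loadings/eigenvalue/iteration metadata as JSON.
#'
#' @param fit a `size_scores` object.
#' @param x the measurement matrix the scores were computed from.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the score table data frame.
#' @export
write_scores <- function(fit, x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(fit, "size_scores"))
  tab <- data.frame(taxon = names(fit$scores), pc1 = unname(fit$scores),
                    n_observed = rowSums(!is.na(x))[names(fit$scores)])
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON export")
    jsonlite::write_json(
      list(loadings_pc1 = as.list(setNames(fit$loadings[, 1L],
                                           rownames(fit$loadings))),
           eigenvalues = fit$eigenvalues, iterations = fit$iterations,
           converged = fit$converged),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
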