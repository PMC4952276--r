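#' Maximal information coefficient between two vectors
#'
#' MIC is a \[0, 1\] dependence statistic that approaches 1 for a wide class
#' of noiseless functional relationships and 0 for independent variables.
#' It is computed by searching over two-dimensional grids with at most
#' `n^alpha` cells for the grid that maximises the normalised mutual
#' information, using the standard dynamic-programming approximation
#' (equipartitioned rows, optimised columns, both orientations).
#'
#' @param x,y numeric vectors of equal length (n >= 8 recommended).
#' @param alpha grid-size exponent: grids are limited to `n^alpha` cells.
#' @param c candidate-partition factor: the column search works on at most
#'   `c` times the allowed number of columns "clumps".
#' @return the MIC estimate in `[0, 1]`.
#' @export
mic <- function(x, y, alpha = 0.6, c = 15) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) {
    x <- x[ok]
    y <- y[ok]
  }
  if (length(x) < 4) stop("need at least 4 paired finite observations")
  mic_cpp(x, y, alpha, c)
}

#' MIC of every other feature with a target feature
#'
#' @param X an `omics_matrix` or named numeric matrix (samples x features).
#' @param f target feature identifier.
#' @param measure dependence measure: `"mic"` (default) or `"spearman"`
#'   (absolute Spearman correlation, a faster drop-in).
#' @param alpha,c MIC parameters, see [mic()].
#' @return named numeric vector of scores in `[0, 1]` for all features
#'   except `f`. A constant target yields all-zero scores with a warning.
#' @export
mic_scores <- function(X, f, measure = c("mic", "spearman"),
                       alpha = 0.6, c = 15) {
  measure <- match.arg(measure)
  v <- as_values(X)
  if (!f %in% colnames(v)) stop("feature not found: ", f)
  others <- setdiff(colnames(v), f)
  if (length(others) < 2) stop("need at least 2 other features")
  xf <- v[, f]
  if (sd(xf) == 0) {
    warning("feature ", f, " is constant; all dependence scores set to 0")
    return(stats::setNames(rep(0, length(others)), others))
  }
  scores <- vapply(others, function(g) {
    xg <- v[, g]
    if (sd(xg) == 0) return(0)
    if (measure == "mic") mic(xf, xg, alpha = alpha, c = c)
    else abs(stats::cor(xf, xg, method = "spearman"))
  }, numeric(1))
  scores
}

#' Select the top predictors of a feature by dependence score
#'
#' Keeps the `k` highest-scoring features where
#' `k = min(n_other, max(5, ceiling(0.05 * n_other)))`: the top 5% of the
#' other features, or the top 5 when 5% would give fewer than five. Ties in
#' score are broken by lexicographic feature order for determinism.
#'
#' @param scores named numeric vector of dependence scores (one per
#'   candidate feature).
#' @param top_frac fraction of features forming the "top" set (default 5%).
#' @param top_min minimum number of predictors (default 5).
#' @return character vector of selected feature identifiers, ordered by
#'   decreasing score.
#' @export
top_predictors <- function(scores, top_frac = 0.05, top_min = 5) {
  n_other <- length(scores)
  if (n_other < 1) stop("empty score vector")
  k <- min(n_other, max(top_min, ceiling(top_frac * n_other)))
  ord <- order(-scores, names(scores))
  names(scores)[ord[seq_len(k)]]
}
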