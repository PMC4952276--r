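#' Fit reliability models for a set of features
#'
#' For every feature `f` in `features`, scores all other columns of the
#' (standardised) training matrix with the chosen dependence measure,
#' selects the top predictors by the 5-or-5% rule ([top_predictors()]), and
#' fits a squared-exponential Gaussian process predicting `f` from them.
#'
#' @param Xs standardised training matrix (samples x features).
#' @param features feature identifiers to model.
#' @param measure,mic_alpha,mic_c see [mic_scores()].
#' @param gp_restarts optimisation restarts per GP.
#' @return named list of `confens_reliability` objects (fields: `feature`,
#'   `predictors`, `scores`, `gp`).
#' @export
fit_reliability_models <- function(Xs, features, measure = "mic",
                                   mic_alpha = 0.6, mic_c = 15,
                                   gp_restarts = 3) {
  out <- lapply(features, function(f) {
    scores <- mic_scores(Xs, f, measure = measure,
                         alpha = mic_alpha, c = mic_c)
    preds <- top_predictors(scores)
    gp <- gp_fit(Xs[, preds, drop = FALSE], Xs[, f],
                 n_restarts = gp_restarts)
    structure(list(feature = f, predictors = preds,
                   scores = scores[preds], gp = gp),
              class = "confens_reliability")
  })
  stats::setNames(out, features)
}

#' Per-sample confidence of a feature
#'
#' The reliability of an observed feature value is the two-sided tail
#' probability of that value under the feature's predictive posterior:
#' `c_f = 2 * F(-|z|)` with `z = (x_f - mu) / sigma` and `F` the standard
#' normal CDF. A value at the posterior mean scores 1; values far in the
#' tail score near 0. `sigma` is floored at 1e-8.
#'
#' @param r a `confens_reliability` model.
#' @param x named numeric vector holding the feature and all its predictors
#'   (on the same standardised scale the model was fitted on), or a one-row
#'   matrix.
#' @return confidence in `(0, 1]`.
#' @export
feature_confidence <- function(r, x) {
  if (is.matrix(x)) x <- x[1, ]
  need <- c(r$feature, r$predictors)
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("sample is missing value(s) for: ", paste(missing, collapse = ", "))
  post <- gp_predict(r$gp, matrix(x[r$predictors], nrow = 1))
  confidence_from_z((x[[r$feature]] - post$mean) / max(post$sd, .SIGMA_FLOOR))
}

# c_f as a function of the standardised residual
confidence_from_z <- function(z) 2 * pnorm(-abs(z))

# vectorised feature confidences for a whole standardised matrix:
# returns samples x features matrix of c_f values
feature_confidence_matrix <- function(models, Xs) {
  out <- matrix(NA_real_, nrow = nrow(Xs), ncol = length(models),
                dimnames = list(rownames(Xs), names(models)))
  for (f in names(models)) {
    r <- models[[f]]
    post <- gp_predict(r$gp, Xs[, r$predictors, drop = FALSE])
    z <- (Xs[, r$feature] - post$mean) / pmax(post$sd, .SIGMA_FLOOR)
    out[, f] <- confidence_from_z(z)
  }
  out
}
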