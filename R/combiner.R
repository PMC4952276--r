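#' Aggregate feature confidences into a classifier's feature reliability
#'
#' The overall feature reliability of a classifier is the |weight|-weighted
#' average of its features' confidences:
#' `c1 = sum_f c_f |w(f)| / sum_f |w(f)|`.
#'
#' @param learner a `confens_learner`.
#' @param cf named numeric vector of per-feature confidences covering the
#'   learner's feature set.
#' @return `c1` in `(0, 1]`.
#' @export
learner_feature_confidence <- function(learner, cf) {
  if (length(learner$phi) == 0) stop("learner has an empty feature set")
  missing <- setdiff(learner$phi, names(cf))
  if (length(missing))
    stop("confidence missing for feature(s): ",
         paste(missing, collapse = ", "))
  w <- abs(learner$weights[learner$phi])
  sum(cf[learner$phi] * w) / sum(w)
}

#' Output confidence of a classifier from its decision value
#'
#' How unusual the decision value is relative to its training distribution:
#' `c2 = 1 - 2 * F(-|z|)` with `z = (d - mu) / sigma`, using the training
#' mean and standard deviation of the learner's decision values. A decision
#' value at the training mean scores 0 (maximally ambiguous); values far
#' from it approach 1.
#'
#' @param learner a `confens_learner`.
#' @param decision_value numeric decision value(s).
#' @return `c2` in `[0, 1)`, vectorised over `decision_value`.
#' @export
learner_output_confidence <- function(learner, decision_value) {
  z <- (decision_value - learner$mu_dec) / max(learner$sigma_dec,
                                               .SIGMA_FLOOR)
  1 - 2 * pnorm(-abs(z))
}

#' Final confidence of a classifier
#'
#' @param c1 feature reliability in `(0, 1]`.
#' @param c2 output confidence in `[0, 1)`.
#' @return the product `c1 * c2`.
#' @export
learner_confidence <- function(c1, c2) c1 * c2

#' Confidence-weighted vote among classifiers
#'
#' Returns the sign of the confidence-weighted mean of the predicted labels,
#' `sign(sum_i c_i l_i / sum_i c_i)`, with `sign(0) := +1`. The normalised
#' sum itself (the vote score, in `[-1, 1]`) is also returned for ROC
#' analysis. When all confidences are (numerically) zero, the vote falls
#' back to the unweighted mean of the labels with a warning.
#'
#' @param confidences numeric vector of per-learner confidences (>= 0).
#' @param labels numeric vector of per-learner predicted labels in
#'   `{-1, +1}`.
#' @return list with `label` (-1 or +1) and `score` (numeric in `[-1, 1]`).
#' @export
weighted_vote <- function(confidences, labels) {
  if (length(confidences) < 1) stop("need at least one learner")
  if (length(confidences) != length(labels))
    stop("confidences and labels must align")
  total <- sum(confidences)
  if (total < .CONF_EPS) {
    warning("all classifier confidences are ~0; falling back to the ",
            "unweighted mean of the labels")
    score <- mean(labels)
  } else {
    score <- sum(confidences * labels) / total
  }
  list(label = sign_pos(score), score = score)
}

#' Confidence-weighted predictions for new samples
#'
#' For every sample: per-feature confidences `c_f` from the reliability
#' models, per-learner feature reliability `c1`, output confidence `c2`,
#' final confidence `c = c1 * c2`, and the confidence-weighted vote over
#' the learners' predicted labels. Every intermediate value is reported.
#'
#' @param object a `confens_ensemble` fitted with reliability models.
#' @param X an `omics_matrix` or named numeric matrix containing all
#'   features used by the learners and reliability models.
#' @param weighting `"confidence"` (default) or `"uniform"` (all learners
#'   weighted equally; the baseline the confidence weighting is compared
#'   against).
#' @param ... unused.
#' @return a `confens_prediction`: a data frame with one row per sample
#'   (`sample_id`, `label` on the original label scale, `yhat` in
#'   `{-1, +1}`, `vote_score`, and per-learner `d`, `lab`, `c1`, `c2`, `c`
#'   columns), with the per-feature confidence matrix in
#'   `attr(, "feature_confidence")`.
#' @export
predict.confens_ensemble <- function(object, X,
                                     weighting = c("confidence", "uniform"),
                                     ...) {
  weighting <- match.arg(weighting)
  if (is.null(object$reliability_models))
    stop("model was fitted with reliability = FALSE; ",
         "confidence-weighted prediction needs reliability models")
  Xs <- standardize_like(object, X)
  n <- nrow(Xs)
  nl <- length(object$learners)

  cf <- feature_confidence_matrix(object$reliability_models, Xs)
  d <- vapply(object$learners, function(lr) learner_decision(lr, Xs),
              numeric(n))
  d <- matrix(d, nrow = n)
  lab <- sign_pos(d)
  c1 <- vapply(object$learners, function(lr) {
    w <- abs(lr$weights[lr$phi])
    drop(cf[, lr$phi, drop = FALSE] %*% w) / sum(w)
  }, numeric(n))
  c1 <- matrix(c1, nrow = n)
  c2 <- vapply(seq_len(nl), function(i)
    learner_output_confidence(object$learners[[i]], d[, i]), numeric(n))
  c2 <- matrix(c2, nrow = n)
  cc <- if (weighting == "confidence") c1 * c2
        else matrix(1, nrow = n, ncol = nl)

  votes <- lapply(seq_len(n), function(s)
    suppressWarnings(weighted_vote(cc[s, ], lab[s, ])))
  yhat <- vapply(votes, `[[`, numeric(1), "label")
  score <- vapply(votes, `[[`, numeric(1), "score")

  rep_df <- data.frame(sample_id = rownames(Xs),
                       label = decode_labels(object, yhat),
                       yhat = yhat, vote_score = score,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nl)) {
    rep_df[[paste0("d_L", i)]] <- d[, i]
    rep_df[[paste0("lab_L", i)]] <- lab[, i]
    rep_df[[paste0("c1_L", i)]] <- c1[, i]
    rep_df[[paste0("c2_L", i)]] <- c2[, i]
    rep_df[[paste0("c_L", i)]] <- c1[, i] * c2[, i]
  }
  attr(rep_df, "feature_confidence") <- cf
  attr(rep_df, "weighting") <- weighting
  attr(rep_df, "learner_features") <- lapply(object$learners, function(lr)
    list(phi = lr$phi, weights = lr$weights))
  class(rep_df) <- c("confens_prediction", "data.frame")
  rep_df
}

#' Per-feature confidences of a prediction in long format
#'
#' @param pred a `confens_prediction`.
#' @return data frame with columns `sample_id`, `learner`, `feature`,
#'   `weight`, `c_f` (one row per learner feature per sample).
#' @export
explain_prediction <- function(pred) {
  cf <- attr(pred, "feature_confidence")
  if (is.null(cf)) stop("prediction carries no feature confidences")
  learners <- attr(pred, "learner_features")
  if (is.null(learners)) stop("prediction carries no learner feature map")
  do.call(rbind, lapply(seq_along(learners), function(i) {
    phi <- learners[[i]]$phi
    do.call(rbind, lapply(seq_len(nrow(pred)), function(s) {
      data.frame(sample_id = pred$sample_id[s],
                 learner = paste0("L", i), feature = phi,
                 weight = unname(learners[[i]]$weights[phi]),
                 c_f = unname(cf[s, phi]),
                 stringsAsFactors = FALSE)
    }))
  }))
}
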