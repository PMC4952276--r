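#' Train a confidence-weighted ensemble of disjoint sparse classifiers
#'
#' Iteratively fits up to `n_learners` sparse linear classifiers: each round
#' removes every feature already selected by earlier learners, fits a new
#' classifier on the remainder, and adds its selected features to the
#' excluded set, so the learners' feature sets are mutually disjoint. The
#' loop stops early when a learner selects no features or no features
#' remain. Afterwards (unless `reliability = FALSE`) a reliability model is
#' fitted for every selected feature: its most dependent peers among *all*
#' other training features are chosen by [mic_scores()] + [top_predictors()]
#' and a Gaussian process predicts the feature from them, giving a
#' per-sample predictive posterior used at test time to score how
#' trustworthy the observed feature value is.
#'
#' Features are z-scored with training statistics before fitting; test data
#' reuse those statistics.
#'
#' @param X an `omics_matrix` or named numeric matrix (samples x features).
#' @param y binary labels: numeric `{-1, +1}`, or a factor/character/logical
#'   with two levels (the first sorted level maps to -1).
#' @param n_learners maximum number of learners N.
#' @param reg_strength L1 penalty shared by all learners.
#' @param reliability fit per-feature reliability models (needed for
#'   confidence-weighted prediction; skip for speed when only the learners
#'   are of interest).
#' @param measure dependence measure for predictor selection, see
#'   [mic_scores()].
#' @param mic_alpha,mic_c MIC parameters.
#' @param gp_restarts optimisation restarts per Gaussian process.
#' @return an object of class `confens_ensemble`.
#' @export
fit_disjoint_ensemble <- function(X, y, n_learners = 4, reg_strength = 0.1,
                                  reliability = TRUE,
                                  measure = c("mic", "spearman"),
                                  mic_alpha = 0.6, mic_c = 15,
                                  gp_restarts = 3) {
  measure <- match.arg(measure)
  v <- as_values(X)
  if (n_learners < 1) stop("n_learners must be >= 1")
  lm_ <- encode_labels(y, nrow(v))
  ylab <- lm_$y

  center <- colMeans(v)
  scale <- apply(v, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(v, 2, center), 2, scale, "/")

  learners <- list()
  excluded <- character(0)
  for (i in seq_len(n_learners)) {
    allowed <- setdiff(colnames(Xs), excluded)
    if (length(allowed) == 0) break
    lr <- fit_sparse_learner(Xs[, allowed, drop = FALSE], ylab,
                             reg_strength = reg_strength, index = i)
    if (is.null(lr)) {
      if (i == 1)
        stop("no predictive features at this regularization (reg_strength = ",
             reg_strength, ")")
      break
    }
    learners[[i]] <- lr
    excluded <- c(excluded, lr$phi)
  }

  model <- structure(list(
    learners = learners,
    excluded = excluded,
    reliability_models = NULL,
    center = center,
    scale = scale,
    label_map = lm_$map,
    config = list(n_learners = n_learners, reg_strength = reg_strength,
                  measure = measure, mic_alpha = mic_alpha, mic_c = mic_c,
                  gp_restarts = gp_restarts)
  ), class = "confens_ensemble")

  if (reliability)
    model$reliability_models <- fit_reliability_models(
      Xs, excluded, measure = measure, mic_alpha = mic_alpha,
      mic_c = mic_c, gp_restarts = gp_restarts)
  model
}

encode_labels <- function(y, n) {
  if (length(y) != n) stop("length(y) must match the number of samples")
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    return(list(y = as.numeric(y), map = c(`-1` = "-1", `1` = "1")))
  }
  f <- factor(y)
  if (nlevels(f) != 2) stop("labels must be binary")
  lv <- levels(f)
  list(y = ifelse(f == lv[2], 1, -1),
       map = stats::setNames(lv, c("-1", "1")))
}

decode_labels <- function(model, y) {
  map <- model$label_map
  unname(map[as.character(y)])
}

#' Per-learner decision values for new samples
#'
#' Applies the training standardisation, then evaluates each learner's
#' linear decision function. The predicted label of a learner is the sign
#' of its decision value, with `sign(0) := +1`.
#'
#' @param model a `confens_ensemble`.
#' @param X an `omics_matrix` or named numeric matrix; must contain every
#'   feature in the model's excluded set.
#' @return numeric matrix (samples x learners) of decision values.
#' @export
decision_values <- function(model, X) {
  Xs <- standardize_like(model, X)
  vapply(model$learners, function(lr) learner_decision(lr, Xs),
         numeric(nrow(Xs)))
}

standardize_like <- function(model, X) {
  v <- as_values(X)
  needed <- unique(c(model$excluded,
                     unlist(lapply(model$reliability_models,
                                   function(r) r$predictors))))
  missing <- setdiff(needed, colnames(v))
  if (length(missing))
    stop("matrix is missing feature(s): ", paste(missing, collapse = ", "))
  feats <- intersect(names(model$center), colnames(v))
  sweep(sweep(v[, feats, drop = FALSE], 2, model$center[feats]), 2,
        model$scale[feats], "/")
}

#' @export
print.confens_ensemble <- function(x, ...) {
  cat(sprintf("<confens_ensemble> %d learner(s), %d selected feature(s)\n",
              length(x$learners), length(x$excluded)))
  for (lr in x$learners)
    cat(sprintf("  L%d: %d feature(s): %s\n", lr$index, length(lr$phi),
                paste(lr$phi, collapse = ", ")))
  if (is.null(x$reliability_models))
    cat("  (no reliability models fitted)\n")
  invisible(x)
}
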