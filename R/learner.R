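#' Fit one sparse linear classifier
#'
#' Fits an L1-penalised (lasso) linear classifier on the supplied feature
#' block and records the selected features, their weights, and the
#' empirical mean and standard deviation of the training decision values.
#' The decision value is the signed linear score `x . w + b`; its sign is
#' the predicted class. Stronger `reg_strength` selects fewer features.
#'
#' Inputs are expected to be standardised already (the ensemble fit z-scores
#' with training statistics before delegating here); the penalty is applied
#' to the coefficients as-is.
#'
#' @param X numeric matrix (samples x allowed features), standardised.
#' @param y labels in `{-1, +1}`.
#' @param reg_strength L1 penalty (glmnet `lambda`); larger = sparser.
#' @param index integer position of the learner in the ensemble.
#' @param tol coefficients with absolute value below `tol` count as zero.
#' @return an object of class `confens_learner`, or `NULL` when no feature
#'   survives the penalty (the signal the training loop stops on).
#' @export
fit_sparse_learner <- function(X, y, reg_strength, index = 1L,
                               tol = .COEF_TOL) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("no allowed features")
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")

  y01 <- (y + 1) / 2
  fit <- tryCatch(
    glmnet::glmnet(X, y01, family = "binomial", alpha = 1,
                   lambda = reg_strength, standardize = FALSE,
                   intercept = TRUE),
    error = function(e)
      stop("sparse solver failed at reg_strength = ", reg_strength, ": ",
           conditionMessage(e)))
  beta <- as.numeric(coef(fit, s = reg_strength))
  intercept <- beta[1]
  w <- beta[-1]
  names(w) <- colnames(X)

  phi <- names(w)[abs(w) > tol]
  if (length(phi) == 0) return(NULL)
  w <- w[phi]

  d <- drop(X[, phi, drop = FALSE] %*% w) + intercept
  structure(list(index = as.integer(index), phi = phi, weights = w,
                 intercept = intercept, mu_dec = mean(d),
                 sigma_dec = max(sd(d), .SIGMA_FLOOR)),
            class = "confens_learner")
}

# decision values of one learner on a standardised matrix
learner_decision <- function(learner, Xs) {
  missing <- setdiff(learner$phi, colnames(Xs))
  if (length(missing))
    stop("matrix is missing feature(s): ", paste(missing, collapse = ", "))
  drop(Xs[, learner$phi, drop = FALSE] %*% learner$weights) +
    learner$intercept
}

# sign with the documented tie convention sign(0) := +1
sign_pos <- function(x) ifelse(x >= 0, 1, -1)
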