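#' Serialize an ensemble model to JSON
#'
#' Writes every component needed to reproduce predictions exactly:
#' learners (selected features, weights, intercept, decision-value
#' statistics), reliability models (predictors, dependence scores, GP
#' hyperparameters and training data), standardisation statistics, label
#' map and the configuration echo. Numbers are written at full double
#' precision, so a written-and-reread model predicts identically to within
#' floating-point round-off.
#'
#' @param model a `confens_ensemble`.
#' @param path output `.json` path.
#' @export
write_ensemble <- function(model, path) {
  ser <- list(
    format = "confens_ensemble",
    version = 1L,
    config = model$config,
    label_map = as.list(model$label_map),
    center = as.list(model$center),
    scale = as.list(model$scale),
    excluded = model$excluded,
    learners = lapply(model$learners, function(lr) list(
      index = lr$index, phi = lr$phi, weights = as.list(lr$weights),
      intercept = lr$intercept, mu_dec = lr$mu_dec,
      sigma_dec = lr$sigma_dec)),
    reliability_models = if (is.null(model$reliability_models)) NULL else
      lapply(model$reliability_models, function(r) list(
        feature = r$feature, predictors = r$predictors,
        scores = as.list(r$scores),
        gp = list(X = r$gp$X, y = r$gp$y, ymean = r$gp$ymean,
                  alpha = r$gp$alpha, L = r$gp$L, ell = r$gp$ell,
                  sf2 = r$gp$sf2, sn2 = r$gp$sn2)))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, na = "null")
  invisible(path)
}

#' Read an ensemble model from JSON
#'
#' @param path path written by [write_ensemble()].
#' @return a `confens_ensemble`.
#' @export
read_ensemble <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(ser$format, "confens_ensemble"))
    stop("not a confens ensemble file: ", path)
  as_named <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  learners <- lapply(ser$learners, function(lr) {
    structure(list(index = as.integer(lr$index),
                   phi = as.character(lr$phi),
                   weights = as_named(lr$weights),
                   intercept = lr$intercept, mu_dec = lr$mu_dec,
                   sigma_dec = lr$sigma_dec),
              class = "confens_learner")
  })
  rel <- NULL
  if (!is.null(ser$reliability_models)) {
    rel <- lapply(ser$reliability_models, function(r) {
      gp <- structure(list(X = as.matrix(r$gp$X),
                           y = as.numeric(r$gp$y), ymean = r$gp$ymean,
                           alpha = as.numeric(r$gp$alpha),
                           L = as.matrix(r$gp$L), ell = r$gp$ell,
                           sf2 = r$gp$sf2, sn2 = r$gp$sn2),
                      class = "confens_gp")
      structure(list(feature = r$feature,
                     predictors = as.character(r$predictors),
                     scores = as_named(r$scores), gp = gp),
                class = "confens_reliability")
    })
  }
  structure(list(learners = learners,
                 excluded = as.character(ser$excluded),
                 reliability_models = rel,
                 center = as_named(ser$center),
                 scale = as_named(ser$scale),
                 label_map = unlist(ser$label_map),
                 config = ser$config),
            class = "confens_ensemble")
}
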