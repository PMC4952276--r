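#' Train an ensemble from files
#'
#' Reads a samples-by-features TSV matrix and a two-column labels TSV
#' (`sample_id`, `label`), fits the disjoint ensemble, reports each
#' learner's feature set, and serializes the model to JSON.
#'
#' @param matrix_path TSV as written by [write_omics_tsv()].
#' @param labels_path TSV with columns `sample_id` and `label` (binary).
#' @param out_path output model JSON path.
#' @param n_learners,reg_strength,measure see [fit_disjoint_ensemble()].
#' @param seed integer seed (controls GP restarts).
#' @param assay assay tag of the input matrix.
#' @return the fitted `confens_ensemble`, invisibly.
#' @export
run_train <- function(matrix_path, labels_path, out_path, n_learners = 4,
                      reg_strength = 0.1, measure = "mic", seed = 1,
                      assay = "expression") {
  X <- read_omics_tsv(matrix_path, assay = assay)
  lab <- read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(lab)))
    stop("labels file needs columns `sample_id` and `label`")
  idx <- match(sample_ids(X), lab$sample_id)
  if (anyNA(idx)) stop("labels missing for some samples")
  y <- lab$label[idx]
  if (length(unique(y)) != 2) stop("labels must be binary")

  set.seed(seed)
  model <- fit_disjoint_ensemble(X, y, n_learners = n_learners,
                                 reg_strength = reg_strength,
                                 measure = measure)
  model$config$seed <- as.integer(seed)
  for (lr in model$learners)
    message(sprintf("learner %d selected %d feature(s): %s", lr$index,
                    length(lr$phi), paste(lr$phi, collapse = ", ")))
  write_ensemble(model, out_path)
  invisible(model)
}

#' Predict from a serialized model and a matrix file
#'
#' Writes a predictions TSV (sample, label on the original scale, vote
#' score, per-learner confidences) with the model configuration echoed in
#' `#`-prefixed header lines; with `explain = TRUE` an additional
#' long-format TSV of per-feature confidences is written next to it.
#'
#' @param model_path model JSON from [run_train()]/[write_ensemble()].
#' @param matrix_path TSV matrix of samples to predict.
#' @param out_path output predictions TSV.
#' @param explain also write `<out_path>.features.tsv`.
#' @param assay assay tag of the input matrix.
#' @return the `confens_prediction`, invisibly.
#' @export
run_predict <- function(model_path, matrix_path, out_path,
                        explain = FALSE, assay = "expression") {
  model <- read_ensemble(model_path)
  X <- read_omics_tsv(matrix_path, assay = assay)
  pred <- predict(model, X)
  write_tsv_with_config(as.data.frame(pred), out_path, model$config)
  if (explain) {
    long <- explain_prediction(pred)
    write_tsv_with_config(long, paste0(out_path, ".features.tsv"),
                          model$config)
  }
  invisible(pred)
}

#' Generate synthetic data to files
#'
#' @param out_prefix path prefix; writes `<prefix>_train.tsv`,
#'   `<prefix>_train_labels.tsv`, `<prefix>_test.tsv`,
#'   `<prefix>_test_labels.tsv`.
#' @param ... passed to [sim_config()].
#' @return the generated data list, invisibly.
#' @export
run_simulate <- function(out_prefix, ...) {
  dat <- generate_sim_data(sim_config(...))
  write_omics_tsv(dat$train, paste0(out_prefix, "_train.tsv"))
  write_omics_tsv(dat$test, paste0(out_prefix, "_test.tsv"))
  wl <- function(x, y, path)
    write.table(data.frame(sample_id = sample_ids(x), label = y),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  wl(dat$train, dat$train_labels, paste0(out_prefix, "_train_labels.tsv"))
  wl(dat$test, dat$test_labels, paste0(out_prefix, "_test_labels.tsv"))
  invisible(dat)
}

write_tsv_with_config <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(config))
    writeLines(sprintf("# %s=%s", k,
                       paste(format(config[[k]]), collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
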