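#' Configuration for the block-correlated synthetic generator
#'
#' Defaults describe the reference simulation used throughout the package:
#' 240 training and 60 test samples, 10 feature blocks of 10 features,
#' 2 signal blocks, within-block correlation 0.8, unit effect size with
#' label-noise standard deviation 0.5, and (optionally) a mean shift of
#' `bias_shift` feature standard deviations applied to the biased blocks of
#' the *test* samples only — emulating a batch effect or distribution shift
#' confined to part of the measured features.
#'
#' @param n_train,n_test sample sizes.
#' @param n_blocks,block_size number of feature blocks and features per
#'   block.
#' @param n_signal_blocks how many blocks carry label signal.
#' @param within_block_correlation pairwise correlation of features within
#'   a block, in `[0, 1)`.
#' @param effect_size coefficient of the summed signal-block latents in the
#'   label model.
#' @param noise_sd standard deviation of the label noise.
#' @param biased_blocks integer indices of blocks whose test-set features
#'   are shifted.
#' @param bias_shift shift in units of feature standard deviation.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_train = 240, n_test = 60, n_blocks = 10,
                       block_size = 10, n_signal_blocks = 2,
                       within_block_correlation = 0.8, effect_size = 1,
                       noise_sd = 0.5, biased_blocks = integer(0),
                       bias_shift = 0, seed = 1) {
  cfg <- list(n_train = n_train, n_test = n_test, n_blocks = n_blocks,
              block_size = block_size, n_signal_blocks = n_signal_blocks,
              within_block_correlation = within_block_correlation,
              effect_size = effect_size, noise_sd = noise_sd,
              biased_blocks = as.integer(biased_blocks),
              bias_shift = bias_shift, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_train < 4 || n_test < 1) stop("invalid sample sizes")
    if (n_signal_blocks > n_blocks)
      stop("n_signal_blocks must not exceed n_blocks")
    if (within_block_correlation < 0 || within_block_correlation >= 1)
      stop("within_block_correlation must lie in [0, 1)")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (length(biased_blocks) &&
        (min(biased_blocks) < 1 || max(biased_blocks) > n_blocks))
      stop("biased_blocks out of range")
  })
  invisible(cfg)
}

#' Generate block-correlated train/test data with optional test-set bias
#'
#' Every block `b` has a per-sample latent factor `z_b ~ N(0, 1)`; its
#' features are `sqrt(r) * z_b + sqrt(1 - r) * eps` with
#' `r = within_block_correlation`, so features have unit variance and
#' pairwise within-block correlation `r`. The label is the sign of
#' `effect_size * sum of signal-block latents + N(0, noise_sd)`. Signal
#' blocks are blocks `1..n_signal_blocks`. Test samples in biased blocks
#' get `bias_shift` added to every feature of those blocks.
#'
#' @param cfg a [sim_config()].
#' @return list with `train`, `test` (`omics_matrix`), `train_labels`,
#'   `test_labels` (in `{-1, +1}`) and `config`.
#' @export
generate_sim_data <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  draw <- function(n, biased) {
    r <- cfg$within_block_correlation
    z <- matrix(rnorm(n * cfg$n_blocks), n, cfg$n_blocks)
    x <- matrix(NA_real_, n, cfg$n_blocks * cfg$block_size)
    for (b in seq_len(cfg$n_blocks)) {
      cols <- (b - 1) * cfg$block_size + seq_len(cfg$block_size)
      eps <- matrix(rnorm(n * cfg$block_size), n, cfg$block_size)
      x[, cols] <- sqrt(r) * z[, b] + sqrt(1 - r) * eps
    }
    latent <- rowSums(z[, seq_len(cfg$n_signal_blocks), drop = FALSE])
    y <- sign_pos(cfg$effect_size * latent + rnorm(n, sd = cfg$noise_sd))
    if (biased && length(cfg$biased_blocks) && cfg$bias_shift != 0) {
      for (b in cfg$biased_blocks) {
        cols <- (b - 1) * cfg$block_size + seq_len(cfg$block_size)
        x[, cols] <- x[, cols] + cfg$bias_shift
      }
    }
    colnames(x) <- unlist(lapply(seq_len(cfg$n_blocks), function(b)
      paste0("B", b, "_F", seq_len(cfg$block_size))))
    list(x = x, y = y, latent = latent)
  }
  tr <- draw(cfg$n_train, biased = FALSE)
  te <- draw(cfg$n_test, biased = TRUE)
  rownames(tr$x) <- paste0("train_", seq_len(cfg$n_train))
  rownames(te$x) <- paste0("test_", seq_len(cfg$n_test))
  list(train = omics_matrix(tr$x), train_labels = tr$y,
       test = omics_matrix(te$x), test_labels = te$y,
       train_latent = tr$latent, test_latent = te$latent,
       config = cfg)
}

#' Rank-based AUC of continuous scores against binary labels
#'
#' Mann-Whitney formulation with ties averaged: the probability that a
#' random positive sample scores above a random negative one (ties count
#' one half).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels labels in `{-1, +1}` (or logical / 0-1).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  if (all(labels %in% c(0, 1))) labels <- ifelse(labels == 1, 1, -1)
  if (!all(labels %in% c(-1, 1))) stop("labels must be binary")
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified-split benchmark of scoring methods
#'
#' For each repetition the data are split into stratified random
#' train/test portions, every scorer is fitted on the training part, and
#' the AUC of its continuous test scores is recorded. A scorer is a
#' function `f(X_train, y_train, X_test)` returning one numeric score per
#' test sample; a scorer error is recorded as `NA` for that repetition and
#' the run continues.
#'
#' @param X an `omics_matrix` or named numeric matrix.
#' @param y labels in `{-1, +1}` (or any binary vector).
#' @param scorers named list of scorer functions.
#' @param n_rep number of repetitions (default 100).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed; the whole benchmark is reproducible given it.
#' @return a `benchmark_result`: list with matrix `auc` (n_rep x scorers),
#'   `n_rep`, `train_frac`, `seed`.
#' @export
repeated_split_benchmark <- function(X, y, scorers, n_rep = 100,
                                     train_frac = 0.8, seed = 1) {
  v <- as_values(X)
  lm_ <- encode_labels(y, nrow(v))
  y <- lm_$y
  if (min(table(y)) < 10) stop("need at least 10 samples per class")
  if (is.null(names(scorers)))
    names(scorers) <- paste0("scorer", seq_along(scorers))
  aucs <- matrix(NA_real_, n_rep, length(scorers),
                 dimnames = list(NULL, names(scorers)))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(rep_seeds[r])
    idx_tr <- stratified_train_indices(y, train_frac)
    Xtr <- v[idx_tr, , drop = FALSE]
    Xte <- v[-idx_tr, , drop = FALSE]
    ytr <- y[idx_tr]
    yte <- y[-idx_tr]
    for (s in names(scorers)) {
      sc <- tryCatch(scorers[[s]](Xtr, ytr, Xte), error = function(e) NULL)
      if (!is.null(sc) && length(sc) == length(yte) && all(is.finite(sc)))
        aucs[r, s] <- auc_score(sc, yte)
    }
  }
  structure(list(auc = aucs, n_rep = n_rep, train_frac = train_frac,
                 seed = seed),
            class = "benchmark_result")
}

stratified_train_indices <- function(y, train_frac) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, floor(length(ix) * train_frac))))
  sort(idx)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d repetitions, train fraction %.2f\n",
              x$n_rep, x$train_frac))
  q <- apply(x$auc, 2, quantile, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  print(round(t(q), 4))
  invisible(x)
}

#' Bias-robustness experiment
#'
#' The headline behaviour of the confidence weighting: train the disjoint
#' ensemble on unbiased data, then evaluate it on a test set in which one
#' signal block has been shifted. Because the reliability models flag the
#' shifted features as untrustworthy, the learner leaning most on the
#' shifted block should receive a lower feature-reliability weight `c1`
#' than its cleaner sibling, and the confidence-weighted vote should rank
#' test samples at least as well as a uniform-weight vote. Each seed
#' generates a fresh data set, trains one ensemble, and evaluates it on
#' both the biased test set and its unbiased twin.
#'
#' @param n_seeds number of simulated repetitions.
#' @param cfg base [sim_config()]; its `biased_blocks`/`bias_shift` define
#'   the corruption (defaults: first signal block shifted by 3 sd).
#' @param n_learners,reg_strength ensemble settings.
#' @param seed master seed from which per-repetition seeds are drawn.
#' @param verbose print a dot per seed.
#' @return data frame with one row per seed: AUCs of the weighted and
#'   uniform votes on the biased and unbiased test sets, the mean `c1` of
#'   the most- and least-corrupted learners, and the corrupted learner's
#'   biased-weight fraction.
#' @export
bias_experiment <- function(n_seeds = 100,
                            cfg = sim_config(biased_blocks = 1,
                                             bias_shift = 3),
                            n_learners = 2, reg_strength = 0.1,
                            seed = 1, verbose = FALSE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_seeds)
  rows <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    cfg_k <- cfg
    cfg_k$seed <- seeds[k]
    dat <- generate_sim_data(cfg_k)

    # unbiased twin: same seed, no shift -> identical data minus the shift
    cfg0 <- cfg_k
    cfg0$bias_shift <- 0
    dat0 <- generate_sim_data(cfg0)

    set.seed(seeds[k])  # GP restarts etc.
    model <- fit_disjoint_ensemble(dat$train, dat$train_labels,
                                   n_learners = n_learners,
                                   reg_strength = reg_strength)
    pred_w <- predict(model, dat$test, weighting = "confidence")
    pred_u <- predict(model, dat$test, weighting = "uniform")
    pred_w0 <- predict(model, dat0$test, weighting = "confidence")
    pred_u0 <- predict(model, dat0$test, weighting = "uniform")

    biased_feats <- grep(paste0("^B", cfg$biased_blocks[1], "_"),
                         model$excluded, value = TRUE)
    frac <- vapply(model$learners, function(lr) {
      w <- abs(lr$weights)
      sum(w[names(w) %in% biased_feats]) / sum(w)
    }, numeric(1))
    corrupted <- which.max(frac)
    clean <- which.min(frac)
    mean_c1 <- vapply(seq_along(model$learners), function(i)
      mean(pred_w[[paste0("c1_L", i)]]), numeric(1))

    rows[[k]] <- data.frame(
      seed = seeds[k],
      auc_weighted = auc_score(pred_w$vote_score, dat$test_labels),
      auc_uniform = auc_score(pred_u$vote_score, dat$test_labels),
      auc_weighted_nobias = auc_score(pred_w0$vote_score, dat0$test_labels),
      auc_uniform_nobias = auc_score(pred_u0$vote_score, dat0$test_labels),
      c1_corrupted = mean_c1[corrupted],
      c1_clean = mean_c1[clean],
      corrupted_frac = frac[corrupted],
      n_learners = length(model$learners))
    if (verbose) cat(".")
  }
  if (verbose) cat("\n")
  do.call(rbind, rows)
}
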