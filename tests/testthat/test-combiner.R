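fake_learner <- function(weights, mu = 0, sigma = 1) {
  structure(list(index = 1L, phi = names(weights), weights = weights,
                 intercept = 0, mu_dec = mu, sigma_dec = sigma),
            class = "confens_learner")
}

test_that("classifier feature reliability is the |weight|-weighted mean of feature confidences", {
  lr1 <- fake_learner(c(a = 2))
  expect_equal(learner_feature_confidence(lr1, c(a = 0.7)), 0.7)

  lr2 <- fake_learner(c(a = 1, b = -1))
  expect_equal(learner_feature_confidence(lr2, c(a = 0.2, b = 0.8)), 0.5)

  lr3 <- fake_learner(c(a = 3, b = 1))
  expect_equal(learner_feature_confidence(lr3, c(a = 1, b = 0)), 0.75)

  expect_error(learner_feature_confidence(lr3, c(a = 1)), "b")
})

test_that("output confidence follows the two-sided normal tail of the decision value", {
  lr <- fake_learner(c(a = 1), mu = 2, sigma = 0.5)
  expect_equal(learner_output_confidence(lr, 2), 0)
  expect_equal(learner_output_confidence(lr, 2.5), 1 - 2 * pnorm(-1),
               tolerance = 1e-12)
  expect_equal(learner_output_confidence(lr, 2.5), 0.68269, tolerance = 1e-4)
  expect_gt(learner_output_confidence(lr, 2 + 3.5 * 0.5), 0.99)
})

test_that("final confidence is the product of the two components", {
  expect_equal(learner_confidence(1, 0.5), 0.5)
  expect_equal(learner_confidence(0.5, 0.5), 0.25)
  expect_equal(learner_confidence(0.8, 0), 0)
})

test_that("the weighted vote follows the documented arithmetic and tie rules", {
  v <- weighted_vote(c(0.3), c(1))
  expect_equal(v$label, 1)
  expect_equal(v$score, 1)

  v <- weighted_vote(c(0.9, 0.1), c(1, -1))
  expect_equal(v$score, 0.8, tolerance = 1e-12)
  expect_equal(v$label, 1)

  v <- weighted_vote(c(0.5, 0.5), c(1, -1))
  expect_equal(v$score, 0)
  expect_equal(v$label, 1)     # sign(0) := +1

  expect_warning(v0 <- weighted_vote(c(0, 0), c(-1, -1)), "confidences")
  expect_equal(v0$label, -1)   # fallback to unweighted mean
})

test_that("the vote is invariant to rescaling confidences and bounded in [-1, 1]", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    conf <- runif(k)
    labs <- sample(c(-1, 1), k, replace = TRUE)
    v1 <- weighted_vote(conf, labs)
    v2 <- weighted_vote(conf * runif(1, 0.1, 10), labs)
    expect_equal(v1$score, v2$score, tolerance = 1e-12)
    expect_true(v1$score >= -1 && v1$score <= 1)
    if (all(labs == 1)) expect_equal(v1$score, 1)
  }
})

test_that("the full prediction pipeline matches the scalar equation oracle", {
  for (seed in c(51, 52)) {
    m <- make_tiny_model(seed)
    fx <- make_block_fixture(n = 10, block = 4, n_blocks = 3, n_signal = 2,
                             seed = seed + 100)
    pred <- predict(m, fx$x)
    for (s in c(1, 5, 10)) {
      want <- combine_oracle(m, fx$x[s, ])
      expect_equal(pred$vote_score[s], want$score, tolerance = 1e-10)
      expect_equal(pred$yhat[s], want$yhat)
      for (i in seq_along(m$learners)) {
        expect_equal(pred[[paste0("c1_L", i)]][s], unname(want$c1[i]),
                     tolerance = 1e-10)
        expect_equal(pred[[paste0("c2_L", i)]][s], unname(want$c2[i]),
                     tolerance = 1e-10)
        expect_equal(pred[[paste0("d_L", i)]][s], unname(want$d[i]),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("a one-learner ensemble predicts exactly like its lone learner", {
  fx <- make_block_fixture(n = 40, block = 4, n_blocks = 3, seed = 53)
  set.seed(53)
  m <- fit_disjoint_ensemble(fx$x, fx$y, n_learners = 1, reg_strength = 0.05)
  pred <- predict(m, fx$x)
  d <- decision_values(m, fx$x)[, 1]
  expect_identical(pred$yhat, unname(ifelse(d >= 0, 1, -1)))
})

test_that("when all learners agree the vote returns the common label", {
  m <- make_tiny_model(54)
  fx <- make_block_fixture(n = 20, block = 4, n_blocks = 3, seed = 154)
  pred <- predict(m, fx$x)
  nl <- length(m$learners)
  labs <- as.matrix(pred[paste0("lab_L", seq_len(nl))])
  agree <- apply(labs, 1, function(r) length(unique(r)) == 1)
  expect_identical(pred$yhat[agree], labs[agree, 1])
})

test_that("explain_prediction reports one row per learner feature per sample", {
  m <- make_tiny_model(55)
  fx <- make_block_fixture(n = 6, block = 4, n_blocks = 3, seed = 155)
  pred <- predict(m, fx$x)
  long <- explain_prediction(pred)
  expect_equal(nrow(long),
               nrow(fx$x) * sum(lengths(lapply(m$learners, `[[`, "phi"))))
  expect_true(all(long$c_f > 0 & long$c_f <= 1))
})
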