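test_that("a perfectly separating single feature is selected and classified correctly", {
  set.seed(31)
  n <- 40
  x <- cbind(sig = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
             noise = rnorm(n))
  x <- scale(x)
  rownames(x) <- paste0("s", seq_len(n))
  y <- rep(c(-1, 1), each = n / 2)
  lr <- fit_sparse_learner(x, y, reg_strength = 0.05)
  expect_identical(lr$phi, "sig")
  d <- x[, "sig"] * lr$weights[["sig"]] + lr$intercept
  expect_true(all(sign(d) == y))
})

test_that("duplicated informative features collapse to one under the L1 penalty", {
  set.seed(32)
  n <- 60
  base <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  x <- cbind(f1 = base, f2 = base, noise = rnorm(n))
  x <- scale(x)
  rownames(x) <- paste0("s", seq_len(n))
  y <- rep(c(-1, 1), each = n / 2)
  lr <- fit_sparse_learner(x, y, reg_strength = 0.1)
  expect_lte(sum(c("f1", "f2") %in% lr$phi), 1)
})

test_that("pure-noise features under a strong penalty yield no learner", {
  set.seed(33)
  x <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(paste0("s", 1:50), paste0("f", 1:8)))
  y <- rep(c(-1, 1), 25)
  expect_null(fit_sparse_learner(x, y, reg_strength = 0.5))
  expect_error(fit_disjoint_ensemble(x, y, n_learners = 2,
                                     reg_strength = 0.5),
               "no predictive features")
})

test_that("learner feature sets are mutually disjoint across 100 seeded trainings", {
  for (seed in 1:100) {
    fx <- make_block_fixture(n = 60, block = 5, n_blocks = 4, n_signal = 2,
                             seed = seed)
    set.seed(seed)
    m <- fit_disjoint_ensemble(fx$x, fx$y, n_learners = 3,
                               reg_strength = 0.05, reliability = FALSE)
    phis <- lapply(m$learners, `[[`, "phi")
    if (length(phis) > 1) {
      for (i in seq_len(length(phis) - 1))
        for (j in seq((i + 1), length(phis)))
          expect_length(intersect(phis[[i]], phis[[j]]), 0)
    }
    # monotone exclusion: excluded set is the union in training order
    expect_identical(m$excluded, unlist(phis, use.names = FALSE))
  }
})

test_that("training stops early when the signal is exhausted", {
  set.seed(34)
  n <- 80
  sig <- c(rnorm(n / 2, -2.5), rnorm(n / 2, 2.5))
  x <- cbind(s1 = sig + rnorm(n, sd = .2), noise1 = rnorm(n),
             noise2 = rnorm(n))
  rownames(x) <- paste0("s", seq_len(n))
  y <- rep(c(-1, 1), each = n / 2)
  m <- fit_disjoint_ensemble(x, y, n_learners = 5, reg_strength = 0.2,
                             reliability = FALSE)
  expect_lt(length(m$learners), 5)
})

test_that("decision values match an explicit dot-product oracle to 1e-12", {
  set.seed(35)
  for (rep in 1:20) {
    fx <- make_block_fixture(n = 50, block = 4, n_blocks = 3, seed = rep)
    m <- fit_disjoint_ensemble(fx$x, fx$y, n_learners = 2,
                               reg_strength = 0.05, reliability = FALSE)
    idx <- sample(nrow(fx$x), 1)
    d <- decision_values(m, fx$x)[idx, ]
    xs <- (fx$x[idx, ] - m$center) / m$scale
    want <- vapply(m$learners, function(lr)
      sum(lr$weights * xs[lr$phi]) + lr$intercept, numeric(1))
    expect_equal(unname(d), unname(want), tolerance = 1e-12)
  }
})

test_that("training is deterministic given data and penalty", {
  fx <- make_block_fixture(n = 60, block = 5, n_blocks = 4, seed = 77)
  set.seed(77)
  m1 <- fit_disjoint_ensemble(fx$x, fx$y, n_learners = 2,
                              reg_strength = 0.05, reliability = FALSE)
  set.seed(77)
  m2 <- fit_disjoint_ensemble(fx$x, fx$y, n_learners = 2,
                              reg_strength = 0.05, reliability = FALSE)
  expect_identical(lapply(m1$learners, `[[`, "phi"),
                   lapply(m2$learners, `[[`, "phi"))
  for (i in seq_along(m1$learners))
    expect_equal(m1$learners[[i]]$weights, m2$learners[[i]]$weights,
                 tolerance = 1e-10)
})

test_that("missing model features are reported by name", {
  fx <- make_block_fixture(n = 50, block = 4, n_blocks = 3, seed = 36)
  m <- fit_disjoint_ensemble(fx$x, fx$y, n_learners = 1,
                             reg_strength = 0.05, reliability = FALSE)
  f <- m$learners[[1]]$phi[1]
  expect_error(decision_values(m, fx$x[, setdiff(colnames(fx$x), f)]), f)
})

test_that("labels other than -1/+1 are mapped and decoded consistently", {
  fx <- make_block_fixture(n = 60, block = 5, n_blocks = 4, seed = 37)
  lab <- ifelse(fx$y == 1, "poor", "favorable")
  m <- fit_disjoint_ensemble(fx$x, lab, n_learners = 1,
                             reg_strength = 0.05, reliability = FALSE)
  expect_setequal(unname(m$label_map), c("favorable", "poor"))
  # first sorted level maps to -1
  expect_identical(unname(m$label_map["-1"]), "favorable")
})
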