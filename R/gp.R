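#' Fit a squared-exponential Gaussian-process regressor
#'
#' Standard GP regression with an isotropic squared-exponential kernel
#' `k(x, x') = sf2 * exp(-||x - x'||^2 / (2 * ell^2))` plus additive noise
#' `sn2`. Hyperparameters `(ell, sf2, sn2)` are set by maximising the log
#' marginal likelihood (L-BFGS-B on the log scale, analytic gradients) from
#' `n_restarts` jittered starting points; the noise variance is bounded
#' below for numerical stability. The predictive distribution returned by
#' [gp_predict()] includes the noise term, so it describes a new *observed*
#' value rather than the latent function.
#'
#' @param X numeric matrix of inputs (n x d).
#' @param y numeric response vector of length n.
#' @param n_restarts number of optimisation restarts (first start is a
#'   data-driven heuristic, the rest are jittered; uses the current RNG).
#' @param noise_floor lower bound on the noise variance.
#' @param optimize if `FALSE`, keep the heuristic initial hyperparameters
#'   (useful for fast oracle comparisons).
#' @return an object of class `confens_gp`.
#' @export
gp_fit <- function(X, y, n_restarts = 3, noise_floor = 1e-6,
                   optimize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("GP training values must be finite")

  ymean <- mean(y)
  yc <- y - ymean
  D2 <- sq_dist(X, X)

  # heuristic start: median pairwise distance, data variance, 10% noise
  med <- sqrt(median(D2[upper.tri(D2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  vy <- var(yc)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  theta0 <- c(log(med), log(vy), log(max(0.1 * vy, noise_floor)))

  lower <- c(log(med) - log(1e3), log(1e-8), log(noise_floor))
  upper <- c(log(med) + log(1e3), log(1e4 * vy), log(1e4 * vy))

  theta_best <- pmin(pmax(theta0, lower), upper)
  if (optimize) {
    best_nll <- Inf
    cache <- new.env(parent = emptyenv())
    nll_at <- function(theta) {
      key <- paste(format(theta, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        cache$key <- key
        cache$val <- gp_nll_grad_cpp(theta, D2, yc)
      }
      cache$val
    }
    for (r in seq_len(max(1, n_restarts))) {
      # later restarts perturb the best parameters found so far
      start <- if (r == 1) theta0 else theta_best + rnorm(3, sd = 0.5)
      start <- pmin(pmax(start, lower), upper)
      fit <- tryCatch(
        optim(start, fn = function(th) nll_at(th)$nll,
              gr = function(th) nll_at(th)$grad,
              method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = 40, factr = 1e9)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < best_nll) {
        best_nll <- fit$value
        theta_best <- fit$par
      }
    }
  }

  ell <- exp(theta_best[1])
  sf2 <- exp(theta_best[2])
  sn2 <- max(exp(theta_best[3]), noise_floor)

  K <- sf2 * exp(-0.5 * D2 / ell^2)
  diag(K) <- diag(K) + sn2
  L <- chol_safe(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))

  structure(list(X = X, y = y, ymean = ymean, alpha = alpha, L = L,
                 ell = ell, sf2 = sf2, sn2 = sn2),
            class = "confens_gp")
}

#' Gaussian-process posterior mean and standard deviation
#'
#' @param gp a fitted `confens_gp`.
#' @param Xnew numeric matrix of query inputs (m x d), or a vector for a
#'   single query.
#' @return list with numeric vectors `mean` and `sd` (predictive sd of an
#'   observed value, i.e. including the noise variance, floored at 1e-8).
#' @export
gp_predict <- function(gp, Xnew) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Xnew <- as.matrix(Xnew)
  storage.mode(Xnew) <- "double"
  Ks <- gp$sf2 * exp(-0.5 * sq_dist(gp$X, Xnew) / gp$ell^2)  # n x m
  mu <- gp$ymean + drop(crossprod(Ks, gp$alpha))
  V <- forwardsolve(t(gp$L), Ks)                             # n x m
  varf <- pmax(gp$sf2 - colSums(V^2), 0)
  sdv <- pmax(sqrt(varf + gp$sn2), .SIGMA_FLOOR)
  list(mean = as.numeric(mu), sd = as.numeric(sdv))
}

# squared Euclidean distances between rows of A (n x d) and rows of B (m x d)
sq_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# upper-triangular Cholesky with growing jitter on failure
chol_safe <- function(K) {
  jitter <- 0
  scale <- mean(diag(K))
  for (attempt in 1:6) {
    L <- tryCatch(chol(K + diag(jitter, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jitter <- if (jitter == 0) 1e-10 * scale else jitter * 100
  }
  stop("kernel matrix is not positive definite even after jitter")
}
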