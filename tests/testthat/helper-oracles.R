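# Independent oracles and fixture builders used across the test files.
# Everything here is written as plainly as possible and avoids the package's
# own code paths for the quantity being checked.

# --- closed-form GP posterior by direct matrix algebra ----------------------
# (predictive sd includes the noise term, matching the package contract)
gp_posterior_oracle <- function(Xtr, ytr, Xnew, ell, sf2, sn2) {
  kern <- function(A, B) {
    K <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A)))
      for (j in seq_len(nrow(B)))
        K[i, j] <- sf2 * exp(-0.5 * sum((A[i, ] - B[j, ])^2) / ell^2)
    K
  }
  m <- mean(ytr)
  K <- kern(Xtr, Xtr) + diag(sn2, nrow(Xtr))
  Ks <- kern(Xtr, Xnew)
  Kinv_y <- solve(K, ytr - m)
  mu <- m + drop(t(Ks) %*% Kinv_y)
  var_f <- sf2 - colSums(Ks * solve(K, Ks))
  list(mean = mu, sd = sqrt(pmax(var_f, 0) + sn2))
}

# --- straight-line scalar re-implementation of the combining equations ------
# takes a fitted ensemble and ONE raw sample (named vector); recomputes every
# confidence with scalar arithmetic, using the GP oracle above for posteriors
combine_oracle <- function(model, x_raw) {
  feats <- names(model$center)
  xs <- (x_raw[feats] - model$center) / model$scale

  c_f <- sapply(names(model$reliability_models), function(f) {
    r <- model$reliability_models[[f]]
    post <- gp_posterior_oracle(r$gp$X, r$gp$y, matrix(xs[r$predictors],
                                                      nrow = 1),
                                r$gp$ell, r$gp$sf2, r$gp$sn2)
    z <- (xs[[f]] - post$mean) / max(post$sd, 1e-8)
    2 * pnorm(-abs(z))
  })

  nl <- length(model$learners)
  c1 <- c2 <- cc <- d <- lab <- numeric(nl)
  for (i in seq_len(nl)) {
    lr <- model$learners[[i]]
    d[i] <- sum(lr$weights * xs[lr$phi]) + lr$intercept
    lab[i] <- if (d[i] >= 0) 1 else -1
    num <- 0; den <- 0
    for (f in lr$phi) {
      num <- num + c_f[[f]] * abs(lr$weights[[f]])
      den <- den + abs(lr$weights[[f]])
    }
    c1[i] <- num / den
    c2[i] <- 1 - 2 * pnorm(-abs((d[i] - lr$mu_dec) / lr$sigma_dec))
    cc[i] <- c1[i] * c2[i]
  }
  score <- sum(cc * lab) / sum(cc)
  list(c_f = c_f, d = d, lab = lab, c1 = c1, c2 = c2, c = cc,
       score = score, yhat = if (score >= 0) 1 else -1)
}

# --- AUC by brute-force pair counting ---------------------------------------
auc_pair_oracle <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == -1)
  tot <- 0
  for (i in pos)
    for (j in neg)
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# --- BFS all-pairs distances (independent of igraph::distances) -------------
bfs_distances <- function(adj, from) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!is.finite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

# nodes and edges on ANY shortest path between any pair of terminals,
# enumerated from BFS distance matrices
sp_union_oracle <- function(edge_mat, n_nodes, terminals) {
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edge_mat))) {
    a <- edge_mat[k, 1]; b <- edge_mat[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- t(sapply(seq_len(n_nodes), function(v) bfs_distances(adj, v)))
  keep_v <- rep(FALSE, n_nodes)
  keep_e <- rep(FALSE, nrow(edge_mat))
  keep_v[terminals] <- TRUE
  for (a in terminals) for (b in terminals) {
    if (a >= b || !is.finite(D[a, b])) next
    for (w in seq_len(n_nodes))
      if (is.finite(D[a, w]) && is.finite(D[w, b]) &&
          D[a, w] + D[w, b] == D[a, b]) keep_v[w] <- TRUE
    for (k in seq_len(nrow(edge_mat))) {
      u <- edge_mat[k, 1]; v <- edge_mat[k, 2]
      if ((is.finite(D[a, u]) && is.finite(D[v, b]) &&
           D[a, u] + 1 + D[v, b] == D[a, b]) ||
          (is.finite(D[a, v]) && is.finite(D[u, b]) &&
           D[a, v] + 1 + D[u, b] == D[a, b])) keep_e[k] <- TRUE
    }
  }
  list(vertices = which(keep_v), edges = which(keep_e))
}

# --- fixture builders --------------------------------------------------------
# small two-block data set with clear signal; returns matrix + labels
make_block_fixture <- function(n = 60, block = 5, n_blocks = 4,
                               n_signal = 2, r = 0.8, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n_blocks), n, n_blocks)
  x <- matrix(NA_real_, n, n_blocks * block)
  for (b in seq_len(n_blocks)) {
    cols <- (b - 1) * block + seq_len(block)
    x[, cols] <- sqrt(r) * z[, b] + sqrt(1 - r) *
      matrix(rnorm(n * block), n, block)
  }
  colnames(x) <- paste0("B", rep(seq_len(n_blocks), each = block),
                        "_F", rep(seq_len(block), n_blocks))
  rownames(x) <- paste0("s", seq_len(n))
  y <- ifelse(rowSums(z[, seq_len(n_signal), drop = FALSE]) +
                rnorm(n, sd = 0.3) >= 0, 1, -1)
  list(x = x, y = y)
}

# tiny fully fitted ensemble (with reliability models) for pipeline oracles
make_tiny_model <- function(seed, n = 30, reg = 0.05) {
  fx <- make_block_fixture(n = n, block = 4, n_blocks = 3, n_signal = 2,
                           seed = seed)
  set.seed(seed)
  fit_disjoint_ensemble(fx$x, fx$y, n_learners = 2, reg_strength = reg)
}
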