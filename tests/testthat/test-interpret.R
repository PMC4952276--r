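toy_graph <- function(edges) {
  igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                              directed = FALSE)
}

test_that("the per-sample model graph mirrors the reported confidences", {
  m <- make_tiny_model(61)
  fx <- make_block_fixture(n = 5, block = 4, n_blocks = 3, seed = 161)
  pred <- predict(m, fx$x)
  g <- sample_model_graph(m, pred, sample_id = pred$sample_id[2])
  n_feat <- sum(lengths(lapply(m$learners, `[[`, "phi")))
  expect_equal(igraph::ecount(g), n_feat)
  expect_equal(igraph::vcount(g), n_feat + length(m$learners))
  cf <- attr(pred, "feature_confidence")
  f <- m$learners[[1]]$phi[1]
  expect_equal(igraph::V(g)$confidence[igraph::V(g)$name == f],
               unname(cf[2, f]))
  lconf <- igraph::V(g)$confidence[igraph::V(g)$name == "L_1"]
  expect_equal(lconf, pred$c_L1[2])
  expect_true(all(igraph::V(g)$shade >= 0 & igraph::V(g)$shade <= 1))
})

test_that("graph attributes survive a GraphML round trip", {
  m <- make_tiny_model(62)
  fx <- make_block_fixture(n = 5, block = 4, n_blocks = 3, seed = 162)
  pred <- predict(m, fx$x)
  g <- sample_model_graph(m, pred)
  path <- tempfile(fileext = ".graphml")
  write_graphml(g, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  ord <- match(igraph::V(g)$name, igraph::V(g2)$name)
  expect_equal(igraph::V(g2)$confidence[ord], igraph::V(g)$confidence,
               tolerance = 1e-9)
})

test_that("connectors on the path between selected genes are kept, pendant chains pruned", {
  g <- toy_graph(c("A", "x", "x", "B", "x", "y", "y", "w"))
  sub <- ppi_subnetwork(g, c("A", "B"))
  expect_setequal(igraph::V(sub)$name, c("A", "x", "B"))  # y,w pruned
  expect_equal(igraph::ecount(sub), 2)
  expect_true(all(igraph::V(sub)$in_ppi))
})

test_that("selected genes absent from the network come back flagged and isolated", {
  g <- toy_graph(c("A", "B"))
  sub <- ppi_subnetwork(g, c("A", "Z1", "Z2"))
  v <- igraph::as_data_frame(sub, what = "vertices")
  expect_setequal(v$name, c("A", "Z1", "Z2"))
  expect_false(v$in_ppi[v$name == "Z1"])
  expect_equal(igraph::ecount(sub), 0)
})

test_that("shortest-path union matches the brute-force BFS oracle on random toys", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    # random connected-ish sparse graph: a ring plus random chords
    edges <- rbind(cbind(1:(n - 1), 2:n),
                   cbind(sample(n, 10, TRUE), sample(n, 10, TRUE)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- unique(t(apply(edges, 1, sort)))
    g <- igraph::graph_from_edgelist(
      matrix(paste0("n", edges), ncol = 2), directed = FALSE)
    terminals_i <- sample(n, 5)
    terminals <- paste0("n", terminals_i)
    terminals <- intersect(terminals, igraph::V(g)$name)

    sub <- confens:::shortest_path_union(g, terminals)

    name_to_id <- match(igraph::V(g)$name, paste0("n", seq_len(n)))
    el <- igraph::as_edgelist(g)
    edge_mat <- cbind(name_to_id[match(el[, 1], igraph::V(g)$name)],
                      name_to_id[match(el[, 2], igraph::V(g)$name)])
    want <- sp_union_oracle(edge_mat, n, sort(unique(
      name_to_id[match(terminals, igraph::V(g)$name)])))

    got_edges <- apply(igraph::as_edgelist(sub), 1, function(e)
      paste(sort(e), collapse = "-"))
    want_edges <- apply(edge_mat[want$edges, , drop = FALSE], 1, function(e)
      paste(sort(paste0("n", e)), collapse = "-"))
    expect_setequal(got_edges, want_edges)
  }
})

test_that("the pruned subnetwork is a forest whose leaves are all selected genes", {
  for (seed in 21:30) {
    set.seed(seed)
    n <- 30
    edges <- rbind(cbind(1:(n - 1), 2:n),
                   cbind(sample(n, 12, TRUE), sample(n, 12, TRUE)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(paste0("n", edges), ncol = 2), directed = FALSE)
    g <- igraph::simplify(g)
    selected <- paste0("n", sample(n, 4))
    sub <- ppi_subnetwork(g, toupper(selected))
    sub_named <- igraph::induced_subgraph(
      sub, igraph::V(sub)$name[igraph::V(sub)$in_ppi])
    # acyclic per component: |E| = |V| - number of components
    comp <- igraph::components(sub_named)
    expect_equal(igraph::ecount(sub_named),
                 igraph::vcount(sub_named) - comp$no)
    deg <- igraph::degree(sub_named)
    leaves <- igraph::V(sub_named)$name[deg <= 1]
    expect_true(all(leaves %in% toupper(selected)))
  }
})

fake_model <- function(...) {
  phis <- list(...)
  structure(list(learners = lapply(seq_along(phis), function(i)
    structure(list(index = i, phi = phis[[i]],
                   weights = stats::setNames(rep(1, length(phis[[i]])),
                                             phis[[i]]),
                   intercept = 0, mu_dec = 0, sigma_dec = 1),
              class = "confens_learner")),
    excluded = unlist(phis)), class = "confens_ensemble")
}

test_that("co-occurrence counts match the hand-counted example and a nested-loop oracle", {
  models <- list(fake_model(c("A", "B")), fake_model(c("A", "B")),
                 fake_model(c("A", "C")))
  g <- build_cooccurrence_graph(models)
  v <- igraph::as_data_frame(g, what = "vertices")
  expect_equal(unname(v$freq[v$name == "A"]), 3)
  e <- igraph::as_data_frame(g, what = "edges")
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_equal(unname(e$weight[key == "A B"]), 2)
  expect_equal(unname(e$weight[key == "A C"]), 1)

  # disjoint singletons -> no edges
  g0 <- build_cooccurrence_graph(list(fake_model("A", "B"),
                                      fake_model("C")))
  expect_equal(igraph::ecount(g0), 0)

  # random fixture vs nested-loop oracle
  set.seed(71)
  models <- lapply(1:12, function(i) {
    k <- sample(2:4, 1)
    do.call(fake_model, lapply(seq_len(k), function(j)
      sample(LETTERS[1:8], sample(1:3, 1))))
  })
  g <- build_cooccurrence_graph(models)
  pair_count <- new.env(parent = emptyenv())
  freq_count <- new.env(parent = emptyenv())
  for (m in models) for (lr in m$learners) {
    for (f in lr$phi)
      assign(f, (if (exists(f, freq_count)) get(f, freq_count) else 0) + 1,
             freq_count)
    if (length(lr$phi) >= 2) {
      ps <- t(utils::combn(sort(lr$phi), 2))
      for (k in seq_len(nrow(ps))) {
        key <- paste(ps[k, 1], ps[k, 2])
        assign(key,
               (if (exists(key, pair_count)) get(key, pair_count) else 0) + 1,
               pair_count)
      }
    }
  }
  e <- igraph::as_data_frame(g, what = "edges")
  expect_equal(nrow(e), length(ls(pair_count)))
  for (k in seq_len(nrow(e))) {
    key <- paste(pmin(e$from[k], e$to[k]), pmax(e$from[k], e$to[k]))
    expect_equal(unname(e$weight[k]), get(key, pair_count))
  }
  v <- igraph::as_data_frame(g, what = "vertices")
  for (k in seq_len(nrow(v)))
    expect_equal(unname(v$freq[k]), get(v$name[k], freq_count))
  # edge weight can never exceed either endpoint frequency
  for (k in seq_len(nrow(e)))
    expect_lte(e$weight[k], min(v$freq[v$name == e$from[k]],
                                v$freq[v$name == e$to[k]]))
})

test_that("the KDE threshold sits at the distribution's 90th percentile", {
  # one draw of n = 1000 has q90 sampling noise ~0.05 on top of the
  # kernel-smoothing inflation, so the location check averages over draws
  # while the estimator itself is checked per-draw against a direct
  # Gaussian-sum oracle
  thrs <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- rnorm(1000)
    thr <- kde_percentile_threshold(x, 90)
    h <- stats::bw.nrd(x)
    cdf_at <- function(t) mean(pnorm((t - x) / h))
    expect_lt(abs(cdf_at(thr) - 0.9), 0.01)
    thr
  }, numeric(1))
  expect_lt(abs(mean(thrs) - qnorm(0.9)), 0.08)

  expect_equal(kde_percentile_threshold(c(3, 3, 3)), 3)
  two <- kde_percentile_threshold(c(1, 10))
  expect_true(two > 1 && two <= 10)
})

test_that("pruning keeps only heavy edges and never grows the graph", {
  set.seed(73)
  # 90 weight-1 edges, 10 weight-10 edges
  n_nodes <- 40
  mk_edge <- function(k) {
    e <- t(replicate(k, sample(n_nodes, 2)))
    e
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, n_nodes, name = paste0("g", seq_len(n_nodes)),
                            freq = sample(1:3, n_nodes, TRUE))
  e1 <- mk_edge(90); e2 <- mk_edge(10)
  g <- igraph::add_edges(g, t(rbind(e1, e2)),
                         weight = c(rep(1, 90), rep(10, 10)))
  class(g) <- c("confens_cooccurrence", class(g))
  pg <- prune_graph(g)
  thr <- igraph::graph_attr(pg, "edge_threshold")
  expect_true(thr > 1 && thr < 10)
  expect_true(all(igraph::E(pg)$weight == 10))
  expect_lte(igraph::vcount(pg), igraph::vcount(g))
  expect_lte(igraph::ecount(pg), igraph::ecount(g))
  expect_true(all(igraph::E(pg)$weight > thr))

  empty <- igraph::make_empty_graph(directed = FALSE)
  class(empty) <- c("confens_cooccurrence", class(empty))
  expect_equal(igraph::vcount(prune_graph(empty)), 0)
})
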