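#' Per-sample classifier/feature confidence graph
#'
#' Bipartite graph for one predicted sample: one node per classifier
#' (labelled `L_i`, carrying its final confidence `c_li`) connected to the
#' features it uses (carrying their per-sample reliability `c_f`).
#' Confidences are also min-max normalised across the graph into a
#' `shade` attribute in \[0, 1\] for colour scales (darker = more
#' confident).
#'
#' @param model a `confens_ensemble`.
#' @param pred a `confens_prediction` from [predict.confens_ensemble()].
#' @param sample_id which sample of `pred` to draw (default: first).
#' @return an `igraph` graph with vertex attributes `kind`
#'   (`"learner"`/`"feature"`), `confidence` and `shade`.
#' @export
sample_model_graph <- function(model, pred, sample_id = pred$sample_id[1]) {
  s <- match(sample_id, pred$sample_id)
  if (is.na(s)) stop("sample not found in prediction: ", sample_id)
  cf <- attr(pred, "feature_confidence")

  edges <- character(0)
  vnames <- character(0)
  vconf <- numeric(0)
  vkind <- character(0)
  for (lr in model$learners) {
    lname <- paste0("L_", lr$index)
    vnames <- c(vnames, lname)
    vconf <- c(vconf, pred[[paste0("c_L", lr$index)]][s])
    vkind <- c(vkind, "learner")
    for (f in lr$phi) {
      edges <- c(edges, lname, f)
      vnames <- c(vnames, f)
      vconf <- c(vconf, cf[s, f])
      vkind <- c(vkind, "feature")
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(vnames), name = vnames,
                            kind = vkind, confidence = vconf)
  g <- igraph::add_edges(g, match(edges, vnames))
  rng <- range(vconf)
  shade <- if (diff(rng) > 0) (vconf - rng[1]) / diff(rng)
           else rep(0.5, length(vconf))
  igraph::set_vertex_attr(g, "shade", value = shade)
}

#' Read a protein-interaction edge list
#'
#' Two-column tab-delimited gene-symbol pairs (HPRD-style, no header).
#' Self-loops and duplicate edges are dropped; names are uppercased.
#'
#' @param path file path.
#' @return an undirected `igraph` graph.
#' @export
read_ppi_edges <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected at least two columns of gene symbols")
  el <- cbind(toupper(trimws(df[[1]])), toupper(trimws(df[[2]])))
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Protein-interaction subnetwork connecting selected genes
#'
#' Connects the selected genes through the PPI network in three steps:
#' (1) the union of *all* shortest paths between every pair of selected
#' genes (per connected component); (2) the minimum spanning tree of that
#' union subgraph (unweighted, deterministic via lexicographic edge
#' ordering); (3) iterative pruning of non-selected leaves until every leaf
#' is a selected gene. Selected genes absent from the PPI network are
#' returned as isolated nodes flagged `in_ppi = FALSE`.
#'
#' @param ppi undirected `igraph` PPI network (e.g. [read_ppi_edges()]).
#' @param selected character vector of selected gene symbols.
#' @param mst take the minimum spanning tree of the shortest-path union
#'   (default `TRUE`, as in the reference procedure).
#' @return an `igraph` graph with logical vertex attributes `selected` and
#'   `in_ppi`.
#' @export
ppi_subnetwork <- function(ppi, selected, mst = TRUE) {
  selected <- unique(toupper(selected))
  if (length(selected) == 0) stop("`selected` must be nonempty")
  present <- intersect(selected, igraph::V(ppi)$name)
  absent <- setdiff(selected, present)

  sub <- shortest_path_union(ppi, present)
  if (mst && igraph::ecount(sub) > 0) {
    ekey <- apply(igraph::as_edgelist(sub), 1, function(e)
      paste(sort(e), collapse = "|"))
    # unit weights with a tiny lexicographic tie-break -> unique MST
    w <- 1 + rank(ekey) * 1e-9
    sub <- igraph::mst(sub, weights = w)
  }
  sub <- prune_unselected_leaves(sub, present)
  if (length(absent))
    sub <- igraph::add_vertices(sub, length(absent), name = absent)
  vsel <- igraph::V(sub)$name %in% selected
  vin <- !(igraph::V(sub)$name %in% absent)
  sub <- igraph::set_vertex_attr(sub, "selected", value = vsel)
  igraph::set_vertex_attr(sub, "in_ppi", value = vin)
}

# union of all shortest paths between every pair of terminals, using the
# distance-matrix characterisation: vertex w lies on a geodesic a-b iff
# d(a,w) + d(w,b) = d(a,b); edge (u,v) iff d(a,u) + 1 + d(v,b) = d(a,b)
# (or the symmetric condition)
shortest_path_union <- function(g, terminals) {
  if (length(terminals) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  dT <- igraph::distances(g, v = terminals)          # terminals x all
  keep_v <- rep(FALSE, igraph::vcount(g))
  names(keep_v) <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  keep_e <- rep(FALSE, nrow(el))
  nt <- length(terminals)
  if (nt >= 1) keep_v[terminals] <- TRUE
  if (nt >= 2) {
    for (i in seq_len(nt - 1)) {
      for (j in seq((i + 1), nt)) {
        dab <- dT[i, terminals[j]]
        if (!is.finite(dab)) next  # different components
        on_path <- is.finite(dT[i, ]) & is.finite(dT[j, ]) &
          (dT[i, ] + dT[j, ] == dab)
        keep_v <- keep_v | on_path
        du <- dT[i, el[, 1]]; dv <- dT[j, el[, 2]]
        du2 <- dT[i, el[, 2]]; dv2 <- dT[j, el[, 1]]
        keep_e <- keep_e |
          (is.finite(du) & is.finite(dv) & du + 1 + dv == dab) |
          (is.finite(du2) & is.finite(dv2) & du2 + 1 + dv2 == dab)
      }
    }
  }
  sub <- igraph::subgraph_from_edges(g, which(keep_e), delete.vertices = TRUE)
  # terminals that sit on no kept edge (isolated in their component)
  lone <- setdiff(names(keep_v)[keep_v],
                  igraph::V(sub)$name)
  lone <- intersect(lone, terminals)
  if (length(lone))
    sub <- igraph::add_vertices(sub, length(lone), name = lone)
  sub
}

prune_unselected_leaves <- function(g, selected) {
  repeat {
    deg <- igraph::degree(g)
    drop <- igraph::V(g)$name[deg <= 1 &
                                !(igraph::V(g)$name %in% selected)]
    if (length(drop) == 0) return(g)
    g <- igraph::delete_vertices(g, drop)
  }
}

#' Feature co-occurrence graph across repeated trainings
#'
#' One node per feature ever selected by any learner of any model; node
#' frequency counts how many (model, learner) pairs selected it, and the
#' weight of edge (s, t) counts how many learners selected both s and t
#' together.
#'
#' @param models list of `confens_ensemble` objects (e.g. one per random
#'   train/test partition).
#' @return an `igraph` graph with vertex attribute `freq` and edge
#'   attribute `weight`, wrapped with class `confens_cooccurrence`.
#' @export
build_cooccurrence_graph <- function(models) {
  if (length(models) == 0) stop("need at least one model")
  freq <- new.env(parent = emptyenv())
  pair <- new.env(parent = emptyenv())
  for (m in models) {
    for (lr in m$learners) {
      phi <- sort(lr$phi)
      for (f in phi)
        assign(f, (if (exists(f, freq)) get(f, freq) else 0) + 1, freq)
      if (length(phi) >= 2) {
        cmb <- utils::combn(phi, 2)
        for (k in seq_len(ncol(cmb))) {
          key <- paste(cmb[1, k], cmb[2, k], sep = "\t")
          assign(key, (if (exists(key, pair)) get(key, pair) else 0) + 1,
                 pair)
        }
      }
    }
  }
  feats <- sort(ls(freq))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(feats), name = feats,
                            freq = vapply(feats, get, numeric(1),
                                          envir = freq))
  keys <- ls(pair)
  if (length(keys)) {
    el <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    g <- igraph::add_edges(g, t(cbind(match(el[, 1], feats),
                                      match(el[, 2], feats))),
                           weight = vapply(keys, get, numeric(1),
                                           envir = pair))
  }
  class(g) <- c("confens_cooccurrence", class(g))
  g
}

#' Kernel-density percentile threshold
#'
#' Fits a Gaussian kernel density estimate (Scott's rule-of-thumb
#' bandwidth) to the values and returns the point where the estimated CDF
#' first reaches `percentile`/100, found by numeric integration on a grid
#' of at least 512 points spanning `[min - 3h, max + 3h]`. The result is
#' clamped to the observed value range so the threshold is always
#' attainable by the data (with very few values the rule-of-thumb
#' bandwidth can push the nominal percentile outside the range). With
#' fewer than two distinct values the maximum is returned.
#'
#' @param values positive numeric vector (e.g. edge weights).
#' @param percentile percentile in (0, 100), default 90.
#' @param n_grid grid size (>= 512).
#' @return the threshold value.
#' @export
kde_percentile_threshold <- function(values, percentile = 90,
                                     n_grid = 512) {
  values <- as.numeric(values)
  if (length(unique(values)) < 2) return(max(values))
  n_grid <- max(n_grid, 512)
  h <- stats::bw.nrd(values)
  if (!is.finite(h) || h <= 0) h <- sd(values) * length(values)^(-1 / 5)
  d <- stats::density(values, bw = h, n = n_grid,
                      from = min(values) - 3 * h, to = max(values) + 3 * h)
  dx <- diff(d$x[1:2])
  cdf <- cumsum((d$y[-1] + d$y[-n_grid]) / 2) * dx  # trapezoid
  cdf <- cdf / cdf[length(cdf)]
  idx <- which(cdf >= percentile / 100)[1]
  min(max(d$x[idx + 1], min(values)), max(values))
}

#' Prune a co-occurrence graph by KDE-percentile thresholds
#'
#' Edges whose weight does not exceed the edge threshold (the KDE
#' percentile of the edge weights) are removed; nodes whose selection
#' frequency exceeds the node threshold (same rule on the frequencies) are
#' flagged `labeled`; isolated unlabeled nodes are dropped.
#'
#' @param g a `confens_cooccurrence` graph.
#' @param percentile percentile used for both thresholds (default 90).
#' @return the pruned graph, with attributes `edge_threshold` and
#'   `node_threshold` attached as graph attributes.
#' @export
prune_graph <- function(g, percentile = 90) {
  if (igraph::vcount(g) == 0) return(g)
  et <- if (igraph::ecount(g) > 0)
    kde_percentile_threshold(igraph::E(g)$weight, percentile) else Inf
  nt <- kde_percentile_threshold(igraph::V(g)$freq, percentile)
  if (igraph::ecount(g) > 0)
    g <- igraph::delete_edges(g, which(igraph::E(g)$weight <= et))
  labeled <- igraph::V(g)$freq > nt
  g <- igraph::set_vertex_attr(g, "labeled", value = labeled)
  drop <- which(igraph::degree(g) == 0 & !labeled)
  if (length(drop)) g <- igraph::delete_vertices(g, drop)
  g <- igraph::set_graph_attr(g, "edge_threshold", et)
  igraph::set_graph_attr(g, "node_threshold", nt)
}

#' Write a graph as GraphML (optionally also DOT)
#'
#' @param g an `igraph` graph.
#' @param path output path (`.graphml`).
#' @param dot_path optional additional DOT output path.
#' @export
write_graphml <- function(g, path, dot_path = NULL) {
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(dot_path))
    igraph::write_graph(g, dot_path, format = "dot")
  invisible(path)
}
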