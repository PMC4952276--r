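#' Aggregate expression probes to gene-level features
#'
#' Maps microarray probes to genes and collapses multiple probes per gene by
#' taking, for every sample, the median of the probe values. Probes without
#' a gene mapping (empty or `NA` gene symbol) and probes mapped ambiguously
#' to several genes (symbols containing `;`, `,`, `|` or `///`) are dropped,
#' with a message reporting how many.
#'
#' @param probes data frame with columns `probe_id`, `gene`, then one
#'   numeric column per sample.
#' @return an `omics_matrix` (samples x genes, assay `"expression"`).
#' @export
aggregate_expression <- function(probes) {
  aggregate_probes(probes, assay = "expression")
}

#' Aggregate methylation probes to gene-level promoter features
#'
#' Keeps only probes annotated to the promoter region of their gene,
#' discards the rest, and collapses the surviving probes per gene by the
#' median beta value per sample. Genes left without any promoter probe are
#' absent from the output. Beta values outside \[0, 1\] are a validation
#' error.
#'
#' @param probes data frame with columns `probe_id`, `gene`, `region`
#'   (`"promoter"` marks retained probes), then one numeric column per
#'   sample.
#' @return an `omics_matrix` (samples x genes, assay `"methylation"`).
#' @export
aggregate_methylation <- function(probes) {
  if (!"region" %in% names(probes))
    stop("methylation probe table needs a `region` column")
  vals <- probe_value_columns(probes, extra = "region")
  v <- as.matrix(probes[vals])
  if (any(is.finite(v) & (v < 0 | v > 1)))
    stop("methylation beta values must lie in [0, 1]")
  keep <- !is.na(probes$region) & probes$region == "promoter"
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " non-promoter probe(s) discarded")
  probes <- probes[keep, , drop = FALSE]
  if (nrow(probes) == 0)
    stop("no promoter probes left after filtering")
  aggregate_probes(probes[setdiff(names(probes), "region")],
                   assay = "methylation")
}

probe_value_columns <- function(probes, extra = character()) {
  required <- c("probe_id", "gene", extra)
  missing <- setdiff(required, names(probes))
  if (length(missing))
    stop("probe table is missing column(s): ", paste(missing, collapse = ", "))
  vals <- setdiff(names(probes), required)
  if (length(vals) == 0) stop("probe table has no sample columns")
  vals
}

aggregate_probes <- function(probes, assay) {
  if (!is.data.frame(probes) || nrow(probes) == 0)
    stop("empty probe table")
  vals <- probe_value_columns(probes)
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id values")

  gene <- as.character(probes$gene)
  unmapped <- is.na(gene) | gene == ""
  ambiguous <- !unmapped & grepl("[;,|]|///", gene)
  if (any(unmapped))
    message(sum(unmapped), " probe(s) without gene mapping dropped")
  if (any(ambiguous))
    message(sum(ambiguous), " probe(s) mapped to multiple genes dropped")
  keep <- !unmapped & !ambiguous
  if (!any(keep)) stop("no mapped probes left to aggregate")
  probes <- probes[keep, , drop = FALSE]
  gene <- gene[keep]

  v <- as.matrix(probes[vals])
  storage.mode(v) <- "double"
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, nrow = length(vals), ncol = length(genes),
                dimnames = list(vals, genes))
  idx <- split(seq_along(gene), gene)
  for (g in genes) {
    block <- v[idx[[g]], , drop = FALSE]  # probes x samples
    out[, g] <- apply(block, 2, median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  omics_matrix(out, assay = assay)
}

#' Drop poorly observed features and impute the rest
#'
#' Features whose missing fraction exceeds `max_missing_rate` are removed;
#' remaining missing entries are imputed with the feature's median over the
#' observed (training) values. A summary of dropped and imputed counts is
#' reported via `message()`.
#'
#' @param m an `omics_matrix` (may contain `NA`s).
#' @param max_missing_rate maximum tolerated fraction of missing values per
#'   feature, in `[0, 1)`.
#' @return an `omics_matrix` with finite values.
#' @export
handle_missing <- function(m, max_missing_rate = 0.2) {
  if (!is.numeric(max_missing_rate) || max_missing_rate < 0 ||
      max_missing_rate >= 1)
    stop("`max_missing_rate` must lie in [0, 1)")
  v <- as_values(m)
  miss <- colMeans(is.na(v))
  keep <- miss <= max_missing_rate
  if (!any(keep))
    stop("all features exceed the missing-rate threshold")
  if (any(!keep))
    message(sum(!keep), " feature(s) dropped (> ",
            round(100 * max_missing_rate), "% missing)")
  v <- v[, keep, drop = FALSE]
  n_imputed <- sum(is.na(v))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(v))) {
      na <- is.na(v[, j])
      if (any(na)) v[na, j] <- median(v[!na, j])
    }
    message(n_imputed, " missing value(s) imputed with feature medians")
  }
  assay <- if (inherits(m, "omics_matrix")) m$assay else "expression"
  omics_matrix(v, assay = assay)
}

#' Read a probe-level table from TSV/CSV
#'
#' First column `probe_id`, annotation columns `gene` (and `region` for
#' methylation), then one numeric column per sample.
#'
#' @param path file path; comma- or tab-delimited inferred from extension.
#' @return a data frame.
#' @export
read_probe_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}
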