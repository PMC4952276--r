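#' Construct a samples-by-features omics matrix
#'
#' Light container for the numeric matrix the models consume: rows are
#' samples, columns are features (typically gene symbols), plus an assay
#' tag. Methylation values are validated to lie in \[0, 1\].
#'
#' @param values numeric matrix, samples in rows, features in columns; must
#'   carry unique row and column names.
#' @param assay `"expression"` or `"methylation"`.
#' @param check if `TRUE`, validate invariants (unique identifiers, beta
#'   range for methylation).
#' @return an object of class `omics_matrix`: a list with elements `values`
#'   and `assay`.
#' @export
omics_matrix <- function(values, assay = c("expression", "methylation"),
                         check = TRUE) {
  assay <- match.arg(assay)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample (row) and feature (column) names")
  if (check) {
    if (anyDuplicated(rownames(values)))
      stop("duplicate sample identifiers")
    if (anyDuplicated(colnames(values)))
      stop("duplicate feature identifiers")
    if (assay == "methylation") {
      v <- values[is.finite(values)]
      if (length(v) && (min(v) < 0 || max(v) > 1))
        stop("methylation beta values must lie in [0, 1]")
    }
  }
  structure(list(values = values, assay = assay), class = "omics_matrix")
}

#' @export
as.matrix.omics_matrix <- function(x, ...) x$values

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$assay))
  invisible(x)
}

#' Feature identifiers of an omics matrix
#' @param x an `omics_matrix`
#' @return character vector of feature (column) names
#' @export
feature_ids <- function(x) colnames(as_values(x))

#' Sample identifiers of an omics matrix
#' @param x an `omics_matrix`
#' @return character vector of sample (row) names
#' @export
sample_ids <- function(x) rownames(as_values(x))

# accept either an omics_matrix or a bare named numeric matrix
as_values <- function(x) {
  if (inherits(x, "omics_matrix")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(colnames(x)))
      stop("matrix input must have feature (column) names")
    if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
    return(x)
  }
  stop("expected an omics_matrix or a named numeric matrix")
}

#' Write an omics matrix as TSV (samples in rows, features in columns)
#'
#' @param x an `omics_matrix`
#' @param path output file path
#' @export
write_omics_tsv <- function(x, path) {
  v <- as_values(x)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics matrix from TSV
#'
#' Expects the layout written by [write_omics_tsv()]: a header row of
#' feature names, first column `sample_id`.
#'
#' @param path input file path
#' @param assay assay tag for the resulting object
#' @return an `omics_matrix`
#' @export
read_omics_tsv <- function(path, assay = c("expression", "methylation")) {
  assay <- match.arg(assay)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("expected a `sample_id` column in ", path)
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  omics_matrix(m, assay = assay)
}
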