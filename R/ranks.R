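#' Validate a gene-by-sample expression matrix
#'
#' Checks the contract every `hypotrees` entry point relies on: a numeric
#' genes x samples matrix with unique, non-empty row (gene) and column
#' (sample) names, no negative values, no missing values, and at least two
#' genes and one sample.
#'
#' @param mat A numeric matrix, genes in rows, samples in columns.
#' @param arg Name used in error messages.
#' @return `mat`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(mat, arg = "mat") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop(arg, " must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop(arg, " must have gene rownames and sample colnames", call. = FALSE)
  }
  if (nrow(mat) < 2L) {
    stop(arg, " must contain at least 2 genes", call. = FALSE)
  }
  if (ncol(mat) < 1L) {
    stop(arg, " must contain at least 1 sample", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    stop(arg, " has duplicated gene IDs: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    dup <- unique(colnames(mat)[duplicated(colnames(mat))])
    stop(arg, " has duplicated sample IDs: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(mat)) stop(arg, " contains missing values", call. = FALSE)
  if (any(mat < 0)) stop(arg, " contains negative values", call. = FALSE)
  invisible(mat)
}

#' Convert expression values to within-sample rank percentiles
#'
#' The single-sample representation used throughout the package: within each
#' sample (column), genes receive average competition ranks (smallest value
#' gets rank 1, ties get the mean of the ranks they cover) and the rank `r`
#' of each of the `G` genes is rescaled to a percentile
#' `100 * (r - 1) / (G - 1)`, so the most expressed gene in a sample sits at
#' 100 and the least expressed at 0. Because only the within-sample ordering
#' matters, the representation is invariant to sequencing depth and to any
#' strictly increasing per-sample transformation (CPM, log, VST, ...).
#'
#' Percentiles are computed over all genes present in `mat`. Restricting to a
#' signature afterwards (see [subset_genes()]) does not re-rank: thresholds
#' learned on full-transcriptome ranks must be applied to
#' full-transcriptome ranks.
#'
#' @param mat Non-negative numeric matrix, genes x samples, with unique
#'   dimnames. At least 2 genes.
#' @return A numeric matrix of the same shape and dimnames with values in
#'   `[0, 100]`. Columns whose values are all equal (e.g. an empty spatial
#'   spot) are set to 50 everywhere with a warning; they carry no ranking
#'   information.
#' @examples
#' m <- matrix(c(5, 1, 0, 0), ncol = 1,
#'             dimnames = list(c("A", "B", "C", "D"), "s1"))
#' rank_percentile(m)
#' @export
rank_percentile <- function(mat) {
  validate_expression_matrix(mat)
  G <- nrow(mat)
  out <- apply(mat, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    100 * (r - 1) / (G - 1)
  })
  out <- matrix(out, nrow = G, dimnames = dimnames(mat))
  flat <- which(matrixStats_colAllEqual(mat))
  if (length(flat)) {
    warning("column(s) with all-equal values set to percentile 50: ",
            paste(utils::head(colnames(mat)[flat], 5), collapse = ", "),
            if (length(flat) > 5) ", ..." else "",
            call. = FALSE)
    out[, flat] <- 50
  }
  out
}

# all(col == col[1]) per column, without allocating a comparison matrix per call
matrixStats_colAllEqual <- function(mat) {
  vapply(seq_len(ncol(mat)),
         function(j) {
           col <- mat[, j]
           all(col == col[[1L]])
         },
         logical(1))
}

#' Restrict a rank-percentile matrix to a gene list
#'
#' Rows are restricted and ordered as requested; percentiles are *not*
#' recomputed, so they still refer to each gene's position in the full
#' original ranking.
#'
#' @param rpm Rank-percentile matrix from [rank_percentile()].
#' @param genes Non-empty character vector of gene IDs to keep, in the
#'   requested output order.
#' @param on_missing What to do when a requested gene is absent:
#'   `"error"` (default) fails naming the gene, `"drop"` silently drops it,
#'   `"flag"` drops it with a warning. In all cases the returned matrix
#'   carries the missing IDs in `attr(, "missing_genes")`.
#' @return The restricted matrix with attribute `missing_genes` (character,
#'   possibly empty).
#' @export
subset_genes <- function(rpm, genes, on_missing = c("error", "drop", "flag")) {
  on_missing <- match.arg(on_missing)
  if (!is.character(genes) || length(genes) == 0L) {
    stop("genes must be a non-empty character vector", call. = FALSE)
  }
  if (!is.matrix(rpm) || is.null(rownames(rpm))) {
    stop("rpm must be a matrix with gene rownames", call. = FALSE)
  }
  missing <- setdiff(genes, rownames(rpm))
  if (length(missing) && on_missing == "error") {
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(missing) && on_missing == "flag") {
    warning("dropping gene(s) absent from matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- genes[genes %in% rownames(rpm)]
  out <- rpm[keep, , drop = FALSE]
  attr(out, "missing_genes") <- missing
  out
}
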