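#' Read a genes-by-samples counts TSV
#'
#' Expects a header row of sample IDs, a first column of gene IDs, and a
#' tab-separated numeric body. Malformed input is rejected, never coerced:
#' a non-numeric cell is reported with its gene and sample, duplicate gene
#' IDs and negative values are errors.
#'
#' @param path File path.
#' @return A validated expression matrix (genes x samples).
#' @export
read_counts_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2L) stop("counts file needs a gene column plus >=1 sample",
                           call. = FALSE)
  genes <- tab[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicated gene ID(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  body <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value '", body[bad[1, 1], bad[1, 2]], "' at gene ",
         genes[bad[1, 1]], ", sample ", colnames(tab)[-1L][bad[1, 2]],
         call. = FALSE)
  }
  if (anyNA(num)) stop("missing values in counts file", call. = FALSE)
  dimnames(num) <- list(genes, colnames(tab)[-1L])
  validate_expression_matrix(num, arg = path)
  num
}

#' Write a genes-by-samples counts TSV
#'
#' Inverse of [read_counts_tsv()]: files written here read back
#' bit-identically (full numeric precision).
#'
#' @param mat Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(mat, path) {
  tab <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write sample labels as TSV
#' @param labels Tibble with `sample_id` and `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  stopifnot(all(c("sample_id", "label") %in% names(labels)))
  readr::write_tsv(labels[c("sample_id", "label")], path)
  invisible(path)
}

#' Read sample labels from TSV
#' @param path File with columns `sample_id` and `label`.
#' @return Tibble with `sample_id`, `label`.
#' @export
read_labels_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  stopifnot(all(c("sample_id", "label") %in% names(tab)))
  as_hypoxia_indicator(tab$label)   # validates vocabulary
  tab[c("sample_id", "label")]
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_tsv_maybe_gz <- function(path, ...) {
  readr::read_tsv(path, col_names = FALSE,
                  col_types = readr::cols(.default = "c"), progress = FALSE)
}

#' Read a 10x-style Matrix Market directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' each optionally gzipped. Gene IDs are taken from the features table's
#' symbol column (second column when present), deduplicated by suffixing;
#' barcodes become sample IDs.
#'
#' @param dir Directory path.
#' @return Dense expression matrix, genes x spots.
#' @export
read_mtx_dir <- function(dir) {
  mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(mtx) || is.null(feat) || is.null(bc)) {
    stop("directory must contain matrix.mtx, features.tsv (or genes.tsv) ",
         "and barcodes.tsv (plain or .gz)", call. = FALSE)
  }
  # readMM opens and closes the connection itself
  m <- Matrix::readMM(if (grepl("\\.gz$", mtx)) gzfile(mtx) else mtx)
  features <- read_tsv_maybe_gz(feat)
  barcodes <- read_tsv_maybe_gz(bc)
  if (nrow(features) != nrow(m)) {
    stop("features table has ", nrow(features), " rows but matrix has ",
         nrow(m), " genes", call. = FALSE)
  }
  if (nrow(barcodes) != ncol(m)) {
    stop("barcodes table has ", nrow(barcodes), " rows but matrix has ",
         ncol(m), " spots", call. = FALSE)
  }
  symbols <- if (ncol(features) >= 2L) features[[2L]] else features[[1L]]
  out <- as.matrix(m)
  dimnames(out) <- list(make.unique(symbols, sep = "."), barcodes[[1L]])
  out
}

#' Write an expression matrix as a 10x-style Matrix Market directory
#'
#' Produces `matrix.mtx`, `features.tsv` (id and symbol columns) and
#' `barcodes.tsv`, readable by [read_mtx_dir()] with identical values.
#'
#' @param mat Matrix, genes x spots.
#' @param dir Output directory (created if needed).
#' @param gzip Also gzip the three files (the plain files are replaced).
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(mat, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(id = rownames(mat), symbol = rownames(mat)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(mat)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  if (gzip) {
    for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
      p <- file.path(dir, f)
      con_in <- file(p, "rb")
      con_out <- gzfile(paste0(p, ".gz"), "wb")
      writeBin(readBin(con_in, "raw", file.size(p)), con_out)
      close(con_in); close(con_out)
      unlink(p)
    }
  }
  invisible(dir)
}

## ---- tree JSON -------------------------------------------------------------

TREE_SCHEMA_VERSION <- 1L

node_to_doc <- function(nodes, id) {
  if (nodes$is_leaf[id]) {
    list(class = nodes$class[id],
         probability = nodes$prob[id],
         fraction = nodes$frac[id])
  } else {
    list(gene = nodes$gene[id],
         threshold = nodes$threshold[id],
         class = nodes$class[id],
         probability = nodes$prob[id],
         fraction = nodes$frac[id],
         low_branch = node_to_doc(nodes, nodes$low_child[id]),
         high_branch = node_to_doc(nodes, nodes$high_child[id]))
  }
}

tree_to_doc <- function(tree) {
  doc <- list(
    schema_version = TREE_SCHEMA_VERSION,
    tree_id = tree$tree_id,
    metadata = tree$metadata[!vapply(tree$metadata, is.null, logical(1))],
    root = node_to_doc(tree$nodes, 1L)
  )
  # round-trip fidelity: unknown top-level fields seen at load time survive
  extra <- attr(tree, "extra_fields")
  if (!is.null(extra)) doc <- c(doc, extra)
  doc
}

doc_to_nodes <- function(node, path = "root") {
  rows <- new.env(parent = emptyenv())
  rows$lst <- list()
  add <- function(rec) {
    rows$lst[[length(rows$lst) + 1L]] <- rec
    length(rows$lst)
  }
  rec_build <- function(nd, depth, where) {
    if (!is.list(nd)) stop("malformed tree node at ", where, call. = FALSE)
    is_leaf <- is.null(nd$gene) && is.null(nd$low_branch)
    for (fld in c("class", "probability", "fraction")) {
      if (is.null(nd[[fld]])) {
        stop("tree node at ", where, " lacks required field '", fld, "'",
             call. = FALSE)
      }
    }
    if (!is_leaf) {
      for (fld in c("gene", "threshold", "low_branch", "high_branch")) {
        if (is.null(nd[[fld]])) {
          stop("internal tree node at ", where, " lacks required field '",
               fld, "'", call. = FALSE)
        }
      }
      if (nd$threshold < 0 || nd$threshold > 100) {
        stop("threshold out of [0,100] at ", where, call. = FALSE)
      }
    }
    if (nd$probability < 0 || nd$probability > 1) {
      stop("probability out of [0,1] at ", where, call. = FALSE)
    }
    rec <- list(depth = depth, is_leaf = is_leaf,
                gene = if (is_leaf) NA_character_ else as.character(nd$gene),
                threshold = if (is_leaf) NA_real_ else as.numeric(nd$threshold),
                class = as.character(nd$class),
                prob = as.numeric(nd$probability),
                frac = as.numeric(nd$fraction),
                low_child = NA_integer_, high_child = NA_integer_)
    id <- add(rec)
    if (!is_leaf) {
      rec$low_child <- rec_build(nd$low_branch, depth + 1L,
                                 paste0(where, "/low"))
      rec$high_child <- rec_build(nd$high_branch, depth + 1L,
                                  paste0(where, "/high"))
      rows$lst[[id]] <- rec
    }
    id
  }
  rec_build(node, 0L, path)
  lst <- rows$lst
  tibble::tibble(
    node_id = seq_along(lst),
    depth = vapply(lst, `[[`, integer(1), "depth"),
    is_leaf = vapply(lst, `[[`, logical(1), "is_leaf"),
    gene = vapply(lst, `[[`, character(1), "gene"),
    threshold = vapply(lst, `[[`, numeric(1), "threshold"),
    class = vapply(lst, `[[`, character(1), "class"),
    prob = vapply(lst, `[[`, numeric(1), "prob"),
    frac = vapply(lst, `[[`, numeric(1), "frac"),
    low_child = vapply(lst, `[[`, integer(1), "low_child"),
    high_child = vapply(lst, `[[`, integer(1), "high_child")
  )
}

doc_to_tree <- function(doc) {
  if (is.null(doc$root)) stop("tree document lacks 'root'", call. = FALSE)
  tree <- new_hypoxia_tree(doc_to_nodes(doc$root),
                           tree_id = as.character(doc$tree_id %||% "1"),
                           metadata = doc$metadata %||% list())
  known <- c("schema_version", "tree_id", "metadata", "root")
  extra <- doc[setdiff(names(doc), known)]
  if (length(extra)) attr(tree, "extra_fields") <- extra
  tree
}

#' Save trees as JSON documents
#'
#' Writes the canonical exchange format: one JSON document per tree with a
#' `schema_version`, the `tree_id`, holdout metadata, and a recursive node
#' record (internal nodes: `gene`, `threshold`, `low_branch`,
#' `high_branch`; all nodes: `class`, `probability`, `fraction`).
#' Thresholds are in rank-percentile units. If `path` ends in `.json` all
#' trees go into one array; otherwise `path` is a directory with one
#' `tree_<id>.json` per tree.
#'
#' @param ensemble A `hypoxia_ensemble`, `tree_population`, or single
#'   `hypoxia_tree`.
#' @param path Output file (`.json`) or directory.
#' @return `path`, invisibly.
#' @export
save_trees <- function(ensemble, path) {
  trees <- if (inherits(ensemble, "hypoxia_tree")) list(ensemble)
           else if (inherits(ensemble, "hypoxia_ensemble")) ensemble$trees
           else unclass(ensemble)
  docs <- purrr::map(trees, tree_to_doc)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (d in docs) {
      jsonlite::write_json(d, file.path(path, paste0("tree_", d$tree_id, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  invisible(path)
}

#' Load trees from JSON
#'
#' Accepts a single tree document, an array of documents, or a directory of
#' `.json` files. Trees are ordered by `tree_id` (numeric where possible).
#' Schema violations name the offending node path.
#'
#' @param path JSON file or directory.
#' @return A `hypoxia_ensemble`.
#' @export
load_trees <- function(path) {
  docs <- if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
    if (!length(files)) stop("no .json files in ", path, call. = FALSE)
    purrr::map(files, function(f) jsonlite::read_json(f, simplifyVector = FALSE))
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.null(doc$root)) list(doc) else doc
  }
  trees <- purrr::map(docs, doc_to_tree)
  ids <- vapply(trees, function(t) t$tree_id, character(1))
  num <- suppressWarnings(as.numeric(ids))
  ord <- if (anyNA(num)) order(ids, method = "radix") else order(num)
  new_hypoxia_ensemble(trees[ord], provenance = list(source = path))
}

#' Write an importance table as TSV
#' @param importance Tibble from [permutation_importance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance_tsv <- function(importance, path) {
  readr::write_tsv(importance, path)
  invisible(path)
}

#' Classify spatial-transcriptomics spots
#'
#' Ranks each spot over the full gene universe of the matrix (never a
#' signature subset), then applies the consensus ensemble. Blank spots
#' (all-equal values, e.g. empty capture areas) carry no ranking
#' information: their consensus probability is still reported but the label
#' is `NA` and `blank` is flagged.
#'
#' @param ensemble A `hypoxia_ensemble` already compatible with the
#'   matrix's genes (see [filter_by_available_features()]).
#' @param mat Raw expression matrix, genes x spots (e.g. from
#'   [read_mtx_dir()] or [generate_spatial()]).
#' @param threshold Strict consensus threshold.
#' @param coords Optional tibble with `sample_id`, `row`, `col` to attach.
#' @return Tibble: `sample_id`, (`row`, `col`,) `mean_prob`, `label`,
#'   `n_trees_used`, `blank`.
#' @export
classify_spots <- function(ensemble, mat, threshold = 0.5, coords = NULL) {
  if (ncol(mat) == 0L) stop("matrix contains zero spots", call. = FALSE)
  blank <- matrixStats_colAllEqual(mat)
  rpm <- withCallingHandlers(
    rank_percentile(mat),
    warning = function(w) {
      if (grepl("all-equal values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  res <- ensemble_predict(ensemble, rpm, threshold = threshold)
  out <- res$samples
  out$blank <- blank
  out$label[blank] <- NA_character_
  if (!is.null(coords)) {
    out <- dplyr::left_join(out, coords, by = "sample_id") |>
      dplyr::relocate(dplyr::any_of(c("row", "col")), .after = "sample_id")
  }
  out
}
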