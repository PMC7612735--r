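# Core containers: CountMatrix, NormalizedMatrix, CellAnnotations,
# LabelHierarchy, and the readers/writers and gene alignment connecting them.

#' Construct a cells-by-genes count matrix
#'
#' The in-memory convention throughout the package is cells as rows and genes
#' as columns; counts are non-negative integers (UMIs). On-disk Matrix Market
#' files follow the prevailing genes-by-cells convention and are transposed by
#' the readers.
#'
#' @param values A numeric matrix or `Matrix` sparse matrix, cells x genes,
#'   with non-negative integer entries.
#' @param cell_ids Character vector of unique cell identifiers (one per row).
#' @param gene_ids Character vector of unique gene identifiers (one per
#'   column).
#' @return An object of class `CountMatrix` with fields `values` (a
#'   `dgCMatrix`), `cell_ids` and `gene_ids`.
#' @examples
#' m <- count_matrix(matrix(0:5, nrow = 3), c("c1", "c2", "c3"), c("g1", "g2"))
#' dim(m)
#' @export
count_matrix <- function(values, cell_ids, gene_ids) {
  values <- as_dgc(values)
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids)) {
    stop_validation("row count does not match number of cell ids")
  }
  if (ncol(values) != length(gene_ids)) {
    stop_validation("column count does not match number of gene ids")
  }
  if (anyDuplicated(cell_ids)) stop_validation("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop_validation("duplicate gene ids")
  if (length(values@x) && any(values@x < 0)) {
    stop_validation("negative entries in count matrix")
  }
  if (length(values@x) && any(values@x != round(values@x))) {
    stop_validation("non-integer entries in count matrix")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids),
    class = "CountMatrix"
  )
}

as_dgc <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  x <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::drop0(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("<CountMatrix> %d cells x %d genes, %d non-zero entries\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' Construct a normalized expression matrix
#'
#' Holds the post-normalization representation used for training and
#' prediction (by default log1p of counts-per-`target_sum`), together with the
#' normalization descriptor so that models are self-describing.
#'
#' @param values Numeric (sparse) matrix, cells x genes, non-negative reals.
#' @param cell_ids,gene_ids Unique identifiers as in [count_matrix()].
#' @param target_sum The per-cell library-size target used in normalization.
#' @param transform Name of the transform applied (default `"log1p"`).
#' @param zero_cells Character vector of cell ids whose library size was zero
#'   (left all-zero, flagged rather than dropped).
#' @return An object of class `NormalizedMatrix`.
#' @export
normalized_matrix <- function(values, cell_ids, gene_ids, target_sum,
                              transform = "log1p", zero_cells = character()) {
  values <- Matrix::drop0(methods::as(
    methods::as(methods::as(values, "dMatrix"), "generalMatrix"),
    "CsparseMatrix"))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids)) {
    stop_validation("dimension/id mismatch in normalized matrix")
  }
  if (anyDuplicated(cell_ids)) stop_validation("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop_validation("duplicate gene ids")
  if (length(values@x) && any(values@x < 0)) {
    stop_validation("negative entries in normalized matrix")
  }
  assert_scalar_number(target_sum, "target_sum")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         target_sum = target_sum, transform = transform,
         zero_cells = zero_cells),
    class = "NormalizedMatrix"
  )
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf(
    "<NormalizedMatrix> %d cells x %d genes (%s, target_sum = %g)\n",
    nrow(x$values), ncol(x$values), x$transform, x$target_sum))
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Two dialects are supported. `format = "mtx"` reads the standard Matrix
#' Market coordinate triplet with sidecar one-id-per-line barcode and feature
#' lists (genes as rows on disk, transposed to cells x genes in memory).
#' `format = "csv"` reads a dense table with gene ids as the header and cell
#' ids in the first column.
#'
#' @param path For `"mtx"`, the matrix file (default sidecars
#'   `barcodes.tsv`/`features.tsv` in the same directory) or a directory
#'   containing `matrix.mtx`; for `"csv"`, the CSV file.
#' @param format `"mtx"` or `"csv"`.
#' @param barcodes,features Optional explicit sidecar paths for `"mtx"`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx", "csv"),
                        barcodes = NULL, features = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    if (dir.exists(path)) {
      mtx <- file.path(path, "matrix.mtx")
    } else {
      mtx <- path
    }
    dir <- dirname(mtx)
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    features <- features %||% file.path(dir, "features.tsv")
    for (f in c(mtx, barcodes, features)) {
      if (!file.exists(f)) stop_format(sprintf("file not found: %s", f))
    }
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop_format(
                    sprintf("cannot parse Matrix Market file %s: %s",
                            mtx, conditionMessage(e))))
    bc <- readLines(barcodes)
    ft <- readLines(features)
    # on-disk orientation is genes x cells
    if (nrow(m) != length(ft)) {
      stop_format(sprintf(
        "matrix declares %d genes but features list has %d", nrow(m),
        length(ft)))
    }
    if (ncol(m) != length(bc)) {
      stop_format(sprintf(
        "matrix declares %d cells but barcodes list has %d", ncol(m),
        length(bc)))
    }
    count_matrix(Matrix::t(m), bc, ft)
  } else {
    if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop_format("dense CSV needs cell id column plus genes")
    cell_ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop_format("non-numeric entries in dense CSV")
    count_matrix(vals, cell_ids, colnames(df)[-1])
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; `read_counts(write_counts(x))` is the identity
#' in both dialects.
#'
#' @param x A `CountMatrix`.
#' @param path For `"mtx"` a directory (created if needed) receiving
#'   `matrix.mtx`, `barcodes.tsv`, `features.tsv`; for `"csv"` the file path.
#' @param format `"mtx"` or `"csv"`.
#' @return Invisibly, the path written.
#' @export
write_counts <- function(x, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "CountMatrix"))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::t(x$values)            # store genes x cells
    dimnames(m) <- NULL
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
    writeLines(x$gene_ids, file.path(path, "features.tsv"))
  } else {
    df <- data.frame(cell_id = x$cell_ids, as.matrix(x$values),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-cell annotations
#'
#' Expects a tab-delimited table with a header naming at least `cell_id` and
#' `label`; `tissue` and `donor` are optional and recorded as absent (not as
#' empty strings) when the column is missing. Composition statistics refuse
#' annotations without tissue/donor information.
#'
#' @param path TSV file path.
#' @return A `CellAnnotations` data frame with attributes `has_tissue` and
#'   `has_donor`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  cell_annotations(df)
}

#' Construct a cell annotation table
#'
#' @param df Data frame with columns `cell_id`, `label` and optionally
#'   `tissue`, `donor`.
#' @return A `CellAnnotations` object.
#' @export
cell_annotations <- function(df) {
  for (col in c("cell_id", "label")) {
    if (!col %in% names(df)) {
      stop_format(sprintf("annotation table lacks required column '%s'", col),
                  category = "columns")
    }
  }
  keep <- intersect(c("cell_id", "label", "tissue", "donor"), names(df))
  df <- df[, keep, drop = FALSE]
  for (col in keep) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$cell_id)) {
    stop_validation("duplicate cell_id rows in annotations")
  }
  for (col in keep) {
    if (any(is.na(df[[col]]) | df[[col]] == "")) {
      stop_validation(sprintf("empty values in annotation column '%s'", col))
    }
  }
  structure(df,
            class = c("CellAnnotations", "data.frame"),
            has_tissue = "tissue" %in% keep,
            has_donor = "donor" %in% keep)
}

#' Write per-cell annotations as TSV
#' @param x A `CellAnnotations` object (or compatible data frame).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a two-level label hierarchy
#'
#' Maps each fine (low-hierarchy) cell-type label to exactly one coarse
#' (high-hierarchy) label.
#'
#' @param low_to_high Named character vector: names are low labels, values the
#'   corresponding high labels.
#' @return A `LabelHierarchy` object.
#' @export
label_hierarchy <- function(low_to_high) {
  if (is.null(names(low_to_high)) || anyDuplicated(names(low_to_high))) {
    stop_validation("hierarchy must map each low label exactly once")
  }
  if (any(low_to_high == "" | names(low_to_high) == "")) {
    stop_validation("empty labels in hierarchy")
  }
  structure(list(low_to_high = low_to_high), class = "LabelHierarchy")
}

#' Read a label hierarchy from TSV
#'
#' Expects columns `low` and `high` (fine label, coarse label).
#' @param path TSV file path.
#' @return A `LabelHierarchy`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file not found: %s", path), category = "hierarchy")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("low", "high") %in% names(df))) {
    stop_format("hierarchy table needs columns 'low' and 'high'",
                category = "hierarchy")
  }
  label_hierarchy(stats::setNames(as.character(df$high),
                                  as.character(df$low)))
}

#' Write a label hierarchy as TSV
#' @param h A `LabelHierarchy`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hierarchy <- function(h, path) {
  utils::write.table(
    data.frame(low = names(h$low_to_high), high = unname(h$low_to_high)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a hierarchy against the labels actually in use
#'
#' Report-based: the result lists in-use labels missing from the mapping and
#' mapping keys that are never used; it passes iff nothing is missing.
#'
#' @param h A `LabelHierarchy`.
#' @param labels_in_use Character vector of low labels present in the data.
#' @return A list with `pass` (logical), `missing` and `unused` (character).
#' @export
validate_hierarchy <- function(h, labels_in_use) {
  stopifnot(inherits(h, "LabelHierarchy"))
  labels_in_use <- unique(as.character(labels_in_use))
  missing <- setdiff(labels_in_use, names(h$low_to_high))
  unused <- setdiff(names(h$low_to_high), labels_in_use)
  list(pass = length(missing) == 0L, missing = missing, unused = unused)
}

#' Align a matrix to a model feature list
#'
#' Reorders columns to follow `feature_list` exactly: genes present in the
#' input keep their values, genes absent are zero-filled, genes not in
#' `feature_list` are dropped. This is what lets a trained model score a query
#' dataset with a different gene universe. The fraction of `feature_list`
#' found in the input is attached as attribute `"overlap"`; overlap below 0.5
#' is logged as a warning and (near-)zero overlap is an error.
#'
#' @param x A `CountMatrix` or `NormalizedMatrix`.
#' @param feature_list Ordered character vector of gene ids.
#' @return An object of the same class as `x` over exactly `feature_list`,
#'   with attribute `overlap`.
#' @export
align_genes <- function(x, feature_list) {
  stopifnot(inherits(x, "CountMatrix") || inherits(x, "NormalizedMatrix"))
  feature_list <- as.character(feature_list)
  if (anyDuplicated(feature_list)) {
    stop_validation("duplicate genes in feature list")
  }
  idx <- match(feature_list, x$gene_ids)
  overlap <- mean(!is.na(idx))
  if (overlap < 1e-9) {
    stop_validation("no genes shared between matrix and feature list",
                    category = "gene_overlap")
  }
  if (overlap < 0.5) {
    st_log(sprintf("low gene overlap with feature list: %.1f%%",
                   100 * overlap))
  }
  n <- nrow(x$values)
  vals <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(n, length(feature_list)))
  present <- which(!is.na(idx))
  vals[, present] <- x$values[, idx[present], drop = FALSE]
  out <- if (inherits(x, "CountMatrix")) {
    count_matrix(vals, x$cell_ids, feature_list)
  } else {
    normalized_matrix(vals, x$cell_ids, feature_list,
                      target_sum = x$target_sum, transform = x$transform,
                      zero_cells = x$zero_cells)
  }
  attr(out, "overlap") <- overlap
  out
}
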