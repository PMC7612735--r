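# Quality-control filtering and library-size normalization.

#' Filter low-quality cells
#'
#' Removes cells with fewer than `min_umi` total counts or fewer than
#' `min_genes` detected (non-zero) genes; the thresholds are exclusive, so a
#' cell exactly at a threshold is retained. Defaults follow common droplet
#' scRNA-seq practice (1,000 UMIs, 600 genes).
#'
#' @param counts A [count_matrix()].
#' @param min_umi Minimum total UMI count (cells with total < `min_umi`
#'   removed).
#' @param min_genes Minimum number of detected genes.
#' @return A list with `counts` (the filtered `CountMatrix`) and `removed`, a
#'   data frame of removed cells with their totals and the reason
#'   (`"low_umi"`, `"low_genes"` or both).
#' @export
qc_filter <- function(counts, min_umi = 1000, min_genes = 600) {
  stopifnot(inherits(counts, "CountMatrix"))
  assert_scalar_number(min_umi, "min_umi")
  assert_scalar_number(min_genes, "min_genes")
  total <- Matrix::rowSums(counts$values)
  detected <- Matrix::rowSums(counts$values > 0)
  low_umi <- total < min_umi
  low_genes <- detected < min_genes
  drop <- low_umi | low_genes
  reason <- ifelse(low_umi & low_genes, "low_umi;low_genes",
                   ifelse(low_umi, "low_umi", "low_genes"))
  removed <- data.frame(
    cell_id = counts$cell_ids[drop],
    total_umi = as.integer(total[drop]),
    detected_genes = as.integer(detected[drop]),
    reason = reason[drop],
    stringsAsFactors = FALSE
  )
  if (all(drop) && nrow(removed) > 0) {
    warning("qc_filter removed every cell", call. = FALSE)
  }
  kept <- count_matrix(counts$values[!drop, , drop = FALSE],
                       counts$cell_ids[!drop], counts$gene_ids)
  list(counts = kept, removed = removed)
}

#' Normalize counts to log1p counts-per-target
#'
#' Scales each cell to a common library size and applies `ln(1 + x)`: an
#' entry x in a cell with total T becomes `ln(1 + x * target_sum / T)`. Cells
#' with zero total counts are left all-zero and flagged in `zero_cells`.
#' Because the scaling is per cell, the result is invariant to uniform
#' scaling of a cell's counts.
#'
#' @param counts A [count_matrix()].
#' @param target_sum Library-size target (default 10,000, i.e. CP10K).
#' @return A [normalized_matrix()].
#' @export
normalize_log1p <- function(counts, target_sum = 1e4) {
  stopifnot(inherits(counts, "CountMatrix"))
  assert_scalar_number(target_sum, "target_sum")
  total <- Matrix::rowSums(counts$values)
  zero <- total == 0
  if (any(zero)) {
    st_log(sprintf("%d cell(s) with zero total counts left all-zero",
                   sum(zero)))
  }
  scale <- ifelse(zero, 0, target_sum / total)
  vals <- Matrix::Diagonal(x = scale) %*% counts$values
  vals <- methods::as(methods::as(vals, "generalMatrix"), "CsparseMatrix")
  vals@x <- log1p(vals@x)
  normalized_matrix(vals, counts$cell_ids, counts$gene_ids,
                    target_sum = target_sum, transform = "log1p",
                    zero_cells = counts$cell_ids[zero])
}
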