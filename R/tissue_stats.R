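# Cross-tissue composition statistics: inclusion filter, within-tissue
# proportions, donor-stratified Poisson enrichment, BH correction.

#' Build a (cell type, tissue, donor) composition table
#'
#' @param annotations A [cell_annotations()] table carrying tissue and donor
#'   columns; annotations without them are refused.
#' @return A `CompositionTable`: a 3-d integer array
#'   `counts[type, tissue, donor]`.
#' @export
composition_table <- function(annotations) {
  stopifnot(inherits(annotations, "CellAnnotations"))
  if (!isTRUE(attr(annotations, "has_tissue")) ||
      !isTRUE(attr(annotations, "has_donor"))) {
    stop_validation("composition analysis needs tissue and donor columns",
                    category = "columns")
  }
  df <- as.data.frame(annotations)
  tab <- table(type = df$label, tissue = df$tissue, donor = df$donor)
  counts <- array(as.integer(tab), dim = dim(tab), dimnames = dimnames(tab))
  structure(list(counts = counts), class = "CompositionTable")
}

#' @export
print.CompositionTable <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<CompositionTable> %d types x %d tissues x %d donors, %d cells\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Tissue inclusion filter
#'
#' A tissue is included when at least `min_donors` donors each contribute
#' strictly more than `min_cells` cells of the analyzed compartment in that
#' tissue (the default reading of "more than 50 cells in at least two
#' donors"). `rule = "total"` selects the alternative reading: tissue total
#' > `min_cells`, spread over at least `min_donors` donors.
#'
#' @param table A [composition_table()].
#' @param min_cells Per-donor (or total) cell-count threshold, strict.
#' @param min_donors Minimum number of qualifying donors.
#' @param rule `"per_donor"` (default) or `"total"`.
#' @return Character vector of included tissue names.
#' @export
tissue_inclusion_filter <- function(table, min_cells = 50, min_donors = 2,
                                    rule = c("per_donor", "total")) {
  stopifnot(inherits(table, "CompositionTable"))
  rule <- match.arg(rule)
  per_tissue_donor <- apply(table$counts, c(2, 3), sum)  # tissue x donor
  keep <- if (rule == "per_donor") {
    rowSums(per_tissue_donor > min_cells) >= min_donors
  } else {
    rowSums(per_tissue_donor) > min_cells &
      rowSums(per_tissue_donor > 0) >= min_donors
  }
  rownames(per_tissue_donor)[keep]
}

#' Cross-tissue composition proportions
#'
#' Two-step normalization: cell numbers are first normalized within each
#' tissue (donors pooled), `p(t, j) = n(t, j) / N(j)`, and the within-tissue
#' proportions are then expressed as proportions across tissues,
#' `q(t, j) = p(t, j) / sum_j' p(t, j')`, so each cell type's row sums to 1.
#'
#' @param table A [composition_table()].
#' @param tissues Optional tissue subset (e.g. the output of
#'   [tissue_inclusion_filter()]); defaults to all tissues in the table.
#' @return Matrix `q` (types x tissues) with the within-tissue proportion
#'   matrix `p` attached as attribute `"within_tissue"`. Cell types absent
#'   from every tissue are dropped with a warning.
#' @export
composition_proportions <- function(table, tissues = NULL) {
  stopifnot(inherits(table, "CompositionTable"))
  counts <- apply(table$counts, c(1, 2), sum)    # type x tissue, donors pooled
  if (!is.null(tissues)) {
    missing <- setdiff(tissues, colnames(counts))
    if (length(missing)) {
      stop_validation(sprintf("unknown tissues: %s",
                              paste(missing, collapse = ", ")))
    }
    counts <- counts[, tissues, drop = FALSE]
  }
  absent <- rowSums(counts) == 0
  if (any(absent)) {
    warning(sprintf("cell types absent from all tissues dropped: %s",
                    paste(rownames(counts)[absent], collapse = ", ")),
            call. = FALSE)
    counts <- counts[!absent, , drop = FALSE]
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop_validation("tissue with zero cells in composition table")
  }
  p <- sweep(counts, 2L, totals, "/")
  q <- p / rowSums(p)
  attr(q, "within_tissue") <- p
  q
}

#' Donor-stratified Poisson enrichment of one cell type in one tissue
#'
#' Tests whether a cell type is enriched in the target tissue relative to all
#' remaining tissues. For each donor d and group g in \{target, rest\}, the
#' count `n(d, g)` of the cell type is modeled as
#' `log E[n(d, g)] = beta0 + gamma_d + beta1 * 1[g = target] + log N(d, g)`
#' with donor fixed effects `gamma_d` and the donor's total compartment size
#' `N(d, g)` as offset; the returned p-value is the one-sided Wald test of
#' `beta1 > 0` (two-sided available). Donors with a zero offset in either
#' group are dropped (logged); fewer than 2 usable donors gives a
#' not-testable result. When one group holds zero cells of the type the MLE
#' diverges; a Haldane-Anscombe continuity correction (0.5 added to every
#' donor-group count) is then applied and flagged in the result.
#'
#' @param table A [composition_table()].
#' @param cell_type Type to test (row of the table).
#' @param tissue Target tissue.
#' @param tissues Optional tissue universe for target-vs-rest (defaults to
#'   all tissues in the table).
#' @param two_sided If `TRUE` return the two-sided Wald p-value.
#' @return List with `beta1` (log rate ratio), `p` (Wald p-value), `se`,
#'   `testable`, `corrected`, `n_donors`.
#' @export
poisson_enrichment <- function(table, cell_type, tissue, tissues = NULL,
                               two_sided = FALSE) {
  stopifnot(inherits(table, "CompositionTable"))
  counts <- table$counts
  tissues <- tissues %||% colnames(counts)
  if (!cell_type %in% rownames(counts)) {
    stop_validation(sprintf("unknown cell type '%s'", cell_type))
  }
  if (!tissue %in% tissues) {
    stop_validation(sprintf("tissue '%s' not in tissue universe", tissue))
  }
  rest <- setdiff(tissues, tissue)
  donors <- dimnames(counts)[[3]]
  n_target <- counts[cell_type, tissue, ]
  N_target <- apply(counts[, tissue, , drop = FALSE], 3, sum)
  n_rest <- apply(counts[cell_type, rest, , drop = FALSE], 3, sum)
  N_rest <- apply(counts[, rest, , drop = FALSE], 3, sum)
  usable <- N_target > 0 & N_rest > 0
  if (any(!usable)) {
    st_log(sprintf("dropping donor(s) with zero offset: %s",
                   paste(donors[!usable], collapse = ", ")))
  }
  if (sum(usable) < 2L) {
    return(list(beta1 = NA_real_, p = NA_real_, se = NA_real_,
                testable = FALSE, corrected = FALSE,
                n_donors = sum(usable)))
  }
  d <- donors[usable]
  n <- c(n_target[usable], n_rest[usable])
  N <- c(N_target[usable], N_rest[usable])
  corrected <- FALSE
  if (sum(n_target[usable]) == 0 || sum(n_rest[usable]) == 0) {
    n <- n + 0.5   # complete separation: continuity correction
    corrected <- TRUE
  }
  df <- data.frame(
    n = n,
    donor = factor(rep(d, 2L)),
    group = factor(rep(c("target", "rest"), each = length(d)),
                   levels = c("rest", "target")),
    off = log(N)
  )
  # suppressWarnings: the continuity-corrected counts are deliberately
  # non-integer, which the poisson family otherwise warns about
  fit <- suppressWarnings(
    stats::glm(n ~ donor + group, family = stats::poisson(),
               offset = off, data = df,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  sm <- summary(fit)$coefficients
  beta1 <- sm["grouptarget", "Estimate"]
  se <- sm["grouptarget", "Std. Error"]
  z <- beta1 / se
  p <- if (two_sided) {
    2 * stats::pnorm(-abs(z))
  } else {
    stats::pnorm(z, lower.tail = FALSE)
  }
  list(beta1 = beta1, p = p, se = se, testable = TRUE,
       corrected = corrected, n_donors = length(d))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (sort ascending, `adj_i = min over k >= i
#' of p_(k) * m / k`, clipped to 1), returned in the original order.
#' `NA` entries (e.g. not-testable pairs) are passed through and excluded
#' from the family size.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Screen every (cell type, tissue) pair for tissue enrichment
#'
#' Restricts the table to tissues passing [tissue_inclusion_filter()], runs
#' [poisson_enrichment()] for every (type, included tissue) pair against the
#' remaining included tissues, adjusts all testable p-values jointly with
#' [bh_adjust()], and flags pairs with adjusted p < `alpha` and `beta1 > 0`.
#'
#' @param table A [composition_table()].
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @param min_cells,min_donors,rule Passed to [tissue_inclusion_filter()].
#' @param two_sided Passed to [poisson_enrichment()].
#' @return A data frame (class `EnrichmentResult`) with one row per tested
#'   pair: `cell_type`, `tissue`, `beta1`, `p`, `p_adj`, `flagged`,
#'   `testable`, `corrected`.
#' @export
enrichment_screen <- function(table, alpha = 0.05, min_cells = 50,
                              min_donors = 2, rule = "per_donor",
                              two_sided = FALSE) {
  stopifnot(inherits(table, "CompositionTable"))
  tissues <- tissue_inclusion_filter(table, min_cells, min_donors, rule)
  types <- rownames(table$counts)
  if (length(tissues) < 2L || length(types) == 0L) {
    res <- data.frame(cell_type = character(), tissue = character(),
                      beta1 = numeric(), p = numeric(), p_adj = numeric(),
                      flagged = logical(), testable = logical(),
                      corrected = logical(), stringsAsFactors = FALSE)
    class(res) <- c("EnrichmentResult", "data.frame")
    return(res)
  }
  rows <- list()
  for (ty in types) {
    for (ti in tissues) {
      r <- poisson_enrichment(table, ty, ti, tissues = tissues,
                              two_sided = two_sided)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ty, tissue = ti, beta1 = r$beta1, p = r$p,
        testable = r$testable, corrected = r$corrected,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$flagged <- !is.na(res$p_adj) & res$p_adj < alpha &
    !is.na(res$beta1) & res$beta1 > 0
  res <- res[, c("cell_type", "tissue", "beta1", "p", "p_adj", "flagged",
                 "testable", "corrected")]
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Write an enrichment screen as TSV
#' @param x An `EnrichmentResult`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
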