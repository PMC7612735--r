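# Seeded negative-binomial scRNA-seq generator with planted marker programs,
# two-level hierarchy, tissue composition and donor structure.

#' Configuration of the synthetic dataset generator
#'
#' Each cell type owns a disjoint block of `markers_per_type` marker genes
#' whose mean expression is multiplied by `2^log2_fold_change`; every other
#' gene sits at `base_mean`. Each donor applies a multiplicative lognormal
#' nuisance factor (per donor and gene, log-sd `donor_logfc_sd`) to all
#' genes, and counts are drawn negative-binomial with a shared dispersion
#' (variance `mu + dispersion * mu^2`). The composition — how many cells of
#' each type appear in each (tissue, donor) — is given by `cells_per_cell`,
#' either a scalar or a `[type, tissue, donor]` array, so planted tissue
#' restrictions are expressed directly in the table.
#'
#' @param n_types Number of cell types.
#' @param markers_per_type Marker genes planted per type (disjoint blocks).
#' @param log2_fold_change Marker effect size on the log2 scale (>= 0).
#' @param base_mean Baseline per-gene mean expression (counts).
#' @param nb_dispersion Negative-binomial dispersion (> 0).
#' @param n_genes Total genes (must be >= `n_types * markers_per_type`).
#' @param cells_per_cell Scalar, or integer array `[type, tissue, donor]`,
#'   of cells per (type, tissue, donor) combination.
#' @param tissues,donors Character vectors naming tissues and donors.
#' @param donor_logfc_sd Log-sd of the per-donor lognormal nuisance (>= 0).
#' @param hierarchy_groups Named character vector mapping each type name to
#'   its high-level group; `NULL` assigns types round-robin to
#'   `"group_1".."group_3"`.
#' @param type_names Optional type names (default `"type_01"...`).
#' @param seed Integer seed; the dataset is fully determined by it.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_types = 5, markers_per_type = 10,
                       log2_fold_change = 2, base_mean = 0.5,
                       nb_dispersion = 0.5, n_genes = 500,
                       cells_per_cell = 30,
                       tissues = c("tissue_A", "tissue_B"),
                       donors = c("donor_1", "donor_2"),
                       donor_logfc_sd = 0.1, hierarchy_groups = NULL,
                       type_names = NULL, seed = 1L) {
  assert_scalar_number(n_types, "n_types")
  assert_scalar_number(markers_per_type, "markers_per_type")
  assert_scalar_number(base_mean, "base_mean")
  assert_scalar_number(nb_dispersion, "nb_dispersion")
  assert_scalar_number(n_genes, "n_genes")
  if (log2_fold_change < 0) stop_validation("log2_fold_change must be >= 0")
  if (donor_logfc_sd < 0) stop_validation("donor_logfc_sd must be >= 0")
  if (n_types * markers_per_type > n_genes) {
    stop_validation(
      "disjoint marker blocks do not fit: n_types * markers_per_type > n_genes")
  }
  type_names <- type_names %||% sprintf("type_%02d", seq_len(n_types))
  if (length(type_names) != n_types || anyDuplicated(type_names)) {
    stop_validation("type_names must be n_types unique names")
  }
  if (is.null(hierarchy_groups)) {
    hierarchy_groups <- stats::setNames(
      sprintf("group_%d", ((seq_len(n_types) - 1L) %% 3L) + 1L), type_names)
  }
  if (!all(type_names %in% names(hierarchy_groups))) {
    stop_validation("hierarchy_groups must cover every type")
  }
  if (length(cells_per_cell) == 1L) {
    cells <- array(as.integer(cells_per_cell),
                   dim = c(n_types, length(tissues), length(donors)),
                   dimnames = list(type_names, tissues, donors))
  } else {
    cells <- cells_per_cell
    if (!is.array(cells) ||
        !all(dim(cells) == c(n_types, length(tissues), length(donors)))) {
      stop_validation("cells_per_cell must be scalar or [type,tissue,donor]")
    }
    dimnames(cells) <- list(type_names, tissues, donors)
  }
  if (any(cells < 0)) stop_validation("negative cell counts in config")
  structure(
    list(n_types = as.integer(n_types),
         markers_per_type = as.integer(markers_per_type),
         log2_fold_change = log2_fold_change, base_mean = base_mean,
         nb_dispersion = nb_dispersion, n_genes = as.integer(n_genes),
         cells = cells, tissues = tissues, donors = donors,
         donor_logfc_sd = donor_logfc_sd,
         hierarchy_groups = hierarchy_groups[type_names],
         type_names = type_names, seed = as.integer(seed)),
    class = "SimConfig"
  )
}

# The composition implied by a SimConfig is deterministic: it is the cells
# table itself, enumerated in (type, tissue, donor) order.
sim_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  blocks <- expand.grid(type = cfg$type_names, tissue = cfg$tissues,
                        donor = cfg$donors, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  blocks$n <- mapply(function(ty, ti, d) cfg$cells[ty, ti, d],
                     blocks$type, blocks$tissue, blocks$donor)
  blocks <- blocks[blocks$n > 0, , drop = FALSE]
  total <- sum(blocks$n)
  df <- data.frame(
    cell_id = sprintf("cell_%06d", seq_len(total)),
    label = rep(blocks$type, blocks$n),
    tissue = rep(blocks$tissue, blocks$n),
    donor = rep(blocks$donor, blocks$n),
    stringsAsFactors = FALSE
  )
  cell_annotations(df)
}

#' Generate a synthetic scRNA-seq dataset
#'
#' Draws a counts matrix, per-cell annotations, the type-to-group hierarchy
#' and the ground-truth marker map from a [sim_config()]. Cell order and all
#' draws are fully determined by `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `annotations`
#'   (a [cell_annotations()]), `hierarchy` (a [label_hierarchy()]) and
#'   `markers` (named list: type -> character vector of its marker genes).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  ann <- sim_annotations(cfg)
  n_cells <- nrow(ann)
  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  markers <- lapply(seq_len(cfg$n_types), function(i) {
    gene_ids[((i - 1L) * cfg$markers_per_type + 1L):
               (i * cfg$markers_per_type)]
  })
  names(markers) <- cfg$type_names
  mult <- 2^cfg$log2_fold_change
  base <- rep(cfg$base_mean, cfg$n_genes)
  size <- 1 / cfg$nb_dispersion
  counts <- withr::with_seed(cfg$seed, {
    donor_fac <- matrix(
      exp(stats::rnorm(length(cfg$donors) * cfg$n_genes,
                       sd = cfg$donor_logfc_sd)),
      nrow = length(cfg$donors),
      dimnames = list(cfg$donors, NULL))
    out <- matrix(0L, n_cells, cfg$n_genes)
    # cells sharing (type, donor) share a mean vector; draw block-wise
    grp <- paste(ann$label, ann$donor, sep = "\r")
    for (g in unique(grp)) {
      idx <- which(grp == g)
      ty <- ann$label[idx[1]]
      d <- ann$donor[idx[1]]
      mu <- base * donor_fac[d, ]
      mi <- match(markers[[ty]], gene_ids)
      mu[mi] <- mu[mi] * mult
      out[idx, ] <- matrix(
        stats::rnbinom(length(idx) * cfg$n_genes, size = size,
                       mu = rep(mu, each = length(idx))),
        nrow = length(idx))
    }
    out
  })
  cm <- count_matrix(counts, ann$cell_id, gene_ids)
  hierarchy <- label_hierarchy(cfg$hierarchy_groups)
  list(counts = cm, annotations = ann, hierarchy = hierarchy,
       markers = markers)
}

#' Default benchmark configuration
#'
#' The reference conditions used throughout the package's tests and worked
#' examples: 10 cell types in 3 high-level groups, 2,000 genes with 20
#' disjoint markers per type at log2 fold-change 2 over a base mean of 0.5,
#' negative-binomial dispersion 0.5, 3 tissues x 3 donors with 50 cells per
#' (type, tissue, donor) — except one type (`DC_migratory`) restricted to a
#' single tissue (`lymph_node`) as a planted tissue enrichment. Donor
#' nuisance log-sd 0.1, seed 42 unless overridden.
#'
#' @param seed Integer seed (default 42).
#' @return A [sim_config()].
#' @export
default_benchmark_config <- function(seed = 42L) {
  type_names <- c("T_naive", "T_memory", "T_reg", "T_cytotoxic",
                  "B_naive", "B_memory", "Plasma",
                  "Monocyte", "Macrophage", "DC_migratory")
  groups <- stats::setNames(
    c(rep("T_cells", 4), rep("B_cells", 3), rep("Myeloid", 3)), type_names)
  tissues <- c("spleen", "lymph_node", "gut")
  donors <- c("donor_1", "donor_2", "donor_3")
  cells <- array(50L, dim = c(10, 3, 3),
                 dimnames = list(type_names, tissues, donors))
  cells["DC_migratory", c("spleen", "gut"), ] <- 0L   # planted restriction
  sim_config(n_types = 10, markers_per_type = 20, log2_fold_change = 2,
             base_mean = 0.5, nb_dispersion = 0.5, n_genes = 2000,
             cells_per_cell = cells, tissues = tissues, donors = donors,
             donor_logfc_sd = 0.1, hierarchy_groups = groups,
             type_names = type_names, seed = seed)
}

#' Write a generated dataset bundle to disk
#'
#' Writes the Matrix Market + sidecar bundle, the annotation and hierarchy
#' TSVs, and a `truth.json` echoing the configuration and the planted marker
#' map.
#'
#' @param dataset Output of [generate_dataset()].
#' @param cfg The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(dataset$counts, dir, format = "mtx")
  write_annotations(dataset$annotations, file.path(dir, "annotations.tsv"))
  write_hierarchy(dataset$hierarchy, file.path(dir, "hierarchy.tsv"))
  truth <- list(
    markers = dataset$markers,
    config = list(
      n_types = cfg$n_types, markers_per_type = cfg$markers_per_type,
      log2_fold_change = cfg$log2_fold_change, base_mean = cfg$base_mean,
      nb_dispersion = cfg$nb_dispersion, n_genes = cfg$n_genes,
      tissues = cfg$tissues, donors = cfg$donors,
      donor_logfc_sd = cfg$donor_logfc_sd, seed = cfg$seed,
      type_names = cfg$type_names,
      hierarchy_groups = as.list(cfg$hierarchy_groups))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
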