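# Two-round mini-batch SGD multinomial logistic regression: training,
# feature selection, prediction, marker extraction, model update and
# serialization.

#' Training configuration
#'
#' Collects every tunable of the classifier. The loss is multinomial softmax
#' cross-entropy plus an L2 penalty `(lambda/2) * ||W||^2` on the weights
#' (intercepts unpenalized); optimization is mini-batch stochastic gradient
#' descent over seeded shuffles of the cells, with either a constant learning
#' rate or the inverse scaling schedule
#' `eta_t = eta0 / (1 + lambda * eta0 * t)`.
#'
#' @param batch_size Cells per mini-batch (default 1000).
#' @param epochs Passes over the training data per round (default 30; with
#'   mini-batches of 1000 cells an epoch contributes few updates, so more
#'   passes are needed than in per-sample SGD).
#' @param l2_strength L2 penalty strength lambda (default 1e-4).
#' @param learning_rate0 Initial learning rate eta0 (default 0.02; log1p
#'   CP10K features are not standardized, and larger steps oscillate).
#' @param lr_schedule `"inverse"` (default) or `"constant"`.
#' @param n_top_genes Genes kept per class in round-1 feature selection
#'   (default 300).
#' @param seed Integer seed controlling mini-batch shuffles and splits.
#' @param validation_fraction Fraction held out for learning curves
#'   (default 0.1).
#' @param unassigned_threshold Optional probability threshold below which a
#'   prediction is reported as `"Unassigned"` (default `NULL`, disabled).
#' @param mode `"multinomial"` (default, softmax) or `"ovr"` (one-vs-rest
#'   binary fits with renormalized probabilities).
#' @return A `TrainingConfig` list.
#' @export
training_config <- function(batch_size = 1000, epochs = 30,
                            l2_strength = 1e-4, learning_rate0 = 0.02,
                            lr_schedule = c("inverse", "constant"),
                            n_top_genes = 300, seed = 1L,
                            validation_fraction = 0.1,
                            unassigned_threshold = NULL,
                            mode = c("multinomial", "ovr")) {
  lr_schedule <- match.arg(lr_schedule)
  mode <- match.arg(mode)
  assert_scalar_number(batch_size, "batch_size")
  assert_scalar_number(epochs, "epochs")
  assert_scalar_number(l2_strength, "l2_strength")
  assert_scalar_number(learning_rate0, "learning_rate0")
  assert_scalar_number(n_top_genes, "n_top_genes")
  if (batch_size != round(batch_size) || epochs != round(epochs) ||
      n_top_genes != round(n_top_genes)) {
    stop_validation("batch_size, epochs and n_top_genes must be integers")
  }
  if (!is.numeric(validation_fraction) || validation_fraction <= 0 ||
      validation_fraction >= 1) {
    stop_validation("validation_fraction must be in (0, 1)")
  }
  if (!is.null(unassigned_threshold) &&
      (unassigned_threshold < 0 || unassigned_threshold > 1)) {
    stop_validation("unassigned_threshold must be in [0, 1]")
  }
  structure(
    list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         l2_strength = l2_strength, learning_rate0 = learning_rate0,
         lr_schedule = lr_schedule, n_top_genes = as.integer(n_top_genes),
         seed = as.integer(seed), validation_fraction = validation_fraction,
         unassigned_threshold = unassigned_threshold, mode = mode),
    class = "TrainingConfig"
  )
}

#' Construct a classifier model object
#'
#' Usually produced by [fit_round()] / [train_two_round()]; exposed so models
#' can be built or inspected programmatically.
#'
#' @param class_names Ordered character vector of the K class labels.
#' @param feature_genes Ordered character vector of the G feature genes.
#' @param weights K x G numeric weight matrix.
#' @param intercepts Length-K numeric intercept vector.
#' @param normalization List describing the expected input representation,
#'   e.g. `list(target_sum = 1e4, transform = "log1p")`.
#' @param hierarchy_level Free tag, e.g. `"high"` or `"low"`.
#' @param version Model version, incremented by [update_model()].
#' @param provenance Character vector recording the corpora incorporated.
#' @return A `ClassifierModel`.
#' @export
classifier_model <- function(class_names, feature_genes, weights, intercepts,
                             normalization = list(target_sum = 1e4,
                                                  transform = "log1p"),
                             hierarchy_level = "low", version = 1L,
                             provenance = character()) {
  class_names <- as.character(class_names)
  feature_genes <- as.character(feature_genes)
  weights <- as.matrix(weights)
  intercepts <- as.numeric(intercepts)
  if (length(class_names) < 2L) stop_validation("a model needs >= 2 classes")
  if (anyDuplicated(class_names)) stop_validation("duplicate class names")
  if (anyDuplicated(feature_genes)) stop_validation("duplicate feature genes")
  if (!all(dim(weights) == c(length(class_names), length(feature_genes)))) {
    stop_validation("weight matrix must be K x G")
  }
  if (length(intercepts) != length(class_names)) {
    stop_validation("intercept length must equal number of classes")
  }
  if (version < 1) stop_validation("version must be >= 1")
  dimnames(weights) <- list(class_names, feature_genes)
  structure(
    list(class_names = class_names, feature_genes = feature_genes,
         weights = weights, intercepts = intercepts,
         normalization = normalization, hierarchy_level = hierarchy_level,
         version = as.integer(version), provenance = provenance),
    class = "ClassifierModel"
  )
}

#' @export
print.ClassifierModel <- function(x, ...) {
  cat(sprintf(
    "<ClassifierModel> %d classes x %d genes, version %d (%s hierarchy)\n",
    length(x$class_names), length(x$feature_genes), x$version,
    x$hierarchy_level))
  invisible(x)
}

#' Partition cells into shuffled mini-batches
#'
#' A seeded uniform shuffle of `1..n_cells` split into consecutive blocks of
#' `batch_size`; the final remainder block is retained rather than dropped, so
#' the blocks are disjoint and cover every cell.
#'
#' @param n_cells Number of cells.
#' @param batch_size Cells per batch.
#' @param seed Integer seed.
#' @return A list of integer index vectors.
#' @export
make_minibatches <- function(n_cells, batch_size, seed) {
  if (batch_size <= 0) stop_validation("batch_size must be > 0")
  perm <- withr::with_seed(as.integer(seed), sample.int(n_cells))
  unname(split(perm, ceiling(seq_along(perm) / batch_size)))
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Fit one round of the mini-batch SGD classifier
#'
#' Fits a multinomial (or one-vs-rest) L2-regularized logistic regression by
#' mini-batch SGD: `epochs` passes over a fresh seeded shuffle of the cells,
#' each pass split into blocks of `batch_size`. Weights and intercepts start
#' at zero, so the fit is deterministic given (data, config, seed).
#'
#' @param X A [normalized_matrix()].
#' @param labels Character vector of per-cell class labels (length = cells).
#' @param config A [training_config()].
#' @param feature_subset Optional gene list; `X` is passed through
#'   [align_genes()] first.
#' @param eval_fun Optional `function(model, epoch)` called at each epoch
#'   boundary (used for learning curves).
#' @return A list with `model` (a [classifier_model()]) and `history`, a data
#'   frame of per-update mini-batch losses.
#' @export
fit_round <- function(X, labels, config = training_config(),
                      feature_subset = NULL, eval_fun = NULL) {
  stopifnot(inherits(X, "NormalizedMatrix"))
  labels <- as.character(labels)
  if (length(labels) != nrow(X$values)) {
    stop_validation("labels length must equal number of cells")
  }
  if (any(is.na(labels) | labels == "")) {
    stop_validation("empty or missing labels")
  }
  if (!is.null(feature_subset)) X <- align_genes(X, feature_subset)
  if (anyNA(X$values@x) || any(!is.finite(X$values@x))) {
    stop_validation("non-finite values in expression matrix")
  }
  class_names <- sort(unique(labels))
  K <- length(class_names)
  if (K < 2L) stop_validation("training requires >= 2 distinct labels")
  n <- nrow(X$values)
  G <- ncol(X$values)
  y <- match(labels, class_names)
  lambda <- config$l2_strength
  eta0 <- config$learning_rate0
  W <- matrix(0, K, G)
  b <- numeric(K)
  t_upd <- 0L
  hist_it <- integer(); hist_epoch <- integer(); hist_loss <- numeric()
  Xv <- X$values
  for (epoch in seq_len(config$epochs)) {
    batches <- make_minibatches(n, config$batch_size,
                                derive_seed(config$seed, epoch - 1L))
    for (idx in batches) {
      Xb <- Xv[idx, , drop = FALSE]
      yb <- y[idx]
      B <- length(idx)
      S <- as.matrix(Xb %*% t(W))
      S <- sweep(S, 2L, b, "+")
      if (config$mode == "multinomial") {
        P <- softmax_rows(S)
        loss <- -mean(log(pmax(P[cbind(seq_len(B), yb)], 1e-300))) +
          lambda / 2 * sum(W^2)
        R <- P
        R[cbind(seq_len(B), yb)] <- R[cbind(seq_len(B), yb)] - 1
      } else {
        # one-vs-rest: K independent binary logistic fits sharing the pass
        P <- 1 / (1 + exp(-S))
        Yb <- matrix(0, B, K)
        Yb[cbind(seq_len(B), yb)] <- 1
        loss <- -mean(rowSums(Yb * log(pmax(P, 1e-300)) +
                                (1 - Yb) * log(pmax(1 - P, 1e-300)))) +
          lambda / 2 * sum(W^2)
        R <- P - Yb
      }
      gW <- as.matrix(Matrix::crossprod(R, Xb)) / B + lambda * W
      gb <- colSums(R) / B
      eta <- if (config$lr_schedule == "inverse") {
        eta0 / (1 + lambda * eta0 * t_upd)
      } else {
        eta0
      }
      W <- W - eta * gW
      b <- b - eta * gb
      t_upd <- t_upd + 1L
      hist_it <- c(hist_it, t_upd)
      hist_epoch <- c(hist_epoch, epoch)
      hist_loss <- c(hist_loss, loss)
    }
    if (!is.null(eval_fun)) {
      snap <- classifier_model(class_names, X$gene_ids, W, b,
                               normalization = list(
                                 target_sum = X$target_sum,
                                 transform = X$transform))
      eval_fun(snap, epoch)
    }
  }
  model <- classifier_model(class_names, X$gene_ids, W, b,
                            normalization = list(target_sum = X$target_sum,
                                                 transform = X$transform))
  history <- data.frame(iteration = hist_it, epoch = hist_epoch,
                        loss = hist_loss)
  list(model = model, history = history)
}

#' Select each class's top-weighted genes
#'
#' For every class, genes are ranked by descending signed weight (markers are
#' genes positively associated with the class); the first
#' `min(n_top, G)` per class are pooled and the union returned in the model's
#' original gene order. Ranking ties are broken by gene order.
#'
#' @param model A [classifier_model()].
#' @param n_top Genes to keep per class.
#' @return Character vector of selected genes (size at most `K * n_top`).
#' @export
select_top_features <- function(model, n_top) {
  stopifnot(inherits(model, "ClassifierModel"))
  assert_scalar_number(n_top, "n_top")
  G <- length(model$feature_genes)
  take <- min(as.integer(n_top), G)
  sel <- logical(G)
  for (k in seq_along(model$class_names)) {
    ord <- order(-model$weights[k, ], seq_len(G))
    sel[ord[seq_len(take)]] <- TRUE
  }
  model$feature_genes[sel]
}

#' Extract the top markers of one class
#'
#' @param model A [classifier_model()].
#' @param class_name One of `model$class_names`.
#' @param k Number of genes to return (capped at G).
#' @return Data frame with columns `gene` and `weight`, by descending weight.
#' @export
extract_markers <- function(model, class_name, k = 10) {
  stopifnot(inherits(model, "ClassifierModel"))
  ki <- match(class_name, model$class_names)
  if (is.na(ki)) {
    stop_validation(sprintf("unknown class '%s'", class_name))
  }
  G <- length(model$feature_genes)
  take <- min(as.integer(k), G)
  ord <- order(-model$weights[ki, ], seq_len(G))[seq_len(take)]
  data.frame(gene = model$feature_genes[ord],
             weight = unname(model$weights[ki, ord]),
             stringsAsFactors = FALSE)
}

#' Two-round training
#'
#' Round 1 fits on all genes; the union of each class's `n_top_genes`
#' top-weighted genes is then used as the feature set for a second, final
#' round of training. The returned model's `feature_genes` is that union.
#'
#' @inheritParams fit_round
#' @return A list with `model` (the round-2 model), `history` (both rounds,
#'   tagged by a `round` column) and `round1_model`.
#' @export
train_two_round <- function(X, labels, config = training_config()) {
  r1 <- fit_round(X, labels, config)
  feats <- select_top_features(r1$model, config$n_top_genes)
  r2 <- fit_round(X, labels, config, feature_subset = feats)
  h1 <- cbind(round = 1L, r1$history)
  h2 <- cbind(round = 2L, r2$history)
  list(model = r2$model, history = rbind(h1, h2), round1_model = r1$model)
}

#' Predict class probabilities for a query matrix
#'
#' The query is aligned to the model's feature genes (missing genes
#' zero-filled, overlap logged) and scored with a row-wise softmax of
#' `X W' + b`. The predicted label is the argmax class, or `"Unassigned"`
#' when a threshold is set and the maximum probability falls below it.
#'
#' @param model A [classifier_model()].
#' @param X A [normalized_matrix()] (any gene universe with non-zero overlap).
#' @param threshold Optional probability threshold for `"Unassigned"`.
#' @return A `PredictionResult`: list with `cell_ids`, `probabilities`
#'   (cells x K matrix), `predicted_label` and `confidence` (row maxima).
#' @export
predict_probabilities <- function(model, X, threshold = NULL) {
  stopifnot(inherits(model, "ClassifierModel"),
            inherits(X, "NormalizedMatrix"))
  Xa <- align_genes(X, model$feature_genes)
  S <- as.matrix(Xa$values %*% t(model$weights))
  S <- sweep(S, 2L, model$intercepts, "+")
  P <- softmax_rows(S)
  colnames(P) <- model$class_names
  rownames(P) <- X$cell_ids
  conf <- apply(P, 1L, max)
  lab <- model$class_names[max.col(P, ties.method = "first")]
  if (!is.null(threshold)) {
    lab[conf < threshold] <- "Unassigned"
  }
  structure(
    list(cell_ids = X$cell_ids, probabilities = P, predicted_label = lab,
         confidence = unname(conf), overlap = attr(Xa, "overlap")),
    class = "PredictionResult"
  )
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf("<PredictionResult> %d cells x %d classes (gene overlap %.2f)\n",
              length(x$cell_ids), ncol(x$probabilities), x$overlap))
  invisible(x)
}

#' Update a model with newly curated labels
#'
#' Retrains two-round on the concatenation of the old and new corpora. Gene
#' universes are reconciled onto the union of both gene lists with zero-fill
#' for genes a corpus lacks; new labels are validated against the hierarchy
#' first. The class set becomes the union of old and new labels, the version
#' is incremented and the provenance extended.
#'
#' @param old_model The current [classifier_model()].
#' @param old_corpus List with `X` (a `NormalizedMatrix`) and `labels` — the
#'   corpus the old model was trained on (models do not embed training data).
#' @param new_corpus List with `X` and `labels` for the newly curated cells;
#'   may be empty (`NULL` entries) for a no-op retrain.
#' @param hierarchy A [label_hierarchy()] covering all new labels.
#' @param config A [training_config()].
#' @return The updated `ClassifierModel`.
#' @export
update_model <- function(old_model, old_corpus, new_corpus, hierarchy,
                         config = training_config()) {
  stopifnot(inherits(old_model, "ClassifierModel"))
  empty_new <- is.null(new_corpus$X) || nrow(new_corpus$X$values) == 0L
  if (!empty_new) {
    rep <- validate_hierarchy(hierarchy, new_corpus$labels)
    if (!rep$pass) {
      stop_validation(
        sprintf("new labels missing from hierarchy: %s",
                paste(rep$missing, collapse = ", ")),
        category = "hierarchy")
    }
  }
  if (empty_new) {
    X <- old_corpus$X
    labels <- as.character(old_corpus$labels)
    prov_line <- "update: no new cells (no-op retrain)"
  } else {
    genes <- union(old_corpus$X$gene_ids, new_corpus$X$gene_ids)
    Xo <- align_genes(old_corpus$X, genes)
    Xn <- align_genes(new_corpus$X, genes)
    new_ids <- Xn$cell_ids
    if (any(new_ids %in% Xo$cell_ids)) {
      new_ids <- paste0("new:", new_ids)   # corpora may reuse barcodes
    }
    X <- normalized_matrix(rbind(Xo$values, Xn$values),
                           c(Xo$cell_ids, new_ids), genes,
                           target_sum = old_corpus$X$target_sum,
                           transform = old_corpus$X$transform)
    labels <- c(as.character(old_corpus$labels),
                as.character(new_corpus$labels))
    prov_line <- sprintf(
      "update: +%d cells, classes now {%s}", nrow(Xn$values),
      paste(sort(unique(labels)), collapse = ", "))
  }
  fit <- train_two_round(X, labels, config)
  model <- fit$model
  model$hierarchy_level <- old_model$hierarchy_level
  model$version <- old_model$version + 1L
  model$provenance <- c(old_model$provenance, prov_line)
  model
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load classifier models
#'
#' The on-disk format is a single JSON object: metadata fields
#' (`format_version`, `class_names`, `feature_genes`, `normalization`,
#' `hierarchy_level`, `version`, `provenance`, `n_classes`, `n_genes`) plus
#' the dense numeric payload as base64-encoded little-endian float64,
#' column-major K x G for `weights_b64` and length-K for `intercepts_b64`.
#' The round-trip is lossless to the byte.
#'
#' @param model A [classifier_model()].
#' @param path File path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   reconstructed `ClassifierModel`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ClassifierModel"))
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                  endian = "little"))
  }
  obj <- list(
    format = "sctyper-model",
    format_version = MODEL_FORMAT_VERSION,
    n_classes = length(model$class_names),
    n_genes = length(model$feature_genes),
    class_names = model$class_names,
    feature_genes = model$feature_genes,
    normalization = model$normalization,
    hierarchy_level = model$hierarchy_level,
    version = model$version,
    provenance = model$provenance,
    weights_b64 = enc(model$weights),
    intercepts_b64 = enc(model$intercepts)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop_format(
                    sprintf("cannot parse model file: %s",
                            conditionMessage(e))))
  if (!identical(obj$format, "sctyper-model")) {
    stop_format("not a sctyper model file")
  }
  if (!identical(as.integer(obj$format_version), MODEL_FORMAT_VERSION)) {
    stop_format(sprintf("model format version %s, expected %d",
                        obj$format_version, MODEL_FORMAT_VERSION))
  }
  dec <- function(b64, n) {
    raw <- jsonlite::base64_dec(b64)
    if (length(raw) != 8L * n) {
      stop_format("model payload has wrong length")
    }
    readBin(raw, "numeric", n = n, size = 8L, endian = "little")
  }
  K <- as.integer(obj$n_classes)
  G <- as.integer(obj$n_genes)
  if (K < 2L) stop_format("model declares fewer than 2 classes")
  W <- matrix(dec(obj$weights_b64, K * G), K, G)
  b <- dec(obj$intercepts_b64, K)
  classifier_model(obj$class_names, obj$feature_genes, W, b,
                   normalization = as.list(obj$normalization),
                   hierarchy_level = obj$hierarchy_level,
                   version = obj$version,
                   provenance = as.character(obj$provenance))
}
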