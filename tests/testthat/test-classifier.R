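# Mini-batch SGD training, feature selection, prediction, serialization.

toy_normalized <- function(values, cells = paste0("c", seq_len(nrow(values))),
                           genes = paste0("g", seq_len(ncol(values)))) {
  normalized_matrix(values, cells, genes, target_sum = 1e4)
}

# 40 cells, one perfectly separating gene (5 in class A, 0 in class B).
separable_toy <- function() {
  vals <- matrix(0, 40, 3)
  vals[1:20, 1] <- 5
  vals[, 2] <- rep(c(1, 2), 20)
  toy_normalized(vals)
}

test_that("make_minibatches partitions a seeded shuffle into blocks", {
  b <- make_minibatches(10, 5, seed = 3)
  expect_equal(lengths(b), c(5L, 5L))
  expect_setequal(unlist(b), 1:10)

  b2 <- make_minibatches(10, 4, seed = 3)
  expect_equal(lengths(b2), c(4L, 4L, 2L))
  expect_setequal(unlist(b2), 1:10)

  expect_identical(make_minibatches(100, 7, seed = 5),
                   make_minibatches(100, 7, seed = 5))
  expect_false(identical(unlist(make_minibatches(100, 7, seed = 5)),
                         unlist(make_minibatches(100, 7, seed = 6))))
  expect_error(make_minibatches(10, 0, seed = 1),
               class = "sctyper_validation_error")
})

test_that("fit_round separates a perfectly separating gene", {
  X <- separable_toy()
  labels <- rep(c("A", "B"), each = 20)
  fit <- fit_round(X, labels, training_config(batch_size = 8, seed = 2))
  pred <- predict_probabilities(fit$model, X)
  expect_equal(mean(pred$predicted_label == labels), 1.0)
  # and agrees with the full-batch reference optimizer on the same data
  ref <- reference_softmax_fit(X, labels, lambda = 1e-4)
  expect_equal(mean(pred$predicted_label == ref$predicted), 1.0)
})

test_that("degenerate training inputs are rejected", {
  X <- separable_toy()
  expect_error(fit_round(X, rep("A", 40), training_config()),
               class = "sctyper_validation_error")
  Xbad <- X
  Xbad$values[1, 1] <- NaN
  expect_error(fit_round(Xbad, rep(c("A", "B"), each = 20),
                         training_config()),
               class = "sctyper_validation_error")
  expect_error(fit_round(X, rep("", 40), training_config()),
               class = "sctyper_validation_error")
})

test_that("a dominating L2 penalty shrinks probabilities toward uniform", {
  X <- separable_toy()
  labels <- rep(c("A", "B"), each = 20)
  fit <- fit_round(X, labels, training_config(l2_strength = 1e6, seed = 2))
  expect_lt(max(abs(fit$model$weights)), 1e-3)
  pred <- predict_probabilities(fit$model, X)
  expect_equal(unname(pred$probabilities[, "A"]), rep(0.5, 40),
               tolerance = 0.02)
})

test_that("weight norm is non-increasing in the penalty strength", {
  ds <- small_dataset()
  X <- normalize_log1p(ds$counts)
  labels <- ds$annotations$label
  norms <- sapply(c(1e-4, 1e-2, 1, 100), function(lam) {
    fit <- fit_round(X, labels, training_config(l2_strength = lam,
                                                epochs = 10, seed = 4))
    sqrt(sum(fit$model$weights^2))
  })
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("select_top_features ranks by signed weight and unions per class", {
  model <- classifier_model(
    class_names = c("A", "B"), feature_genes = paste0("g", 1:4),
    weights = rbind(c(3, 1, -2, 0), c(0, 2, 5, 1)), intercepts = c(0, 0))
  expect_equal(select_top_features(model, 2), c("g1", "g2", "g3"))
  expect_equal(select_top_features(model, 10), paste0("g", 1:4))
})

test_that("extract_markers returns top weighted genes for one class", {
  model <- classifier_model(
    class_names = c("A", "B"), feature_genes = paste0("g", 1:4),
    weights = rbind(c(3, 1, -2, 0), c(0, 2, 5, 1)), intercepts = c(0, 0))
  mk <- extract_markers(model, "A", k = 1)
  expect_equal(mk$gene, "g1")
  expect_equal(mk$weight, 3)
  expect_equal(nrow(extract_markers(model, "B", k = 99)), 4)
  expect_error(extract_markers(model, "Z", 1),
               class = "sctyper_validation_error")
})

test_that("planted markers dominate the learned marker rankings", {
  ds <- small_dataset()
  X <- normalize_log1p(ds$counts)
  fit <- fit_round(X, ds$annotations$label, training_config(seed = 3))
  for (ty in names(ds$markers)) {
    top <- extract_markers(fit$model, ty, k = 5)$gene
    expect_gte(length(intersect(top, ds$markers[[ty]])), 4)
  }
})

test_that("two-round training restricts features to the selected union", {
  ds <- small_dataset()
  X <- normalize_log1p(ds$counts)
  cfg <- training_config(n_top_genes = 5, seed = 3)
  fit <- train_two_round(X, ds$annotations$label, cfg)
  expect_true(all(fit$model$feature_genes %in% X$gene_ids))
  expect_lte(length(fit$model$feature_genes), 3 * 5)
  expect_equal(sort(unique(fit$history$round)), c(1L, 2L))

  # n_top_genes = G degenerates to the full gene set
  cfg_all <- training_config(n_top_genes = ncol(X$values), seed = 3)
  fit_all <- train_two_round(X, ds$annotations$label, cfg_all)
  expect_equal(fit_all$model$feature_genes, X$gene_ids)
})

test_that("softmax predictions are normalized, symmetric and thresholdable", {
  model <- classifier_model(
    class_names = paste0("k", 1:4), feature_genes = c("g1", "g2"),
    weights = matrix(0, 4, 2), intercepts = rep(0, 4))
  X <- toy_normalized(matrix(c(1, 2, 0, 1), 2, 2))
  pred <- predict_probabilities(model, X)
  expect_equal(unname(pred$probabilities),
               matrix(0.25, 2, 4), tolerance = 1e-12)

  m2 <- classifier_model(
    class_names = c("A", "B"), feature_genes = c("g1", "g2"),
    weights = diag(2), intercepts = c(0, 0))
  p <- predict_probabilities(m2, toy_normalized(matrix(c(1, 0), 1, 2)))
  expect_equal(unname(p$probabilities[1, ]),
               c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)), tolerance = 1e-9)
  expect_equal(p$confidence, exp(1) / (exp(1) + 1), tolerance = 1e-9)

  pthr <- predict_probabilities(m2, toy_normalized(matrix(c(1, 0), 1, 2)),
                                threshold = 0.8)
  expect_equal(pthr$predicted_label, "Unassigned")
})

test_that("probability rows always sum to one", {
  ds <- small_dataset()
  X <- normalize_log1p(ds$counts)
  fit <- fit_round(X, ds$annotations$label, training_config(seed = 5))
  pred <- predict_probabilities(fit$model, X)
  expect_true(all(abs(rowSums(pred$probabilities) - 1) < 1e-9))
  expect_true(all(pred$probabilities > 0 & pred$probabilities < 1))
  expect_equal(pred$confidence, unname(apply(pred$probabilities, 1, max)))
})

test_that("predictions are invariant to permuting query gene columns", {
  ds <- small_dataset()
  X <- normalize_log1p(ds$counts)
  fit <- fit_round(X, ds$annotations$label, training_config(seed = 5))
  perm <- withr::with_seed(9, sample(ncol(X$values)))
  Xp <- normalized_matrix(X$values[, perm], X$cell_ids, X$gene_ids[perm],
                          target_sum = X$target_sum)
  p1 <- predict_probabilities(fit$model, X)
  p2 <- predict_probabilities(fit$model, Xp)
  expect_equal(p1$probabilities, p2$probabilities, tolerance = 1e-12)
})

test_that("identical data, config and seed give bitwise-identical models", {
  ds <- small_dataset()
  X <- normalize_log1p(ds$counts)
  cfg <- training_config(seed = 7)
  f1 <- train_two_round(X, ds$annotations$label, cfg)
  f2 <- train_two_round(X, ds$annotations$label, cfg)
  expect_identical(f1$model$weights, f2$model$weights)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_model(f1$model, p1)
  save_model(f2$model, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("one-vs-rest mode trains and predicts on separable data", {
  X <- separable_toy()
  labels <- rep(c("A", "B"), each = 20)
  fit <- fit_round(X, labels, training_config(batch_size = 8, seed = 2,
                                              mode = "ovr"))
  pred <- predict_probabilities(fit$model, X)
  expect_equal(mean(pred$predicted_label == labels), 1.0)
})

test_that("model serialization round-trips losslessly and rejects bad files", {
  ds <- small_dataset()
  X <- normalize_log1p(ds$counts)
  fit <- fit_round(X, ds$annotations$label, training_config(seed = 5))
  model <- fit$model
  model$provenance <- "unit-test corpus"
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(back$weights, model$weights)
  expect_identical(back$intercepts, model$intercepts)
  expect_identical(back$class_names, model$class_names)
  expect_identical(back$feature_genes, model$feature_genes)
  expect_identical(back$version, model$version)
  expect_identical(back$provenance, model$provenance)
  expect_equal(back$normalization$target_sum, 1e4)

  # truncation leaves no partial model
  txt <- readLines(f)
  writeLines(txt[1:(length(txt) %/% 2)], f)
  expect_error(load_model(f), class = "sctyper_format_error")

  # format tag is checked
  writeLines('{"format": "something-else"}', f)
  expect_error(load_model(f), class = "sctyper_format_error")
})

test_that("update_model extends the class set and increments the version", {
  ds <- small_dataset()
  X <- normalize_log1p(ds$counts)
  labels <- ds$annotations$label
  cfg <- training_config(epochs = 10, seed = 7)
  base_fit <- train_two_round(X, labels, cfg)
  h <- label_hierarchy(c(ds$hierarchy$low_to_high, type_99 = "group_1"))

  # a new corpus carrying a new class and a partially different gene universe
  new_ds <- generate_dataset(sim_config(
    n_types = 1, markers_per_type = 5, log2_fold_change = 3,
    base_mean = 0.5, nb_dispersion = 0.4, n_genes = 50,
    cells_per_cell = 20, tissues = "spleen", donors = "d1",
    type_names = "type_99", seed = 31))
  Xn <- normalize_log1p(new_ds$counts)
  upd <- update_model(base_fit$model,
                      old_corpus = list(X = X, labels = labels),
                      new_corpus = list(X = Xn,
                                        labels = new_ds$annotations$label),
                      hierarchy = h, config = cfg)
  expect_setequal(upd$class_names, c(unique(labels), "type_99"))
  expect_equal(upd$version, base_fit$model$version + 1L)
  expect_true(any(grepl("type_99", upd$provenance)))

  # unknown label is refused
  expect_error(
    update_model(base_fit$model, list(X = X, labels = labels),
                 list(X = Xn, labels = rep("mystery", nrow(Xn$values))),
                 hierarchy = h, config = cfg),
    class = "sctyper_validation_error")

  # empty new corpus: retrain-only no-op, version still bumped
  upd0 <- update_model(base_fit$model, list(X = X, labels = labels),
                       list(X = NULL, labels = NULL), hierarchy = h,
                       config = cfg)
  expect_setequal(upd0$class_names, unique(labels))
  expect_equal(upd0$version, base_fit$model$version + 1L)

  # determinism: identical corpora and seed serialize byte-identically
  upd2 <- update_model(base_fit$model, list(X = X, labels = labels),
                       list(X = Xn, labels = new_ds$annotations$label),
                       hierarchy = h, config = cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_model(upd, f1); save_model(upd2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
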