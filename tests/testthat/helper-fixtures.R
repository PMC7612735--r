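# Shared fixtures and independent oracles used across test files.

# A small, well-separated 3-type dataset with tissue/donor structure.
small_cfg <- function(seed = 11L, markers_per_type = 5,
                      log2_fold_change = 3, ...) {
  sim_config(n_types = 3, markers_per_type = markers_per_type,
             log2_fold_change = log2_fold_change,
             base_mean = 0.5, nb_dispersion = 0.4, n_genes = 60,
             cells_per_cell = 25, tissues = c("spleen", "gut"),
             donors = c("d1", "d2"), seed = seed, ...)
}

small_dataset <- function(seed = 11L, ...) {
  generate_dataset(small_cfg(seed = seed, ...))
}

# The benchmark dataset with a 70/30 stratified split and a two-round fit is
# used by several suites; compute it once per test run.
.fixture_cache <- new.env(parent = emptyenv())

benchmark_fit <- function() {
  if (is.null(.fixture_cache$bench)) {
    cfg <- default_benchmark_config()
    ds <- generate_dataset(cfg)
    X <- normalize_log1p(ds$counts)
    labels <- ds$annotations$label
    test_idx <- sctyper:::stratified_validation_split(labels, 0.3, cfg$seed)
    train_idx <- setdiff(seq_along(labels), test_idx)
    Xtr <- normalized_matrix(X$values[train_idx, , drop = FALSE],
                             X$cell_ids[train_idx], X$gene_ids,
                             target_sum = X$target_sum)
    Xte <- normalized_matrix(X$values[test_idx, , drop = FALSE],
                             X$cell_ids[test_idx], X$gene_ids,
                             target_sum = X$target_sum)
    fit <- train_two_round(Xtr, labels[train_idx], training_config(seed = 1))
    .fixture_cache$bench <- list(
      cfg = cfg, ds = ds, X = X, labels = labels,
      train_idx = train_idx, test_idx = test_idx,
      Xtr = Xtr, Xte = Xte, fit = fit)
  }
  .fixture_cache$bench
}

# Build a CompositionTable directly from a (type, tissue, donor) count array.
comp_from_array <- function(counts) {
  dn <- dimnames(counts)
  rows <- expand.grid(type = dn[[1]], tissue = dn[[2]], donor = dn[[3]],
                      stringsAsFactors = FALSE)
  rows$n <- as.vector(counts)
  rows <- rows[rows$n > 0, ]
  df <- data.frame(
    cell_id = sprintf("c%06d", seq_len(sum(rows$n))),
    label = rep(rows$type, rows$n),
    tissue = rep(rows$tissue, rows$n),
    donor = rep(rows$donor, rows$n))
  composition_table(cell_annotations(df))
}

arr <- function(v, types, tissues, donors) {
  array(v, dim = c(length(types), length(tissues), length(donors)),
        dimnames = list(types, tissues, donors))
}

# --- Independent oracles -------------------------------------------------

# Full-batch deterministic optimizer of the identical penalized softmax loss
# (BFGS on the exact objective); independent of the SGD code path.
reference_softmax_fit <- function(X, labels, lambda) {
  classes <- sort(unique(labels))
  K <- length(classes)
  Xd <- as.matrix(X$values)
  n <- nrow(Xd)
  G <- ncol(Xd)
  y <- match(labels, classes)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y)] <- 1
  unpack <- function(par) {
    list(W = matrix(par[seq_len(K * G)], K, G),
         b = par[K * G + seq_len(K)])
  }
  obj <- function(par) {
    th <- unpack(par)
    S <- Xd %*% t(th$W) + matrix(th$b, n, K, byrow = TRUE)
    S <- S - apply(S, 1, max)
    logZ <- log(rowSums(exp(S)))
    -mean(S[cbind(seq_len(n), y)] - logZ) + lambda / 2 * sum(th$W^2)
  }
  grad <- function(par) {
    th <- unpack(par)
    S <- Xd %*% t(th$W) + matrix(th$b, n, K, byrow = TRUE)
    S <- S - apply(S, 1, max)
    P <- exp(S) / rowSums(exp(S))
    R <- P - Y
    gW <- t(R) %*% Xd / n + lambda * th$W
    gb <- colSums(R) / n
    c(as.vector(gW), gb)
  }
  opt <- stats::optim(rep(0, K * G + K), obj, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  th <- unpack(opt$par)
  S <- Xd %*% t(th$W) + matrix(th$b, n, K, byrow = TRUE)
  list(classes = classes, W = th$W, b = th$b,
       predicted = classes[max.col(S, ties.method = "first")])
}

# Numeric likelihood-maximization oracle for the donor-stratified Poisson
# model; BFGS on the log-likelihood, Wald SE from the analytic Fisher
# information evaluated at the oracle's own optimum.
poisson_oracle <- function(n_target, N_target, n_rest, N_rest) {
  D <- length(n_target)
  n <- c(n_target, n_rest)
  off <- log(c(N_target, N_rest))
  # design: intercept, donor effects 2..D, group indicator
  Xd <- cbind(1,
              rbind(diag(D), diag(D))[, -1, drop = FALSE],
              rep(c(1, 0), each = D))
  nll <- function(beta) {
    eta <- as.vector(Xd %*% beta) + off
    -sum(n * eta - exp(eta))
  }
  gr <- function(beta) {
    mu <- exp(as.vector(Xd %*% beta) + off)
    -as.vector(t(Xd) %*% (n - mu))
  }
  opt <- stats::optim(rep(0, ncol(Xd)), nll, gr, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  mu <- exp(as.vector(Xd %*% opt$par) + off)
  info <- t(Xd) %*% (Xd * mu)
  se <- sqrt(diag(solve(info)))
  j <- ncol(Xd)
  beta1 <- opt$par[j]
  z <- beta1 / se[j]
  list(beta1 = beta1, se = se[j], p = stats::pnorm(z, lower.tail = FALSE))
}

# Step-up enumeration oracle for Benjamini-Hochberg: the literal definition,
# adj_i = min over k >= rank(i) of p_(k) * m / k, clipped to 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- (m / (i:m)) * ps[i:m]
    adj_sorted[i] <- min(1, min(vals))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Brute-force per-cell enumeration of TP/FP/FN for precision/recall/F1.
prf_oracle <- function(true, pred) {
  classes <- sort(unique(true))
  out <- lapply(classes, function(c) {
    tp <- sum(true == c & pred == c)
    fp <- sum(true != c & pred == c)
    fn <- sum(true == c & pred != c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  })
  do.call(rbind, out)
}
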