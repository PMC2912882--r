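# Shared fixtures: tiny descriptor matrices with known structure and a
# cheap deterministic wrapper fitness for selection tests.

# n x p standard-normal matrix with ids and descriptor names
random_matrix <- function(n, p, seed = 1, prefix = "D") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), nrow = n,
                dimnames = list(sprintf("m%03d", seq_len(n)),
                                paste0(prefix, seq_len(p))))
  })
  m
}

# two-class labels over the five-isoform vocabulary
two_class_labels <- function(ids, n_pos, pos = "CYP3A4", neg = "CYP2D6") {
  stats::setNames(c(rep(pos, n_pos), rep(neg, length(ids) - n_pos)), ids)
}

# fitness that needs no SVM: 3-fold CV accuracy of a nearest-centroid
# classifier; fast enough for exhaustive subset oracles
centroid_cv_fitness <- function(folds = 3, seed = 99) {
  function(m, labels) {
    labels <- labels[rownames(m)]
    fold <- kfold_split(rownames(m), folds, seed = seed,
                        stratify_labels = labels)
    correct <- 0
    for (f in sort(unique(fold))) {
      tr <- fold != f
      classes <- unique(labels[tr])
      centroids <- vapply(classes, function(cl) {
        colMeans(m[tr & labels == cl, , drop = FALSE])
      }, numeric(ncol(m)))
      centroids <- matrix(centroids, ncol = length(classes),
                          dimnames = list(colnames(m), classes))
      test <- which(!tr)
      for (i in test) {
        d <- colSums((centroids - m[i, ])^2)
        correct <- correct + (classes[which.min(d)] == labels[i])
      }
    }
    correct / nrow(m)
  }
}

# small labeled dataset with one informative column per class among noise
informative_dataset <- function(n_per_class = 20, n_noise = 8, sep = 3,
                                seed = 5, n_classes = 2) {
  classes <- CYP_ISOFORMS[seq_len(n_classes)]
  n <- n_classes * n_per_class
  ids <- sprintf("m%03d", seq_len(n))
  labels <- stats::setNames(rep(classes, each = n_per_class), ids)
  sig <- paste0("SIG", seq_len(n_classes))
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * (n_classes + n_noise)), nrow = n,
                dimnames = list(ids, c(sig, paste0("NOI", seq_len(n_noise)))))
    for (k in seq_len(n_classes)) {
      m[labels == classes[k], sig[k]] <- m[labels == classes[k], sig[k]] + sep
    }
  })
  list(matrix = m, labels = labels)
}

fast_grid <- function() svm_grid(kernels = "linear", cost = 1)
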