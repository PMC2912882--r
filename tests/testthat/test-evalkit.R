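# Figures of merit, fold machinery and accuracy aggregation.

test_that("compute_metrics reproduces the published figure-of-merit arithmetic", {
  perfect <- compute_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)

  # 35 of 47 CYP2D6 substrates recovered -> the printed 74.47 sensitivity
  expect_equal(compute_metrics(confusion_counts(35, 50, 10, 12))$sensitivity, 74.47)

  m <- compute_metrics(confusion_counts(8, 7, 2, 3))
  expect_equal(m$mcc, 50 / sqrt(9900), tolerance = 1e-12)

  expect_equal(compute_metrics(confusion_counts(0, 0, 0, 5))$mcc, 0) # zero factor
  expect_error(compute_metrics(confusion_counts(-1, 0, 0, 2)), "non-negative")
})

test_that("metrics agree with a direct formula oracle on random confusion counts", {
  withr::with_seed(42, {
    for (i in 1:300) {
      c4 <- sample(0:20, 4, replace = TRUE)
      if (sum(c4) == 0) next
      m <- compute_metrics(confusion_counts(c4[1], c4[2], c4[3], c4[4]))
      tp <- c4[1]; tn <- c4[2]; fp <- c4[3]; fn <- c4[4]
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      expect_equal(m$mcc, if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den),
                   tolerance = 1e-12)
      expect_equal(m$accuracy, round_half_up(100 * (tp + tn) / sum(c4), 2))
      if (tp + fn > 0) {
        expect_equal(m$sensitivity, round_half_up(100 * tp / (tp + fn), 2))
      }
    }
  })
})

test_that("MCC is symmetric under simultaneous TP<->TN, FP<->FN swap", {
  withr::with_seed(1, {
    for (i in 1:50) {
      c4 <- sample(0:15, 4, replace = TRUE) + c(1, 1, 0, 0)
      expect_equal(compute_metrics(confusion_counts(c4[1], c4[2], c4[3], c4[4]))$mcc,
                   compute_metrics(confusion_counts(c4[2], c4[1], c4[4], c4[3]))$mcc)
    }
  })
})

test_that("kfold_split partitions with balanced sizes and strata", {
  ids <- sprintf("m%03d", 1:216)
  fold <- kfold_split(ids, 5, seed = 3)
  expect_setequal(names(fold), ids)
  expect_equal(sort(as.integer(table(fold)), decreasing = TRUE),
               c(44L, 43L, 43L, 43L, 43L))

  labels <- rep(c("CYP3A4", "CYP2D6", "CYP1A2", "CYP2C9", "CYP2C19"),
                c(111, 47, 29, 10, 19))
  ids2 <- sprintf("x%03d", seq_along(labels))
  fold2 <- kfold_split(ids2, 5, seed = 3, stratify_labels = labels)
  expect_true(max(table(fold2)) - min(table(fold2)) <= 1)
  per <- table(labels, fold2)
  for (cl in rownames(per)) {
    expect_lte(max(per[cl, ]) - min(per[cl, ]), 1)
  }
  # class of 19 spread as 3 or 4 per fold
  expect_true(all(per["CYP2C19", ] %in% 3:4))
  # same seed -> same split
  expect_identical(fold2, kfold_split(ids2, 5, seed = 3, stratify_labels = labels))
  expect_warning(kfold_split(ids[1:10], 5, seed = 1,
                             stratify_labels = rep(c("a", "b"), c(7, 3))),
                 "best-effort")
})

test_that("accuracy aggregation matches the published table arithmetic", {
  expect_equal(average_accuracy(c(78.76, 83.19, 87.61, 91.15, 89.38)), 86.02)
  expect_equal(average_accuracy(rep(77.77, 5)), 77.77)
  expect_equal(overall_accuracy(103, 146), 70.55)
  expect_equal(overall_accuracy(0, 50), 0)
  expect_error(overall_accuracy(1, 0), "positive")
  expect_error(overall_accuracy(5, 4))
  # overall equals the class-size-weighted mean of per-class accuracies
  acc <- c(78.76, 83.19, 87.61, 91.15, 89.38)
  sizes <- c(111, 47, 29, 20, 19)
  expect_equal(round_half_up(sum(acc * sizes) / sum(sizes), 2), 82.81)
  correct <- round(acc * sizes / 100)
  expect_equal(overall_accuracy(sum(correct), sum(sizes)),
               round_half_up(100 * sum(correct) / sum(sizes), 2))
})

test_that("cross-validation is deterministic and near-perfect on separable data", {
  ds <- informative_dataset(n_per_class = 18, n_noise = 3, sep = 5)
  cv1 <- cross_validate(ds$matrix, ds$labels, c("SIG1", "SIG2"),
                        hyper = fast_grid(), scheme = "fivefold", seed = 11)
  cv2 <- cross_validate(ds$matrix, ds$labels, c("SIG1", "SIG2"),
                        hyper = fast_grid(), scheme = "fivefold", seed = 11)
  expect_identical(cv1$per_isoform, cv2$per_isoform)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_gte(cv1$overall_accuracy, 90)
  expect_equal(cv1$overall_accuracy,
               overall_accuracy(sum(cv1$predictions == ds$labels),
                                length(ds$labels)))
  expect_equal(cv1$average_accuracy,
               average_accuracy(cv1$per_isoform_accuracy))
})

test_that("LOOCV trains once per example", {
  ds <- informative_dataset(n_per_class = 8, n_noise = 1, sep = 5)
  cv <- cross_validate(ds$matrix, ds$labels, c("SIG1", "SIG2"),
                       hyper = fast_grid(), scheme = "loocv", seed = 2)
  expect_equal(length(unique(cv$folds)), nrow(ds$matrix))
  expect_gte(cv$overall_accuracy, 90)
})

test_that("multi-label evaluation counts per-isoform substrate recovery", {
  ds <- informative_dataset(n_per_class = 15, n_noise = 2, sep = 5)
  suite <- train_suite(ds$matrix, ds$labels, selected = c("SIG1", "SIG2"),
                       hyper = fast_grid(), seed = 4)
  sets <- as.list(ds$labels)
  ev <- evaluate_multilabel(suite, ds$matrix, sets)
  # hand-counted oracle
  pred <- predict_multi_label(suite, ds$matrix)
  for (iso in suite$isoforms) {
    subs <- names(sets)[vapply(sets, function(s) iso %in% s, logical(1))]
    manual <- round_half_up(100 * mean(vapply(subs, function(id)
      iso %in% pred[[id]], logical(1))), 2)
    expect_equal(unname(ev$per_isoform[iso]), manual)
  }
  expect_true(all(is.na(ev$per_isoform[setdiff(CYP_ISOFORMS, suite$isoforms)])))

  # all-thresholds -Inf superset => 100% everywhere it applies
  loose <- suite
  for (iso in loose$isoforms) loose$models[[iso]]$threshold <- -Inf
  ev2 <- evaluate_multilabel(loose, ds$matrix, sets)
  expect_true(all(ev2$per_isoform[loose$isoforms] == 100))
})
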