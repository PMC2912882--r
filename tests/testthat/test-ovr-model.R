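# One-vs-rest suite training, threshold calibration, and the single- and
# multi-label decision rules.

test_that("threshold calibration handles the canonical cases", {
  # separable symmetric: midpoint of the gap, MCC 1, |sens-spec| 0
  expect_equal(calibrate_threshold(c(2, 1, -1, -2), c(TRUE, TRUE, FALSE, FALSE)), 0)
  # all scores identical -> that score
  expect_equal(calibrate_threshold(rep(0.7, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)), 0.7)
  expect_error(calibrate_threshold(1:4, rep(TRUE, 4)), "both classes")
  # 8-point interleaved set equals the exhaustive scan
  s <- c(3.1, 2.0, 1.5, 0.9, 0.4, -0.2, -1.0, -2.2)
  y <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(calibrate_threshold(s, y), brute_force_threshold(s, y))
})

test_that("threshold calibration equals the brute-force scan on random instances", {
  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      y <- rep(FALSE, n)
      y[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
      scores <- round(rnorm(n, mean = ifelse(y, 0.5, -0.5)), 2) # force ties
      expect_equal(calibrate_threshold(scores, y),
                   brute_force_threshold(scores, y))
    }
  })
})

test_that("suite training separates well-separated classes perfectly", {
  tab <- generate_table(synth_spec(
    class_sizes = c(CYP3A4 = 20, CYP2D6 = 15, CYP1A2 = 12, CYP2C9 = 10,
                    CYP2C19 = 10),
    n_informative_per_class = 2, n_noise = 4, n_redundant = 0, n_sparse = 0,
    n_highmissing = 0, missing_frac = 0, class_separation = 8, seed = 3))
  suite <- train_suite(tab$matrix, tab$labels, hyper = fast_grid(), seed = 3)
  expect_s3_class(suite, "model_suite")
  expect_equal(suite$isoforms, CYP_ISOFORMS)
  pred <- predict_single_label(suite, tab$matrix)
  expect_equal(unname(pred), unname(tab$labels[names(pred)]))
  # thresholds calibrated and finite; positive/negative counts recorded
  for (m in suite$models) {
    expect_true(is.finite(m$threshold))
    expect_gte(m$n_positive, 1)
    expect_gte(m$n_negative, 1)
  }
  # identical run -> identical scores
  suite2 <- train_suite(tab$matrix, tab$labels, hyper = fast_grid(), seed = 3)
  expect_identical(score_suite(suite, tab$matrix),
                   score_suite(suite2, tab$matrix))
})

test_that("isoforms with too few positives are skipped with a warning", {
  ds <- informative_dataset(n_per_class = 15, n_noise = 2, sep = 4)
  expect_message(suite <- train_suite(ds$matrix, ds$labels, hyper = fast_grid(),
                                      seed = 1),
                 "no substrates")
  expect_equal(suite$isoforms, c("CYP3A4", "CYP2D6"))
  labels3 <- ds$labels
  labels3[1] <- "CYP1A2" # a single positive for CYP1A2
  expect_warning(suite3 <- train_suite(ds$matrix, labels3, hyper = fast_grid(),
                                       seed = 1),
                 "CYP1A2")
  expect_false("CYP1A2" %in% suite3$isoforms)
})

test_that("scores impute missing descriptors and stay finite", {
  ds <- informative_dataset(n_per_class = 12, n_noise = 2, sep = 4)
  suite <- train_suite(ds$matrix, ds$labels, hyper = fast_grid(), seed = 2)
  x <- ds$matrix[1, ]
  s <- score_suite(suite, x)
  expect_named(s, suite$isoforms)
  x_missing <- x
  x_missing["SIG1"] <- NA
  s2 <- score_suite(suite, x_missing)
  expect_true(all(is.finite(s2)))
  expect_false(identical(s, s2))
  # absent descriptor column is fatal
  expect_error(score_suite(suite, x[-1]), "absent")
  # identical molecules -> identical score maps
  expect_identical(score_suite(suite, x), score_suite(suite, x))
})

test_that("single-label prediction is the argmax with canonical-order ties", {
  ds <- informative_dataset(n_per_class = 12, n_noise = 2, sep = 4)
  suite <- train_suite(ds$matrix, ds$labels, hyper = fast_grid(), seed = 2)
  s <- score_suite(suite, ds$matrix[1, ])
  expect_equal(unname(predict_single_label(suite, ds$matrix[1, ])),
               names(s)[which.max(s)])
  # forced exact tie: identical duplicated model under both names
  tied <- suite
  tied$models[["CYP2D6"]] <- tied$models[["CYP3A4"]]
  expect_equal(unname(predict_single_label(tied, ds$matrix[1, ])), "CYP3A4")
  # single-model suite predicts its isoform always
  solo <- suite
  solo$isoforms <- "CYP2D6"
  solo$models <- suite$models["CYP2D6"]
  expect_true(all(predict_single_label(solo, ds$matrix) == "CYP2D6"))
})

test_that("multi-label prediction thresholds strictly and may be empty", {
  ds <- informative_dataset(n_per_class = 12, n_noise = 2, sep = 4)
  suite <- train_suite(ds$matrix, ds$labels, hyper = fast_grid(), seed = 2)
  s <- score_suite(suite, ds$matrix)
  thr <- vapply(suite$models, `[[`, numeric(1), "threshold")
  ml <- predict_multi_label(suite, ds$matrix)
  for (id in rownames(ds$matrix)) {
    expect_setequal(ml[[id]], suite$isoforms[s[id, ] > thr])
  }
  # all thresholds -Inf -> every isoform for every molecule
  low <- suite
  for (iso in low$isoforms) low$models[[iso]]$threshold <- -Inf
  expect_true(all(lengths(predict_multi_label(low, ds$matrix)) ==
                    length(low$isoforms)))
  # all thresholds +Inf -> empty sets; monotone in each threshold
  high <- suite
  for (iso in high$isoforms) high$models[[iso]]$threshold <- Inf
  expect_true(all(lengths(predict_multi_label(high, ds$matrix)) == 0))
  pt <- predict_table(high, ds$matrix, mode = "multi")
  expect_true(all(pt$multi_label == ""))
  expect_true(all(pt$no_isoform_predicted))
})

test_that("accuracy degrades monotonically as class separation shrinks", {
  accs <- vapply(c(6, 2, 0), function(sep) {
    tab <- generate_table(synth_spec(
      class_sizes = c(CYP3A4 = 56, CYP2D6 = 24, CYP1A2 = 15, CYP2C9 = 10,
                      CYP2C19 = 10),
      n_noise = 10, n_redundant = 0, n_sparse = 0, n_highmissing = 0,
      missing_frac = 0, class_separation = sep, seed = 14))
    cross_validate(tab$matrix, tab$labels, tab$manifest$informative,
                   hyper = fast_grid(), scheme = "fivefold",
                   seed = 14)$overall_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
  expect_gte(accs[1], 90)   # separated: near-perfect
  expect_lt(accs[3], 60)    # no signal: far below the separated case
})

test_that("rarer isoforms attain lower one-vs-rest MCC at matched difficulty", {
  # matched per-class difficulty: identical separation everywhere, so any
  # systematic MCC differences come from the positive-example counts
  res <- t(vapply(1:10, function(s) {
    tab <- generate_table(synth_spec(class_separation = 2, n_noise = 10,
                                     n_redundant = 0, n_sparse = 0,
                                     n_highmissing = 0, missing_frac = 0,
                                     seed = s))
    cv <- cross_validate(tab$matrix, tab$labels, tab$manifest$informative,
                         hyper = fast_grid(), scheme = "fivefold", seed = s)
    setNames(cv$per_isoform$mcc, cv$per_isoform$isoform)
  }, numeric(5)))
  # the worst model is one of the two smallest classes in >= 8/10 runs
  worst <- colnames(res)[apply(res, 1, which.min)]
  expect_gte(sum(worst %in% c("CYP2C9", "CYP2C19")), 8)
  # and on average the largest class supports the best model while the
  # two smallest support the weakest
  means <- colMeans(res)
  expect_equal(names(which.max(means)), "CYP3A4")
  expect_lt(max(means[c("CYP2C9", "CYP2C19")]),
            min(means[c("CYP3A4", "CYP2D6", "CYP1A2")]))
})

test_that("model bundles survive a JSON round trip and reject corruption", {
  ds <- informative_dataset(n_per_class = 12, n_noise = 2, sep = 4)
  suite <- train_suite(ds$matrix, ds$labels, hyper = fast_grid(), seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_suite(suite, path)
  back <- load_suite(path)
  expect_equal(back$selected_descriptors, suite$selected_descriptors)
  expect_equal(score_suite(back, ds$matrix), score_suite(suite, ds$matrix))
  expect_identical(predict_single_label(back, ds$matrix),
                   predict_single_label(suite, ds$matrix))
  # version and integrity checks
  bundle <- jsonlite::read_json(path)
  bundle$format_version <- 99
  bad1 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bundle, bad1, auto_unbox = TRUE)
  expect_error(load_suite(bad1), "format version")
  bundle$format_version <- 1
  bundle$models[[1]]$classifier_b64 <- "corrupted!!"
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bundle, bad2, auto_unbox = TRUE)
  expect_error(load_suite(bad2), "corrupted")
})
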