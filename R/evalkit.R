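# Confusion counts, figures of merit, cross-validation machinery and the
# average/overall accuracy aggregation used in the result tables.

#' Confusion counts for a binary classification
#'
#' @param tp,tn,fp,fn non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

# raw MCC without rounding; any zero factor in the denominator -> 0,
# the random-prediction convention
mcc_value <- function(tp, tn, fp, fn) {
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(den2)
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sensitivity = TP/(TP+FN) x 100, specificity = TN/(TN+FP) x 100,
#' accuracy = (TP+TN)/total x 100, and the Matthews correlation
#' coefficient. Percentages are reported half-up to 2 decimals; a zero
#' factor in the MCC denominator yields MCC = 0 (random prediction).
#'
#' @param counts a [confusion_counts()] object, or TP when giving the four
#'   counts positionally.
#' @param tn,fp,fn remaining counts when `counts` is given as TP.
#' @return list with `sensitivity`, `specificity`, `accuracy` (percent) and
#'   `mcc` (unrounded, in \[-1, 1\]).
#' @export
compute_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion_counts(counts, tn, fp, fn)
  }
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated examples", call. = FALSE)
  pct <- function(num, den) if (den == 0) NA_real_ else round_half_up(100 * num / den, 2)
  list(
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    accuracy    = round_half_up(100 * (tp + tn) / total, 2),
    mcc         = mcc_value(tp, tn, fp, fn)
  )
}

#' Stratified or plain k-fold assignment
#'
#' Partitions ids into k folds of near-equal size (sizes differ by at most
#' one). With `stratify_labels`, members of each class are spread so that
#' per-fold class counts deviate from proportional by at most one; classes
#' smaller than k are spread best-effort with a warning.
#'
#' @param ids character or integer vector of unique ids.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratify_labels optional vector of class labels aligned with `ids`.
#' @return integer vector of fold numbers in 1..k, named by `ids`.
#' @export
kfold_split <- function(ids, k, seed = 1L, stratify_labels = NULL) {
  n <- length(ids)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("fewer ids than folds", call. = FALSE)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  groups <- if (is.null(stratify_labels)) rep("all", n) else as.character(stratify_labels)
  if (length(groups) != n) stop("stratify_labels length mismatch", call. = FALSE)
  if (!is.null(stratify_labels)) {
    small <- names(which(table(groups) < k))
    if (length(small) > 0) {
      warning("class(es) smaller than k spread best-effort: ",
              paste(small, collapse = ", "), call. = FALSE)
    }
  }
  fold <- integer(n)
  sizes <- integer(k)
  withr::with_seed(seed, {
    for (g in unique(groups)) {
      members <- sample(which(groups == g))
      # deal members to folds ordered smallest-first so that global fold
      # sizes never drift apart by more than one
      ord <- order(sizes, seq_len(k))
      slots <- rep(ord, length.out = length(members))
      fold[members] <- slots
      sizes <- tabulate(fold[fold > 0L], nbins = k)
    }
  })
  names(fold) <- ids
  fold
}

#' Unweighted mean of per-isoform accuracies
#'
#' The headline "average accuracy": the arithmetic mean of the five
#' per-isoform single-label accuracies, reported half-up to 2 decimals.
#'
#' @param per_isoform_acc numeric vector of per-isoform accuracies (percent).
#' @return percent, rounded to 2 decimals.
#' @export
average_accuracy <- function(per_isoform_acc) {
  round_half_up(mean(per_isoform_acc), 2)
}

#' Overall accuracy
#'
#' Percentage of all evaluated molecules whose single-label prediction is
#' correct, reported half-up to 2 decimals.
#'
#' @param n_correct number of correctly predicted molecules.
#' @param n_total number of evaluated molecules (> 0).
#' @return percent, rounded to 2 decimals.
#' @export
overall_accuracy <- function(n_correct, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_correct < 0 || n_correct > n_total) {
    stop("n_correct must lie in [0, n_total]", call. = FALSE)
  }
  round_half_up(100 * n_correct / n_total, 2)
}

#' Cross-validated evaluation of the one-vs-rest suite
#'
#' Runs the full train/predict cycle under five-fold or leave-one-out
#' cross-validation: for each fold a [train_suite()] is fitted on the
#' complement and the held-out molecules are single-label predicted.
#' Out-of-fold predictions are pooled into per-isoform one-vs-rest
#' confusion counts (micro aggregation) and into the per-isoform,
#' average and overall single-label accuracies.
#'
#' @param matrix descriptor matrix (rows = molecules, NA = missing).
#' @param labels named character vector, one isoform per molecule.
#' @param selected descriptor names to use (ignored when `select_fun` is
#'   given).
#' @param hyper an [svm_grid()] hyperparameter configuration.
#' @param scheme `"fivefold"` or `"loocv"`.
#' @param seed integer seed controlling fold assignment.
#' @param stratify stratify folds by label (default TRUE; ignored for LOOCV).
#' @param select_fun optional `function(matrix, labels) -> descriptor
#'   names` re-run inside every training fold, nesting feature selection
#'   in the cross-validation so the accuracy estimate carries no
#'   selection bias.
#' @return a `cv_result` list: `scheme`, `per_isoform` (data.frame with
#'   POE/NEE and the four metrics), `per_isoform_accuracy`,
#'   `average_accuracy`, `overall_accuracy`, `folds`, `seed`, `predictions`.
#' @export
cross_validate <- function(matrix, labels, selected = colnames(matrix),
                           hyper = svm_grid(),
                           scheme = c("fivefold", "loocv"), seed = 1L,
                           stratify = TRUE, select_fun = NULL) {
  scheme <- match.arg(scheme)
  ids <- rownames(matrix)
  labels <- labels[ids]
  check_labels(labels)
  k <- if (scheme == "loocv") length(ids) else 5L
  folds <- if (scheme == "loocv") {
    stats::setNames(seq_along(ids), ids)
  } else {
    kfold_split(ids, k, seed = seed,
                stratify_labels = if (stratify) labels else NULL)
  }
  pred <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (f in sort(unique(folds))) {
    test_ids <- ids[folds == f]
    train_ids <- ids[folds != f]
    fold_selected <- if (is.null(select_fun)) selected else {
      select_fun(matrix[train_ids, , drop = FALSE], labels[train_ids])
    }
    suite <- train_suite(matrix[train_ids, , drop = FALSE], labels[train_ids],
                         selected = fold_selected, hyper = hyper,
                         calibrate = FALSE, seed = seed)
    pred[test_ids] <- predict_single_label(suite, matrix[test_ids, , drop = FALSE])
  }
  summarize_cv(labels, pred, scheme, folds, seed)
}

# pool out-of-fold single-label predictions into a cv_result
summarize_cv <- function(truth, pred, scheme, folds, seed) {
  isoforms <- intersect(CYP_ISOFORMS, unique(truth))
  per <- lapply(isoforms, function(iso) {
    tp <- sum(truth == iso & pred == iso)
    fn <- sum(truth == iso & pred != iso)
    fp <- sum(truth != iso & pred == iso)
    tn <- sum(truth != iso & pred != iso)
    m <- compute_metrics(confusion_counts(tp, tn, fp, fn))
    data.frame(isoform = iso, POE = tp + fn, NEE = tn + fp,
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, mcc = m$mcc)
  })
  per <- do.call(rbind, per)
  acc <- stats::setNames(per$sensitivity, per$isoform) # percent of each
  # isoform's substrates recovered by the single-label call
  structure(list(
    scheme = scheme,
    per_isoform = per,
    per_isoform_accuracy = acc,
    average_accuracy = average_accuracy(acc),
    overall_accuracy = overall_accuracy(sum(truth == pred), length(truth)),
    folds = folds,
    seed = seed,
    predictions = pred
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (seed %d)\n", x$scheme, x$seed))
  print(x$per_isoform, row.names = FALSE)
  cat(sprintf("Average accuracy: %.2f\nOverall accuracy: %.2f\n",
              x$average_accuracy, x$overall_accuracy))
  invisible(x)
}

#' Render a cv_result as a plain-text table
#'
#' @param x a `cv_result`.
#' @return character vector of table lines.
#' @export
format_cv_table <- function(x) {
  header <- sprintf("%-8s %5s %5s %11s %11s %9s %6s",
                    "Isoform", "POE", "NEE", "Sensitivity", "Specificity",
                    "Accuracy", "MCC")
  rows <- sprintf("%-8s %5d %5d %11.2f %11.2f %9.2f %6.2f",
                  x$per_isoform$isoform, x$per_isoform$POE, x$per_isoform$NEE,
                  x$per_isoform$sensitivity, x$per_isoform$specificity,
                  x$per_isoform$accuracy, x$per_isoform$mcc)
  c(header, rows,
    sprintf("Average accuracy: %.2f", x$average_accuracy),
    sprintf("Overall accuracy: %.2f", x$overall_accuracy))
}

#' Multi-label evaluation against (possibly multi-label) truth
#'
#' For each isoform, accuracy is the percentage of its true substrates
#' whose predicted multi-label set contains that isoform; the unweighted
#' mean over isoforms with at least one substrate is reported alongside.
#'
#' @param suite a fitted [train_suite()] model suite with calibrated
#'   thresholds.
#' @param matrix descriptor matrix for the evaluation molecules.
#' @param true_label_sets named list mapping molecule id to a character
#'   vector of true isoforms.
#' @return list with `per_isoform` (percent, NA for isoforms with no
#'   substrates) and `average`.
#' @export
evaluate_multilabel <- function(suite, matrix, true_label_sets) {
  ids <- rownames(matrix)
  if (is.null(ids) || !all(ids %in% names(true_label_sets))) {
    stop("every matrix row needs an entry in true_label_sets", call. = FALSE)
  }
  pred <- predict_multi_label(suite, matrix)
  per <- stats::setNames(rep(NA_real_, length(suite$isoforms)), suite$isoforms)
  for (iso in suite$isoforms) {
    subs <- ids[vapply(true_label_sets[ids], function(s) iso %in% s, logical(1))]
    if (length(subs) == 0) next
    hit <- vapply(subs, function(id) iso %in% pred[[id]], logical(1))
    per[iso] <- round_half_up(100 * mean(hit), 2)
  }
  list(per_isoform = per,
       average = round_half_up(mean(per, na.rm = TRUE), 2))
}
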