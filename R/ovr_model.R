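# One-vs-rest SVM suite: per-isoform binary classifiers over the selected
# descriptors, kernel/hyperparameter grid search by cross-validated MCC,
# MCC-optimal decision-threshold calibration, and the single-label
# (argmax) and multi-label (threshold) prediction rules.

#' SVM hyperparameter grid
#'
#' The grid searched per isoform during [train_suite()]: every combination
#' of kernel and kernel-specific parameters. The best combination is the
#' one maximizing mean internal-CV MCC (ties: first in grid order).
#'
#' @param kernels subset of `c("linear", "polynomial", "radial")`.
#' @param cost soft-margin C values.
#' @param gamma RBF kernel widths.
#' @param degree polynomial degrees.
#' @param cv_folds internal CV folds used for both grid search and
#'   threshold calibration.
#' @return an `svm_grid` object (list of parameter combinations).
#' @export
svm_grid <- function(kernels = c("linear", "polynomial", "radial"),
                     cost = c(0.1, 1, 10, 100),
                     gamma = c(0.001, 0.01, 0.1, 1),
                     degree = c(2, 3),
                     cv_folds = 5L) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  grid <- list()
  for (k in kernels) {
    combos <- switch(k,
      linear = expand.grid(cost = cost),
      polynomial = expand.grid(cost = cost, degree = degree),
      radial = expand.grid(cost = cost, gamma = gamma))
    for (i in seq_len(nrow(combos))) {
      grid[[length(grid) + 1L]] <- c(list(kernel = k), as.list(combos[i, , drop = FALSE]))
    }
  }
  structure(list(grid = grid, cv_folds = as.integer(cv_folds)),
            class = "svm_grid")
}

# fit one binary SVM; y logical (TRUE = positive). Decision scores are
# oriented so positives score high, whatever libsvm's internal class order.
fit_binary_svm <- function(x, y, par) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  args <- list(x = x, y = yf, kernel = par$kernel, cost = par$cost,
               scale = FALSE, probability = FALSE)
  if (!is.null(par$gamma)) args$gamma <- par$gamma
  if (!is.null(par$degree)) args$degree <- par$degree
  fit <- do.call(e1071::svm, args)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  flip <- mean(dv[y]) < mean(dv[!y])
  list(fit = fit, sign = if (isTRUE(flip)) -1 else 1, par = par)
}

binary_scores <- function(model, x) {
  if (anyNA(x)) stop("internal: NA reached the SVM decision function", call. = FALSE)
  dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  model$sign * unname(dv)
}

# impute test-set missings with training means and z-scale both with
# training statistics
impute_scale <- function(train, test = NULL) {
  impute <- colMeans(train, na.rm = TRUE)
  impute[is.nan(impute)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- impute[j]
    m
  }
  train <- fill(train)
  center <- colMeans(train)
  scale_ <- apply(train, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  out <- list(train = scale(train, center, scale_),
              impute = impute, center = center, scale = scale_)
  if (!is.null(test)) out$test <- scale(fill(test), center, scale_)
  out
}

#' Calibrate the default decision threshold of a binary model
#'
#' Scans candidate thresholds (midpoints between consecutive distinct
#' sorted scores, plus finite accept-all and reject-all sentinels) under
#' the strict rule "positive iff score > threshold". Among candidates
#' achieving the maximum MCC, the one minimizing |sensitivity -
#' specificity| is returned; remaining ties go to the smaller threshold.
#'
#' @param scores numeric decision scores.
#' @param y logical (or 0/1) true labels; both classes must be present.
#' @return the calibrated threshold (finite).
#' @export
calibrate_threshold <- function(scores, y) {
  y <- as.logical(y)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) == 1) return(u) # degenerate: all scores identical
  candidates <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)])
  npos <- sum(y); nneg <- sum(!y)
  stats_at <- function(t) {
    pred <- scores > t
    tp <- sum(pred & y); fp <- sum(pred & !y)
    c(mcc = mcc_value(tp, nneg - (fp), fp, npos - tp),
      gap = abs(tp / npos - (nneg - fp) / nneg))
  }
  st <- vapply(candidates, stats_at, numeric(2))
  best_mcc <- max(st["mcc", ])
  ok <- which(st["mcc", ] >= best_mcc - 1e-12)
  ok <- ok[order(st["gap", ok], candidates[ok])]
  candidates[ok[1]]
}

#' Train the one-vs-rest model suite
#'
#' Pipeline per isoform: subset to `selected` descriptors, impute missing
#' entries with training means, z-scale (training statistics only), fit a
#' binary SVM (positives = the isoform's substrates, negatives = all other
#' molecules) with kernel/hyperparameters chosen by internal stratified CV
#' maximizing mean MCC, then calibrate the default threshold on
#' out-of-fold decision scores. Isoforms with fewer than two positives are
#' skipped with a warning.
#'
#' @param matrix descriptor matrix (rows named by molecule id, NA =
#'   missing).
#' @param labels named character vector, exactly one isoform per molecule.
#' @param selected descriptor names to model on (default: all columns).
#' @param hyper an [svm_grid()].
#' @param calibrate calibrate per-isoform thresholds (default TRUE); when
#'   FALSE thresholds are NA and only single-label prediction is valid.
#' @param seed seed for the internal CV splits.
#' @return a `model_suite`: `isoforms`, `models` (per-isoform fit, sign,
#'   kernel parameters, threshold, n_positive/n_negative), `scaler`,
#'   `imputation_values`, `selected_descriptors`.
#' @export
train_suite <- function(matrix, labels, selected = colnames(matrix),
                        hyper = svm_grid(), calibrate = TRUE, seed = 1L) {
  ids <- rownames(matrix)
  if (is.null(ids)) stop("matrix must have molecule ids as rownames", call. = FALSE)
  labels <- labels[ids]
  check_labels(labels)
  missing_desc <- setdiff(selected, colnames(matrix))
  if (length(missing_desc) > 0) {
    stop("selected descriptors absent from matrix: ",
         paste(missing_desc, collapse = ", "), call. = FALSE)
  }
  m <- matrix[, selected, drop = FALSE]
  if (any(colSums(!is.na(m)) == 0)) {
    stop("descriptor column with no observed values", call. = FALSE)
  }
  impute <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- impute[j]
  center <- colMeans(m)
  scale_ <- apply(m, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  z <- scale(m, center = center, scale = scale_)
  isoforms <- intersect(CYP_ISOFORMS, unique(labels))
  absent <- setdiff(CYP_ISOFORMS, isoforms)
  if (length(absent) > 0) {
    message("no substrates for isoform(s): ", paste(absent, collapse = ", "),
            "; no model fitted")
  }
  models <- list()
  for (iso in isoforms) {
    y <- labels == iso
    if (sum(y) < 2) {
      warning(sprintf("isoform %s has < 2 positives; model skipped", iso),
              call. = FALSE)
      next
    }
    fold <- kfold_split(ids, hyper$cv_folds, seed = seed,
                        stratify_labels = ifelse(y, "pos", "neg"))
    # grid search: mean out-of-fold MCC at the natural zero threshold
    grid_mcc <- vapply(hyper$grid, function(par) {
      oof <- oof_scores(z, y, fold, par)
      pred <- oof > 0
      mcc_value(sum(pred & y), sum(!pred & !y), sum(pred & !y), sum(!pred & y))
    }, numeric(1))
    par <- hyper$grid[[which.max(grid_mcc)]]
    threshold <- NA_real_
    if (calibrate) {
      oof <- oof_scores(z, y, fold, par)
      threshold <- calibrate_threshold(oof, y)
    }
    final <- fit_binary_svm(z, y, par)
    models[[iso]] <- list(isoform = iso, fit = final$fit, sign = final$sign,
                          par = par, threshold = threshold,
                          n_positive = sum(y), n_negative = sum(!y))
  }
  if (length(models) == 0) stop("no isoform had enough positives", call. = FALSE)
  structure(list(isoforms = names(models), models = models,
                 scaler = list(center = center, scale = scale_),
                 imputation_values = impute,
                 selected_descriptors = selected,
                 seed = seed),
            class = "model_suite")
}

# out-of-fold decision scores for one binary problem
oof_scores <- function(z, y, fold, par) {
  oof <- rep(NA_real_, length(y))
  for (f in unique(fold)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    m <- fit_binary_svm(z[tr, , drop = FALSE], y[tr], par)
    oof[!tr] <- binary_scores(m, z[!tr, , drop = FALSE])
  }
  oof[is.na(oof)] <- 0
  oof
}

#' @export
print.model_suite <- function(x, ...) {
  cat(sprintf("one-vs-rest CYP model suite: %d isoforms, %d descriptors\n",
              length(x$models), length(x$selected_descriptors)))
  for (m in x$models) {
    cat(sprintf("  %-8s kernel=%-10s n+=%d n-=%d threshold=%s\n",
                m$isoform, m$par$kernel, m$n_positive, m$n_negative,
                ifelse(is.na(m$threshold), "uncalibrated",
                       sprintf("%.4f", m$threshold))))
  }
  invisible(x)
}

# coerce a vector or matrix of raw descriptor values into the suite's
# imputed, scaled model space
suite_design <- function(suite, x) {
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list("molecule", names(x)))
  }
  missing_desc <- setdiff(suite$selected_descriptors, colnames(x))
  if (length(missing_desc) > 0) {
    stop("descriptors absent from input: ", paste(missing_desc, collapse = ", "),
         call. = FALSE)
  }
  m <- x[, suite$selected_descriptors, drop = FALSE]
  for (j in seq_len(ncol(m))) {
    m[is.na(m[, j]), j] <- suite$imputation_values[j]
  }
  scale(m, center = suite$scaler$center, scale = suite$scaler$scale)
}

#' Decision scores of every isoform model
#'
#' Applies the suite's imputation and scaler, then each model's decision
#' function ("SVM score"). Higher scores mean stronger evidence that the
#' isoform metabolizes the molecule.
#'
#' @param suite a [train_suite()] result.
#' @param x named descriptor vector, or a matrix with one row per molecule;
#'   missing descriptor values (NA) are imputed with the training means.
#' @return for a vector input, a named numeric vector of scores (one per
#'   isoform); for a matrix, a molecules x isoforms score matrix.
#' @export
score_suite <- function(suite, x) {
  z <- suite_design(suite, x)
  s <- vapply(suite$isoforms, function(iso) {
    binary_scores(suite$models[[iso]], z)
  }, numeric(nrow(z)))
  s <- matrix(s, nrow = nrow(z), dimnames = list(rownames(z), suite$isoforms))
  if (!all(is.finite(s))) stop("non-finite decision score", call. = FALSE)
  if (nrow(s) == 1 && is.null(dim(x))) return(s[1, ])
  s
}

#' Single-label prediction: the highest-scoring isoform
#'
#' The isoform with the highest decision score is the predicted
#' metabolizing isoform; exact ties go to the earlier isoform in the
#' suite's canonical order.
#'
#' @inheritParams score_suite
#' @return character vector of isoform names (length = number of
#'   molecules).
#' @export
predict_single_label <- function(suite, x) {
  s <- score_suite(suite, x)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1, dimnames = list(NULL, names(s)))
  stats::setNames(colnames(s)[apply(s, 1, which.max)], rownames(s))
}

#' Multi-label prediction: every isoform scoring above its threshold
#'
#' An isoform is called for a molecule when the decision score is strictly
#' greater than that model's calibrated default threshold. The set may be
#' empty (no isoform predicted).
#'
#' @inheritParams score_suite
#' @return a named list of character vectors (one set per molecule).
#' @export
predict_multi_label <- function(suite, x) {
  thr <- vapply(suite$models, function(m) m$threshold, numeric(1))
  if (any(is.na(thr))) {
    stop("suite thresholds are uncalibrated; train with calibrate = TRUE",
         call. = FALSE)
  }
  s <- score_suite(suite, x)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1, dimnames = list("molecule", names(s)))
  out <- lapply(seq_len(nrow(s)), function(i) {
    suite$isoforms[s[i, suite$isoforms] > thr[suite$isoforms]]
  })
  names(out) <- rownames(s)
  out
}

#' Tabulate predictions for a set of molecules
#'
#' @param suite a calibrated model suite.
#' @param matrix descriptor matrix with molecule ids as rownames.
#' @param mode `"single"`, `"multi"` or `"both"`.
#' @return data.frame with `id`, one `score_<isoform>` column per model,
#'   and `single_label` / `multi_label` (semicolon-joined, possibly empty,
#'   with `no_isoform_predicted` flag) columns per mode.
#' @export
predict_table <- function(suite, matrix, mode = c("both", "single", "multi")) {
  mode <- match.arg(mode)
  s <- score_suite(suite, matrix)
  out <- data.frame(id = rownames(matrix), stringsAsFactors = FALSE)
  for (iso in suite$isoforms) out[[paste0("score_", iso)]] <- unname(s[, iso])
  if (mode %in% c("both", "single")) {
    out$single_label <- unname(predict_single_label(suite, matrix))
  }
  if (mode %in% c("both", "multi")) {
    ml <- predict_multi_label(suite, matrix)
    out$multi_label <- vapply(ml, paste, character(1), collapse = ";")
    out$no_isoform_predicted <- lengths(ml) == 0
  }
  out
}

#' Persist a model suite as a JSON bundle
#'
#' A single JSON file carrying a format-version field, the selected
#' descriptors, scaler, imputation means and thresholds in the clear, and
#' each fitted classifier as a base64-encoded R serialization.
#'
#' @param suite a `model_suite`.
#' @param path output path (conventionally `.json`).
#' @export
save_suite <- function(suite, path) {
  bundle <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("cypred")),
    isoforms = suite$isoforms,
    selected_descriptors = suite$selected_descriptors,
    scaler = suite$scaler,
    imputation_values = as.list(suite$imputation_values),
    seed = suite$seed,
    models = lapply(suite$models, function(m) {
      list(isoform = m$isoform, sign = m$sign, par = m$par,
           threshold = m$threshold,
           n_positive = m$n_positive, n_negative = m$n_negative,
           classifier_b64 = jsonlite::base64_enc(serialize(m$fit, NULL)))
    })
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model suite bundle
#'
#' @param path bundle path written by [save_suite()].
#' @return a `model_suite`.
#' @export
load_suite <- function(path) {
  bundle <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                     error = function(e) {
                       stop("unreadable model bundle: ", conditionMessage(e),
                            call. = FALSE)
                     })
  if (is.null(bundle$format_version) || bundle$format_version != 1L) {
    stop("unsupported or missing bundle format version", call. = FALSE)
  }
  models <- list()
  for (iso in bundle$isoforms) {
    raw <- bundle$models[[iso]]
    fit <- tryCatch(unserialize(jsonlite::base64_dec(raw$classifier_b64)),
                    error = function(e) {
                      stop("corrupted classifier blob for ", iso, call. = FALSE)
                    })
    if (!inherits(fit, "svm")) stop("corrupted classifier blob for ", iso,
                                    call. = FALSE)
    models[[iso]] <- list(isoform = iso, fit = fit, sign = raw$sign,
                          par = as.list(raw$par),
                          threshold = raw$threshold %||% NA_real_,
                          n_positive = raw$n_positive,
                          n_negative = raw$n_negative)
  }
  structure(list(isoforms = bundle$isoforms, models = models,
                 scaler = list(center = unlist(bundle$scaler$center),
                               scale = unlist(bundle$scaler$scale)),
                 imputation_values = unlist(bundle$imputation_values),
                 selected_descriptors = bundle$selected_descriptors,
                 seed = bundle$seed),
            class = "model_suite")
}
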