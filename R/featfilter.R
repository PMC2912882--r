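# Four-rule descriptor-pruning cascade: missingness, sparsity, pairwise
# Pearson correlation and multicollinearity, applied in that order.

#' Filter-cascade configuration
#'
#' Defaults encode the pruning rules: drop descriptors with more than 5%
#' missing values, with less than 10% non-zero values, with an absolute
#' pairwise Pearson correlation of at least 0.90 to an earlier descriptor,
#' or whose R-squared on the remaining descriptors exceeds 0.95.
#'
#' @param max_missing_frac maximum tolerated missing fraction (strict >).
#' @param min_nonzero_frac minimum non-zero fraction among observed values
#'   (strict <).
#' @param corr_threshold pairwise |Pearson r| cutoff (inclusive >=).
#' @param collinearity_threshold R-squared cutoff (strict >).
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_missing_frac = 0.05, min_nonzero_frac = 0.10,
                          corr_threshold = 0.90, collinearity_threshold = 0.95) {
  cfg <- list(max_missing_frac = max_missing_frac,
              min_nonzero_frac = min_nonzero_frac,
              corr_threshold = corr_threshold,
              collinearity_threshold = collinearity_threshold)
  if (any(unlist(cfg) <= 0 | unlist(cfg) > 1)) {
    stop("all filter thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "filter_config")
}

filter_report_entry <- function(descriptor, stage, statistic, reason = stage) {
  data.frame(descriptor = descriptor, stage = stage,
             statistic = statistic, reason = reason,
             stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(descriptor = character(), stage = character(),
             statistic = numeric(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Drop descriptors with too many missing values
#'
#' A column is removed when its missing fraction is strictly greater than
#' `max_missing_frac`. Surviving missing entries are left in place; they
#' are imputed with training means at model-fitting time, not here.
#'
#' @param matrix numeric matrix, NA marking missing entries.
#' @param max_missing_frac threshold (default 0.05).
#' @return list with `matrix` (surviving columns) and `report` (data.frame
#'   `descriptor, stage, statistic, reason` for dropped columns).
#' @export
filter_missing <- function(matrix, max_missing_frac = 0.05) {
  stopifnot(nrow(matrix) > 0, ncol(matrix) > 0)
  frac <- colMeans(is.na(matrix))
  drop <- frac > max_missing_frac
  report <- if (any(drop)) {
    filter_report_entry(colnames(matrix)[drop], "missing", unname(frac[drop]))
  } else empty_report()
  list(matrix = matrix[, !drop, drop = FALSE], report = report)
}

#' Drop near-constant-zero descriptors
#'
#' A column is removed when its non-zero fraction, computed among observed
#' (non-missing) entries, is strictly less than `min_nonzero_frac`.
#'
#' @param matrix numeric matrix, NA marking missing entries.
#' @param min_nonzero_frac threshold (default 0.10).
#' @return list with `matrix` and `report` as in [filter_missing()].
#' @export
filter_sparse <- function(matrix, min_nonzero_frac = 0.10) {
  stopifnot(nrow(matrix) > 0)
  frac <- apply(matrix, 2, function(x) {
    obs <- x[!is.na(x)]
    if (length(obs) == 0) return(0)
    mean(obs != 0)
  })
  drop <- frac < min_nonzero_frac
  report <- if (any(drop)) {
    filter_report_entry(colnames(matrix)[drop], "sparse", unname(frac[drop]))
  } else empty_report()
  list(matrix = matrix[, !drop, drop = FALSE], report = report)
}

#' Drop pairwise-correlated descriptors
#'
#' Scans columns in order; when |Pearson r| between a surviving earlier
#' column and a later column reaches `corr_threshold`, the later column is
#' dropped (keep-earlier tie-break). Correlations use pairwise-complete
#' observations. Zero-variance columns cannot carry a defined correlation
#' and are dropped with reason `"zero variance"`.
#'
#' @param matrix numeric matrix, NA marking missing entries.
#' @param corr_threshold inclusive |r| cutoff (default 0.90).
#' @return list with `matrix` and `report`.
#' @export
filter_correlated <- function(matrix, corr_threshold = 0.90) {
  p <- ncol(matrix)
  if (p == 0) return(list(matrix = matrix, report = empty_report()))
  sds <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  const <- is.na(sds) | sds == 0
  report <- if (any(const)) {
    filter_report_entry(colnames(matrix)[const], "correlation",
                        NA_real_, "zero variance")
  } else empty_report()
  keep_names <- colnames(matrix)[!const]
  m <- matrix[, keep_names, drop = FALSE]
  p <- ncol(m)
  if (p > 1) {
    cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    alive <- rep(TRUE, p)
    for (i in seq_len(p - 1)) {
      if (!alive[i]) next
      for (j in seq((i + 1), p)) {
        if (alive[j] && abs(cc[i, j]) >= corr_threshold) {
          alive[j] <- FALSE
          report <- rbind(report, filter_report_entry(
            colnames(m)[j], "correlation", abs(cc[i, j])))
        }
      }
    }
    m <- m[, alive, drop = FALSE]
  }
  list(matrix = m, report = report)
}

# R^2 of column j regressed on the remaining columns (complete cases),
# with a tiny ridge fallback when the normal equations are singular
column_r2 <- function(m, j) {
  y <- m[, j]
  X <- m[, -j, drop = FALSE]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  fit <- tryCatch(stats::lm.fit(cbind(1, X), y), error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(fit$residuals))) {
    return(max(0, 1 - sum(fit$residuals^2) / tss))
  }
  Xc <- cbind(1, X)
  lambda <- 1e-8 * mean(diag(crossprod(Xc)))
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)), crossprod(Xc, y))
  max(0, 1 - sum((y - Xc %*% beta)^2) / tss)
}

#' Drop multicollinear descriptors
#'
#' Iteratively regresses each surviving descriptor on all the others
#' (complete-case rows) and removes the one with the largest R-squared
#' while that maximum exceeds `collinearity_threshold`.
#'
#' @param matrix numeric matrix, NA marking missing entries.
#' @param collinearity_threshold strict R-squared cutoff (default 0.95).
#' @return list with `matrix` and `report` (statistic = R-squared at drop
#'   time).
#' @export
filter_multicollinear <- function(matrix, collinearity_threshold = 0.95) {
  report <- empty_report()
  if (ncol(matrix) < 2) return(list(matrix = matrix, report = report))
  complete <- stats::complete.cases(matrix)
  m <- matrix[complete, , drop = FALSE]
  if (nrow(m) <= ncol(m)) {
    warning("fewer complete rows than descriptors; collinearity fit may be unstable",
            call. = FALSE)
  }
  alive <- colnames(m)
  repeat {
    if (length(alive) < 2) break
    r2 <- vapply(seq_along(alive), function(j) {
      column_r2(m[, alive, drop = FALSE], j)
    }, numeric(1))
    # ties at the maximum (exact linear dependences) drop the latest
    # column, mirroring the correlation filter's keep-earlier rule
    worst <- max(which(r2 >= max(r2) - 1e-12))
    if (r2[worst] <= collinearity_threshold) break
    report <- rbind(report, filter_report_entry(
      alive[worst], "multicollinearity", r2[worst]))
    alive <- alive[-worst]
  }
  list(matrix = matrix[, alive, drop = FALSE], report = report)
}

#' Run the four-rule filter cascade
#'
#' Applies, in order: missingness (> `max_missing_frac` dropped), sparsity
#' (< `min_nonzero_frac` non-zero dropped), pairwise correlation
#' (|r| >= `corr_threshold`, later column dropped) and multicollinearity
#' (R-squared > `collinearity_threshold`). The cascade is idempotent.
#'
#' @param matrix numeric matrix, NA marking missing entries.
#' @param config a [filter_config()].
#' @return list with `matrix`, `report` (all drops with stage and
#'   statistic) and `counts` (columns before/after each stage).
#' @export
run_filter_cascade <- function(matrix, config = filter_config()) {
  stopifnot(nrow(matrix) > 0, ncol(matrix) > 0)
  stages <- list(
    missing = function(m) filter_missing(m, config$max_missing_frac),
    sparse = function(m) filter_sparse(m, config$min_nonzero_frac),
    correlation = function(m) filter_correlated(m, config$corr_threshold),
    multicollinearity = function(m) filter_multicollinear(m, config$collinearity_threshold)
  )
  report <- empty_report()
  counts <- data.frame(stage = names(stages), before = NA_integer_,
                       after = NA_integer_)
  m <- matrix
  for (s in seq_along(stages)) {
    counts$before[s] <- ncol(m)
    out <- stages[[s]](m)
    m <- out$matrix
    report <- rbind(report, out$report)
    counts$after[s] <- ncol(m)
  }
  if (ncol(m) == 0) stop("filter cascade removed every descriptor", call. = FALSE)
  list(matrix = m, report = report, counts = counts)
}

#' Write a filter report to CSV
#'
#' @param report the `report` data.frame from [run_filter_cascade()].
#' @param path output CSV path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
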