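# Independent oracles: exhaustive subset search and brute-force threshold
# scan. Deliberately simple re-derivations kept apart from the package's
# own algorithms.

exhaustive_best <- function(m, labels, k, fitness) {
  combos <- utils::combn(colnames(m), k, simplify = FALSE)
  vals <- vapply(combos, function(cols) fitness(m[, cols, drop = FALSE], labels),
                 numeric(1))
  combos[[which.max(vals)]]
}

brute_force_threshold <- function(scores, y) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  cands <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)])
  best <- NULL
  for (t in cands) {
    pred <- scores > t
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- sum(!pred & y); tn <- sum(!pred & !y)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    gap <- abs(tp / sum(y) - tn / sum(!y))
    if (is.null(best) ||
        mcc > best["mcc"] + 1e-12 ||
        (abs(mcc - best["mcc"]) <= 1e-12 &&
           (gap < best["gap"] - 1e-12 ||
              (abs(gap - best["gap"]) <= 1e-12 && t < best["t"])))) {
      best <- c(mcc = mcc, gap = gap, t = t)
    }
  }
  unname(best["t"])
}
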