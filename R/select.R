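# Wrapper feature selection over a cascade-filtered descriptor matrix:
# a fixed-size genetic algorithm and greedy forward stepwise search.

#' Genetic-algorithm parameters
#'
#' Chromosomes are binary descriptor masks constrained by repair to exactly
#' `target_k` ones. Defaults (population 50, 100 generations, crossover
#' 0.8, per-bit mutation 0.02) are conventional GA settings; the fitness is
#' pluggable and defaults to the mean cross-validated MCC of the
#' one-vs-rest suite (see [make_cv_mcc_fitness()]).
#'
#' @param target_k size of the selected subset.
#' @param population_size number of chromosomes per generation.
#' @param generations number of generations.
#' @param crossover_prob probability of uniform crossover per offspring.
#' @param mutation_prob per-bit swap-mutation probability.
#' @param fitness `function(matrix_subset, labels) -> numeric`, larger is
#'   better; NULL selects the default CV-MCC wrapper fitness.
#' @param seed integer seed; selection is deterministic given the seed.
#' @return a `ga_params` list.
#' @export
ga_params <- function(target_k, population_size = 50L, generations = 100L,
                      crossover_prob = 0.8, mutation_prob = 0.02,
                      fitness = NULL, seed = 1L) {
  stopifnot(target_k >= 1, population_size >= 2, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(target_k = as.integer(target_k),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 fitness = fitness, seed = as.integer(seed)),
            class = "ga_params")
}

#' Default wrapper fitness: mean CV MCC of the one-vs-rest suite
#'
#' Returns a fitness closure that, for a candidate descriptor subset,
#' cross-validates one binary SVM per isoform (positives = that isoform's
#' substrates, decision score > 0 = positive call) and averages the
#' per-isoform MCC across isoforms.
#'
#' @param hyper an [svm_grid()]; keep it small, the fitness is evaluated
#'   many times.
#' @param folds internal CV folds (default 5).
#' @param seed seed for the internal fold split.
#' @return `function(matrix_subset, labels) -> numeric`.
#' @export
make_cv_mcc_fitness <- function(hyper = svm_grid(kernels = "linear", cost = 1),
                                folds = 5L, seed = 1L) {
  force(hyper); force(folds); force(seed)
  function(m, labels) {
    labels <- labels[rownames(m)]
    isoforms <- intersect(CYP_ISOFORMS, unique(labels))
    fold <- kfold_split(rownames(m), folds, seed = seed,
                        stratify_labels = labels)
    # per-fold train-mean imputation and z-scaling (SVM inputs must be
    # complete and comparable in scale)
    prepped <- lapply(sort(unique(fold)), function(f) {
      tr <- fold != f
      impute_scale(m[tr, , drop = FALSE], m[!tr, , drop = FALSE])
    })
    mccs <- vapply(isoforms, function(iso) {
      y <- labels == iso
      if (sum(y) < 2 || sum(!y) < 2) return(NA_real_)
      pred <- rep(NA, nrow(m))
      for (f in sort(unique(fold))) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2) next
        pr <- prepped[[f]]
        fit <- fit_binary_svm(pr$train, y[tr], hyper$grid[[1]])
        pred[!tr] <- binary_scores(fit, pr$test) > 0
      }
      ok <- !is.na(pred)
      mcc_value(sum(y & pred & ok), sum(!y & !pred & ok),
                sum(!y & pred & ok), sum(y & !pred & ok))
    }, numeric(1))
    mean(mccs, na.rm = TRUE)
  }
}

# impose exactly k ones on a logical mask, deterministically under the
# surrounding RNG: drop/add random bits as needed
repair_mask <- function(mask, k) {
  on <- which(mask)
  if (length(on) > k) {
    mask[sample(on, length(on) - k)] <- FALSE
  } else if (length(on) < k) {
    off <- which(!mask)
    mask[sample(off, k - length(on))] <- TRUE
  }
  mask
}

# univariate F-statistic ranking used to seed one GA chromosome
univariate_f <- function(m, labels) {
  apply(m, 2, function(x) {
    ok <- !is.na(x)
    if (length(unique(labels[ok])) < 2 || stats::sd(x[ok]) == 0) return(0)
    stats::anova(stats::lm(x[ok] ~ labels[ok]))[1, "F value"]
  })
}

#' Genetic-algorithm descriptor selection
#'
#' Fixed-size subset search: binary masks with exactly `target_k` ones,
#' tournament selection, uniform crossover and swap mutation (both followed
#' by repair to `target_k`), elitism of the best chromosome, and fitness
#' caching. One chromosome of the initial population is seeded from the
#' univariate F-statistic ranking. Deterministic given `params$seed`.
#'
#' @param matrix cascade-filtered descriptor matrix.
#' @param labels named single-label vector aligned with `rownames(matrix)`.
#' @param params a [ga_params()].
#' @return character vector of selected descriptor names, in column order.
#' @export
ga_select <- function(matrix, labels, params) {
  p <- ncol(matrix)
  k <- params$target_k
  if (k >= p) {
    if (k > p) warning("target_k exceeds available descriptors; returning all",
                       call. = FALSE)
    return(colnames(matrix))
  }
  fitness <- params$fitness %||% make_cv_mcc_fitness(seed = params$seed)
  labels <- labels[rownames(matrix)]
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness(matrix[, mask, drop = FALSE], labels)
    cache[[key]] <- val
    val
  }
  withr::with_seed(params$seed, {
    pop <- replicate(params$population_size,
                     repair_mask(rep(FALSE, p), k), simplify = FALSE)
    f_rank <- order(univariate_f(matrix, labels), decreasing = TRUE)
    seeded <- rep(FALSE, p); seeded[f_rank[seq_len(k)]] <- TRUE
    pop[[1]] <- seeded
    fit <- vapply(pop, eval_mask, numeric(1))
    for (gen in seq_len(params$generations)) {
      best <- which.max(fit)
      next_pop <- list(pop[[best]])
      while (length(next_pop) < params$population_size) {
        pick <- function() {
          cand <- sample(params$population_size, 2)
          pop[[cand[which.max(fit[cand])]]]
        }
        child <- pick()
        if (stats::runif(1) < params$crossover_prob) {
          other <- pick()
          take <- stats::runif(p) < 0.5
          child[take] <- other[take]
        }
        flip <- stats::runif(p) < params$mutation_prob
        child[flip] <- !child[flip]
        next_pop[[length(next_pop) + 1L]] <- repair_mask(child, k)
      }
      pop <- next_pop
      fit <- vapply(pop, eval_mask, numeric(1))
    }
    best <- pop[[which.max(fit)]]
  })
  colnames(matrix)[best]
}

#' Greedy forward stepwise descriptor selection
#'
#' Starts from the empty set and adds, at each step, the descriptor whose
#' addition maximizes the fitness (ties broken by column order), stopping
#' at `target_k` descriptors or as soon as no addition improves the
#' current fitness.
#'
#' @param matrix cascade-filtered descriptor matrix.
#' @param labels named single-label vector.
#' @param target_k maximum subset size.
#' @param fitness `function(matrix_subset, labels) -> numeric`; NULL for
#'   the default CV-MCC wrapper fitness.
#' @param seed seed for the default fitness's internal folds.
#' @return character vector of selected descriptor names, in selection
#'   order.
#' @export
greedy_stepwise_select <- function(matrix, labels, target_k, fitness = NULL,
                                   seed = 1L) {
  p <- ncol(matrix)
  if (target_k >= p) {
    if (target_k > p) warning("target_k exceeds available descriptors; returning all",
                              call. = FALSE)
    return(colnames(matrix))
  }
  fitness <- fitness %||% make_cv_mcc_fitness(seed = seed)
  labels <- labels[rownames(matrix)]
  chosen <- character(0)
  # empty-model baseline where the fitness supports zero columns;
  # otherwise the first addition is unconditional
  current <- tryCatch(fitness(matrix[, character(0), drop = FALSE], labels),
                      error = function(e) -Inf)
  while (length(chosen) < target_k) {
    remaining <- setdiff(colnames(matrix), chosen)
    vals <- vapply(remaining, function(nm) {
      fitness(matrix[, c(chosen, nm), drop = FALSE], labels)
    }, numeric(1))
    best <- which.max(vals) # first maximum = column-order tie-break
    if (vals[best] <= current) {
      if (length(chosen) == 0) {
        warning("no descriptor improves over the empty model", call. = FALSE)
      } else {
        warning(sprintf("stopping at %d of %d descriptors: no further improvement",
                        length(chosen), target_k), call. = FALSE)
      }
      break
    }
    current <- vals[best]
    chosen <- c(chosen, remaining[best])
  }
  chosen
}

#' Write a selected-descriptor list to a text file
#'
#' One descriptor name per line; the format consumed by the model module.
#'
#' @param selected character vector of descriptor names.
#' @param path output path.
#' @export
write_selected <- function(selected, path) {
  writeLines(selected, path)
  invisible(path)
}

#' Read a selected-descriptor list
#'
#' @param path text file with one descriptor name per line.
#' @return character vector.
#' @export
read_selected <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
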