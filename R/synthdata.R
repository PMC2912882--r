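# Synthetic labeled descriptor tables with planted structure: class-wise
# informative Gaussian columns, pure noise, redundant (linear-combination)
# columns, sparse columns, high-missing columns and uniform missingness.
# The ground-truth manifest makes feature-selection recovery assertable.

#' Specification of a synthetic descriptor table
#'
#' Defaults emulate the structure of the curated single-label substrate
#' dataset: five isoform classes of 111/47/29/20/19 molecules, a handful
#' of genuinely class-informative descriptors per isoform, many
#' uninformative descriptors, plus columns engineered to trip each rule of
#' the filter cascade.
#'
#' @param class_sizes named integer vector, molecules per isoform.
#' @param n_informative_per_class informative descriptors per class. The
#'   per-column shift is `class_separation / sqrt(n_informative_per_class)`
#'   so that the Euclidean distance between the class mean and the
#'   background in the class's informative subspace equals
#'   `class_separation`; splitting the shift also keeps same-class
#'   informative columns below the pairwise-correlation filter threshold.
#' @param n_noise class-independent standard-normal descriptors.
#' @param n_redundant linear combinations `a*informative + b` (exact by
#'   default, see `jitter_sd`) that the correlation filter must remove.
#' @param n_sparse columns with ~5% non-zero entries (below the 10% rule).
#' @param n_highmissing columns with ~10% missing entries (above the 5%
#'   rule).
#' @param class_separation distance between a class's mean and the
#'   background across that class's informative columns, in units of the
#'   within-class SD (1).
#' @param missing_frac uniform missingness injected into informative and
#'   noise columns.
#' @param multilabel_frac fraction of molecules given a second isoform
#'   label (their informative columns for that isoform are shifted to its
#'   class mean, emulating genuinely dual-substrate molecules).
#' @param jitter_sd SD of noise added to redundant columns (0 = exact
#'   linear dependence).
#' @param seed integer seed.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(class_sizes = c(CYP3A4 = 111L, CYP2D6 = 47L,
                                       CYP1A2 = 29L, CYP2C9 = 20L,
                                       CYP2C19 = 19L),
                       n_informative_per_class = 2L, n_noise = 50L,
                       n_redundant = 5L, n_sparse = 3L, n_highmissing = 3L,
                       class_separation = 6, missing_frac = 0.01,
                       multilabel_frac = 0, jitter_sd = 0, seed = 1L) {
  spec <- list(class_sizes = class_sizes,
               n_informative_per_class = as.integer(n_informative_per_class),
               n_noise = as.integer(n_noise),
               n_redundant = as.integer(n_redundant),
               n_sparse = as.integer(n_sparse),
               n_highmissing = as.integer(n_highmissing),
               class_separation = class_separation,
               missing_frac = missing_frac,
               multilabel_frac = multilabel_frac,
               jitter_sd = jitter_sd,
               seed = as.integer(seed))
  stopifnot(all(class_sizes >= 1), sum(class_sizes) >= 10,
            n_informative_per_class >= 0, n_noise >= 0, n_redundant >= 0,
            n_sparse >= 0, n_highmissing >= 0, class_separation >= 0,
            missing_frac >= 0, missing_frac <= 1,
            multilabel_frac >= 0, multilabel_frac <= 1)
  n_inf <- n_informative_per_class * length(class_sizes)
  if (n_redundant > 0 && n_inf == 0) {
    stop("redundant columns require informative columns to copy", call. = FALSE)
  }
  structure(spec, class = "synth_spec")
}

#' Generate a labeled synthetic descriptor table
#'
#' Informative columns are class-conditional Gaussians (class mean
#' `class_separation`, others 0, SD 1); noise columns are standard normal;
#' redundant columns are affine images of informative ones; sparse and
#' high-missing columns are planted to trip the sparsity and missingness
#' filters. Deterministic given `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return list with `matrix` (molecules x descriptors, NA = missing,
#'   rownames `m001...`), `labels` (named single-label vector),
#'   `label_sets` (named list; differs from `labels` only when
#'   `multilabel_frac > 0`) and `manifest` (which columns are informative /
#'   noise / redundant / sparse / high-missing, and the informative
#'   column's class).
#' @export
generate_table <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  classes <- names(spec$class_sizes)
  n <- sum(spec$class_sizes)
  ids <- sprintf("m%03d", seq_len(n))
  labels <- stats::setNames(rep(classes, spec$class_sizes), ids)
  inf_names <- character(0)
  inf_class <- character(0)
  for (cl in classes) {
    for (j in seq_len(spec$n_informative_per_class)) {
      inf_names <- c(inf_names, sprintf("INF_%s_%d", cl, j))
      inf_class <- c(inf_class, cl)
    }
  }
  noise_names <- sprintf("NOISE_%03d", seq_len(spec$n_noise))
  red_names <- sprintf("RED_%02d", seq_len(spec$n_redundant))
  sparse_names <- sprintf("SPARSE_%02d", seq_len(spec$n_sparse))
  miss_names <- sprintf("HIMISS_%02d", seq_len(spec$n_highmissing))
  label_sets <- as.list(labels)
  withr::with_seed(spec$seed, {
    shift <- if (spec$n_informative_per_class > 0) {
      spec$class_separation / sqrt(spec$n_informative_per_class)
    } else 0
    inf <- matrix(stats::rnorm(n * length(inf_names)), nrow = n,
                  dimnames = list(ids, inf_names))
    for (k in seq_along(inf_names)) {
      inf[labels == inf_class[k], k] <- inf[labels == inf_class[k], k] + shift
    }
    # optional second labels: molecules made to genuinely resemble a
    # second class on that class's informative columns
    if (spec$multilabel_frac > 0 && length(classes) > 1) {
      n_ml <- round(spec$multilabel_frac * n)
      picked <- sample(n, n_ml)
      for (i in picked) {
        other <- sample(setdiff(classes, labels[i]), 1)
        cols <- which(inf_class == other)
        inf[i, cols] <- stats::rnorm(length(cols)) + shift
        label_sets[[i]] <- c(labels[[i]], other)
      }
    }
    noise <- matrix(stats::rnorm(n * spec$n_noise), nrow = n,
                    dimnames = list(ids, noise_names))
    red <- NULL
    if (spec$n_redundant > 0) {
      src <- rep(seq_along(inf_names), length.out = spec$n_redundant)
      red <- vapply(seq_len(spec$n_redundant), function(j) {
        a <- stats::runif(1, 0.5, 3)
        b <- stats::rnorm(1)
        a * inf[, src[j]] + b + stats::rnorm(n, sd = spec$jitter_sd)
      }, numeric(n))
      dimnames(red) <- list(ids, red_names)
    }
    sparse <- NULL
    if (spec$n_sparse > 0) {
      sparse <- vapply(seq_len(spec$n_sparse), function(j) {
        x <- numeric(n)
        nz <- sample(n, max(1, round(0.05 * n)))
        x[nz] <- stats::rnorm(length(nz))
        x
      }, numeric(n))
      dimnames(sparse) <- list(ids, sparse_names)
    }
    himiss <- NULL
    if (spec$n_highmissing > 0) {
      himiss <- matrix(stats::rnorm(n * spec$n_highmissing), nrow = n,
                       dimnames = list(ids, miss_names))
      for (j in seq_len(spec$n_highmissing)) {
        himiss[sample(n, max(ceiling(0.10 * n), floor(0.05 * n) + 1)), j] <- NA
      }
    }
    m <- cbind(inf, noise, red, sparse, himiss)
    if (spec$missing_frac > 0) {
      target <- m[, c(inf_names, noise_names), drop = FALSE]
      mask <- matrix(stats::runif(length(target)) < spec$missing_frac,
                     nrow = nrow(target))
      target[mask] <- NA
      m[, c(inf_names, noise_names)] <- target
    }
  })
  manifest <- list(informative = inf_names,
                   informative_class = stats::setNames(inf_class, inf_names),
                   noise = noise_names, redundant = red_names,
                   sparse = sparse_names, highmissing = miss_names)
  list(matrix = m, labels = labels, label_sets = label_sets,
       manifest = manifest)
}

#' Hand-written fixture molecules
#'
#' Twenty small, well-known drug and solvent structures as SMILES with
#' synthetic pseudo-labels spanning all five isoforms (at least two per
#' isoform). The labels are test fixtures, not curated metabolism
#' annotations. Used to smoke-test the chemistry I/O end to end.
#'
#' @return data.frame with columns `id`, `smiles`, `isoform`.
#' @export
make_fixture_molecules <- function() {
  fixtures <- list(
    c("ethanol",       "CCO",                                        "CYP3A4"),
    c("acetone",       "CC(C)=O",                                    "CYP3A4"),
    c("benzene",       "c1ccccc1",                                   "CYP3A4"),
    c("toluene",       "Cc1ccccc1",                                  "CYP3A4"),
    c("aspirin",       "CC(=O)Oc1ccccc1C(=O)O",                      "CYP2D6"),
    c("paracetamol",   "CC(=O)Nc1ccc(O)cc1",                         "CYP2D6"),
    c("ibuprofen",     "CC(C)Cc1ccc(cc1)C(C)C(=O)O",                 "CYP2D6"),
    c("caffeine",      "Cn1cnc2c1c(=O)n(C)c(=O)n2C",                 "CYP1A2"),
    c("theophylline",  "Cn1c2nc[nH]c2c(=O)n(C)c1=O",                 "CYP1A2"),
    c("nicotine",      "CN1CCCC1c1cccnc1",                           "CYP1A2"),
    c("naproxen",      "COc1ccc2cc(ccc2c1)C(C)C(=O)O",               "CYP2C9"),
    c("warfarin_core", "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",      "CYP2C9"),
    c("phenytoin",     "O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1",          "CYP2C9"),
    c("omeprazole_core", "COc1ccc2[nH]c(SC)nc2c1",                   "CYP2C19"),
    c("diazepam_core", "CN1c2ccccc2C(=NCC1=O)c1ccccc1",              "CYP2C19"),
    c("propranolol",   "CC(C)NCC(O)COc1cccc2ccccc12",                "CYP2C19"),
    c("glycerol",      "OCC(O)CO",                                   "CYP3A4"),
    c("pyridine",      "c1ccncc1",                                   "CYP1A2"),
    c("phenol",        "Oc1ccccc1",                                  "CYP2C9"),
    c("anisole",       "COc1ccccc1",                                 "CYP2C19")
  )
  data.frame(id = vapply(fixtures, `[`, character(1), 1),
             smiles = vapply(fixtures, `[`, character(1), 2),
             isoform = vapply(fixtures, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Emits the descriptor CSV, the `id,isoform` labels CSV and a JSON
#' manifest describing the planted column structure.
#'
#' @param table a [generate_table()] result.
#' @param dir output directory (created if needed).
#' @return invisible named vector of the three file paths.
#' @export
write_synth_dataset <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  desc <- file.path(dir, "descriptors.csv")
  labs <- file.path(dir, "labels.csv")
  man <- file.path(dir, "manifest.json")
  write_descriptor_csv(table$matrix, desc)
  rows <- do.call(rbind, lapply(names(table$label_sets), function(id) {
    data.frame(id = id, isoform = table$label_sets[[id]])
  }))
  utils::write.csv(rows, labs, row.names = FALSE)
  jsonlite::write_json(table$manifest, man, auto_unbox = FALSE)
  invisible(c(descriptors = desc, labels = labs, manifest = man))
}
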