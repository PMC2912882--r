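# Molecule input (SMILES / SDF + label sidecar) and 1D/2D descriptor
# computation on an OpenBabel/ChemmineR backend. The descriptor registry
# fixes the column set, so matrices from different inputs align.

#' Construct a molecule set from SMILES strings
#'
#' Parses each SMILES (unparseable entries are skipped with a message),
#' canonicalizes, and attaches optional labels. Duplicate canonical
#' structures are logged but kept.
#'
#' @param smiles character vector of SMILES.
#' @param ids unique molecule ids (default `mol1..n`).
#' @param labels optional named list mapping id to a character vector of
#'   isoforms.
#' @return a `molecule_set`: ids, canonical SMILES, parsed `SDFset`,
#'   labels.
#' @export
molecules_from_smiles <- function(smiles, ids = NULL, labels = NULL) {
  n <- length(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_len(n))
  if (anyDuplicated(ids)) stop("molecule ids must be unique", call. = FALSE)
  # fast path: parse everything in one call; on failure fall back to
  # per-molecule parsing so one bad SMILES does not sink the batch
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))),
    error = function(e) NULL)
  if (!is.null(sdf) && length(sdf) == n) {
    # batch parse succeeded; unparseable entries surface as atom-less
    # records rather than errors
    ok <- vapply(seq_len(n), function(i) {
      nrow(ChemmineR::atomblock(sdf[[i]])) > 0
    }, logical(1))
    sdf <- if (all(ok)) sdf else sdf[ok]
  } else {
    parsed <- vector("list", n)
    for (i in seq_len(n)) {
      parsed[[i]] <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[i], ids[i]))),
        error = function(e) NULL)
      if (!is.null(parsed[[i]]) &&
          nrow(ChemmineR::atomblock(parsed[[i]][[1]])) == 0) {
        parsed[[i]] <- NULL
      }
    }
    ok <- !vapply(parsed, is.null, logical(1))
    if (!any(ok)) stop("no parseable molecules", call. = FALSE)
    sdf <- Reduce(function(a, b) c(a, b), parsed[ok])
  }
  if (!all(ok)) {
    message(sprintf("skipped %d unparseable molecule(s): %s",
                    sum(!ok), paste(ids[!ok], collapse = ", ")))
  }
  if (!any(ok)) stop("no parseable molecules", call. = FALSE)
  ChemmineR::cid(sdf) <- ids[ok]
  canonical <- tryCatch(ChemmineR::propOB(sdf)$cansmi,
                        error = function(e) smiles[ok])
  dup <- duplicated(canonical)
  if (any(dup)) {
    message("duplicate structures (kept): ",
            paste(ids[ok][dup], collapse = ", "))
  }
  new_molecule_set(ids[ok], canonical, sdf, labels)
}

new_molecule_set <- function(ids, smiles, sdf, labels = NULL) {
  lab <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) lab[[id]] <- character(0)
  if (!is.null(labels)) {
    extra <- setdiff(names(labels), ids)
    if (length(extra) > 0) {
      stop("label id(s) absent from structures: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    for (id in names(labels)) {
      check_labels(labels[[id]])
      lab[[id]] <- unique(labels[[id]])
    }
  }
  structure(list(ids = ids, smiles = smiles, sdf = sdf, labels = lab),
            class = "molecule_set")
}

#' @export
length.molecule_set <- function(x) length(x$ids)

#' @export
print.molecule_set <- function(x, ...) {
  n_lab <- sum(lengths(x$labels) > 0)
  cat(sprintf("molecule set: %d molecules (%d labeled)\n", length(x$ids), n_lab))
  invisible(x)
}

read_labels_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "isoform") %in% names(tab))) {
    stop("labels CSV must have columns id,isoform", call. = FALSE)
  }
  check_labels(tab$isoform)
  split(tab$isoform, tab$id)
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one `SMILES<whitespace>id` per line (the id is
#' optional). SDF ids come from the title line or, with `id_tag`, from a
#' named SD data field. Unparseable entries are skipped with a message;
#' an unreadable file, a label id missing from the structures, or an
#' unknown isoform name is fatal.
#'
#' @param path structure file.
#' @param format `"smiles"` or `"sdf"`.
#' @param labels_path optional CSV with columns `id,isoform`, one row per
#'   id-isoform pair.
#' @param id_tag optional SD data-field name to use as the id (SDF only).
#' @return a `molecule_set`.
#' @export
read_molecules <- function(path, format = c("smiles", "sdf"),
                           labels_path = NULL, id_tag = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  labels <- if (!is.null(labels_path)) read_labels_csv(labels_path)
  if (format == "smiles") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("empty SMILES file", call. = FALSE)
    parts <- strsplit(lines, "[[:space:]]+")
    smiles <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i)
    }, character(1))
    return(molecules_from_smiles(smiles, ids, labels))
  }
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("cannot parse SDF: ",
                                           conditionMessage(e), call. = FALSE))
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid)) {
    message(sprintf("skipped %d malformed SDF record(s) at index: %s",
                    sum(!valid), paste(which(!valid), collapse = ", ")))
  }
  if (!any(valid)) stop("no valid SDF records", call. = FALSE)
  sdf <- sdf[valid]
  ids <- if (!is.null(id_tag)) {
    unname(vapply(seq_along(ChemmineR::cid(sdf)), function(i) {
      ChemmineR::datablock(sdf[[i]])[[id_tag]]
    }, character(1)))
  } else {
    unname(vapply(seq_along(ChemmineR::cid(sdf)), function(i) {
      ChemmineR::header(sdf[[i]])[["Molecule_Name"]]
    }, character(1)))
  }
  if (anyDuplicated(ids)) stop("duplicate molecule ids in SDF", call. = FALSE)
  ChemmineR::cid(sdf) <- ids
  canonical <- tryCatch(ChemmineR::propOB(sdf)$cansmi,
                        error = function(e) rep(NA_character_, length(ids)))
  dup <- duplicated(canonical) & !is.na(canonical)
  if (any(dup)) message("duplicate structures (kept): ",
                        paste(ids[dup], collapse = ", "))
  new_molecule_set(ids, canonical, sdf, labels)
}

#' Single-label vector of a molecule set
#'
#' @param molecules a `molecule_set` whose molecules each carry exactly
#'   one label.
#' @return named character vector id -> isoform.
#' @export
single_labels <- function(molecules) {
  nl <- lengths(molecules$labels)
  if (any(nl != 1)) {
    stop("molecules without exactly one label: ",
         paste(molecules$ids[nl != 1], collapse = ", "), call. = FALSE)
  }
  stats::setNames(vapply(molecules$labels, `[`, character(1), 1), molecules$ids)
}

# ---- descriptor registry -------------------------------------------------

OB_PROPS <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
FCT_GROUPS <- c("RNH2", "R2NH", "R3N", "ROPO3", "ROH", "RCHO", "RCOR",
                "RCOOH", "RCOOR", "ROR", "RCCH", "RCN")
GRAPH_DESCRIPTORS <- c("n_heavy_atoms", "n_bonds", "n_double_bonds",
                       "n_triple_bonds", "n_rotatable_bonds",
                       "n_terminal_atoms", "n_branch_atoms", "mean_degree",
                       "wiener_index", "graph_diameter", "graph_radius",
                       "mean_topo_distance", "zagreb_m1", "zagreb_m2",
                       "randic_chi", "balaban_j", "eccentric_connectivity",
                       "kappa1", "kappa2", "kappa3")

#' Registered descriptor sets
#'
#' Currently one set, `"cmb2d"`: OpenBabel bulk properties (MW, logP,
#' TPSA, molar refractivity, H-bond donor/acceptor counts, ...), fixed
#' per-element heavy-atom counts, ring and functional-group counts, and
#' topological graph indices (Wiener, Zagreb, Randic, Balaban J, Kier
#' kappa shape, eccentric connectivity, ...). 1D/2D only; no conformers
#' or quantum-chemical terms.
#'
#' @return named list; each entry has `names` (the fixed column set).
#' @export
descriptor_sets <- function() {
  list(cmb2d = list(names = c(
    OB_PROPS,
    paste0("n_", ELEMENTS), "n_hetero", "n_halogen",
    "ring_count", "aromatic_ring_count",
    paste0("grp_", FCT_GROUPS),
    GRAPH_DESCRIPTORS)))
}

# topological indices of the heavy-atom graph of one SDF record;
# undefined quantities (disconnected graphs, too-small molecules) are NA
graph_block <- function(sdf1) {
  out <- stats::setNames(rep(NA_real_, length(GRAPH_DESCRIPTORS)),
                         GRAPH_DESCRIPTORS)
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  a <- nrow(ab)
  if (a == 0) return(out)
  # bond-less molecules carry a placeholder zero row; keep only real bonds
  real <- nrow(bb) > 0 && ncol(bb) >= 3
  keep <- if (real) bb[, 1] >= 1 & bb[, 2] >= 1 else logical(0)
  edges <- if (real && any(keep)) cbind(bb[keep, 1], bb[keep, 2]) else matrix(0L, 0, 2)
  order_ <- if (real && any(keep)) bb[keep, 3] else integer(0)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, a - igraph::vcount(g)))
  deg <- igraph::degree(g)
  m <- igraph::ecount(g)
  out["n_heavy_atoms"] <- a
  out["n_bonds"] <- m
  out["n_double_bonds"] <- sum(order_ == 2)
  out["n_triple_bonds"] <- sum(order_ == 3)
  out["n_terminal_atoms"] <- sum(deg == 1)
  out["n_branch_atoms"] <- sum(deg >= 3)
  out["mean_degree"] <- mean(deg)
  if (m > 0) {
    bridge <- rep(FALSE, m)
    bridge[igraph::bridges(g)] <- TRUE
    ends <- igraph::ends(g, igraph::E(g))
    out["n_rotatable_bonds"] <- sum(order_ == 1 & bridge &
                                      deg[ends[, 1]] > 1 & deg[ends[, 2]] > 1)
    out["zagreb_m1"] <- sum(deg^2)
    out["zagreb_m2"] <- sum(deg[ends[, 1]] * deg[ends[, 2]])
    out["randic_chi"] <- sum(1 / sqrt(deg[ends[, 1]] * deg[ends[, 2]]))
  } else {
    out["n_rotatable_bonds"] <- 0
    out["zagreb_m1"] <- 0; out["zagreb_m2"] <- 0; out["randic_chi"] <- 0
  }
  if (igraph::is_connected(g)) {
    d <- igraph::distances(g)
    out["wiener_index"] <- sum(d) / 2
    ecc <- apply(d, 1, max)
    out["graph_diameter"] <- max(ecc)
    out["graph_radius"] <- min(ecc)
    out["mean_topo_distance"] <- if (a > 1) sum(d) / (a * (a - 1)) else 0
    out["eccentric_connectivity"] <- sum(deg * ecc)
    if (m > 0) {
      s <- rowSums(d)
      gamma <- m - a + 1
      ends <- igraph::ends(g, igraph::E(g))
      out["balaban_j"] <- m / (gamma + 1) *
        sum(1 / sqrt(s[ends[, 1]] * s[ends[, 2]]))
    }
    # Kier kappa shape indices from path counts of length 1..3
    p1 <- m
    p2 <- sum(choose(deg, 2))
    tri <- sum(igraph::count_triangles(g)) / 3
    p3 <- if (m > 0) sum((deg[ends[, 1]] - 1) * (deg[ends[, 2]] - 1)) - 3 * tri
          else 0
    if (p1 > 0) out["kappa1"] <- a * (a - 1)^2 / p1^2
    if (p2 > 0) out["kappa2"] <- (a - 1) * (a - 2)^2 / p2^2
    if (p3 > 0) {
      out["kappa3"] <- if (a %% 2 == 1) (a - 1) * (a - 3)^2 / p3^2
                       else (a - 3) * (a - 2)^2 / p3^2
    }
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' Compute the descriptor table of a molecule set
#'
#' One row per molecule, one column per descriptor of the registered set;
#' a descriptor that cannot be computed for a molecule yields NA (the
#' missing marker), never zero. Deterministic, and the column set is fixed
#' by `descriptor_set` regardless of the molecules supplied.
#'
#' @param molecules a `molecule_set` (or data.frame with `id`, `smiles`
#'   columns, converted internally).
#' @param descriptor_set registered set name (default `"cmb2d"`).
#' @return numeric matrix, rows named by molecule id, NA = missing.
#' @export
compute_descriptors <- function(molecules, descriptor_set = "cmb2d") {
  if (is.data.frame(molecules)) {
    molecules <- molecules_from_smiles(molecules$smiles, molecules$id)
  }
  if (length(molecules) == 0) stop("no molecules", call. = FALSE)
  reg <- descriptor_sets()
  if (!descriptor_set %in% names(reg)) {
    stop("unknown descriptor set: ", descriptor_set, call. = FALSE)
  }
  cols <- reg[[descriptor_set]]$names
  n <- length(molecules)
  m <- matrix(NA_real_, nrow = n, ncol = length(cols),
              dimnames = list(molecules$ids, cols))
  for (i in seq_len(n)) {
    sdf1 <- molecules$sdf[i]
    props <- tryCatch(ChemmineR::propOB(sdf1), error = function(e) NULL)
    if (!is.null(props)) {
      for (p in OB_PROPS) {
        v <- suppressWarnings(as.numeric(props[[p]]))
        if (length(v) == 1 && is.finite(v)) m[i, p] <- v
      }
    }
    counts <- tryCatch(ChemmineR::atomcountMA(sdf1, addH = FALSE),
                       error = function(e) NULL)
    if (!is.null(counts)) {
      for (el in ELEMENTS) {
        m[i, paste0("n_", el)] <- if (el %in% colnames(counts)) counts[1, el] else 0
      }
      heavy <- sum(counts[1, ])
      m[i, "n_hetero"] <- heavy - m[i, "n_C"]
      m[i, "n_halogen"] <- sum(m[i, paste0("n_", c("F", "Cl", "Br", "I"))])
    }
    rr <- tryCatch(ChemmineR::rings(molecules$sdf[[i]], upper = 12,
                                    type = "count", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rr)) {
      m[i, "ring_count"] <- rr[["RINGS"]]
      m[i, "aromatic_ring_count"] <- rr[["AROMATIC"]]
    }
    grp <- tryCatch(ChemmineR::groups(sdf1, groups = "fctgroup",
                                      type = "countMA"),
                    error = function(e) NULL)
    if (!is.null(grp)) {
      for (gname in FCT_GROUPS) {
        if (gname %in% colnames(grp)) m[i, paste0("grp_", gname)] <- grp[1, gname]
      }
    }
    gb <- tryCatch(graph_block(molecules$sdf[[i]]), error = function(e) NULL)
    if (!is.null(gb)) m[i, names(gb)] <- gb
    if (all(is.na(m[i, ]))) {
      warning("all descriptors failed for molecule ", molecules$ids[i],
              call. = FALSE)
    }
  }
  m
}

#' Write a descriptor matrix to CSV
#'
#' First column `id`, remaining columns the descriptors; missing values
#' become empty cells. [read_descriptor_csv()] round-trips values and the
#' missing mask exactly.
#'
#' @param matrix numeric matrix with molecule-id rownames.
#' @param path output path.
#' @export
write_descriptor_csv <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a descriptor matrix from CSV
#'
#' @param path CSV with an `id` column; empty cells are missing values.
#' @return numeric matrix, rows named by id, NA = missing.
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = "")
  if (!"id" %in% names(df)) stop("descriptor CSV needs an id column", call. = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate ids in descriptor CSV", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}

#' Read a single-label CSV into a named vector
#'
#' @param path CSV with columns `id,isoform`; every id must occur once.
#' @return named character vector.
#' @export
read_single_labels <- function(path) {
  sets <- read_labels_csv(path)
  nl <- lengths(sets)
  if (any(nl != 1)) {
    stop("ids with multiple labels in single-label context: ",
         paste(names(sets)[nl != 1], collapse = ", "), call. = FALSE)
  }
  stats::setNames(vapply(sets, `[`, character(1), 1), names(sets))
}
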