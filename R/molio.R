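# Molecule parsing, featurisation, 3D embedding, fingerprints, dataset
# loading and scaffold splitting.

# -- atom feature encoding ---------------------------------------------------

.FEAT_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")
.FEAT_HYB <- c("SP", "SP2", "SP3", "SP3D", "SP3D2")
.FEAT_MAX_DEGREE <- 5L
.FEAT_MAX_HS <- 4L

#' Featurizer configuration
#'
#' Controls the per-atom descriptor encoding: one-hot element (common
#' organic elements plus "other"), one-hot heavy-atom degree, formal charge,
#' one-hot hybridisation, aromaticity flag, one-hot total hydrogen count,
#' ring membership and a chirality flag. Hydrogens are implicit: the
#' molecular graph is the heavy-atom graph.
#'
#' @param ecfp_radius Morgan fingerprint radius (default 2).
#' @param ecfp_bits fingerprint length in bits (default 1024).
#' @return a list of class \code{fatetox_featurizer_config}.
#' @export
featurizer_config <- function(ecfp_radius = 2L, ecfp_bits = 1024L) {
  structure(
    list(ecfp_radius = as.integer(ecfp_radius),
         ecfp_bits = as.integer(ecfp_bits)),
    class = "fatetox_featurizer_config"
  )
}

#' Number of per-atom feature dimensions
#' @return integer feature width \code{nf}.
#' @export
n_atom_features <- function() {
  length(.FEAT_ELEMENTS) + 1L +        # element one-hot + other
    (.FEAT_MAX_DEGREE + 1L) + 1L +     # degree one-hot + "more"
    1L +                               # formal charge
    length(.FEAT_HYB) + 1L +           # hybridisation one-hot + other
    1L +                               # aromatic
    (.FEAT_MAX_HS + 1L) +              # total H count one-hot
    1L +                               # in ring
    1L                                 # chiral centre flag
}

one_hot <- function(value, levels) {
  v <- numeric(length(levels) + 1L)
  i <- match(value, levels)
  if (is.na(i)) v[length(v)] <- 1 else v[i] <- 1
  v
}

encode_atom_features <- function(atoms) {
  feats <- vapply(atoms, function(a) {
    c(
      one_hot(a$symbol, .FEAT_ELEMENTS),
      one_hot(min(a$degree, .FEAT_MAX_DEGREE + 1L), 0:.FEAT_MAX_DEGREE),
      a$charge,
      one_hot(a$hyb, .FEAT_HYB),
      as.numeric(a$aromatic),
      one_hot(min(a$n_hs, .FEAT_MAX_HS), 0:.FEAT_MAX_HS)[seq_len(.FEAT_MAX_HS + 1L)],
      as.numeric(a$in_ring),
      as.numeric(!identical(a$chiral, "CHI_UNSPECIFIED"))
    )
  }, numeric(n_atom_features()))
  t(feats)
}

# -- Molecule ----------------------------------------------------------------

new_molecule <- function(record, config) {
  n <- record$n_atoms
  adj <- matrix(0, n, n)
  for (b in record$bonds) {
    i <- b[[1]] + 1L; j <- b[[2]] + 1L
    adj[i, j] <- 1; adj[j, i] <- 1
  }
  ecfp <- integer(config$ecfp_bits)
  ecfp[unlist(record$ecfp_bits) + 1L] <- 1L
  coords3d <- NULL
  if (!is.null(record$coords3d)) {
    coords3d <- do.call(rbind, lapply(record$coords3d, unlist))
  }
  structure(
    list(
      smiles = record$canonical_smiles,
      n_atoms = n,
      atom_features = encode_atom_features(record$atoms),
      coords2d = do.call(rbind, lapply(record$coords2d, unlist)),
      coords3d = coords3d,
      bond_adjacency = adj,
      atom_masses = unlist(record$masses),
      ecfp = ecfp,
      ecfp_radius = config$ecfp_radius,
      scaffold = record$scaffold_smiles,
      raw = record
    ),
    class = "fatetox_molecule"
  )
}

#' @export
print.fatetox_molecule <- function(x, ...) {
  cat("<molecule>", x$smiles, "\n")
  cat("  atoms:", x$n_atoms,
      " bonds:", sum(x$bond_adjacency) / 2,
      " 3D:", if (is.null(x$coords3d)) "none" else "embedded", "\n")
  invisible(x)
}

#' Parse and featurize a molecule from SMILES
#'
#' Builds the heavy-atom molecular graph: per-atom feature vectors, 2D
#' depiction coordinates, bond adjacency, atomic masses and the
#' extended-connectivity fingerprint. 3D coordinates are left unset until
#' \code{\link{embed_3d}} is called.
#'
#' @param smiles a single SMILES string.
#' @param config a \code{\link{featurizer_config}}.
#' @return an object of class \code{fatetox_molecule}.
#' @seealso \code{\link{embed_3d}}, \code{\link{compute_ecfp}}
#' @export
featurize_molecule <- function(smiles, config = featurizer_config()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  rec <- chem_query(smiles, ecfp_radius = config$ecfp_radius,
                    ecfp_bits = config$ecfp_bits)[[1]]
  if (!isTRUE(rec$ok)) {
    stop(errorCondition(
      paste0("SMILES could not be parsed/sanitized: ", smiles),
      class = c("fatetox_parse_error", "fatetox_error")
    ))
  }
  new_molecule(rec, config)
}

#' Generate and attach 3D conformer coordinates
#'
#' Embeds a single conformer (distance-geometry ETKDG, seeded) and relaxes
#' it with the MMFF94 force field; heavy-atom coordinates in Angstrom are
#' attached to the molecule. Deterministic for a fixed seed.
#'
#' @param mol a \code{fatetox_molecule}.
#' @param seed integer random seed for the conformer search.
#' @return the molecule with \code{coords3d} populated.
#' @export
embed_3d <- function(mol, seed = 1L) {
  stopifnot(inherits(mol, "fatetox_molecule"))
  rec <- chem_query(mol$smiles, embed_seed = seed,
                    ecfp_radius = mol$ecfp_radius,
                    ecfp_bits = length(mol$ecfp))[[1]]
  if (isTRUE(rec$embed_failed) || is.null(rec$coords3d)) {
    stop(errorCondition(
      paste0("no 3D conformer could be generated for: ", mol$smiles),
      class = c("fatetox_embed_error", "fatetox_error")
    ))
  }
  mol$coords3d <- do.call(rbind, lapply(rec$coords3d, unlist))
  mol
}

#' Extended-connectivity fingerprint of a molecule
#'
#' @param mol a \code{fatetox_molecule}.
#' @param radius Morgan radius (default 2).
#' @param n_bits fingerprint length (default 1024).
#' @return an integer 0/1 vector of length \code{n_bits}.
#' @export
compute_ecfp <- function(mol, radius = 2L, n_bits = 1024L) {
  stopifnot(inherits(mol, "fatetox_molecule"))
  if (radius == mol$ecfp_radius && n_bits == length(mol$ecfp)) {
    return(mol$ecfp)
  }
  rec <- chem_query(mol$smiles, ecfp_radius = radius, ecfp_bits = n_bits)[[1]]
  ecfp <- integer(n_bits)
  ecfp[unlist(rec$ecfp_bits) + 1L] <- 1L
  ecfp
}

# -- LabeledDataset ----------------------------------------------------------

new_labeled_dataset <- function(molecules, labels, observed, task_names,
                                recovery_log, splits = NULL) {
  labels <- as.matrix(labels)
  observed <- as.matrix(observed)
  stopifnot(
    nrow(labels) == length(molecules),
    all(dim(labels) == dim(observed)),
    ncol(labels) == length(task_names),
    all(labels[observed == 1] %in% c(0, 1))
  )
  structure(
    list(molecules = molecules, labels = labels, observed = observed,
         task_names = task_names, recovery_log = recovery_log,
         splits = splits),
    class = "fatetox_dataset"
  )
}

#' @export
print.fatetox_dataset <- function(x, ...) {
  cat("<labeled dataset>", length(x$molecules), "molecules x",
      length(x$task_names), "task(s):",
      paste(x$task_names, collapse = ", "), "\n")
  cat("  observed label density:",
      round(mean(x$observed), 3), "\n")
  rl <- x$recovery_log
  cat("  recovered:", rl$embedded, "/", rl$n_input,
      "(", rl$dropped, "dropped )\n")
  invisible(x)
}

#' Load a labeled molecular dataset from CSV
#'
#' Parses, featurizes and 3D-embeds every molecule in a CSV table of SMILES
#' and binary task labels. Molecules that cannot be parsed or for which no
#' conformer can be generated are dropped and counted in the recovery log;
#' empty label cells become unobserved entries in the task mask.
#'
#' @param path CSV file path.
#' @param smiles_column name of the SMILES column.
#' @param task_columns character vector of label column names (values 0, 1
#'   or empty).
#' @param seed integer seed for conformer embedding.
#' @param config a \code{\link{featurizer_config}}.
#' @return an object of class \code{fatetox_dataset}.
#' @export
load_dataset <- function(path, smiles_column = "smiles",
                         task_columns = NULL, seed = 1L,
                         config = featurizer_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (is.null(task_columns)) {
    task_columns <- setdiff(names(df), smiles_column)
  }
  missing_cols <- setdiff(c(smiles_column, task_columns), names(df))
  if (length(missing_cols)) {
    stop(errorCondition(
      paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = c("fatetox_missing_column", "fatetox_error")
    ))
  }
  dataset_from_smiles(
    smiles = df[[smiles_column]],
    labels = df[task_columns],
    task_names = task_columns,
    seed = seed, config = config
  )
}

# Shared builder for load_dataset and the fixture generator.
dataset_from_smiles <- function(smiles, labels, task_names, seed = 1L,
                                config = featurizer_config()) {
  labels <- as.data.frame(labels)
  recs <- chem_query(smiles, embed_seed = seed,
                     ecfp_radius = config$ecfp_radius,
                     ecfp_bits = config$ecfp_bits)
  ok_parse <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
  ok_embed <- ok_parse & vapply(
    recs, function(r) !isTRUE(r$embed_failed) && !is.null(r$coords3d),
    logical(1)
  )
  recovery_log <- list(
    n_input = length(smiles),
    parsed = sum(ok_parse),
    embedded = sum(ok_embed),
    dropped = length(smiles) - sum(ok_embed),
    dropped_parse = sum(!ok_parse),
    dropped_embed = sum(ok_parse) - sum(ok_embed),
    dropped_smiles = smiles[!ok_embed]
  )
  if (!any(ok_embed)) {
    stop(errorCondition(
      "no molecule survived parsing and 3D embedding",
      class = c("fatetox_all_dropped", "fatetox_error")
    ))
  }
  molecules <- lapply(recs[ok_embed], new_molecule, config = config)
  lab_chr <- as.matrix(labels[ok_embed, , drop = FALSE])
  observed <- matrix(
    as.numeric(!is.na(lab_chr) & nzchar(trimws(lab_chr))),
    nrow = nrow(lab_chr)
  )
  lab_num <- suppressWarnings(
    matrix(as.numeric(lab_chr), nrow = nrow(lab_chr))
  )
  lab_num[observed == 0] <- 0
  new_labeled_dataset(molecules, lab_num, observed, task_names, recovery_log)
}

# -- scaffold split ----------------------------------------------------------

#' Scaffold split of a dataset
#'
#' Groups molecules by their Bemis-Murcko scaffold SMILES and assigns each
#' scaffold group whole to the train, validation or test set, filling the
#' largest groups into train first (ties broken by scaffold string). No
#' scaffold ever spans two sets, so the test set contains only unseen
#' scaffolds.
#'
#' @param dataset a \code{fatetox_dataset}.
#' @param fractions length-3 non-negative vector (train, val, test) summing
#'   to 1; the train fraction must be positive.
#' @param seed kept for interface stability; the fill is deterministic.
#' @return a list of class \code{fatetox_splits} with integer index vectors
#'   \code{$train}, \code{$val}, \code{$test}.
#' @export
scaffold_split <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(dataset, "fatetox_dataset"),
            length(fractions) == 3, all(fractions >= 0),
            fractions[1] > 0, abs(sum(fractions) - 1) < 1e-8)
  m <- length(dataset$molecules)
  if (m == 0) {
    stop(errorCondition("empty dataset",
                        class = c("fatetox_empty_dataset", "fatetox_error")))
  }
  scaffolds <- vapply(dataset$molecules, function(x) x$scaffold, character(1))
  # acyclic molecules have an empty scaffold; treat each as its own group
  key <- ifelse(nzchar(scaffolds), scaffolds,
                paste0("__acyclic__", seq_len(m)))
  groups <- split(seq_len(m), key)
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  n_train <- round(fractions[1] * m)
  n_val <- round(fractions[2] * m)
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (g in groups) {
    if (length(train) + length(g) <= n_train || length(train) == 0) {
      train <- c(train, g)
    } else if (length(val) + length(g) <= n_val ||
               (length(val) == 0 && fractions[2] > 0)) {
      val <- c(val, g)
    } else {
      test <- c(test, g)
    }
  }
  structure(list(train = sort(train), val = sort(val), test = sort(test)),
            class = "fatetox_splits")
}

#' Write a JSON recovery report
#'
#' @param dataset a \code{fatetox_dataset}.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_recovery_report <- function(dataset, path) {
  jsonlite::write_json(dataset$recovery_log, path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
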