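# Deterministic synthetic dataset generation: drug-like ring scaffolds with
# two substituent slots, labeled by SMARTS-checked substructure rules, so
# every pipeline stage is testable without downloads.

.FIXTURE_TEMPLATES <- c(
  benzene = "c1cc({A})cc({B})c1",
  pyridine = "c1cc({A})cc({B})n1",
  pyrimidine = "c1nc({A})nc({B})c1",
  furan = "c1c({A})cc({B})o1",
  thiophene = "c1c({A})cc({B})s1",
  cyclohexane = "C1CC({A})CC({B})C1",
  piperidine = "C1CC({A})CN({B})C1",
  oxane = "C1CC({A})CC({B})O1",
  naphthalene = "c1cc({A})c2cc({B})ccc2c1",
  pyridine24 = "c1cc({A})nc({B})c1"
)
.FIXTURE_AROMATIC_N <- c("pyridine", "pyrimidine", "pyridine24")

.FIXTURE_BENIGN <- c("", "C", "CC", "CCC", "O", "OC", "N", "CN", "C(C)C",
                     "CCO", "S", "C#N", "COC")

.FIXTURE_RULES <- list(
  HAS_NITRO = list(
    smarts = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
    subs = c("[N+](=O)[O-]", "C[N+](=O)[O-]")
  ),
  HAS_CARBOXYL = list(
    smarts = "[CX3](=O)[OX2H1]",
    subs = c("C(=O)O", "CC(=O)O")
  ),
  HAS_HALOGEN = list(
    smarts = "[F,Cl,Br,I]",
    subs = c("Cl", "Br", "F", "CCl")
  ),
  SCAFFOLD_CLASS = list(
    smarts = "n",   # aromatic nitrogen in the ring system
    subs = character(0)
  )
)

#' Specification for a synthetic rule-labeled dataset
#'
#' @param n_molecules number of distinct molecules (>= 4).
#' @param label_rules one or two of \code{"HAS_NITRO"},
#'   \code{"HAS_CARBOXYL"}, \code{"HAS_HALOGEN"}, \code{"SCAFFOLD_CLASS"}.
#' @param positive_fraction fraction of positives per task, in (0, 1).
#' @param seed integer seed; generation is fully deterministic.
#' @return a \code{fatetox_fixture_spec} list.
#' @export
fixture_spec <- function(n_molecules, label_rules = "HAS_NITRO",
                         positive_fraction = 0.5, seed = 1L) {
  stopifnot(n_molecules >= 4,
            positive_fraction > 0, positive_fraction < 1,
            length(label_rules) %in% 1:2,
            all(label_rules %in% names(.FIXTURE_RULES)))
  if (length(label_rules) == 2 && "SCAFFOLD_CLASS" %in% label_rules) {
    stop("SCAFFOLD_CLASS is only supported as a single task")
  }
  structure(
    list(n_molecules = as.integer(n_molecules), label_rules = label_rules,
         positive_fraction = positive_fraction, seed = as.integer(seed),
         n_tasks = length(label_rules)),
    class = "fatetox_fixture_spec"
  )
}

fixture_assemble <- function(template, sub_a, sub_b) {
  s <- sub("\\(\\{A\\}\\)",
           if (nzchar(sub_a)) paste0("(", sub_a, ")") else "", template)
  sub("\\(\\{B\\}\\)",
      if (nzchar(sub_b)) paste0("(", sub_b, ")") else "", s)
}

#' Generate a deterministic rule-labeled synthetic dataset
#'
#' Molecules are assembled from ring scaffolds and substituents under a
#' seeded RNG; positives for a task carry the rule substructure in one
#' substituent slot (or, for \code{SCAFFOLD_CLASS}, an aromatic
#' N-heterocycle core). Labels are then verified by SMARTS matching, all
#' molecules are guaranteed parsable and 3D-embeddable, and the CSV written
#' for a given spec is byte-identical across runs.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param path optional CSV output path.
#' @param config a \code{\link{featurizer_config}}.
#' @return a \code{fatetox_dataset}.
#' @export
generate_fixture_dataset <- function(spec, path = NULL,
                                     config = featurizer_config()) {
  stopifnot(inherits(spec, "fatetox_fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_molecules
  rules <- .FIXTURE_RULES[spec$label_rules]
  labels <- matrix(0L, n, spec$n_tasks)
  for (t in seq_len(spec$n_tasks)) {
    n_pos <- round(spec$positive_fraction * n)
    if (n_pos < 1 || n_pos > n - 1) {
      stop(errorCondition("positive_fraction infeasible for n_molecules",
                          class = c("fatetox_infeasible_spec",
                                    "fatetox_error")))
    }
    labels[sample(n, n_pos), t] <- 1L
  }

  smiles <- character(n)
  seen <- character(0)
  scaffold_task <- match("SCAFFOLD_CLASS", spec$label_rules)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in 1:200) {
      if (!is.na(scaffold_task)) {
        pool <- if (labels[i, scaffold_task] == 1) .FIXTURE_AROMATIC_N
        else setdiff(names(.FIXTURE_TEMPLATES), .FIXTURE_AROMATIC_N)
        tmpl <- .FIXTURE_TEMPLATES[[sample(pool, 1)]]
      } else {
        tmpl <- .FIXTURE_TEMPLATES[[sample(length(.FIXTURE_TEMPLATES), 1)]]
      }
      # slot t carries task t's substituent; slots not owned by a
      # substructure rule get a benign substituent for variety
      slot_subs <- c(sample(.FIXTURE_BENIGN, 1), sample(.FIXTURE_BENIGN, 1))
      for (t in seq_len(spec$n_tasks)) {
        if (identical(spec$label_rules[t], "SCAFFOLD_CLASS")) next
        slot_subs[t] <- if (labels[i, t] == 1) {
          sample(rules[[t]]$subs, 1)
        } else {
          sample(.FIXTURE_BENIGN, 1)
        }
      }
      s <- fixture_assemble(tmpl, slot_subs[1], slot_subs[2])
      if (!(s %in% seen)) {
        smiles[i] <- s
        seen <- c(seen, s)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(errorCondition(
        "could not assemble enough distinct molecules for this spec",
        class = c("fatetox_infeasible_spec", "fatetox_error")
      ))
    }
  }

  # verify the construction labels against SMARTS ground truth
  counts <- chem_smarts_counts(smiles,
                               vapply(rules, `[[`, character(1), "smarts"))
  truth <- (counts > 0) * 1L
  if (!identical(unname(truth), unname(labels * 1L))) {
    stop("internal error: constructed labels disagree with SMARTS check")
  }

  df <- data.frame(smiles = smiles, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (t in seq_len(spec$n_tasks)) df[[spec$label_rules[t]]] <- labels[, t]
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  ds <- dataset_from_smiles(smiles, df[spec$label_rules],
                            task_names = spec$label_rules,
                            seed = spec$seed, config = config)
  if (ds$recovery_log$dropped > 0) {
    stop("internal error: a curated fixture molecule failed embedding")
  }
  ds
}

#' Panel of named reference molecules used across tests
#'
#' Case-study drugs (diphenhydramine, cetirizine, propranolol, atenolol,
#' Sudan I, pramipexole) plus simple probes (ethane, benzene, toluene,
#' ethanol, hexane, and a few small functionalised molecules).
#'
#' @return named character vector of SMILES.
#' @export
fixture_molecule_panel <- function() {
  c(
    ethane = "CC",
    benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    ethanol = "CCO",
    hexane = "CCCCCC",
    cyclohexane = "C1CCCCC1",
    nitrobenzene = "O=[N+]([O-])c1ccccc1",
    benzoic_acid = "OC(=O)c1ccccc1",
    chlorobenzene = "Clc1ccccc1",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    diphenhydramine = "CN(C)CCOC(c1ccccc1)c1ccccc1",
    cetirizine = "OC(=O)COCCN1CCN(C(c2ccccc2)c2ccc(Cl)cc2)CC1",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    sudan_i = "Oc1ccc2ccccc2c1N=Nc1ccccc1",
    pramipexole = "CCCN[C@H]1CCc2nc(N)sc2C1"
  )
}
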