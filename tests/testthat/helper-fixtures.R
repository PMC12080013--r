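# Shared test fixtures. Molecules are featurized/embedded once per session
# (the chemistry backend caches per SMILES), so helpers can be called freely.

.test_env <- new.env(parent = emptyenv())

# small model configuration used across tests
test_config <- function(ecfp_bits = 64L, n_layers = 1L, eg_layers = 1L) {
  fatetox_config(
    transformer = transformer_config(n_head = 2L, nf = 8L,
                                     n_layers = n_layers),
    egnn = egnn_config(n_layers = eg_layers, k_neighbors = 3L,
                       hidden_dim = 8L),
    ecfp_bits = ecfp_bits
  )
}

# embedded panel molecules, built once
panel_mols <- function() {
  if (is.null(.test_env$panel)) {
    panel <- fixture_molecule_panel()
    .test_env$panel <- lapply(panel, function(s) {
      embed_3d(featurize_molecule(s), seed = 7L)
    })
  }
  .test_env$panel
}

one_mol <- function(name = "aspirin") panel_mols()[[name]]

# a molecule compiled together with small params, for model-level tests
test_model_setup <- function(n_tasks = 1L, smiles = "CC(=O)Oc1ccccc1C(=O)O",
                             seed = 9L, config = test_config()) {
  mol <- embed_3d(featurize_molecule(smiles), seed = 3L)
  mol$ecfp <- compute_ecfp(mol, 2L, config$ecfp_bits)
  params <- init_fatetox_params(n_tasks, config, seed = seed)
  list(mol = mol, params = params, config = config)
}

# random rigid transform (rotation or rotoreflection + translation)
random_rigid_transform <- function(translation_sd = 5) {
  r <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (runif(1) < 0.5) r[, 1] <- -r[, 1]
  list(R = r, t = rnorm(3, sd = translation_sd))
}

apply_rigid <- function(coords, tr) {
  coords %*% tr$R + matrix(tr$t, nrow(coords), 3, byrow = TRUE)
}

# brute-force AUROC oracle: fraction of positive/negative pairs correctly
# ordered, ties counting 1/2
auroc_bruteforce <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

expect_valid_partition <- function(assignment, mol) {
  atoms <- sort(unlist(assignment$fragments))
  expect_identical(atoms, seq_len(mol$n_atoms))
  expect_true(all(lengths(assignment$fragments) > 0))
  for (f in assignment$fragments) {
    comps <- fatetox:::connected_components(mol$bond_adjacency, f)
    expect_length(comps, 1)
  }
}
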