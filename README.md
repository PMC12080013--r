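# fatetox

Multi-organ molecular toxicity prediction with a dual-branch graph neural
network: a fragment-attention transformer combined with E(3)-equivariant
graph convolutions over 3D conformers, trained jointly across toxicity
endpoints with gradient surgery, and interpretable through its attention
coefficients.

## Who this is for

Computational chemists and ML practitioners who want to (a) train binary
toxicity classifiers from SMILES + label CSVs, (b) study multi-task
learning across endpoints whose labels live in different datasets, or
(c) generate toxicophore hypotheses by highlighting the atoms a trained
model attends to. Everything runs on one CPU; no downloads are required —
the package ships a deterministic synthetic-data generator with
substructure-rule labels so the whole pipeline is testable offline.

## The model

A molecule is a heavy-atom graph G = (V, X, A<sup>bond</sup>) with per-atom
features h<sub>i</sub>, 2D depiction coordinates and MMFF-relaxed 3D
conformer coordinates. Two branches encode it:

* **Atom branch** — the molecular graph itself.
* **Fragment branch** — three fragment-level graphs from BRICS cleavage,
  Bemis–Murcko scaffold/side-chain separation, and RDKit functional-group
  matching. Fragment features are sum-pooled
  (h<sub>k</sub> = Σ<sub>i∈F_k</sub> h<sub>i</sub>) and fragment
  coordinates are centres of mass
  (c<sub>k</sub> = Σ m<sub>i</sub>c<sub>i</sub> / Σ m<sub>i</sub>).

Each branch runs a transformer whose per-head attention is a convex
combination

P<sub>weighted</sub> = λ<sub>attn</sub>·softmax(QKᵀ/√d_k) +
λ<sub>dist</sub>·softmax(−D) + λ<sub>adj</sub>·Â,
  λ<sub>attn</sub>+λ<sub>dist</sub>+λ<sub>adj</sub> = 1,

with D the 2D distance matrix and Â the row-normalised bond adjacency,
followed by E(3)-equivariant graph convolutions over the 3D coordinates
(messages on squared distances over a kNN graph; equivariant coordinate
updates). Mean readout gives a branch embedding; the three fragment-view
embeddings are fused by a weighted sum (λ_b, λ_m, λ_f), and a linear head
over concat(e_atom, e_frag, ECFP) yields per-task probabilities. Because
geometry enters only through pairwise distances and coordinates never reach
the readout, predictions are invariant under rotations, translations and
reflections of the conformer — a property the test suite asserts
numerically.

Training minimises a masked multi-task binary cross-entropy (unobserved
cells contribute nothing) with Adam; with ≥ 2 tasks, per-task gradients of
the shared parameters are combined by PCGrad, which projects away
conflicting components (g_i ← g_i − (g_i·g_j/‖g_j‖²) g_j when
g_i·g_j < 0) before summation. Attention from the final transformer layer,
averaged over heads and aggregated per atom, drives the toxicophore
highlighting rule: atoms above the molecule-mean score, plus bonds whose
both endpoints qualify.

## Requirements and installation

R (≥ 4.1) with `jsonlite`, plus a system `python` with the `rdkit` package
on the PATH (set `FATETOX_PYTHON` to point elsewhere). RDKit supplies
parsing, depiction layout, seeded conformer embedding, fingerprints and
substructure matching; the model, training and interpretation are pure R.

```sh
R CMD INSTALL .
# run the test suite
Rscript -e 'testthat::test_dir("tests/testthat", package = "fatetox", load_package = "installed")'
```

## Worked example

```r
library(fatetox)

# 60 synthetic molecules; label = presence of a nitro group
ds <- generate_fixture_dataset(fixture_spec(60, "HAS_NITRO", 0.5, seed = 7))
ds
#> <labeled dataset> 60 molecules x 1 task(s): HAS_NITRO
#>   observed label density: 1
#>   recovered: 60 / 60 ( 0 dropped )

fit <- fatetox(ds, control = train_config(max_epochs = 30, seed = 1))
summary(fit)
#> Dual-branch molecular toxicity model
#>   tasks: HAS_NITRO
#>   molecules: 60 (train 48 / val 6 / test 6)
#>   epochs trained: 30
#>   parameters: 8097
#>   train AUROC: mean 0.967  [HAS_NITRO=0.967]
#>   val   AUROC: mean 1.000  [HAS_NITRO=1.000]
#>   test  AUROC: mean 1.000  [HAS_NITRO=1.000]

predict(fit, c("O=[N+]([O-])c1ccc(Cl)cc1", "CCO",
               "Oc1ccc2ccccc2c1N=Nc1ccccc1"), seed = 1)
#>                            HAS_NITRO
#> O=[N+]([O-])c1ccc(Cl)cc1       0.584
#> CCO                            0.461
#> Oc1ccc2ccccc2c1N=Nc1ccccc1     0.416
```

The summary AUROCs are computed on the scaffold split made at fit time:
1.0 on validation and test means every held-out nitro-bearing molecule
outranks every nitro-free one. The predicted probabilities order the
nitro-substituted aryl chloride above ethanol and Sudan I (neither carries
a nitro group); absolute probabilities stay near 0.5 after 30 epochs on 60
molecules — ranking converges before calibration.

Attention-based highlighting on nitrobenzene:

```r
mol <- embed_3d(featurize_molecule("O=[N+]([O-])c1ccccc1"), seed = 1)
ex <- explain_molecule(mol, fit$params, fit$config)
round(ex$atom_scores, 3)
#> [1] 0.084 0.163 0.085 0.126 0.105 0.110 0.110 0.110 0.105
ex$highlighted_atoms
#> [1] 2 4
```

Atoms 2 and 4 (1-based, canonical SMILES order) are the nitro nitrogen and
the ipso ring carbon — the atoms above the molecule-mean attention score.

Fragmentation and the command-line interface:

```sh
Rscript inst/cli/fatetox.R fragment \
  --smiles "CN(C)CCOC(c1ccccc1)c1ccccc1" --method brics
# {"smiles":"CN(C)CCOC(c1ccccc1)c1ccccc1","method":"BRICS",
#  "fragments":[[0,1,2],[3,4],[5],[6],[7..12],[13..18]]}
```

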