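---
title: "Dual-branch fragment-attention models for molecular toxicity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch fragment-attention models for molecular toxicity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

A single drug candidate can be toxic to several organ systems at once, and
the substructures responsible differ between endpoints: a moiety that drives
hepatotoxicity need not be the one that blocks the hERG channel. `fatetox`
models binary toxicity endpoints jointly from molecular structure, using two
complementary resolutions of the same molecule — individual atoms and
chemically meaningful fragments — and both 2D connectivity and 3D conformer
geometry. The attention weights of the trained model double as a
toxicophore-hypothesis tool: atoms that receive high attention can be
highlighted on the structure.

## Model

### Molecular graphs

A molecule with $N$ heavy atoms is a graph $G = (V, X, A^\text{bond})$.
Each atom $i$ carries a feature vector $h_i \in \mathbb{R}^{nf}$ (one-hot
element, degree, formal charge, hybridisation, aromaticity, hydrogen count,
ring membership, chirality flag; $nf = 32$ with the default featurizer), 2D
depiction coordinates $c_i^\text{2D}$ and 3D conformer coordinates
$c_i^\text{3D}$ in ångström. $A^\text{bond}$ is the binary bond adjacency,
ignoring bond order. Conformers come from seeded distance-geometry
embedding followed by MMFF94 force-field relaxation; molecules for which no
conformer can be generated are dropped and counted in the dataset's recovery
log. Hydrogens are implicit throughout, the dominant convention for
molecular graph learning.

### Fragment-level graphs

Three fragmentation schemes partition the atom set, each capturing a
different chemical notion of "part":

* **BRICS** severs bonds matched by retrosynthetic cleavage rules; the
  connected components that remain are the fragments. Attachment dummy
  atoms are never materialised — membership is defined on the original
  atom indices.
* **Bemis–Murcko** separates the scaffold (ring systems plus linkers) from
  its side chains. The scaffold is one fragment; each connected side-chain
  component is another. The scheme is not usually phrased as a partition,
  so the package fixes one operationally: acyclic molecules, whose scaffold
  is empty, become a single whole-molecule fragment.
* **Functional groups** are matches of the RDKit functional-group
  catalogue (SMARTS patterns whose first atom is an attachment point and is
  excluded). Overlapping matches are merged into one fragment — merging is
  order-independent and keeps the partition property, unlike
  priority-ordering. Unmatched atoms form connected "backbone" fragments.

A partition lifts the molecule to a fragment graph: fragment features are
sum-pooled atom features, $h_k^\text{frag} = \sum_{i \in F_k} h_i$,
fragment coordinates are centres of mass,

$$c_k^\text{frag} = \frac{\sum_{i \in F_k} m_i\, c_i}{\sum_{i \in F_k} m_i},$$

(mass-weighted in both 3D and, analogously, 2D — the 2D case is needed
because the fragment branch's transformer consumes a 2D distance matrix),
and two fragments are adjacent iff a bond crosses between them. Centre of
mass commutes with rigid motions, so the fragment graph inherits the
equivariance story below. Sum-pooling is linear; note one consequence: a
signed descriptor such as formal charge can cancel within a fragment (a
nitro group pools to net charge zero).

### Graph-augmented self-attention

Each branch first refines its 2D graph with a transformer whose per-head
attention mixes three row-stochastic matrices:

$$P_\text{weighted} = \lambda_\text{attn} P_\text{attn}
  + \lambda_\text{dist} D' + \lambda_\text{adj} A', \qquad
  \lambda_\text{attn} + \lambda_\text{dist} + \lambda_\text{adj} = 1,$$

where $P_\text{attn} = \mathrm{softmax}(QK^\top / \sqrt{d_k})$ is learned
attention, $D' = \mathrm{softmax}(-D)$ is the softmax-transformed 2D
distance matrix, and $A'$ is the bond adjacency normalised by row sums. A
convex combination of row-stochastic matrices is row-stochastic, which both
keeps the usual attention semantics and makes the combined matrix directly
interpretable for atom scoring. Heads are applied to the values,
concatenated, linearly transformed, and wrapped in a residual connection
with layer normalisation. The three $\lambda$s default to $1/3$ each; they
are structural priors to be tuned per dataset, not trained.

Two conventions the equations leave open are fixed as follows: rows of
$A^\text{bond}$ without any bond (isolated atoms) fall back to a
self-attention weight of 1 on the diagonal rather than dividing by zero,
and the three component matrices are normalised *before* mixing, with no
re-normalisation afterwards (unnecessary, since the mixture is already
row-stochastic).

### E(3)-equivariant graph convolutions

The transformer output $h^\text{trans}$ enters a stack of equivariant
graph convolutional layers over the 3D coordinates, with messages on a
$k$-nearest-neighbour graph $A^\text{knn}$ built from the initial
conformer (ties in distance broken by atom index; edges symmetrised):

$$m_{ij} = \phi_e\!\left(h_i, h_j, \lVert c_i - c_j \rVert^2,
  a^\text{knn}_{ij}\right), \qquad
  m_i = \sum_{j \ne i} m_{ij}, \qquad
  h_i' = \phi_h(h_i, m_i),$$

$$c_i' = c_i + c_\text{scale} \sum_{j \ne i} (c_i - c_j)\, \phi_x(m_{ij}).$$

$\phi_e$, $\phi_h$, $\phi_x$ are small SiLU networks; $\phi_h$ is residual.
Because features see geometry only through squared distances, $h'$ is
invariant and $c'$ covariant under any rotation, translation or reflection
— the property holds by construction and is asserted numerically in the
test suite (tolerance $10^{-5}$; double precision achieves $\sim 10^{-15}$).

The readout is a mean over node embeddings (configurable to sum):
permutation-invariant and robust to molecule size. Updated coordinates are
carried through the layer stack but never enter the readout or head, which
is what makes the final prediction exactly E(3)-invariant. A structural
consequence worth knowing: the *last* layer's coordinate network
$\phi_x$ receives no gradient (its output influences nothing downstream);
earlier layers' coordinate updates do train, via the next layer's
distances.

### Fusion and prediction head

The fragment branch — one set of shared parameters — encodes each of the
three fragment views; the embeddings are fused by a weighted sum
$\lambda_b e_\text{BRICS} + \lambda_m e_\text{Murcko} + \lambda_f
e_\text{FG}$ with weights on the simplex (default uniform). The weight
naming follows the view each subscript abbreviates: $\lambda_b$ with
BRICS, $\lambda_m$ with Murcko, $\lambda_f$ with functional groups. The
head is a single linear map over
$\mathrm{concat}(e_\text{atom}, e_\text{frag}, \text{ECFP})$ followed by a
per-task sigmoid; the fingerprint shortcut gives the model direct access to
circular substructure indicators (radius 2, 1024 bits by default).

### Multi-task training

Datasets merged by canonical SMILES have block-sparse labels, so the loss
is a masked binary cross-entropy: each task's loss is the mean over its
*observed* cells only, the total is the sum over tasks, and a fully masked
task contributes exactly nothing — including zero gradient, which the test
suite verifies numerically.

With two or more tasks, per-task gradients can conflict. At every Adam
step the per-task gradients of the shared parameters are combined with
PCGrad: tasks are visited in random order, and whenever
$g_i \cdot g_j < 0$ the offending component is removed by projecting onto
the normal plane of $g_j$,

$$g_i^\text{PC} \leftarrow g_i^\text{PC}
  - \frac{g_i^\text{PC} \cdot g_j}{\lVert g_j \rVert^2}\, g_j,$$

then the projected gradients are summed (a mean is available). Zero-norm
gradients are skipped. The per-task head columns receive their own task's
gradient directly — their pairwise dot products are zero by construction,
so surgery there would be a no-op at best. Two caveats are documented
rather than hidden: the non-conflict guarantee
$g_i^\text{PC} \cdot g_j \ge 0$ holds for task *pairs*; with three or more
tasks a later projection can reintroduce a small conflict with an earlier
task (a known property of sequential projection). And with one task the
whole procedure reduces to plain Adam, which the tests check bit-for-bit.

### Interpretation

For a trained model, the combined attention matrices of the final
transformer layer are averaged over heads, and each atom is scored by the
*column* mean — the attention it receives, averaged over source atoms (a
row-mean variant is available; the choice between "received" and "emitted"
attention is genuinely open, and column means match the intuition of an
attention sink). Atoms scoring strictly above the molecule-mean score are
highlighted, and a bond is highlighted when both endpoints are. With
uniform attention no atom exceeds the mean and nothing is highlighted — the
rule deliberately returns "no hypothesis" rather than arbitrary picks.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `lambda_attn/dist/adj` | 1/3 each | attention vs 2D geometry vs topology prior; must sum to 1 |
| `n_head`, `nf` | 4, 16 | heads and model width; `nf` divisible by `n_head` |
| transformer `n_layers` | 1 | 2D refinement depth |
| `k_neighbors` | 5 | kNN graph size over 3D coordinates |
| EGCL `n_layers`, `hidden_dim` | 1, 16 | message-passing depth/width |
| `coord_scale` | 0.1 | magnitude of positional updates (dimensionless multiplier on ångström displacements); small values keep early-training geometry stable |
| `readout` | mean | permutation-invariant aggregation |
| `ecfp_radius`, `ecfp_bits` | 2, 1024 | fingerprint fed to the head |
| `lambda_b/m/f` | 1/3 each | fragment-view fusion weights |
| `learning_rate` | 3e-3 | Adam step size; at desk scale (tens of epochs, hundreds of molecules) the loss plateaus far too slowly below ~1e-3 |
| `batch_size` | 32 | mini-batch of molecules |
| `use_pcgrad` | TRUE | gradient surgery when T >= 2 |

Model sizes are deliberately small: every forward/backward pass is plain R
matrix algebra, and a 20-atom molecule (atom branch plus three fragment
views) costs roughly 10 ms per gradient step on one CPU. The network is
intentionally in the regime where the ECFP shortcut plus the two graph
branches saturate the synthetic benchmarks in minutes.

## The synthetic data generator

Real toxicity benchmarks are downloaded artifacts; the package instead
ships a generator whose labels are *knowable by construction*. Molecules
are assembled from ten di-substitutable ring scaffolds (benzene, pyridine,
pyrimidine, furan, thiophene, cyclohexane, piperidine, oxane, naphthalene —
nine distinct Murcko scaffolds) and a pool of benign substituents, plus
rule substituents (nitro, carboxyl, halogen). A task's label is the
presence of its rule substructure, verified independently by SMARTS
matching after assembly; every generated molecule is parsable and
embeddable, and generation is byte-deterministic given the seed.

What the generator emulates: valid drug-like chemistry, scaffold structure
(so scaffold splits are meaningful), fully observed or block-sparse label
matrices, single- and two-task settings. What it does not emulate: real
structure–activity relationships (labels here are single-substructure
rules, linearly detectable from atom features and fingerprints), label
noise, activity cliffs, class imbalance beyond the chosen positive
fraction, conformational ensembles, or assay artifacts. Passing the
generalisation test therefore shows the *pipeline* is wired correctly —
featurisation, fragmentation, both branches, fusion, training, scaffold
splitting — not that the architecture would reach any particular AUROC on
real endpoints.

The sanity conditions are fixed once: overfitting uses 32 molecules at
positive fraction 0.5; generalisation uses 250 molecules, a scaffold split
with fractions (0.8, 0, 0.2), and the mean test AUROC of three training
seeds. Because scaffold groups are assigned whole, the realised sizes are
approximately 183 train / 67 test rather than exactly 200/50.

## Numerical choices and degenerate inputs

* Layer normalisation uses $\varepsilon = 10^{-5}$; BCE clamps
  probabilities to $[10^{-12}, 1 - 10^{-12}]$.
* Isolated nodes: row-normalised adjacency falls back to an identity row;
  a single-atom molecule flows through every stage ($1 \times 1$ attention
  equals 1, empty EGCL message sum, coordinates unchanged).
* All atoms coincident (degenerate geometry): squared distances are zero,
  softmax of a constant row is uniform — finite everywhere, no NaN.
* kNN ties broken by atom index; the graph is symmetrised (an edge exists
  if either endpoint selected the other).
* AUROC uses mean ranks, so tied scores contribute 1/2 pair weight; a task
  with a single observed class in a split is undefined and is excluded
  from the mean with a warning rather than silently scored.
* Training aborts with a classed error on non-finite loss.
* Scaffold-split fill is deterministic (largest scaffold groups to train
  first, ties by scaffold string); the seed argument exists for interface
  stability.

## Known limitations

* The chemistry backend shells out to RDKit through the system `python`;
  without it, parsing and embedding are unavailable (everything downstream
  of a built `fatetox_molecule` is pure R).
* One conformer per molecule; no ensemble averaging.
* No pretraining or transfer; the package trains from scratch on the data
  given.
* Desk-scale throughput (~100 molecule-gradients/s); real benchmark-scale
  studies would want a compiled backend.
* Attention highlighting is a hypothesis generator, not an attribution
  guarantee; it is not calibrated against perturbation-based explanations.
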