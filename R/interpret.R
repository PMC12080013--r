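# Attention-based atom scoring and toxicophore highlighting.

#' Per-atom attention scores from an attention record
#'
#' Averages the combined attention matrices over heads at the chosen layer
#' and aggregates to one score per atom: by default the column mean, i.e.
#' the attention an atom receives averaged over source atoms (set
#' \code{aggregate = "row"} for attention emitted).
#'
#' @param record a branch attention record: list over layers, each a list of
#'   per-head N x N combined attention matrices (as returned by
#'   \code{\link{forward_molecule}}).
#' @param layer layer index; default the final layer.
#' @param aggregate \code{"column"} (default) or \code{"row"} mean.
#' @return list of class \code{fatetox_atom_scores} with \code{scores}
#'   (length N) and \code{layer}.
#' @export
extract_atom_attention <- function(record, layer = length(record),
                                   aggregate = c("column", "row")) {
  aggregate <- match.arg(aggregate)
  if (length(record) == 0) stop("empty attention record")
  if (layer < 1 || layer > length(record)) {
    stop(errorCondition("layer index out of range",
                        class = c("fatetox_layer_error", "fatetox_error")))
  }
  heads <- record[[layer]]
  avg <- Reduce(`+`, heads) / length(heads)
  scores <- if (aggregate == "column") colMeans(avg) else rowMeans(avg)
  structure(list(scores = as.numeric(scores), layer = layer),
            class = "fatetox_atom_scores")
}

#' Highlight candidate toxicophore atoms and bonds
#'
#' Atoms scoring strictly above the molecule-mean attention score are
#' highlighted; a bond is highlighted when both its endpoints are. Per-atom
#' intensities are min-max normalised scores.
#'
#' @param mol a \code{fatetox_molecule}.
#' @param scores a \code{fatetox_atom_scores} (or numeric vector of length
#'   N).
#' @return list with \code{highlighted_atoms} (1-based indices),
#'   \code{highlighted_bonds} (2-column matrix of atom index pairs) and
#'   \code{intensities} (length N in [0, 1]).
#' @export
highlight <- function(mol, scores) {
  s <- if (inherits(scores, "fatetox_atom_scores")) scores$scores else scores
  if (length(s) != mol$n_atoms) {
    stop(errorCondition("scores length != number of atoms",
                        class = c("fatetox_shape_error", "fatetox_error")))
  }
  rng <- range(s)
  intensities <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else rep(0, length(s))
  atoms <- which(s > mean(s))
  bonds <- which(mol$bond_adjacency > 0, arr.ind = TRUE)
  bonds <- bonds[bonds[, 1] < bonds[, 2], , drop = FALSE]
  keep <- bonds[, 1] %in% atoms & bonds[, 2] %in% atoms
  list(
    highlighted_atoms = atoms,
    highlighted_bonds = unname(bonds[keep, , drop = FALSE]),
    intensities = intensities
  )
}

#' Explain a prediction by attention highlighting
#'
#' Convenience wrapper: runs the forward pass, extracts final-layer
#' atom-branch attention scores, and applies the highlighting rule.
#'
#' @param mol a \code{fatetox_molecule} with 3D coordinates.
#' @param params model parameters.
#' @param config a \code{\link{fatetox_config}}.
#' @param branch which attention record to use (default \code{"atom"}).
#' @return list with \code{smiles}, \code{probabilities},
#'   \code{atom_scores} and the \code{\link{highlight}} annotation.
#' @export
explain_molecule <- function(mol, params, config = fatetox_config(),
                             branch = "atom") {
  fw <- forward_molecule(mol, params, config)
  scores <- extract_atom_attention(fw$attention[[branch]])
  c(list(smiles = mol$smiles, probabilities = fw$probabilities,
         atom_scores = scores$scores),
    highlight(mol, scores))
}
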