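# Three fragmentation schemes (BRICS, Bemis-Murcko, functional groups) and
# the lifting of a molecule to its fragment-level graph (sum-pooled
# features, center-of-mass coordinates, fragment adjacency).

new_fragment_assignment <- function(method, fragments) {
  structure(list(method = method, fragments = fragments),
            class = "fatetox_fragments")
}

#' @export
print.fatetox_fragments <- function(x, ...) {
  cat("<fragmentation:", x$method, ">", length(x$fragments), "fragment(s)\n")
  for (f in x$fragments) cat("  {", paste(f - 1L, collapse = ","), "}\n")
  invisible(x)
}

# connected components of the subgraph induced by `atoms` (1-based indices)
connected_components <- function(adjacency, atoms) {
  comps <- list()
  remaining <- atoms
  while (length(remaining)) {
    frontier <- remaining[1]
    comp <- frontier
    remaining <- remaining[-1]
    while (length(frontier)) {
      nbrs <- unique(unlist(lapply(
        frontier, function(i) which(adjacency[i, ] > 0)
      )))
      nbrs <- intersect(nbrs, remaining)
      comp <- c(comp, nbrs)
      remaining <- setdiff(remaining, nbrs)
      frontier <- nbrs
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

validate_partition <- function(mol, fragments) {
  n <- mol$n_atoms
  all_atoms <- sort(unlist(fragments))
  if (!identical(all_atoms, seq_len(n))) {
    stop(errorCondition("fragments do not partition the atom set",
                        class = c("fatetox_partition_error", "fatetox_error")))
  }
  if (any(lengths(fragments) == 0)) {
    stop(errorCondition("empty fragment",
                        class = c("fatetox_partition_error", "fatetox_error")))
  }
  for (f in fragments) {
    if (length(connected_components(mol$bond_adjacency, f)) != 1) {
      stop(errorCondition("fragment induces a disconnected subgraph",
                          class = c("fatetox_partition_error",
                                    "fatetox_error")))
    }
  }
  invisible(TRUE)
}

#' BRICS fragmentation
#'
#' Severs every bond matched by the BRICS retrosynthetic cleavage rules and
#' returns the resulting connected components as an atom partition (dummy
#' attachment atoms are never introduced; membership is defined on the
#' original atom indices). A molecule with no cleavable bond yields a
#' single whole-molecule fragment.
#'
#' @param mol a \code{fatetox_molecule}.
#' @return a \code{fatetox_fragments} object (1-based atom index sets).
#' @export
fragment_brics <- function(mol) {
  stopifnot(inherits(mol, "fatetox_molecule"))
  adj <- mol$bond_adjacency
  for (b in mol$raw$brics_bonds) {
    i <- b[[1]] + 1L; j <- b[[2]] + 1L
    adj[i, j] <- 0; adj[j, i] <- 0
  }
  frags <- connected_components(adj, seq_len(mol$n_atoms))
  new_fragment_assignment("BRICS", frags)
}

#' Bemis-Murcko scaffold fragmentation
#'
#' The Murcko scaffold (ring systems plus linkers) forms one fragment; each
#' remaining connected side-chain component forms an additional fragment.
#' Acyclic molecules, whose scaffold is empty, yield one whole-molecule
#' fragment.
#'
#' @inheritParams fragment_brics
#' @return a \code{fatetox_fragments} object.
#' @export
fragment_murcko <- function(mol) {
  stopifnot(inherits(mol, "fatetox_molecule"))
  scaffold <- unlist(mol$raw$murcko_atoms) + 1L
  n <- mol$n_atoms
  if (length(scaffold) == 0) {
    frags <- connected_components(mol$bond_adjacency, seq_len(n))
  } else {
    side <- setdiff(seq_len(n), scaffold)
    frags <- c(list(sort(scaffold)),
               connected_components(mol$bond_adjacency, side))
  }
  new_fragment_assignment("MURCKO", frags)
}

#' Functional-group fragmentation
#'
#' Matches the RDKit functional-group catalogue (SMARTS patterns; the
#' attachment atom of each pattern is not part of the group). Overlapping
#' matches are merged into single fragments; atoms matched by no pattern
#' are grouped into connected backbone fragments.
#'
#' @inheritParams fragment_brics
#' @return a \code{fatetox_fragments} object.
#' @export
fragment_functional_groups <- function(mol) {
  stopifnot(inherits(mol, "fatetox_molecule"))
  n <- mol$n_atoms
  matches <- lapply(mol$raw$fg_matches, function(m) unlist(m) + 1L)
  matches <- Filter(length, matches)
  if (length(matches) == 0) {
    frags <- connected_components(mol$bond_adjacency, seq_len(n))
    return(new_fragment_assignment("FUNCTIONAL_GROUP", frags))
  }
  # merge matches that share atoms (union-find over match ids)
  parent <- seq_along(matches)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  owner <- integer(n) # 0 = unmatched
  for (k in seq_along(matches)) {
    for (a in matches[[k]]) {
      if (owner[a] == 0) {
        owner[a] <- k
      } else {
        ri <- find(owner[a]); rk <- find(k)
        if (ri != rk) parent[rk] <- ri
      }
    }
  }
  roots <- vapply(seq_along(matches), find, integer(1))
  merged <- lapply(split(seq_along(matches), roots), function(ids) {
    sort(unique(unlist(matches[ids])))
  })
  matched_atoms <- sort(unique(unlist(merged)))
  backbone <- connected_components(mol$bond_adjacency,
                                   setdiff(seq_len(n), matched_atoms))
  frags <- c(unname(merged), backbone)
  new_fragment_assignment("FUNCTIONAL_GROUP", frags)
}

#' Lift a molecule to its fragment-level graph
#'
#' Fragment features are sum-pooled atom features; fragment coordinates are
#' the mass-weighted centers (center of mass in 3D, and analogously for the
#' 2D depiction coordinates); two fragments are adjacent iff some bond
#' crosses between them.
#'
#' @param mol a \code{fatetox_molecule} with 3D coordinates.
#' @param assignment a \code{fatetox_fragments} partition of \code{mol}.
#' @return a list of class \code{fatetox_fragment_graph} with elements
#'   \code{n_frags}, \code{frag_features}, \code{frag_coords3d},
#'   \code{frag_coords2d}, \code{frag_adjacency}, \code{frag_distances2d}.
#' @export
build_fragment_graph <- function(mol, assignment) {
  stopifnot(inherits(mol, "fatetox_molecule"),
            inherits(assignment, "fatetox_fragments"))
  validate_partition(mol, assignment$fragments)
  frags <- assignment$fragments
  k <- length(frags)
  nf <- ncol(mol$atom_features)
  feat <- matrix(0, k, nf)
  c3 <- matrix(0, k, 3)
  c2 <- matrix(0, k, 2)
  for (i in seq_len(k)) {
    f <- frags[[i]]
    feat[i, ] <- colSums(mol$atom_features[f, , drop = FALSE])
    w <- mol$atom_masses[f]
    if (!is.null(mol$coords3d)) {
      c3[i, ] <- colSums(mol$coords3d[f, , drop = FALSE] * w) / sum(w)
    }
    c2[i, ] <- colSums(mol$coords2d[f, , drop = FALSE] * w) / sum(w)
  }
  adj <- matrix(0, k, k)
  atom2frag <- integer(mol$n_atoms)
  for (i in seq_len(k)) atom2frag[frags[[i]]] <- i
  bonded <- which(mol$bond_adjacency > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(bonded))) {
    fi <- atom2frag[bonded[r, 1]]; fj <- atom2frag[bonded[r, 2]]
    if (fi != fj) { adj[fi, fj] <- 1; adj[fj, fi] <- 1 }
  }
  structure(
    list(n_frags = k,
         fragments = frags,
         method = assignment$method,
         frag_features = feat,
         frag_coords3d = if (is.null(mol$coords3d)) NULL else c3,
         frag_coords2d = c2,
         frag_adjacency = adj,
         frag_distances2d = as.matrix(stats::dist(c2))),
    class = "fatetox_fragment_graph"
  )
}

#' All three fragment views of a molecule
#'
#' @param mol a \code{fatetox_molecule} with 3D coordinates.
#' @return named list of \code{fatetox_fragment_graph} objects
#'   (\code{brics}, \code{murcko}, \code{fg}).
#' @export
fragment_views <- function(mol) {
  list(
    brics = build_fragment_graph(mol, fragment_brics(mol)),
    murcko = build_fragment_graph(mol, fragment_murcko(mol)),
    fg = build_fragment_graph(mol, fragment_functional_groups(mol))
  )
}
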