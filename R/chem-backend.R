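# Interface to the bundled RDKit helper script, run through the system
# `python`. All chemistry primitives (parsing, depiction layout, conformer
# embedding, fingerprints, substructure matches) come from here; everything
# downstream is computed in R. Results are cached per session so repeated
# featurisation of the same SMILES does not re-launch the interpreter.

.chem_cache <- new.env(parent = emptyenv())

chem_backend_script <- function() {
  p <- system.file("python", "chem_backend.py", package = "fatetox")
  if (!nzchar(p)) {
    # during development (pkgload) inst/ may not be installed flat
    p <- system.file("inst", "python", "chem_backend.py", package = "fatetox")
  }
  if (!nzchar(p)) stop("chem_backend.py not found in the installed package")
  p
}

chem_python <- function() {
  Sys.getenv("FATETOX_PYTHON", unset = "python")
}

#' Check that the RDKit chemistry backend is available
#'
#' The package delegates molecule parsing, 3D embedding, fingerprints and
#' substructure matching to RDKit through the system \code{python}
#' interpreter (override with the \code{FATETOX_PYTHON} environment
#' variable).
#'
#' @return \code{TRUE} invisibly if the backend responds; otherwise an error.
#' @export
chem_backend_available <- function() {
  out <- tryCatch(
    suppressWarnings(system2(
      chem_python(), c("-c", shQuote("import rdkit")),
      stdout = TRUE, stderr = TRUE
    )),
    error = function(e) "error"
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0 || identical(out, "error")) {
    stop("python with rdkit is required but was not found on the PATH")
  }
  invisible(TRUE)
}

chem_run_backend <- function(smiles, embed_seed = NULL,
                             ecfp_radius = 2L, ecfp_bits = 1024L,
                             fragments = TRUE, smarts = NULL) {
  req <- list(
    smiles = as.list(unname(smiles)),
    ecfp = list(radius = ecfp_radius, n_bits = ecfp_bits),
    fragments = fragments
  )
  if (!is.null(smarts)) req$smarts <- as.list(unname(smarts))
  if (!is.null(embed_seed)) req$embed3d <- list(seed = as.integer(embed_seed))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(req, fin, auto_unbox = TRUE, digits = NA, null = "null")
  res <- suppressWarnings(system2(
    chem_python(), c(chem_backend_script(), fin, fout),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop(
      "chemistry backend failed (is python with rdkit on the PATH?):\n",
      paste(res, collapse = "\n")
    )
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)$molecules
}

# Count SMARTS pattern matches per molecule (uncached; one backend call).
# Returns an integer matrix length(smiles) x length(smarts); NA for
# unparsable molecules.
chem_smarts_counts <- function(smiles, smarts) {
  recs <- chem_run_backend(smiles, fragments = FALSE, smarts = smarts)
  out <- matrix(NA_integer_, length(smiles), length(smarts))
  for (i in seq_along(recs)) {
    if (isTRUE(recs[[i]]$ok)) {
      out[i, ] <- unlist(recs[[i]]$smarts_counts)
    }
  }
  out
}

# Cached batched query. Returns one backend record per SMILES. The base
# record (atoms, bonds, 2D coords, ECFP, fragment primitives) is cached per
# (smiles, ecfp params); 3D coordinates are cached per (smiles, seed) and
# spliced into the returned records as record$coords3d.
chem_query <- function(smiles, embed_seed = NULL,
                       ecfp_radius = 2L, ecfp_bits = 1024L) {
  base_keys <- paste0(smiles, "|r", ecfp_radius, "b", ecfp_bits)
  need_base <- !vapply(base_keys, exists, logical(1), envir = .chem_cache)
  seed_keys <- NULL
  need_3d <- rep(FALSE, length(smiles))
  if (!is.null(embed_seed)) {
    seed_keys <- paste0(smiles, "|seed", embed_seed)
    need_3d <- !vapply(seed_keys, exists, logical(1), envir = .chem_cache)
  }
  todo <- need_base | need_3d
  if (any(todo)) {
    recs <- chem_run_backend(
      smiles[todo],
      embed_seed = if (!is.null(embed_seed)) embed_seed else NULL,
      ecfp_radius = ecfp_radius, ecfp_bits = ecfp_bits
    )
    idx <- which(todo)
    for (k in seq_along(idx)) {
      i <- idx[k]
      rec <- recs[[k]]
      coords3d <- rec$coords3d
      rec$coords3d <- NULL
      base <- rec
      if (identical(rec$error, "embed")) {
        # parse succeeded; only the conformer failed — keep the base record
        base$ok <- TRUE
        base$error <- NULL
      }
      assign(base_keys[i], base, envir = .chem_cache)
      if (!is.null(seed_keys)) {
        val <- if (identical(rec$error, "embed")) "embed_failure" else coords3d
        assign(seed_keys[i], val, envir = .chem_cache)
      }
    }
  }
  out <- lapply(base_keys, get, envir = .chem_cache)
  if (!is.null(seed_keys)) {
    for (i in seq_along(out)) {
      if (!isTRUE(out[[i]]$ok)) next
      v <- get(seed_keys[i], envir = .chem_cache)
      if (identical(v, "embed_failure")) {
        out[[i]]$embed_failed <- TRUE
      } else {
        out[[i]]$coords3d <- v
      }
    }
  }
  out
}
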