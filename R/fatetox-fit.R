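# The user-facing fitting interface: fatetox() returns a classed model
# object with the usual print/summary/coef/predict/plot/residuals/simulate
# methods.

#' Fit a toxicity prediction model
#'
#' Trains the dual-branch architecture (atom-level and fragment-level graph
#' transformer + E(3)-equivariant convolutions, fused fragment views, ECFP
#' head) on a labeled molecular dataset with masked multi-task binary
#' cross-entropy, Adam, and optional PCGrad gradient surgery.
#'
#' @param data a \code{fatetox_dataset} (see \code{\link{load_dataset}} or
#'   \code{\link{generate_fixture_dataset}}), or a CSV path.
#' @param splits a \code{\link{scaffold_split}} result; by default an
#'   80/10/10 scaffold split is created.
#' @param config a \code{\link{fatetox_config}}.
#' @param control a \code{\link{train_config}}.
#' @param ... when \code{data} is a path, passed to
#'   \code{\link{load_dataset}}.
#' @return an object of class \code{fatetox}.
#' @examples
#' \dontrun{
#' ds <- generate_fixture_dataset(fixture_spec(60, "HAS_NITRO", 0.5, seed = 7))
#' fit <- fatetox(ds, control = train_config(max_epochs = 20))
#' summary(fit)
#' predict(fit, "O=[N+]([O-])c1ccc(Cl)cc1")
#' }
#' @export
fatetox <- function(data, splits = NULL, config = fatetox_config(),
                    control = train_config(), ...) {
  if (is.character(data)) data <- load_dataset(data, ...)
  stopifnot(inherits(data, "fatetox_dataset"))
  if (is.null(splits)) {
    splits <- if (!is.null(data$splits)) data$splits
    else scaffold_split(data, c(0.8, 0.1, 0.1), seed = control$seed)
  }
  params0 <- init_fatetox_params(
    n_tasks = ncol(data$labels), config = config,
    nf_in = ncol(data$molecules[[1]]$atom_features), seed = control$seed
  )
  res <- train(params0, data, splits, control, config)
  structure(
    list(params = res$params, config = config, control = control,
         history = res$history, splits = splits, dataset = data,
         task_names = data$task_names, call = match.call()),
    class = "fatetox"
  )
}

#' @export
print.fatetox <- function(x, ...) {
  cat("Dual-branch molecular toxicity model\n")
  cat("  tasks:", paste(x$task_names, collapse = ", "), "\n")
  cat("  molecules:", length(x$dataset$molecules),
      sprintf("(train %d / val %d / test %d)", length(x$splits$train),
              length(x$splits$val), length(x$splits$test)), "\n")
  cat("  epochs trained:", nrow(x$history), "\n")
  cat("  parameters:", length(flatten_params(x$params)), "\n")
  invisible(x)
}

#' @export
summary.fatetox <- function(object, ...) {
  out <- list(model = object, auroc = list())
  for (set in c("train", "val", "test")) {
    idx <- object$splits[[set]]
    if (length(idx) == 0) next
    out$auroc[[set]] <- suppressWarnings(tryCatch(
      evaluate_auroc(object$params, object$dataset, idx, object$config),
      error = function(e) NULL
    ))
  }
  class(out) <- "summary.fatetox"
  out
}

#' @export
print.summary.fatetox <- function(x, ...) {
  print(x$model)
  for (set in names(x$auroc)) {
    a <- x$auroc[[set]]
    if (is.null(a)) next
    cat(sprintf("  %-5s AUROC: mean %.3f  [%s]\n", set, a$mean,
                paste(sprintf("%s=%.3f", names(a$per_task), a$per_task),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.fatetox <- function(object, ...) {
  unlist(object$params)
}

#' Predict toxicity probabilities
#'
#' @param object a fitted \code{fatetox} model.
#' @param newdata a \code{fatetox_dataset}, a list of
#'   \code{fatetox_molecule}s, a character vector of SMILES, or \code{NULL}
#'   (fitted values on the training data).
#' @param seed conformer-embedding seed used when \code{newdata} is SMILES.
#' @param ... unused.
#' @return an M x T matrix of probabilities.
#' @export
predict.fatetox <- function(object, newdata = NULL, seed = 1L, ...) {
  mols <- if (is.null(newdata)) {
    object$dataset$molecules
  } else if (inherits(newdata, "fatetox_dataset")) {
    newdata$molecules
  } else if (is.character(newdata)) {
    lapply(newdata, function(s) embed_3d(featurize_molecule(s), seed = seed))
  } else if (inherits(newdata, "fatetox_molecule")) {
    list(newdata)
  } else {
    newdata
  }
  mds <- lapply(mols, compile_molecule, config = object$config)
  p <- predict_compiled(object$params, mds, object$config)
  colnames(p) <- object$task_names
  rownames(p) <- vapply(mols, `[[`, character(1), "smiles")
  p
}

#' @export
fitted.fatetox <- function(object, ...) {
  predict.fatetox(object)
}

#' @export
residuals.fatetox <- function(object, ...) {
  r <- (object$dataset$labels - fitted.fatetox(object)) *
    object$dataset$observed
  colnames(r) <- object$task_names
  r
}

#' @export
plot.fatetox <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training history", ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' @export
simulate.fatetox <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- fitted.fatetox(object)
  out <- lapply(seq_len(nsim), function(i) {
    matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p),
           dimnames = dimnames(p))
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# -- checkpointing -----------------------------------------------------------

#' Save a fitted model checkpoint
#'
#' Writes the parameter tensors and history as an RDS archive plus a JSON
#' sidecar with the full configuration, sufficient for bit-reproducible
#' reload.
#'
#' @param object a fitted \code{fatetox} model.
#' @param path output path (\code{.rds}); the sidecar gets \code{.json}.
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object[c("params", "config", "control", "history",
                   "task_names")], path)
  jsonlite::write_json(
    list(task_names = object$task_names,
         config = unclass_deep(object$config),
         control = unclass_deep(object$control)),
    paste0(sub("\\.rds$", "", path), ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Load a model checkpoint
#'
#' @param path path written by \code{\link{save_checkpoint}}.
#' @return a list with \code{params}, \code{config}, \code{control},
#'   \code{history} and \code{task_names}; usable with
#'   \code{\link{forward_molecule}} and \code{\link{evaluate_auroc}}.
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
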