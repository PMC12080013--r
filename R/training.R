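# Masked multi-task loss, PCGrad gradient surgery, dataset merging, the
# Adam training loop and AUROC evaluation.

#' Masked binary cross-entropy over a multi-task label matrix
#'
#' Each task's loss is the mean BCE over that task's observed cells; cells
#' with \code{observed == 0} contribute nothing, and a task with no observed
#' cell contributes 0. The total is the sum of per-task losses.
#'
#' @param probabilities M x T matrix of predicted probabilities.
#' @param labels M x T matrix, binary where observed.
#' @param observed M x T 0/1 mask.
#' @return list with \code{total} and \code{per_task}.
#' @export
masked_bce_loss <- function(probabilities, labels, observed) {
  probabilities <- as.matrix(probabilities)
  labels <- as.matrix(labels)
  observed <- as.matrix(observed)
  if (!all(dim(probabilities) == dim(labels)) ||
      !all(dim(labels) == dim(observed))) {
    stop(errorCondition("probabilities/labels/observed shapes differ",
                        class = c("fatetox_shape_error", "fatetox_error")))
  }
  eps <- 1e-12
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  cell <- -(labels * log(p) + (1 - labels) * log(1 - p)) * observed
  n_obs <- colSums(observed)
  per_task <- ifelse(n_obs > 0, colSums(cell) / pmax(n_obs, 1), 0)
  list(total = sum(per_task), per_task = as.numeric(per_task))
}

# gradient of the masked loss w.r.t. the logits (M x T)
masked_loss_logit_grad <- function(probabilities, labels, observed,
                                   loss = c("bce", "mse")) {
  loss <- match.arg(loss)
  n_obs <- colSums(observed)
  scale <- rep(ifelse(n_obs > 0, 1 / pmax(n_obs, 1), 0),
               each = nrow(observed))
  if (loss == "bce") {
    (probabilities - labels) * observed * scale
  } else {
    2 * (probabilities - labels) * probabilities *
      (1 - probabilities) * observed * scale
  }
}

masked_mse_loss <- function(probabilities, labels, observed) {
  n_obs <- colSums(observed)
  cell <- (probabilities - labels)^2 * observed
  per_task <- ifelse(n_obs > 0, colSums(cell) / pmax(n_obs, 1), 0)
  list(total = sum(per_task), per_task = as.numeric(per_task))
}

#' PCGrad gradient surgery
#'
#' Projects conflicting task gradients: visiting tasks in random order, each
#' task's gradient is projected onto the normal plane of every other task's
#' gradient with which it has a negative dot product, and the projected
#' gradients are summed. Conflict-free gradient sets pass through unchanged.
#' The visiting orders are drawn from R's RNG; seed the session for
#' reproducibility.
#'
#' @param grads list of equal-length numeric gradient vectors, one per task.
#' @param aggregate \code{"sum"} (default) or \code{"mean"} over projected
#'   task gradients.
#' @param return_projected return the list of projected per-task gradients
#'   instead of their aggregate.
#' @return the combined gradient vector (or, with
#'   \code{return_projected = TRUE}, the list of projected task gradients).
#' @export
pcgrad <- function(grads, aggregate = c("sum", "mean"),
                   return_projected = FALSE) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(grads) >= 1)
  len <- lengths(grads)
  if (any(len != len[1])) {
    stop(errorCondition("task gradients have different lengths",
                        class = c("fatetox_shape_error", "fatetox_error")))
  }
  n_task <- length(grads)
  if (n_task == 1) {
    return(if (return_projected) grads else grads[[1]])
  }
  sq_norms <- vapply(grads, function(g) sum(g * g), numeric(1))
  projected <- vector("list", n_task)
  for (i in sample(seq_len(n_task))) {
    g_pc <- grads[[i]]
    for (j in sample(setdiff(seq_len(n_task), i))) {
      if (sq_norms[j] == 0) next
      dot <- sum(g_pc * grads[[j]])
      if (dot < 0) g_pc <- g_pc - (dot / sq_norms[j]) * grads[[j]]
    }
    projected[[i]] <- g_pc
  }
  if (return_projected) return(projected)
  out <- Reduce(`+`, projected)
  if (aggregate == "mean") out <- out / n_task
  out
}

#' Merge labeled datasets for multi-task learning
#'
#' Molecules are keyed by canonical SMILES; the merged task set is the
#' concatenation of the sources' tasks, with \code{observed = 0} where a
#' molecule carries no label for a task. If the sources carry scaffold
#' splits, memberships are preserved: a molecule appearing in any source
#' test set stays in test (conflicts are resolved toward test and counted).
#'
#' @param datasets list of \code{fatetox_dataset} objects.
#' @return a merged \code{fatetox_dataset} (with merged \code{$splits} if
#'   every source had them).
#' @export
merge_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  task_names <- make.unique(unlist(lapply(datasets, `[[`, "task_names")))
  keys <- character(0)
  molecules <- list()
  for (d in datasets) {
    for (mol in d$molecules) {
      if (!(mol$smiles %in% keys)) {
        keys <- c(keys, mol$smiles)
        molecules[[length(molecules) + 1L]] <- mol
      }
    }
  }
  m <- length(molecules)
  t_total <- length(task_names)
  labels <- matrix(0, m, t_total)
  observed <- matrix(0, m, t_total)
  col_off <- 0L
  membership <- matrix("", m, length(datasets))
  for (di in seq_along(datasets)) {
    d <- datasets[[di]]
    rows <- match(vapply(d$molecules, `[[`, character(1), "smiles"), keys)
    t_d <- length(d$task_names)
    cols <- col_off + seq_len(t_d)
    # a molecule repeated across sources keeps every observed label
    labels[rows, cols] <- d$labels
    observed[rows, cols] <- pmax(observed[rows, cols], d$observed)
    if (!is.null(d$splits)) {
      mem <- character(length(d$molecules))
      mem[d$splits$train] <- "train"
      mem[d$splits$val] <- "val"
      mem[d$splits$test] <- "test"
      membership[rows, di] <- mem
    }
    col_off <- col_off + t_d
  }
  splits <- NULL
  have_splits <- all(vapply(datasets, function(d) !is.null(d$splits),
                            logical(1)))
  n_conflicts <- 0L
  if (have_splits) {
    assign_set <- character(m)
    for (i in seq_len(m)) {
      mem <- unique(membership[i, nzchar(membership[i, ])])
      if (length(mem) > 1) {
        n_conflicts <- n_conflicts + 1L
        assign_set[i] <- if ("test" %in% mem) "test" else "val"
      } else if (length(mem) == 1) {
        assign_set[i] <- mem
      } else {
        assign_set[i] <- "train"
      }
    }
    if (n_conflicts > 0) {
      warning(n_conflicts,
              " molecule(s) had conflicting split memberships; kept in test")
    }
    splits <- structure(
      list(train = which(assign_set == "train"),
           val = which(assign_set == "val"),
           test = which(assign_set == "test")),
      class = "fatetox_splits"
    )
  }
  recovery <- list(
    n_input = sum(vapply(datasets,
                         function(d) d$recovery_log$n_input, numeric(1))),
    parsed = sum(vapply(datasets,
                        function(d) d$recovery_log$parsed, numeric(1))),
    embedded = m,
    dropped = sum(vapply(datasets,
                         function(d) d$recovery_log$dropped, numeric(1))),
    split_conflicts = n_conflicts
  )
  new_labeled_dataset(molecules, labels, observed, task_names,
                      recovery, splits)
}

# -- AUROC -------------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC; ties in scores contribute 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @return AUROC in [0, 1], or \code{NA} if only one class is present.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

predict_compiled <- function(params, mds, config) {
  do.call(rbind, lapply(mds, function(md) {
    model_forward(params, md, config)$prob
  }))
}

#' Per-task AUROC on a dataset split
#'
#' AUROC is computed over the observed cells of each task; a task whose
#' split contains a single class is undefined and is excluded from the mean
#' with a warning.
#'
#' @param params model parameters.
#' @param dataset a \code{fatetox_dataset}.
#' @param indices integer molecule indices (e.g. a component of
#'   \code{\link{scaffold_split}}); default all molecules.
#' @param config a \code{\link{fatetox_config}}.
#' @param probabilities optional precomputed M x T matrix for
#'   \code{dataset} rows \code{indices} (skips the forward pass).
#' @return list with \code{per_task} (named, possibly NA) and \code{mean}.
#' @export
evaluate_auroc <- function(params, dataset,
                           indices = seq_along(dataset$molecules),
                           config = fatetox_config(),
                           probabilities = NULL) {
  if (length(indices) == 0) {
    stop(errorCondition("empty split",
                        class = c("fatetox_empty_split", "fatetox_error")))
  }
  if (is.null(probabilities)) {
    mds <- lapply(dataset$molecules[indices], compile_molecule,
                  config = config)
    probabilities <- predict_compiled(params, mds, config)
  }
  t_total <- ncol(dataset$labels)
  per_task <- setNames(rep(NA_real_, t_total), dataset$task_names)
  for (t in seq_len(t_total)) {
    obs <- dataset$observed[indices, t] == 1
    y <- dataset$labels[indices, t][obs]
    s <- probabilities[obs, t]
    per_task[t] <- auroc(s, y)
  }
  if (all(is.na(per_task))) {
    stop(errorCondition("no task has both classes in this split",
                        class = c("fatetox_no_defined_task", "fatetox_error")))
  }
  if (any(is.na(per_task))) {
    warning("task(s) with a single observed class excluded from mean AUROC: ",
            paste(names(per_task)[is.na(per_task)], collapse = ", "))
  }
  list(per_task = per_task, mean = mean(per_task, na.rm = TRUE))
}

# -- Adam --------------------------------------------------------------------

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

# -- training configuration and loop ----------------------------------------

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs number of passes over the training split.
#' @param seed integer seed controlling shuffling, initialisation and the
#'   PCGrad visiting order.
#' @param use_pcgrad apply gradient surgery when there are >= 2 tasks.
#' @param loss \code{"bce"} (default) or \code{"mse"}.
#' @param pcgrad_aggregate \code{"sum"} or \code{"mean"}.
#' @param patience early-stopping patience on validation mean AUROC
#'   (\code{Inf} disables early stopping).
#' @param verbose print per-epoch progress.
#' @return a \code{fatetox_train_config} list.
#' @export
train_config <- function(learning_rate = 3e-3, batch_size = 32L,
                         max_epochs = 50L, seed = 1L, use_pcgrad = TRUE,
                         loss = c("bce", "mse"),
                         pcgrad_aggregate = c("sum", "mean"),
                         patience = Inf, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), seed = as.integer(seed),
         use_pcgrad = isTRUE(use_pcgrad), loss = loss,
         pcgrad_aggregate = match.arg(pcgrad_aggregate),
         patience = patience, verbose = isTRUE(verbose)),
    class = "fatetox_train_config"
  )
}

# which elements of the flat parameter vector belong to the prediction head
head_mask <- function(params) {
  skel <- rapply(params, function(x) x * 0, how = "replace")
  skel$head <- rapply(skel$head, function(x) x + 1, how = "replace")
  flatten_params(skel) == 1
}

#' Train model parameters on a labeled dataset
#'
#' Mini-batch Adam on the masked multi-task loss. With
#' \code{use_pcgrad} and at least two tasks, per-task gradients of the
#' shared parameters (both branches) are combined by PCGrad at every step;
#' the per-task prediction-head columns receive their own task's gradient
#' directly. Fully seeded: identical configs give identical histories.
#'
#' @param params initial parameters (\code{\link{init_fatetox_params}}).
#' @param dataset a \code{fatetox_dataset}.
#' @param splits a \code{fatetox_splits}; validation may be empty.
#' @param config a \code{\link{train_config}}.
#' @param model_config a \code{\link{fatetox_config}}.
#' @return list with \code{params} (best-validation, or final when no
#'   validation split), \code{history} (per-epoch data frame) and
#'   \code{final_params}.
#' @export
train <- function(params, dataset, splits, config = train_config(),
                  model_config = fatetox_config()) {
  train_idx <- splits$train
  if (length(train_idx) == 0) stop("empty training split")
  val_idx <- splits$val
  t_total <- ncol(dataset$labels)
  use_pc <- config$use_pcgrad && t_total >= 2

  all_idx <- sort(unique(c(train_idx, val_idx)))
  mds <- vector("list", length(dataset$molecules))
  mds[all_idx] <- lapply(dataset$molecules[all_idx], compile_molecule,
                         config = model_config)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  flat <- flatten_params(params)
  opt <- adam_init(length(flat))
  hmask <- head_mask(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auroc = numeric(0))
  best <- list(auroc = -Inf, params = params)
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(train_idx)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      fws <- lapply(mds[batch], function(md)
        model_forward(params, md, model_config))
      probs <- do.call(rbind, lapply(fws, `[[`, "prob"))
      y <- dataset$labels[batch, , drop = FALSE]
      obs <- dataset$observed[batch, , drop = FALSE]
      lss <- if (config$loss == "bce") masked_bce_loss(probs, y, obs)
      else masked_mse_loss(probs, y, obs)
      if (!is.finite(lss$total)) {
        stop(errorCondition(
          paste0("non-finite loss at epoch ", epoch),
          class = c("fatetox_nonfinite_loss", "fatetox_error")
        ))
      }
      epoch_loss <- epoch_loss + lss$total * length(batch)
      dz <- masked_loss_logit_grad(probs, y, obs, config$loss)
      if (use_pc) {
        task_flat <- vector("list", t_total)
        for (t in seq_len(t_total)) {
          g_acc <- NULL
          for (b in seq_along(batch)) {
            if (dz[b, t] == 0) next
            dzt <- numeric(t_total)
            dzt[t] <- dz[b, t]
            g <- model_backward(params, mds[[batch[b]]], fws[[b]], dzt,
                                model_config)
            g_acc <- if (is.null(g_acc)) g else add_params(g_acc, g)
          }
          task_flat[[t]] <- if (is.null(g_acc)) numeric(length(flat))
          else flatten_params(g_acc)
        }
        shared <- pcgrad(lapply(task_flat, function(g) g * !hmask),
                         aggregate = config$pcgrad_aggregate)
        head_g <- Reduce(`+`, lapply(task_flat, function(g) g * hmask))
        gflat <- shared * !hmask + head_g * hmask
      } else {
        g_acc <- NULL
        for (b in seq_along(batch)) {
          g <- model_backward(params, mds[[batch[b]]], fws[[b]], dz[b, ],
                              model_config)
          g_acc <- if (is.null(g_acc)) g else add_params(g_acc, g)
        }
        gflat <- flatten_params(g_acc)
      }
      opt <- adam_step(opt, gflat, config$learning_rate)
      flat <- flat + opt$delta
      params <- unflatten_params(flat, params)
    }
    epoch_loss <- epoch_loss / length(train_idx)
    val_loss <- NA_real_
    val_auc <- NA_real_
    if (length(val_idx) > 0) {
      vprobs <- predict_compiled(params, mds[val_idx], model_config)
      vy <- dataset$labels[val_idx, , drop = FALSE]
      vobs <- dataset$observed[val_idx, , drop = FALSE]
      val_loss <- masked_bce_loss(vprobs, vy, vobs)$total
      val_auc <- suppressWarnings(tryCatch(
        evaluate_auroc(params, dataset, val_idx, model_config,
                       probabilities = vprobs)$mean,
        error = function(e) NA_real_
      ))
      if (!is.na(val_auc) && val_auc > best$auroc) {
        best <- list(auroc = val_auc, params = params)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss,
      val_loss = val_loss, val_auroc = val_auc
    ))
    if (config$verbose) {
      message(sprintf("epoch %3d  train loss %.4f  val auroc %s",
                      epoch, epoch_loss,
                      ifelse(is.na(val_auc), "-", sprintf("%.3f", val_auc))))
    }
    if (length(val_idx) > 0 && stall >= config$patience) break
  }
  list(
    params = if (length(val_idx) > 0 && is.finite(best$auroc)) best$params
    else params,
    final_params = params,
    history = history
  )
}
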