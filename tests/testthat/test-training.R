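test_that("masked BCE matches analytic values and masking conventions", {
  l <- masked_bce_loss(matrix(0.5), matrix(1), matrix(1))
  expect_equal(l$total, -log(0.5), tolerance = 1e-12)

  # fully masked task contributes 0 loss and no gradient
  p <- matrix(c(0.3, 0.8, 0.6, 0.2), 2)
  y <- matrix(c(0, 1, 1, 0), 2)
  obs <- matrix(c(1, 1, 0, 0), 2)
  l2 <- masked_bce_loss(p, y, obs)
  expect_equal(l2$per_task[2], 0)
  g <- fatetox:::masked_loss_logit_grad(p, y, obs)
  expect_equal(g[, 2], c(0, 0))

  # perfect fit limit
  eps <- 1e-9
  l3 <- masked_bce_loss(matrix(c(eps, 1 - eps), 1),
                        matrix(c(0, 1), 1), matrix(1, 1, 2))
  expect_lt(l3$total, 1e-6)

  expect_error(masked_bce_loss(matrix(0.5), matrix(1), matrix(1, 2, 1)),
               class = "fatetox_shape_error")
})

test_that("PCGrad projects the toy conflict and passes through otherwise", {
  # g1=(1,0), g2=(-1,1): g1 projected to (0.5,0.5), g2 to (0,1); sum fixed
  set.seed(1)
  expect_equal(pcgrad(list(c(1, 0), c(-1, 1))), c(0.5, 1.5))
  proj <- pcgrad(list(c(1, 0), c(-1, 1)), return_projected = TRUE)
  expect_equal(proj[[1]], c(0.5, 0.5))
  expect_equal(proj[[2]], c(0, 1))

  # no conflict: unchanged
  expect_equal(pcgrad(list(c(1, 0), c(0, 1))), c(1, 1))
  # single task: identity
  expect_equal(pcgrad(list(c(3, -2))), c(3, -2))
  # zero-norm gradients are skipped, not divided by
  expect_equal(pcgrad(list(c(1, 0), c(0, 0))), c(1, 0))
  expect_error(pcgrad(list(c(1, 0), c(1, 0, 0))),
               class = "fatetox_shape_error")
})

test_that("PCGrad removes pairwise conflicts on random two-task sets", {
  # sequential projection guarantees non-negative dot products against the
  # other task's original gradient for task pairs; with >2 tasks only the
  # most recently processed pair is guaranteed, so the property is checked
  # in its two-task form
  set.seed(77)
  for (rep in 1:100) {
    dim_ <- sample(3:20, 1)
    grads <- list(rnorm(dim_), rnorm(dim_))
    proj <- pcgrad(grads, return_projected = TRUE)
    expect_gte(sum(proj[[1]] * grads[[2]]), -1e-9)
    expect_gte(sum(proj[[2]] * grads[[1]]), -1e-9)

    # conflict-free sets are returned as the plain sum
    n_task <- sample(2:4, 1)
    ortho <- lapply(seq_len(n_task), function(i) {
      v <- numeric(dim_); v[i] <- abs(rnorm(1)); v
    })
    expect_equal(pcgrad(ortho), Reduce(`+`, ortho))
  }
})

test_that("dataset merging unions molecules and preserves labels/splits", {
  smiles_a <- c("CCO", "CCC", "c1ccccc1", "CCN")
  smiles_b <- c("CCCl", "CCBr", "c1ccncc1", "CCO") # one shared molecule
  ds_a <- fatetox:::dataset_from_smiles(
    smiles_a, data.frame(liver = c(1, 0, 1, 0)), "liver", seed = 1L)
  ds_b <- fatetox:::dataset_from_smiles(
    smiles_b, data.frame(heart = c(0, 1, 0, 1)), "heart", seed = 1L)

  merged <- merge_datasets(list(ds_a, ds_b))
  expect_length(merged$molecules, 7L)
  expect_equal(merged$task_names, c("liver", "heart"))
  expect_equal(dim(merged$labels), c(7L, 2L))
  shared <- which(vapply(merged$molecules, `[[`, character(1),
                         "smiles") == "CCO")
  expect_equal(merged$observed[shared, ], c(1, 1))
  expect_equal(merged$labels[shared, ], c(1, 1))
  # disjoint blocks elsewhere: density (4 + 4) / 14
  expect_equal(mean(merged$observed), 8 / 14)

  # merging a dataset with itself keeps M and the label content
  twice <- merge_datasets(list(ds_a, ds_a))
  expect_length(twice$molecules, 4L)
  expect_equal(twice$labels[, 1], twice$labels[, 2])
  expect_equal(twice$labels[, 1], ds_a$labels[, 1])

  # split conflicts resolve to test with a warning
  ds_a$splits <- structure(list(train = 1:3, val = integer(0), test = 4L),
                           class = "fatetox_splits")
  ds_b$splits <- structure(list(train = 1:3, val = integer(0), test = 4L),
                           class = "fatetox_splits")
  # CCO is train in A (its index 1) and test in B (its index 4)
  expect_warning(m2 <- merge_datasets(list(ds_a, ds_b)),
                 "conflicting split")
  cco <- which(vapply(m2$molecules, `[[`, character(1), "smiles") == "CCO")
  expect_true(cco %in% m2$splits$test)
})

test_that("AUROC matches the rank-pair oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  expect_equal(auroc(c(0.6, 0.4), c(0, 1)), 0.0)
  expect_equal(auroc(c(0.6, 0.4), c(1, 0)), 1.0)
  expect_true(is.na(auroc(c(0.5, 0.6), c(1, 1))))

  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2) # coarse grid to exercise ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
  }
})

test_that("evaluate_auroc excludes single-class tasks with a warning", {
  setup <- test_model_setup(n_tasks = 2)
  ds <- fatetox:::dataset_from_smiles(
    c("CCO", "CCC", "CCN"),
    data.frame(a = c(1, 0, 1), b = c(1, 1, 1)), c("a", "b"), seed = 1L)
  params <- init_fatetox_params(2, setup$config, seed = 1L)
  expect_warning(
    ev <- evaluate_auroc(params, ds, config = setup$config),
    "single observed class"
  )
  expect_true(is.na(ev$per_task["b"]))
  expect_false(is.na(ev$mean))
})

test_that("adding a fully-masked task does not perturb the other task", {
  set.seed(303)
  cfg <- test_config(ecfp_bits = 32L)
  mol <- embed_3d(featurize_molecule("CC(=O)Oc1ccccc1"), 2L)
  mol$ecfp <- compute_ecfp(mol, 2L, 32L)
  md <- fatetox:::compile_molecule(mol, cfg)

  p1 <- init_fatetox_params(1, cfg, seed = 4L)
  p2 <- init_fatetox_params(2, cfg, seed = 4L)
  # same shared parameters; task 1's head column identical
  p2$atom <- p1$atom; p2$frag <- p1$frag
  p2$head$W[, 1] <- p1$head$W[, 1]
  p2$head$b[1] <- p1$head$b[1]

  fw1 <- fatetox:::model_forward(p1, md, cfg)
  fw2 <- fatetox:::model_forward(p2, md, cfg)
  y1 <- matrix(1); o1 <- matrix(1)
  y2 <- matrix(c(1, 0), 1); o2 <- matrix(c(1, 0), 1) # task 2 masked
  dz1 <- fatetox:::masked_loss_logit_grad(matrix(fw1$prob, 1), y1, o1)[1, ]
  dz2 <- fatetox:::masked_loss_logit_grad(matrix(fw2$prob, 1), y2, o2)[1, ]
  g1 <- fatetox:::model_backward(p1, md, fw1, dz1, cfg)
  g2 <- fatetox:::model_backward(p2, md, fw2, dz2, cfg)
  expect_lt(max(abs(fatetox:::flatten_params(g1$atom) -
                      fatetox:::flatten_params(g2$atom))), 1e-9)
  expect_lt(max(abs(fatetox:::flatten_params(g1$frag) -
                      fatetox:::flatten_params(g2$frag))), 1e-9)
  expect_lt(max(abs(g1$head$W[, 1] - g2$head$W[, 1])), 1e-9)
  expect_equal(unname(g2$head$W[, 2]), rep(0, nrow(g2$head$W)))
})

test_that("training is seeded-deterministic and PCGrad is a no-op for T=1", {
  ds <- generate_fixture_dataset(fixture_spec(12, "HAS_HALOGEN", 0.5,
                                              seed = 21))
  splits <- structure(list(train = 1:12, val = integer(0),
                           test = integer(0)), class = "fatetox_splits")
  cfg <- test_config(ecfp_bits = 64L)
  params <- init_fatetox_params(1, cfg, seed = 6L)
  ctl <- train_config(max_epochs = 5, seed = 6L, batch_size = 6)
  h1 <- train(params, ds, splits, ctl, cfg)$history
  h2 <- train(params, ds, splits, ctl, cfg)$history
  expect_equal(h1$train_loss, h2$train_loss, tolerance = 1e-12)

  ctl_off <- train_config(max_epochs = 5, seed = 6L, batch_size = 6,
                          use_pcgrad = FALSE)
  h3 <- train(params, ds, splits, ctl_off, cfg)$history
  expect_equal(h1$train_loss, h3$train_loss, tolerance = 1e-12)
})

test_that("two-task training with PCGrad learns both rules", {
  ds <- generate_fixture_dataset(
    fixture_spec(24, c("HAS_NITRO", "HAS_CARBOXYL"), 0.5, seed = 31)
  )
  expect_equal(dim(ds$labels), c(24L, 2L))
  splits <- structure(list(train = 1:24, val = integer(0),
                           test = integer(0)), class = "fatetox_splits")
  cfg <- test_config(ecfp_bits = 128L)
  params <- init_fatetox_params(2, cfg, seed = 8L)
  res <- train(params, ds, splits,
               train_config(max_epochs = 40, seed = 8L, use_pcgrad = TRUE),
               cfg)
  ev <- evaluate_auroc(res$params, ds, 1:24, cfg)
  expect_gte(min(ev$per_task), 0.9)
  expect_true(all(diff(res$history$train_loss[c(1, 40)]) < 0))
})
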