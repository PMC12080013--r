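random_branch_input <- function(n, nf) {
  adj <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1 # path graph
  }
  c2 <- matrix(rnorm(n * 2), n)
  list(node_features = matrix(rnorm(n * nf), n), adjacency = adj,
       distances2d = as.matrix(dist(c2)), coords3d = matrix(rnorm(n * 3), n))
}

test_that("combined attention rows sum to 1 on the lambda simplex", {
  set.seed(11)
  worst <- 0
  for (rep in 1:100) {
    lam <- as.numeric(stats::rgamma(3, 1))
    lam <- lam / sum(lam)
    cfg <- transformer_config(n_head = 2, nf = 8, lambda_attn = lam[1],
                              lambda_dist = lam[2], lambda_adj = lam[3])
    n <- sample(2:8, 1)
    inp <- random_branch_input(n, 8)
    prm <- fatetox:::init_attention_params(8)
    out <- attention_layer(inp, prm, cfg)
    for (p in out$attention) {
      worst <- max(worst, max(abs(rowSums(p) - 1)))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("degenerate lambda weights reproduce their pure components", {
  set.seed(12)
  inp <- random_branch_input(6, 8)
  prm <- fatetox:::init_attention_params(8)

  # lambda = (1,0,0): pure softmax attention
  cfg <- transformer_config(2, 8, lambda_attn = 1, lambda_dist = 0,
                            lambda_adj = 0)
  out <- attention_layer(inp, prm, cfg)
  h <- inp$node_features
  dk <- 4
  for (m in 1:2) {
    idx <- ((m - 1) * dk + 1):(m * dk)
    q <- (h %*% prm$Wq)[, idx]
    k <- (h %*% prm$Wk)[, idx]
    expect_equal(out$attention[[m]],
                 fatetox:::softmax_rows(q %*% t(k) / sqrt(dk)))
  }

  # lambda = (0,1,0) with all pairwise distances equal (coincident layout):
  # softmax of a constant row is uniform
  inp$distances2d <- matrix(0, 6, 6)
  cfg <- transformer_config(2, 8, lambda_attn = 0, lambda_dist = 1,
                            lambda_adj = 0)
  out <- attention_layer(inp, prm, cfg)
  expect_equal(out$attention[[1]], matrix(1 / 6, 6, 6))

  # single node: every head gives [[1]]
  inp1 <- random_branch_input(1, 8)
  out1 <- attention_layer(inp1, prm, transformer_config(2, 8))
  for (p in out1$attention) expect_equal(p, matrix(1, 1, 1))
})

test_that("config invariants are enforced", {
  expect_error(transformer_config(lambda_attn = 0.5, lambda_dist = 0.5,
                                  lambda_adj = 0.5),
               class = "fatetox_config_error")
  expect_error(transformer_config(n_head = 3, nf = 16),
               class = "fatetox_config_error")
  expect_error(fusion_config(1, 1, 1), class = "fatetox_config_error")
})

test_that("knn graph matches brute force and handles edge cases", {
  pts <- matrix(c(0, 0, 0, 1, 0, 0, 10, 0, 0), 3, byrow = TRUE)
  a <- knn_graph(pts, 1)
  expect_equal(a, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))

  set.seed(21)
  pts <- matrix(rnorm(24), 8)
  expect_equal(knn_graph(pts, 7), 1 - diag(8))
  expect_equal(knn_graph(pts, 99), 1 - diag(8))
  expect_equal(knn_graph(matrix(rnorm(3), 1), 5), matrix(0, 1, 1))

  # brute force: each row must contain that node's k nearest
  a <- knn_graph(pts, 3)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  for (i in 1:8) {
    expect_true(all(a[i, order(d[i, ])[1:3]] == 1))
  }
  expect_equal(a, t(a))
})

test_that("EGCL is E(3)-equivariant and handles degenerate graphs", {
  set.seed(31)
  prm <- fatetox:::init_egcl_params(8, 8)
  cfg <- egnn_config(k_neighbors = 3, hidden_dim = 8)
  h <- matrix(rnorm(48), 6)
  c3 <- matrix(rnorm(18), 6)
  knn <- knn_graph(c3, 3)
  base <- egcl_layer(h, c3, knn, prm, cfg)
  for (i in 1:20) {
    tr <- random_rigid_transform()
    c3t <- apply_rigid(c3, tr)
    out <- egcl_layer(h, c3t, knn_graph(c3t, 3), prm, cfg)
    expect_lt(max(abs(out$h - base$h)), 1e-5)
    expect_lt(max(abs(out$coords - apply_rigid(base$coords, tr))), 1e-5)
  }

  # two nodes mirrored about the origin with identical features stay mirrored
  h2 <- matrix(rep(rnorm(8), 2), 2, byrow = TRUE)
  c2 <- matrix(c(1, 0.5, -2, -1, -0.5, 2), 2, byrow = TRUE)
  out2 <- egcl_layer(h2, c2, knn_graph(c2, 1), prm, cfg)
  expect_equal(out2$coords[1, ], -out2$coords[2, ])

  # isolated node: empty message sum, coordinates unchanged
  h1 <- matrix(rnorm(8), 1)
  c1 <- matrix(c(0, 0, 0), 1)
  out1 <- egcl_layer(h1, c1, matrix(0, 1, 1), prm, cfg)
  expect_equal(out1$coords, c1)
  magg0 <- matrix(0, 1, 8)
  hin <- cbind(h1, magg0)
  u1 <- fatetox:::silu(sweep(hin %*% prm$Wh1, 2, prm$bh1, "+"))
  expected_h <- h1 + sweep(u1 %*% prm$Wh2, 2, prm$bh2, "+")
  expect_equal(out1$h, expected_h)
})

test_that("branch embeddings are invariant to atom permutation and E(3)", {
  set.seed(41)
  cfg <- test_config()
  prm <- fatetox:::init_branch_params(n_atom_features(), cfg$transformer,
                                      cfg$egnn)
  mol <- one_mol("propranolol")
  inp <- list(node_features = mol$atom_features,
              adjacency = mol$bond_adjacency,
              distances2d = as.matrix(dist(mol$coords2d)),
              coords3d = mol$coords3d)
  base <- encode_branch(inp, prm, cfg)

  for (i in 1:5) {
    perm <- sample(mol$n_atoms)
    pinp <- list(node_features = inp$node_features[perm, ],
                 adjacency = inp$adjacency[perm, perm],
                 distances2d = inp$distances2d[perm, perm],
                 coords3d = inp$coords3d[perm, ])
    out <- encode_branch(pinp, prm, cfg)
    expect_lt(max(abs(out$embedding - base$embedding)), 1e-5)

    tr <- random_rigid_transform()
    tinp <- inp
    tinp$coords3d <- apply_rigid(inp$coords3d, tr)
    out <- encode_branch(tinp, prm, cfg)
    expect_lt(max(abs(out$embedding - base$embedding)), 1e-5)
  }

  # single-atom input stays finite
  m1 <- embed_3d(featurize_molecule("C"), 1L)
  i1 <- list(node_features = m1$atom_features, adjacency = m1$bond_adjacency,
             distances2d = matrix(0, 1, 1), coords3d = m1$coords3d)
  expect_true(all(is.finite(encode_branch(i1, prm, cfg)$embedding)))
})

test_that("fragment fusion is the stated convex combination", {
  set.seed(51)
  e1 <- rnorm(8); e2 <- rnorm(8); e3 <- rnorm(8)
  expect_identical(
    fuse_fragment_embeddings(e1, e2, e3, fusion_config(1, 0, 0)), e1
  )
  f <- fuse_fragment_embeddings(e1, e1, e1, fusion_config(0.2, 0.5, 0.3))
  expect_equal(f, e1)
  f <- fuse_fragment_embeddings(e1, e2, e3, fusion_config(0.2, 0.5, 0.3))
  expect_true(all(f <= pmax(e1, e2, e3) + 1e-12))
  expect_true(all(f >= pmin(e1, e2, e3) - 1e-12))
})

test_that("prediction head produces per-task probabilities in (0,1)", {
  setup <- test_model_setup(n_tasks = 3)
  fw <- forward_molecule(setup$mol, setup$params, setup$config)
  expect_length(fw$probabilities, 3L)
  expect_true(all(fw$probabilities > 0 & fw$probabilities < 1))
  expect_error(
    predict_head(rnorm(4), rnorm(4), rep(1, 10), setup$params$head),
    class = "fatetox_shape_error"
  )
})

test_that("end-to-end predictions are E(3)-invariant and deterministic", {
  set.seed(61)
  setup <- test_model_setup(n_tasks = 2)
  base <- forward_molecule(setup$mol, setup$params, setup$config)
  again <- forward_molecule(setup$mol, setup$params, setup$config)
  expect_identical(base$probabilities, again$probabilities)
  for (i in 1:10) {
    tr <- random_rigid_transform()
    m2 <- setup$mol
    m2$coords3d <- apply_rigid(setup$mol$coords3d, tr)
    out <- forward_molecule(m2, setup$params, setup$config)
    expect_lt(max(abs(out$probabilities - base$probabilities)), 1e-4)
  }
})

test_that("degenerate geometry with lambda=(1,0,0) stays finite", {
  setup <- test_model_setup(
    config = fatetox_config(
      transformer = transformer_config(2, 8, lambda_attn = 1,
                                       lambda_dist = 0, lambda_adj = 0),
      egnn = egnn_config(k_neighbors = 3, hidden_dim = 8),
      ecfp_bits = 64L
    )
  )
  m <- setup$mol
  m$coords3d <- matrix(1, m$n_atoms, 3) # all atoms at one point
  out <- forward_molecule(m, setup$params, setup$config)
  expect_true(all(is.finite(out$probabilities)))
})

test_that("analytic gradients match finite differences", {
  set.seed(71)
  cfg <- fatetox_config(
    transformer = transformer_config(n_head = 2, nf = 8, n_layers = 2),
    egnn = egnn_config(n_layers = 2, k_neighbors = 3, hidden_dim = 6),
    ecfp_bits = 32L
  )
  mol <- embed_3d(featurize_molecule("CC(=O)Oc1ccccc1"), 3L)
  mol$ecfp <- compute_ecfp(mol, 2L, 32L)
  params <- init_fatetox_params(2, cfg, seed = 5L)
  md <- fatetox:::compile_molecule(mol, cfg)
  y <- matrix(c(1, 0), 1); obs <- matrix(1, 1, 2)
  lossfn <- function(p) {
    f <- fatetox:::model_forward(p, md, cfg)
    masked_bce_loss(matrix(f$prob, 1), y, obs)$total
  }
  fw <- fatetox:::model_forward(params, md, cfg)
  dz <- fatetox:::masked_loss_logit_grad(matrix(fw$prob, 1), y, obs)[1, ]
  g <- fatetox:::flatten_params(
    fatetox:::model_backward(params, md, fw, dz, cfg)
  )
  flat <- fatetox:::flatten_params(params)
  idx <- sort(sample(length(flat), 50))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    fp <- flat; fp[i] <- fp[i] + eps
    fm <- flat; fm[i] <- fm[i] - eps
    (lossfn(fatetox:::unflatten_params(fp, params)) -
        lossfn(fatetox:::unflatten_params(fm, params))) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - g[idx])), 1e-6)
})

test_that("every trainable parameter receives gradient on a random batch", {
  set.seed(81)
  cfg <- test_config(ecfp_bits = 32L, eg_layers = 2L)
  params <- init_fatetox_params(1, cfg, seed = 2L)
  smiles <- c("CCO", "c1ccccc1C(=O)O", "CC(C)Cl", "O=[N+]([O-])c1ccco1")
  g_acc <- NULL
  for (s in smiles) {
    mol <- embed_3d(featurize_molecule(s), 2L)
    mol$ecfp <- compute_ecfp(mol, 2L, 32L)
    md <- fatetox:::compile_molecule(mol, cfg)
    fw <- fatetox:::model_forward(params, md, cfg)
    g <- fatetox:::model_backward(params, md, fw, fw$prob - 1, cfg)
    g_acc <- if (is.null(g_acc)) g else fatetox:::add_params(g_acc, g)
  }
  # the final EGCL layer's coordinate network is structurally gradient-free
  # (updated coordinates never feed the readout, preserving invariance), as
  # are head weight rows of fingerprint bits absent from the batch;
  # everything else must be touched
  # likewise W_in rows of one-hot feature categories absent from the batch
  drop_structural <- function(branch, active_features) {
    last <- length(branch$eg)
    branch$eg[[last]]$Wx1 <- NULL
    branch$eg[[last]]$bx1 <- NULL
    branch$eg[[last]]$Wx2 <- NULL
    branch$W_in <- branch$W_in[active_features, , drop = FALSE]
    branch
  }
  feats <- lapply(smiles, function(s) featurize_molecule(s)$atom_features)
  active_atom <- which(colSums(abs(do.call(rbind, feats))) > 0)
  # the fragment branch sees sum-pooled features, where signed descriptors
  # (formal charge) can cancel within a fragment
  frag_feats <- do.call(rbind, unlist(lapply(smiles, function(s) {
    views <- fragment_views(embed_3d(featurize_molecule(s), 2L))
    lapply(views, `[[`, "frag_features")
  }), recursive = FALSE))
  active_frag <- which(colSums(abs(frag_feats)) > 0)
  expect_true(all(fatetox:::flatten_params(
    drop_structural(g_acc$atom, active_atom)) != 0))
  expect_true(all(fatetox:::flatten_params(
    drop_structural(g_acc$frag, active_frag)) != 0))
  expect_true(all(g_acc$atom$eg[[1]]$Wx2 != 0)) # earlier layers are trained
  expect_true(all(g_acc$head$b != 0))
  on_bits <- which(rowSums(vapply(
    smiles, function(s) compute_ecfp(featurize_molecule(s), 2L, 32L),
    integer(32L)
  )) > 0)
  d <- cfg$transformer$nf
  expect_true(all(g_acc$head$W[c(seq_len(2 * d), 2 * d + on_bits), ] != 0))
})
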