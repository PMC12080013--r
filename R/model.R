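# The dual-branch architecture: graph-augmented multi-head self-attention
# over the 2D graph, E(3)-equivariant graph convolutions over the 3D
# conformer, mean readout, fragment-view fusion and a linear prediction
# head over concat(atom embedding, fragment embedding, ECFP).

# -- configs -----------------------------------------------------------------

#' Transformer branch configuration
#'
#' @param n_head number of attention heads.
#' @param nf model width (must be divisible by \code{n_head}; the per-head
#'   key dimension is \code{nf / n_head}).
#' @param n_layers number of transformer blocks.
#' @param lambda_attn,lambda_dist,lambda_adj non-negative mixing weights for
#'   the learned attention, the softmax-transformed 2D distance matrix and
#'   the row-normalised bond adjacency; they must sum to 1.
#' @return a \code{fatetox_transformer_config} list.
#' @export
transformer_config <- function(n_head = 4L, nf = 16L, n_layers = 1L,
                               lambda_attn = 1 / 3, lambda_dist = 1 / 3,
                               lambda_adj = 1 / 3) {
  lambdas <- c(lambda_attn, lambda_dist, lambda_adj)
  if (any(lambdas < 0) || abs(sum(lambdas) - 1) > 1e-8) {
    stop(errorCondition(
      "lambda_attn + lambda_dist + lambda_adj must equal 1 (all >= 0)",
      class = c("fatetox_config_error", "fatetox_error")
    ))
  }
  if (nf %% n_head != 0) {
    stop(errorCondition("nf must be divisible by n_head",
                        class = c("fatetox_config_error", "fatetox_error")))
  }
  structure(
    list(n_head = as.integer(n_head), nf = as.integer(nf),
         n_layers = as.integer(n_layers),
         lambda_attn = lambda_attn, lambda_dist = lambda_dist,
         lambda_adj = lambda_adj),
    class = "fatetox_transformer_config"
  )
}

#' EGNN branch configuration
#'
#' @param n_layers number of equivariant graph convolutional layers.
#' @param k_neighbors neighbourhood size of the kNN graph over the 3D
#'   coordinates.
#' @param hidden_dim width of the edge/node update networks.
#' @param coord_scale scaling constant for the positional updates.
#' @return a \code{fatetox_egnn_config} list.
#' @export
egnn_config <- function(n_layers = 1L, k_neighbors = 5L, hidden_dim = 16L,
                        coord_scale = 0.1) {
  stopifnot(k_neighbors >= 1, n_layers >= 1, hidden_dim >= 1,
            coord_scale > 0)
  structure(
    list(n_layers = as.integer(n_layers),
         k_neighbors = as.integer(k_neighbors),
         hidden_dim = as.integer(hidden_dim), coord_scale = coord_scale),
    class = "fatetox_egnn_config"
  )
}

#' Fragment-view fusion configuration
#'
#' Weights for the BRICS, Murcko and functional-group fragment embeddings;
#' must be non-negative and sum to 1.
#'
#' @param lambda_b,lambda_m,lambda_f weights for the BRICS, Murcko and
#'   functional-group views.
#' @return a \code{fatetox_fusion_config} list.
#' @export
fusion_config <- function(lambda_b = 1 / 3, lambda_m = 1 / 3,
                          lambda_f = 1 / 3) {
  lambdas <- c(lambda_b, lambda_m, lambda_f)
  if (any(lambdas < 0) || abs(sum(lambdas) - 1) > 1e-8) {
    stop(errorCondition("lambda_b + lambda_m + lambda_f must equal 1",
                        class = c("fatetox_config_error", "fatetox_error")))
  }
  structure(list(lambda_b = lambda_b, lambda_m = lambda_m,
                 lambda_f = lambda_f),
            class = "fatetox_fusion_config")
}

#' Full model configuration
#'
#' @param transformer a \code{\link{transformer_config}} (shared by both
#'   branches).
#' @param egnn an \code{\link{egnn_config}}.
#' @param fusion a \code{\link{fusion_config}}.
#' @param readout node aggregation, \code{"mean"} (default) or \code{"sum"}.
#' @param ecfp_bits fingerprint width fed to the prediction head.
#' @return a \code{fatetox_config} list.
#' @export
fatetox_config <- function(transformer = transformer_config(),
                           egnn = egnn_config(),
                           fusion = fusion_config(),
                           readout = c("mean", "sum"),
                           ecfp_bits = 1024L) {
  readout <- match.arg(readout)
  structure(
    list(transformer = transformer, egnn = egnn, fusion = fusion,
         readout = readout, ecfp_bits = as.integer(ecfp_bits)),
    class = "fatetox_config"
  )
}

# -- parameter initialisation ------------------------------------------------

init_attention_params <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d), bo = numeric(d),
       ln_g = rep(1, d), ln_b = numeric(d))
}

init_egcl_params <- function(d, hd) {
  list(We1 = glorot(2 * d + 2, hd), be1 = numeric(hd),
       We2 = glorot(hd, hd), be2 = numeric(hd),
       Wh1 = glorot(d + hd, hd), bh1 = numeric(hd),
       Wh2 = glorot(hd, d), bh2 = numeric(d),
       Wx1 = glorot(hd, hd), bx1 = numeric(hd),
       Wx2 = glorot(hd, 1))
}

init_branch_params <- function(nf_in, cfg_t, cfg_e) {
  d <- cfg_t$nf
  list(
    W_in = glorot(nf_in, d), b_in = numeric(d),
    tf = lapply(seq_len(cfg_t$n_layers), function(i) init_attention_params(d)),
    eg = lapply(seq_len(cfg_e$n_layers),
                function(i) init_egcl_params(d, cfg_e$hidden_dim))
  )
}

#' Initialise model parameters
#'
#' @param n_tasks number of prediction tasks.
#' @param config a \code{\link{fatetox_config}}.
#' @param nf_in per-atom feature width (default the package featurizer's).
#' @param seed integer seed.
#' @return nested list of parameter matrices (atom branch, shared fragment
#'   branch, prediction head).
#' @export
init_fatetox_params <- function(n_tasks, config = fatetox_config(),
                                nf_in = n_atom_features(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- config$transformer$nf
  list(
    atom = init_branch_params(nf_in, config$transformer, config$egnn),
    frag = init_branch_params(nf_in, config$transformer, config$egnn),
    head = list(W = glorot(2 * d + config$ecfp_bits, n_tasks),
                b = numeric(n_tasks))
  )
}

# -- graph-augmented attention -----------------------------------------------

attn_forward <- function(h, a_norm, d_soft, prm, cfg) {
  n <- nrow(h); d <- ncol(h)
  nh <- cfg$n_head; dk <- d %/% nh
  q <- h %*% prm$Wq; k <- h %*% prm$Wk; v <- h %*% prm$Wv
  ocat <- matrix(0, n, d)
  heads <- vector("list", nh)
  for (m in seq_len(nh)) {
    idx <- ((m - 1L) * dk + 1L):(m * dk)
    s <- tcrossprod(q[, idx, drop = FALSE], k[, idx, drop = FALSE]) / sqrt(dk)
    p_attn <- softmax_rows(s)
    p <- cfg$lambda_attn * p_attn + cfg$lambda_dist * d_soft +
      cfg$lambda_adj * a_norm
    ocat[, idx] <- p %*% v[, idx, drop = FALSE]
    heads[[m]] <- list(p_attn = p_attn, p = p)
  }
  o <- ocat %*% prm$Wo
  o <- sweep(o, 2, prm$bo, "+")
  res <- h + o
  ln <- layernorm_forward(res, prm$ln_g, prm$ln_b)
  list(out = ln$out,
       record = lapply(heads, `[[`, "p"),
       cache = list(h = h, q = q, k = k, v = v, ocat = ocat,
                    heads = heads, ln = ln$cache, dk = dk))
}

attn_backward <- function(cache, prm, cfg, dout) {
  lb <- layernorm_backward(cache$ln, dout)
  dres <- lb$dx
  dh <- dres
  do_ <- dres
  dwo <- crossprod(cache$ocat, do_)
  dbo <- colSums(do_)
  docat <- do_ %*% t(prm$Wo)
  n <- nrow(dh); d <- ncol(dh)
  nh <- cfg$n_head; dk <- cache$dk
  dq <- matrix(0, n, d); dk_ <- matrix(0, n, d); dv <- matrix(0, n, d)
  for (m in seq_len(nh)) {
    idx <- ((m - 1L) * dk + 1L):(m * dk)
    hd_ <- cache$heads[[m]]
    dom <- docat[, idx, drop = FALSE]
    vh <- cache$v[, idx, drop = FALSE]
    dp <- tcrossprod(dom, vh)
    dv[, idx] <- crossprod(hd_$p, dom)
    dpa <- cfg$lambda_attn * dp
    ds <- softmax_rows_backward(hd_$p_attn, dpa)
    dq[, idx] <- ds %*% cache$k[, idx, drop = FALSE] / sqrt(dk)
    dk_[, idx] <- crossprod(ds, cache$q[, idx, drop = FALSE]) / sqrt(dk)
  }
  dh <- dh + tcrossprod(dq, prm$Wq) + tcrossprod(dk_, prm$Wk) +
    tcrossprod(dv, prm$Wv)
  grads <- list(Wq = crossprod(cache$h, dq),
                Wk = crossprod(cache$h, dk_),
                Wv = crossprod(cache$h, dv),
                Wo = dwo, bo = dbo, ln_g = lb$dg, ln_b = lb$db)
  list(dx = dh, grads = grads)
}

#' Graph-augmented self-attention layer
#'
#' One transformer block. Per head, the learned attention
#' \code{softmax(Q K' / sqrt(d_k))} is mixed with the softmax-transformed 2D
#' distance matrix and the row-normalised bond adjacency using the three
#' lambda weights, then applied to the values; heads are concatenated,
#' linearly transformed, and passed through a residual connection with layer
#' normalisation.
#'
#' @param input list with \code{node_features} (N x nf), \code{adjacency}
#'   (binary N x N) and \code{distances2d} (N x N).
#' @param params layer parameters (see \code{\link{init_fatetox_params}}).
#' @param config a \code{\link{transformer_config}}.
#' @return list with \code{features} (updated N x nf matrix) and
#'   \code{attention} (per-head combined N x N matrices).
#' @export
attention_layer <- function(input, params, config) {
  h <- input$node_features
  if (ncol(h) != config$nf) {
    stop(errorCondition("node feature width does not match config nf",
                        class = c("fatetox_shape_error", "fatetox_error")))
  }
  a_norm <- unname(normalize_adjacency(as.matrix(input$adjacency)))
  d_soft <- unname(softmax_rows(-as.matrix(input$distances2d)))
  fw <- attn_forward(h, a_norm, d_soft, params, config)
  list(features = fw$out, attention = fw$record)
}

# -- kNN graph and EGCL ------------------------------------------------------

#' k-nearest-neighbour graph over 3D coordinates
#'
#' Each node is linked to its \code{min(k, N-1)} nearest Euclidean
#' neighbours (ties broken by node index); the result is symmetrised and has
#' a zero diagonal.
#'
#' @param coords3d N x 3 coordinate matrix.
#' @param k neighbourhood size.
#' @return binary N x N adjacency matrix.
#' @export
knn_graph <- function(coords3d, k) {
  coords3d <- as.matrix(coords3d)
  n <- nrow(coords3d)
  a <- matrix(0, n, n)
  if (n <= 1) return(a)
  d <- as.matrix(stats::dist(coords3d))
  diag(d) <- Inf
  kk <- min(k, n - 1L)
  for (i in seq_len(n)) {
    nbrs <- order(d[i, ])[seq_len(kk)]
    a[i, nbrs] <- 1
  }
  a <- pmax(a, t(a))
  diag(a) <- 0
  a
}

egcl_forward <- function(h, c3, mask, prm, cfg) {
  n <- nrow(h); d <- ncol(h)
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  dx <- outer(c3[, 1], c3[, 1], "-")
  dy <- outer(c3[, 2], c3[, 2], "-")
  dz <- outer(c3[, 3], c3[, 3], "-")
  d2 <- dx^2 + dy^2 + dz^2
  av <- as.vector(mask)
  e <- cbind(h[ii, , drop = FALSE], h[jj, , drop = FALSE],
             as.vector(d2), av)
  z1 <- sweep(e %*% prm$We1, 2, prm$be1, "+")
  m1 <- silu(z1)
  z2 <- sweep(m1 %*% prm$We2, 2, prm$be2, "+")
  mraw <- silu(z2)
  mij <- mraw * av
  magg <- rowsum(mij, ii)
  dimnames(magg) <- NULL
  hin <- cbind(h, magg)
  zh1 <- sweep(hin %*% prm$Wh1, 2, prm$bh1, "+")
  u1 <- silu(zh1)
  hup <- sweep(u1 %*% prm$Wh2, 2, prm$bh2, "+")
  hout <- h + hup
  zx1 <- sweep(mij %*% prm$Wx1, 2, prm$bx1, "+")
  x1 <- silu(zx1)
  w <- x1 %*% prm$Wx2
  wm <- as.vector(w) * av
  wmat <- matrix(wm, n, n)
  cout <- c3 + cfg$coord_scale * cbind(
    rowSums(dx * wmat), rowSums(dy * wmat), rowSums(dz * wmat)
  )
  list(h = hout, coords = cout,
       cache = list(h = h, c3 = c3, ii = ii, jj = jj, av = av,
                    dx = dx, dy = dy, dz = dz, e = e,
                    z1 = z1, m1 = m1, z2 = z2, mij = mij,
                    hin = hin, zh1 = zh1, u1 = u1,
                    zx1 = zx1, x1 = x1, wmat = wmat, n = n, d = d))
}

egcl_backward <- function(cache, prm, cfg, dh_out, dc_out) {
  n <- cache$n; d <- cache$d
  ii <- cache$ii; jj <- cache$jj; av <- cache$av
  cs <- cfg$coord_scale

  # h' = h + phi_h([h, m_i])
  dh <- dh_out
  dhup <- dh_out
  dwh2 <- crossprod(cache$u1, dhup)
  dbh2 <- colSums(dhup)
  du1 <- tcrossprod(dhup, prm$Wh2)
  dzh1 <- du1 * silu_grad(cache$zh1)
  dwh1 <- crossprod(cache$hin, dzh1)
  dbh1 <- colSums(dzh1)
  dhin <- tcrossprod(dzh1, prm$Wh1)
  dh <- dh + dhin[, seq_len(d), drop = FALSE]
  dmagg <- dhin[, d + seq_len(ncol(cache$mij)), drop = FALSE]
  dmij <- dmagg[ii, , drop = FALSE]

  # coordinate update c' = c + cs * sum_j (c_i - c_j) w_ij
  dc <- dc_out
  dwmat <- cs * (cache$dx * dc_out[, 1] + cache$dy * dc_out[, 2] +
                   cache$dz * dc_out[, 3])
  ddx <- cs * cache$wmat * dc_out[, 1]
  ddy <- cs * cache$wmat * dc_out[, 2]
  ddz <- cs * cache$wmat * dc_out[, 3]
  dw <- as.vector(dwmat) * av
  dx1 <- matrix(dw, ncol = 1) %*% t(prm$Wx2)
  dwx2 <- crossprod(cache$x1, matrix(dw, ncol = 1))
  dzx1 <- dx1 * silu_grad(cache$zx1)
  dwx1 <- crossprod(cache$mij, dzx1)
  dbx1 <- colSums(dzx1)
  dmij <- dmij + tcrossprod(dzx1, prm$Wx1)

  # mij = silu(z2) * mask
  dmraw <- dmij * av
  dz2 <- dmraw * silu_grad(cache$z2)
  dwe2 <- crossprod(cache$m1, dz2)
  dbe2 <- colSums(dz2)
  dm1 <- tcrossprod(dz2, prm$We2)
  dz1 <- dm1 * silu_grad(cache$z1)
  dwe1 <- crossprod(cache$e, dz1)
  dbe1 <- colSums(dz1)
  de <- tcrossprod(dz1, prm$We1)
  dh <- dh + rowsum(de[, seq_len(d), drop = FALSE], ii) +
    rowsum(de[, d + seq_len(d), drop = FALSE], jj)
  dd2 <- matrix(de[, 2 * d + 1], n, n)
  ddx <- ddx + 2 * cache$dx * dd2
  ddy <- ddy + 2 * cache$dy * dd2
  ddz <- ddz + 2 * cache$dz * dd2
  dc[, 1] <- dc[, 1] + rowSums(ddx) - colSums(ddx)
  dc[, 2] <- dc[, 2] + rowSums(ddy) - colSums(ddy)
  dc[, 3] <- dc[, 3] + rowSums(ddz) - colSums(ddz)

  grads <- list(We1 = dwe1, be1 = dbe1, We2 = dwe2, be2 = dbe2,
                Wh1 = dwh1, bh1 = dbh1, Wh2 = dwh2, bh2 = dbh2,
                Wx1 = dwx1, bx1 = dbx1, Wx2 = dwx2)
  list(dh = dh, dc = dc, grads = grads)
}

#' E(3)-equivariant graph convolutional layer
#'
#' Messages are computed from both endpoint embeddings, the squared
#' Euclidean distance and the edge attribute, aggregated over kNN
#' neighbours; features are updated through a residual node network and
#' coordinates through scaled weighted directional vectors, so that feature
#' outputs are invariant and coordinate outputs covariant under rotations,
#' translations and reflections.
#'
#' @param h N x d node feature matrix.
#' @param coords3d N x 3 coordinate matrix.
#' @param knn binary symmetric kNN adjacency (see \code{\link{knn_graph}}).
#' @param params layer parameters.
#' @param config an \code{\link{egnn_config}}.
#' @return list with updated \code{h} and \code{coords}.
#' @export
egcl_layer <- function(h, coords3d, knn, params, config) {
  stopifnot(nrow(h) == nrow(coords3d), nrow(knn) == nrow(h))
  fw <- egcl_forward(h, as.matrix(coords3d), knn, params, config)
  list(h = fw$h, coords = fw$coords)
}

# -- branch encoder ----------------------------------------------------------

# precompute the constant matrices a branch needs
compile_branch_input <- function(node_features, adjacency, distances2d,
                                 coords3d, config) {
  list(
    x = unname(as.matrix(node_features)),
    a_norm = unname(normalize_adjacency(as.matrix(adjacency))),
    d_soft = unname(softmax_rows(-as.matrix(distances2d))),
    c3 = unname(as.matrix(coords3d)),
    knn = knn_graph(coords3d, config$egnn$k_neighbors)
  )
}

branch_forward <- function(prm, comp, config) {
  h <- sweep(comp$x %*% prm$W_in, 2, prm$b_in, "+")
  tf_caches <- vector("list", length(prm$tf))
  records <- vector("list", length(prm$tf))
  for (l in seq_along(prm$tf)) {
    fw <- attn_forward(h, comp$a_norm, comp$d_soft, prm$tf[[l]],
                       config$transformer)
    h <- fw$out
    tf_caches[[l]] <- fw$cache
    records[[l]] <- fw$record
  }
  c3 <- comp$c3
  eg_caches <- vector("list", length(prm$eg))
  for (l in seq_along(prm$eg)) {
    fw <- egcl_forward(h, c3, comp$knn, prm$eg[[l]], config$egnn)
    h <- fw$h
    c3 <- fw$coords
    eg_caches[[l]] <- fw$cache
  }
  e <- if (config$readout == "mean") colMeans(h) else colSums(h)
  list(embedding = e, attention = records,
       cache = list(tf = tf_caches, eg = eg_caches, n = nrow(h)))
}

branch_backward <- function(prm, comp, cache, de, config) {
  n <- cache$n
  d <- length(de)
  dh <- matrix(de, n, d, byrow = TRUE)
  if (config$readout == "mean") dh <- dh / n
  dc <- matrix(0, n, 3)
  g_eg <- vector("list", length(prm$eg))
  for (l in rev(seq_along(prm$eg))) {
    bk <- egcl_backward(cache$eg[[l]], prm$eg[[l]], config$egnn, dh, dc)
    dh <- bk$dh
    dc <- bk$dc
    g_eg[[l]] <- bk$grads
  }
  g_tf <- vector("list", length(prm$tf))
  for (l in rev(seq_along(prm$tf))) {
    bk <- attn_backward(cache$tf[[l]], prm$tf[[l]], config$transformer, dh)
    dh <- bk$dx
    g_tf[[l]] <- bk$grads
  }
  list(grads = list(W_in = crossprod(comp$x, dh), b_in = colSums(dh),
                    tf = g_tf, eg = g_eg))
}

#' Encode one graph branch to a fixed-length embedding
#'
#' Transformer stack over the 2D graph, then EGCL stack over the 3D
#' coordinates and kNN graph, then permutation-invariant readout.
#'
#' @param input list with \code{node_features}, \code{adjacency},
#'   \code{distances2d} and \code{coords3d}.
#' @param params branch parameters (\code{$atom} or \code{$frag} of
#'   \code{\link{init_fatetox_params}}).
#' @param config a \code{\link{fatetox_config}}.
#' @return list with \code{embedding} and per-layer \code{attention}
#'   records.
#' @export
encode_branch <- function(input, params, config = fatetox_config()) {
  comp <- compile_branch_input(input$node_features, input$adjacency,
                               input$distances2d, input$coords3d, config)
  fw <- branch_forward(params, comp, config)
  list(embedding = fw$embedding, attention = fw$attention)
}

# -- fusion and head ---------------------------------------------------------

#' Fuse the three fragment-view embeddings
#'
#' Weighted summation of the BRICS, Murcko and functional-group branch
#' embeddings.
#'
#' @param e_brics,e_murcko,e_fg equal-length embedding vectors.
#' @param config a \code{\link{fusion_config}}.
#' @return the fused embedding vector.
#' @export
fuse_fragment_embeddings <- function(e_brics, e_murcko, e_fg,
                                     config = fusion_config()) {
  stopifnot(length(e_brics) == length(e_murcko),
            length(e_murcko) == length(e_fg))
  config$lambda_b * e_brics + config$lambda_m * e_murcko +
    config$lambda_f * e_fg
}

#' Prediction head
#'
#' Linear map over the concatenation of the atom-branch embedding, fused
#' fragment embedding and ECFP, followed by a per-task sigmoid.
#'
#' @param e_atom,e_frag branch embeddings.
#' @param ecfp fingerprint 0/1 vector.
#' @param head list with \code{W} and \code{b} (see
#'   \code{\link{init_fatetox_params}}).
#' @return per-task probabilities in (0, 1).
#' @export
predict_head <- function(e_atom, e_frag, ecfp, head) {
  zin <- c(e_atom, e_frag, ecfp)
  if (length(zin) != nrow(head$W)) {
    stop(errorCondition("head input width mismatch",
                        class = c("fatetox_shape_error", "fatetox_error")))
  }
  as.numeric(sigmoid(drop(zin %*% head$W) + head$b))
}

# -- whole-model forward / backward -----------------------------------------

# Precompute every constant the network needs for one molecule.
compile_molecule <- function(mol, config, views = NULL) {
  if (is.null(mol$coords3d)) {
    stop("molecule has no 3D coordinates; call embed_3d() first")
  }
  if (is.null(views)) views <- fragment_views(mol)
  atom <- compile_branch_input(
    mol$atom_features, mol$bond_adjacency,
    as.matrix(stats::dist(mol$coords2d)), mol$coords3d, config
  )
  frag <- lapply(views, function(v) {
    compile_branch_input(v$frag_features, v$frag_adjacency,
                         v$frag_distances2d, v$frag_coords3d, config)
  })
  ecfp <- mol$ecfp
  if (length(ecfp) != config$ecfp_bits) {
    ecfp <- compute_ecfp(mol, mol$ecfp_radius, config$ecfp_bits)
  }
  list(atom = atom, frag = frag, ecfp = ecfp, views = views)
}

model_forward <- function(params, md, config) {
  ba <- branch_forward(params$atom, md$atom, config)
  bf <- lapply(md$frag, function(cmp) branch_forward(params$frag, cmp, config))
  fus <- config$fusion
  e_frag <- fus$lambda_b * bf$brics$embedding +
    fus$lambda_m * bf$murcko$embedding +
    fus$lambda_f * bf$fg$embedding
  zin <- c(ba$embedding, e_frag, md$ecfp)
  z <- drop(zin %*% params$head$W) + params$head$b
  list(prob = as.numeric(sigmoid(z)), logits = z, zin = zin,
       atom = ba, frag = bf)
}

# dz: gradient of the loss w.r.t. the T logits
model_backward <- function(params, md, fw, dz, config) {
  d <- length(fw$atom$embedding)
  g_head <- list(W = outer(fw$zin, dz), b = dz)
  dzin <- drop(params$head$W %*% dz)
  de_atom <- dzin[seq_len(d)]
  de_frag <- dzin[d + seq_len(d)]
  g_atom <- branch_backward(params$atom, md$atom, fw$atom$cache,
                            de_atom, config)$grads
  fus <- config$fusion
  lam <- c(brics = fus$lambda_b, murcko = fus$lambda_m, fg = fus$lambda_f)
  g_frag <- NULL
  for (v in names(md$frag)) {
    gv <- branch_backward(params$frag, md$frag[[v]], fw$frag[[v]]$cache,
                          lam[[v]] * de_frag, config)$grads
    g_frag <- if (is.null(g_frag)) gv else add_params(g_frag, gv)
  }
  list(atom = g_atom, frag = g_frag, head = g_head)
}

#' Full forward pass for one molecule
#'
#' Runs the atom branch on the molecular graph and the shared fragment
#' branch on each of the three fragment views, fuses the fragment
#' embeddings, and applies the prediction head.
#'
#' @param mol a \code{fatetox_molecule} with 3D coordinates.
#' @param params model parameters from \code{\link{init_fatetox_params}} or
#'   a fitted model's \code{$params}.
#' @param config a \code{\link{fatetox_config}}.
#' @return list with \code{probabilities} (length T), \code{attention}
#'   (per branch: per layer, per head combined attention matrices) and the
#'   three \code{fragment_views}.
#' @export
forward_molecule <- function(mol, params, config = fatetox_config()) {
  md <- compile_molecule(mol, config)
  fw <- model_forward(params, md, config)
  list(
    probabilities = fw$prob,
    attention = c(list(atom = fw$atom$attention),
                  lapply(fw$frag, `[[`, "attention")),
    fragment_views = md$views
  )
}
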