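# Dense-layer primitives with analytic backpropagation. Everything works on
# plain base-R matrices; parameters and gradients share one nested-list
# layout so they can be flattened with unlist() and rebuilt with relist().

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

# numerically stable row-wise softmax
softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# given P = softmax(S) by rows and dL/dP, return dL/dS
softmax_rows_backward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

# row-normalised adjacency; rows without any bond fall back to a
# self-attention weight of 1 on the diagonal
normalize_adjacency <- function(adjacency) {
  n <- nrow(adjacency)
  rs <- rowSums(adjacency)
  out <- adjacency / ifelse(rs > 0, rs, 1)
  for (i in seq_len(n)) if (rs[i] == 0) out[i, i] <- 1
  out
}

# -- layer norm (per row) ----------------------------------------------------

.LN_EPS <- 1e-5

layernorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  sd_ <- sqrt(v + .LN_EPS)
  xhat <- xc / sd_
  out <- sweep(xhat, 2, g, "*")
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(xhat = xhat, sd = sd_, g = g))
}

layernorm_backward <- function(cache, dout) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, cache$g, "*")
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dx = dx,
       dg = colSums(dout * xhat),
       db = colSums(dout))
}

# -- parameter initialisation ------------------------------------------------

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))),
         n_in, n_out)
}

zeros_like <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skeleton) utils::relist(v, skeleton)

add_params <- function(a, b) {
  if (is.list(a)) {
    out <- mapply(add_params, a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else {
    a + b
  }
}

scale_params <- function(p, s) rapply(p, function(x) x * s, how = "replace")
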