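#' Encoder configuration
#'
#' Hyperparameters of the cell-manifold encoder. `H` is the width of the
#' gene-name and expression embeddings; tokens live in `2H` because the
#' two embeddings are concatenated. The per-head dimension satisfies
#' `D * n_heads = 2H`.
#'
#' @param H Embedding width (default 256).
#' @param n_layers Number of graph-attention layers (default 6; reduce
#'   for CPU-scale experiments).
#' @param n_heads Attention heads (default 8).
#' @param coordinate_dim Cell-coordinate dimension (default 2048).
#' @param D_max Shortest-path distance cap (default 8); distances are
#'   bucketed as 0..D_max plus an unreachable sentinel and a dedicated
#'   CLS bucket.
#' @param max_train_genes Training-time cap on sampled genes (2048).
#' @param L Shifted-log normalization scale (1e4).
#' @param degree_cap Degrees are clipped to this bucket before the
#'   centrality-embedding lookup (default 64).
#' @param mlp_hidden Hidden width of the per-layer MLP (default `4H`).
#' @param decoder_hidden Hidden width of the reconstruction decoder
#'   (default `2H`).
#' @param pre_norm If `TRUE` (default) layer normalization and the MLP
#'   are applied before multihead self-attention; `FALSE` gives the
#'   conventional post-attention MLP ordering for ablation.
#' @return A `model_config` list with derived field `D = 2H / n_heads`.
#' @export
model_config <- function(H = 256, n_layers = 6, n_heads = 8,
                         coordinate_dim = 2048, D_max = 8,
                         max_train_genes = 2048, L = 1e4,
                         degree_cap = 64, mlp_hidden = NULL,
                         decoder_hidden = NULL, pre_norm = TRUE) {
  if ((2 * H) %% n_heads != 0)
    stop("n_heads must divide 2 * H")
  stopifnot(H > 0, n_layers >= 1, n_heads > 0, coordinate_dim > 0,
            D_max >= 1, max_train_genes >= 1, L > 0, degree_cap >= 1)
  structure(list(
    H = as.integer(H), n_layers = as.integer(n_layers),
    n_heads = as.integer(n_heads), D = as.integer(2 * H / n_heads),
    coordinate_dim = as.integer(coordinate_dim),
    D_max = as.integer(D_max),
    max_train_genes = as.integer(max_train_genes), L = L,
    degree_cap = as.integer(degree_cap),
    mlp_hidden = as.integer(if (is.null(mlp_hidden)) 4 * H else mlp_hidden),
    decoder_hidden = as.integer(if (is.null(decoder_hidden)) 2 * H
                                else decoder_hidden),
    pre_norm = isTRUE(pre_norm),
    # distance buckets: 0..D_max -> 1..D_max+1, unreachable -> D_max+2,
    # CLS pairs -> D_max+3
    n_dist_buckets = as.integer(D_max + 3)
  ), class = "model_config")
}

# fan-in (Xavier-style) scale by default: keeps activations and
# gradients O(1) through matrix products at any width
rmat <- function(nr, nc, sd = 1 / sqrt(nr)) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

#' Initialize encoder parameters
#'
#' All learnable tensors of the encoder: the gene-name embedding table
#' (one extra row for the CLS token), the expression projection, the CLS
#' expression vector, in/out-degree (centrality) embeddings with a
#' reserved CLS bucket, and per layer the layer norms, MLP, attention
#' projections and the per-head shortest-path bias table.
#'
#' @param config A [model_config].
#' @param n_genes Vocabulary size G.
#' @param seed Integer seed.
#' @param expr_center Typical non-zero normalized expression value of
#'   the training data. The expression-embedding bias is initialized to
#'   `-expr_center * w_expr`, so token embeddings start out centred:
#'   without this, every token's expression component points along the
#'   same direction with nearly the same magnitude and the per-token
#'   layer norm erases most of the expression signal.
#' @return A nested list of numeric arrays (`cmm_params`).
#' @export
init_cmm_params <- function(config, n_genes, seed = 1, expr_center = 0) {
  set.seed(as.integer(seed))
  H <- config$H; W <- 2L * H
  deg_rows <- config$degree_cap + 2L   # degrees 0..cap, then CLS bucket
  layers <- lapply(seq_len(config$n_layers), function(l) list(
    ln1_g = rep(1, W), ln1_b = rep(0, W),
    Wm1 = rmat(W, config$mlp_hidden), bm1 = rep(0, config$mlp_hidden),
    Wm2 = rmat(config$mlp_hidden, W), bm2 = rep(0, W),
    ln2_g = rep(1, W), ln2_b = rep(0, W),
    Wq = rmat(W, W), Wk = rmat(W, W), Wv = rmat(W, W),
    Wo = rmat(W, W), bo = rep(0, W),
    bias = matrix(0, config$n_dist_buckets, config$n_heads)
  ))
  structure(list(
    name_emb = rmat(n_genes + 1L, H, sd = 0.02),   # row 1 = CLS
    w_expr = w_expr <- stats::rnorm(H, sd = 0.02),
    b_expr = -expr_center * w_expr,
    cls_expr = stats::rnorm(H, sd = 0.02),
    z_in = rmat(deg_rows, W, sd = 0.02),
    z_out = rmat(deg_rows, W, sd = 0.02),
    layers = layers,
    ln_f_g = rep(1, W), ln_f_b = rep(0, W),
    Wp = rmat(W, config$coordinate_dim),
    bp = rep(0, config$coordinate_dim),
    n_genes = n_genes
  ), class = "cmm_params")
}

# ---- generic parameter-tree helpers (used by the Adam optimizer) -------

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b)))
      b <- b[names(a)]
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    attributes(out) <- attributes(a)
    out
  } else f(a)
}

tree_zero <- function(a) tree_map(a, function(x) x * 0)

tree_add <- function(a, b) tree_map2(a, b, `+`)

#' @keywords internal
adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

# One Adam update; `params` and `grads` are congruent numeric trees.
# Non-numeric leaves (e.g. bookkeeping scalars) are passed through.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads,
                       function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads,
                       function(v, g) beta2 * v + (1 - beta2) * g * g)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

# ---- numerical primitives with hand-written backward passes ------------

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * invstd
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  d <- ncol(xhat)
  dxhat <- sweep(dy, 2, g, `*`)
  dx <- (dxhat - rowMeans(dxhat) -
           xhat * rowMeans(dxhat * xhat)) * cache$invstd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu_fwd <- function(x) x * stats::pnorm(x)

gelu_bwd <- function(x, dy) dy * (stats::pnorm(x) + x * stats::dnorm(x))

softmax_rows <- function(a) {
  m <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  e <- exp(a - m)
  e / rowSums(e)
}
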