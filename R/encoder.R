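# Graph-aware transformer encoder: forward pass and hand-written
# reverse-mode gradients. Tokens are [CLS] + the cell's (sampled)
# non-zero genes; every state lives in 2H (name embedding ++ expression
# embedding). The prior graph enters twice: learnable in/out-degree
# embeddings added to token states (centrality encoding) and a per-head
# learnable scalar bias over shortest-path distance buckets added to the
# attention logits (spatial encoding).

# distance-bucket index into the bias table: d in 0..D_max -> d+1,
# unreachable -> D_max+2, any pair involving CLS -> D_max+3
dist_to_bucket_idx <- function(S, config) {
  n <- nrow(S) + 1L
  unreach <- attr(S, "unreachable")
  idx <- matrix(config$D_max + 3L, n, n)   # CLS bucket everywhere first
  inner <- S + 1L
  inner[S == unreach] <- config$D_max + 2L
  idx[-1, -1] <- inner
  idx
}

degree_bucket_rows <- function(deg, config) {
  pmin(deg, config$degree_cap) + 1L
}

# Per-cell token features: gene indices (0 = CLS), normalized
# expression, degree-bucket rows and the distance-bucket index matrix,
# all computed on the cell-specific subgraph restricted to the sampled
# genes.
token_features <- function(cell_raw, cell_norm, graph, config,
                           training = FALSE, seed = 1) {
  genes <- sample_nonzero_genes(cell_raw, config$max_train_genes,
                                seed = seed, training = training)
  sub <- cell_specific_subgraph(graph, cell_raw)
  sub_idx <- match(graph$gene_ids[genes], sub$gene_ids)
  deg <- compute_degrees(sub)
  S <- shortest_path_buckets(sub, sub_idx, config$D_max)
  cls_deg_row <- config$degree_cap + 2L
  list(
    genes = genes,
    n_tokens = length(genes) + 1L,
    xnorm = c(0, cell_norm[genes]),
    deg_in = c(cls_deg_row, degree_bucket_rows(deg$in_degree[sub_idx],
                                               config)),
    deg_out = c(cls_deg_row, degree_bucket_rows(deg$out_degree[sub_idx],
                                                config)),
    dist_idx = dist_to_bucket_idx(S, config)
  )
}

input_embedding <- function(feat, params) {
  n <- feat$n_tokens
  name_part <- params$name_emb[c(1L, feat$genes + 1L), , drop = FALSE]
  expr_part <- outer(feat$xnorm, params$w_expr) +
    rep(params$b_expr, each = n)
  expr_part[1, ] <- params$cls_expr
  cbind(name_part, expr_part)
}

attn_sub_fwd <- function(x, lp, ln_g, ln_b, bias, dist_idx, mask, config) {
  ln <- layernorm_fwd(x, ln_g, ln_b)
  X <- ln$y
  n <- nrow(X); D <- config$D
  Q <- X %*% lp$Wq; K <- X %*% lp$Wk; V <- X %*% lp$Wv
  Oc <- matrix(0, n, ncol(X))
  Ps <- vector("list", config$n_heads)
  masked <- !all(mask)
  for (i in seq_len(config$n_heads)) {
    cols <- ((i - 1L) * D + 1L):(i * D)
    A <- tcrossprod(Q[, cols, drop = FALSE],
                    K[, cols, drop = FALSE]) / sqrt(D)
    A <- A + matrix(bias[dist_idx, i], n, n)
    if (masked) A[, !mask] <- -Inf
    P <- softmax_rows(A)
    Ps[[i]] <- P
    Oc[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  y <- Oc %*% lp$Wo + rep(lp$bo, each = n)
  if (masked) y[!mask, ] <- 0
  list(y = y, ln = ln, X = X, Q = Q, K = K, V = V, P = Ps, Oc = Oc)
}

attn_sub_bwd <- function(dy, cache, lp, ln_g, dist_idx, mask, config) {
  if (!all(mask)) dy[!mask, ] <- 0
  X <- cache$X; D <- config$D
  dWo <- crossprod(cache$Oc, dy)
  dbo <- colSums(dy)
  dOc <- tcrossprod(dy, lp$Wo)
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- dQ; dV <- dQ
  dbias <- matrix(0, nrow(lp$bias), ncol(lp$bias))
  for (i in seq_len(config$n_heads)) {
    cols <- ((i - 1L) * D + 1L):(i * D)
    P <- cache$P[[i]]
    dP <- tcrossprod(dOc[, cols, drop = FALSE],
                     cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(P, dOc[, cols, drop = FALSE])
    dA <- P * (dP - rowSums(dP * P))
    s <- rowsum(as.vector(dA), group = as.vector(dist_idx))
    gi <- as.integer(rownames(s))
    dbias[gi, i] <- dbias[gi, i] + s[, 1]
    dQ[, cols] <- (dA %*% cache$K[, cols, drop = FALSE]) / sqrt(D)
    dK[, cols] <- crossprod(dA, cache$Q[, cols, drop = FALSE]) / sqrt(D)
  }
  dX <- tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
    tcrossprod(dV, lp$Wv)
  lnb <- layernorm_bwd(dX, cache$ln, ln_g)
  list(dx = lnb$dx,
       Wq = crossprod(X, dQ), Wk = crossprod(X, dK),
       Wv = crossprod(X, dV), Wo = dWo, bo = dbo, bias = dbias,
       ln_g = lnb$dg, ln_b = lnb$db)
}

mlp_sub_fwd <- function(x, lp, ln_g, ln_b, mask) {
  ln <- layernorm_fwd(x, ln_g, ln_b)
  X <- ln$y
  n <- nrow(X)
  m1 <- X %*% lp$Wm1 + rep(lp$bm1, each = n)
  a1 <- gelu_fwd(m1)
  y <- a1 %*% lp$Wm2 + rep(lp$bm2, each = n)
  if (!all(mask)) y[!mask, ] <- 0
  list(y = y, ln = ln, X = X, m1 = m1, a1 = a1)
}

mlp_sub_bwd <- function(dy, cache, lp, ln_g, mask) {
  if (!all(mask)) dy[!mask, ] <- 0
  dWm2 <- crossprod(cache$a1, dy)
  dbm2 <- colSums(dy)
  da1 <- tcrossprod(dy, lp$Wm2)
  dm1 <- gelu_bwd(cache$m1, da1)
  dWm1 <- crossprod(cache$X, dm1)
  dbm1 <- colSums(dm1)
  dX <- tcrossprod(dm1, lp$Wm1)
  lnb <- layernorm_bwd(dX, cache$ln, ln_g)
  list(dx = lnb$dx, Wm1 = dWm1, bm1 = dbm1, Wm2 = dWm2, bm2 = dbm2,
       ln_g = lnb$dg, ln_b = lnb$db)
}


sub_attn_fwd <- function(x, lp, ln_g, ln_b, dist_idx, mask, config) {
  if (backend_cpp()) {
    out <- .cpp_attn_fwd(x, lp$Wq, lp$Wk, lp$Wv, lp$Wo, lp$bo, lp$bias,
                         dist_idx, mask, ln_g, ln_b, config$n_heads,
                         config$D)
    out$backend <- "cpp"
    out
  } else {
    out <- attn_sub_fwd(x, lp, ln_g, ln_b, lp$bias, dist_idx, mask, config)
    out$backend <- "r"
    out
  }
}

sub_attn_bwd <- function(dy, cache, lp, ln_g, dist_idx, mask, config) {
  if (identical(cache$backend, "cpp"))
    .cpp_attn_bwd(dy, cache, lp$Wq, lp$Wk, lp$Wv, lp$Wo, lp$bias,
                  dist_idx, mask, ln_g, config$n_heads, config$D)
  else
    attn_sub_bwd(dy, cache, lp, ln_g, dist_idx, mask, config)
}

sub_mlp_fwd <- function(x, lp, ln_g, ln_b, mask) {
  if (backend_cpp()) {
    out <- .cpp_mlp_fwd(x, lp$Wm1, lp$bm1, lp$Wm2, lp$bm2, ln_g, ln_b,
                        mask)
    out$backend <- "cpp"
    out
  } else {
    out <- mlp_sub_fwd(x, lp, ln_g, ln_b, mask)
    out$backend <- "r"
    out
  }
}

sub_mlp_bwd <- function(dy, cache, lp, ln_g, mask) {
  if (identical(cache$backend, "cpp"))
    .cpp_mlp_bwd(dy, cache, lp$Wm1, lp$Wm2, ln_g, mask)
  else
    mlp_sub_bwd(dy, cache, lp, ln_g, mask)
}

layer_fwd <- function(h, lp, params, feat, mask, config) {
  Z <- params$z_in[feat$deg_in, , drop = FALSE] +
    params$z_out[feat$deg_out, , drop = FALSE]
  h0 <- h + Z
  if (config$pre_norm) {
    s1 <- sub_mlp_fwd(h0, lp, lp$ln1_g, lp$ln1_b, mask)
    h1 <- h0 + s1$y
    s2 <- sub_attn_fwd(h1, lp, lp$ln2_g, lp$ln2_b, feat$dist_idx, mask,
                       config)
    h2 <- h1 + s2$y
  } else {
    s1 <- sub_attn_fwd(h0, lp, lp$ln1_g, lp$ln1_b, feat$dist_idx, mask,
                       config)
    h1 <- h0 + s1$y
    s2 <- sub_mlp_fwd(h1, lp, lp$ln2_g, lp$ln2_b, mask)
    h2 <- h1 + s2$y
  }
  list(h = h2, s1 = s1, s2 = s2)
}

layer_bwd <- function(dh2, cache, lp, feat, mask, config) {
  if (config$pre_norm) {
    b2 <- sub_attn_bwd(dh2, cache$s2, lp, lp$ln2_g, feat$dist_idx, mask,
                       config)
    dh1 <- dh2 + b2$dx
    b1 <- sub_mlp_bwd(dh1, cache$s1, lp, lp$ln1_g, mask)
    dh0 <- dh1 + b1$dx
    g <- list(ln1_g = b1$ln_g, ln1_b = b1$ln_b,
              Wm1 = b1$Wm1, bm1 = b1$bm1, Wm2 = b1$Wm2, bm2 = b1$bm2,
              ln2_g = b2$ln_g, ln2_b = b2$ln_b,
              Wq = b2$Wq, Wk = b2$Wk, Wv = b2$Wv, Wo = b2$Wo,
              bo = b2$bo, bias = b2$bias)
  } else {
    b2 <- sub_mlp_bwd(dh2, cache$s2, lp, lp$ln2_g, mask)
    dh1 <- dh2 + b2$dx
    b1 <- sub_attn_bwd(dh1, cache$s1, lp, lp$ln1_g, feat$dist_idx, mask,
                       config)
    dh0 <- dh1 + b1$dx
    g <- list(ln1_g = b1$ln_g, ln1_b = b1$ln_b,
              Wm1 = b2$Wm1, bm1 = b2$bm1, Wm2 = b2$Wm2, bm2 = b2$bm2,
              ln2_g = b2$ln_g, ln2_b = b2$ln_b,
              Wq = b1$Wq, Wk = b1$Wk, Wv = b1$Wv, Wo = b1$Wo,
              bo = b1$bo, bias = b1$bias)
  }
  list(dh = dh0, dZ = dh0, grads = g)
}

encode_forward <- function(feat, params, config, mask = NULL) {
  n <- feat$n_tokens
  if (is.null(mask)) mask <- rep(TRUE, n)
  h <- input_embedding(feat, params)
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    st <- layer_fwd(h, params$layers[[l]], params, feat, mask, config)
    caches[[l]] <- st
    h <- st$h
  }
  # final layer norm before the CLS projection keeps the coordinate
  # scale O(1) at initialization (standard for pre-norm transformers)
  lnf <- layernorm_fwd(h, params$ln_f_g, params$ln_f_b)
  coord <- drop(lnf$y[1, ] %*% params$Wp) + params$bp
  list(coord = coord, h_final = h, lnf = lnf, caches = caches,
       mask = mask)
}

encode_backward <- function(fwd, dcoord, feat, params, config) {
  mask <- fwd$mask
  grads <- tree_zero(params)
  grads$Wp <- outer(fwd$lnf$y[1, ], dcoord)
  grads$bp <- dcoord
  dy_ln <- matrix(0, feat$n_tokens, 2L * config$H)
  dy_ln[1, ] <- drop(params$Wp %*% dcoord)
  lnb <- layernorm_bwd(dy_ln, fwd$lnf, params$ln_f_g)
  grads$ln_f_g <- lnb$dg
  grads$ln_f_b <- lnb$db
  dh <- lnb$dx
  for (l in rev(seq_len(config$n_layers))) {
    lb <- layer_bwd(dh, fwd$caches[[l]], params$layers[[l]], feat, mask,
                    config)
    grads$layers[[l]] <- lb$grads
    dZ <- lb$dZ
    if (!all(mask)) dZ[!mask, ] <- 0
    grads$z_in <- scatter_add_rows(grads$z_in, feat$deg_in, dZ)
    grads$z_out <- scatter_add_rows(grads$z_out, feat$deg_out, dZ)
    dh <- lb$dh
  }
  if (!all(mask)) dh[!mask, ] <- 0
  H <- config$H
  dname <- dh[, seq_len(H), drop = FALSE]
  dexpr <- dh[, H + seq_len(H), drop = FALSE]
  grads$name_emb <- scatter_add_rows(grads$name_emb,
                                     c(1L, feat$genes + 1L), dname)
  grads$cls_expr <- dexpr[1, ]
  if (feat$n_tokens > 1L) {
    dg <- dexpr[-1, , drop = FALSE]
    grads$w_expr <- colSums(dg * feat$xnorm[-1])
    grads$b_expr <- colSums(dg)
  }
  grads
}

scatter_add_rows <- function(M, idx, rows) {
  s <- rowsum(rows, group = idx)
  gi <- as.integer(rownames(s))
  M[gi, ] <- M[gi, , drop = FALSE] + s
  M
}

#' One GeneGraph attention layer (forward)
#'
#' Exposed for inspection and testing: applies centrality encoding, the
#' pre- (or post-) norm MLP and biased multihead self-attention to a
#' matrix of token states. Padded positions (where `mask` is `FALSE`)
#' receive no attention mass and emit unchanged states.
#'
#' @param states n x 2H matrix of token states.
#' @param deg_in,deg_out Integer degree-bucket rows per token (as
#'   produced internally; degree d maps to row d+1, CLS to the reserved
#'   last row).
#' @param dist_idx n x n integer matrix of distance-bucket rows into the
#'   layer's bias table.
#' @param layer_params One element of `cmm_params$layers`.
#' @param params The full `cmm_params` (for the shared centrality
#'   tables).
#' @param config A [model_config].
#' @param mask Logical vector, `TRUE` for real tokens.
#' @param return_attention If `TRUE`, attach the per-head attention
#'   matrices as attribute `"attention"`.
#' @return n x 2H matrix of updated states.
#' @export
genegraph_attention_layer <- function(states, deg_in, deg_out, dist_idx,
                                      layer_params, params, config,
                                      mask = rep(TRUE, nrow(states)),
                                      return_attention = FALSE) {
  if (ncol(states) != 2L * config$H) stop("states must have 2H columns")
  if (nrow(dist_idx) != nrow(states)) stop("dist_idx/state shape mismatch")
  feat <- list(deg_in = deg_in, deg_out = deg_out, dist_idx = dist_idx)
  st <- layer_fwd(states, layer_params, params, feat, mask, config)
  out <- st$h
  if (return_attention) {
    cache <- if (config$pre_norm) st$s2 else st$s1
    attn <- if (identical(cache$backend, "cpp"))
      lapply(seq_len(config$n_heads), function(i) cache$P[, , i])
    else cache$P
    attr(out, "attention") <- attn
  }
  out
}

#' Encode one cell to its coordinate
#'
#' Runs the full encoder on one cell: token construction (CLS + sampled
#' non-zero genes), graph featurization on the cell-specific subgraph,
#' `n_layers` GeneGraph attention layers, and the final projection of
#' the CLS state to `coordinate_dim`. Deterministic given parameters and
#' the sampled gene set; invariant to the order of the input genes.
#'
#' @param cell Numeric vector of raw counts for one cell, aligned with
#'   the graph vocabulary.
#' @param graph A [gene_graph] over the expression vocabulary.
#' @param params A `cmm_params` object.
#' @param config A [model_config].
#' @param training If `TRUE`, subsample genes (see
#'   [sample_nonzero_genes()]).
#' @param seed Seed for the training-time gene subsample.
#' @return Numeric vector of length `coordinate_dim` with attributes
#'   `"n_genes_used"`.
#' @export
encode_cell <- function(cell, graph, params, config, training = FALSE,
                        seed = 1) {
  cn <- log1p(config$L * cell / sum(cell))
  feat <- token_features(cell, cn, graph, config, training = training,
                         seed = seed)
  fwd <- encode_forward(feat, params, config)
  structure(fwd$coord, n_genes_used = feat$n_tokens - 1L)
}

#' Build a padded token batch
#'
#' Assembles per-cell token features for a set of cells and pads them to
#' a common length with an attention mask, for callers that want a
#' rectangular batch view. The encoder functions themselves consume the
#' per-cell features.
#'
#' @param counts A [cell_counts] object.
#' @param graph A [gene_graph].
#' @param config A [model_config].
#' @param training Training-time gene sampling flag.
#' @param seed Base seed; cell i uses `seed + i`.
#' @return List with `features` (per-cell feature lists), `token_genes`
#'   (cells x max_tokens matrix, NA = padding), and `mask` (logical
#'   matrix, TRUE = real token).
#' @export
build_token_batch <- function(counts, graph, config, training = FALSE,
                              seed = 1) {
  stopifnot(inherits(counts, "cell_counts"))
  norm <- shifted_log_normalize(counts, config$L)
  feats <- lapply(seq_len(nrow(counts$counts)), function(i)
    token_features(counts$counts[i, ], norm$values[i, ], graph, config,
                   training = training, seed = seed + i))
  nmax <- max(vapply(feats, `[[`, integer(1), "n_tokens"))
  token_genes <- matrix(NA_integer_, length(feats), nmax)
  mask <- matrix(FALSE, length(feats), nmax)
  for (i in seq_along(feats)) {
    n <- feats[[i]]$n_tokens
    token_genes[i, seq_len(n)] <- c(0L, feats[[i]]$genes)
    mask[i, seq_len(n)] <- TRUE
  }
  list(features = feats, token_genes = token_genes, mask = mask)
}
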