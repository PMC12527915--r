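ns <- asNamespace("drivergraph")

test_that("model_config validates and derives the per-head width", {
  cfg <- model_config()
  expect_equal(cfg$D * cfg$n_heads, 2 * cfg$H)
  expect_equal(cfg$coordinate_dim, 2048)
  expect_equal(cfg$n_layers, 6)
  expect_error(model_config(H = 10, n_heads = 7), "divide")
})

test_that("token batches put CLS first and mask padding", {
  cfg <- small_config()
  g <- chain_graph()
  counts <- cell_counts(matrix(c(1, 2, 3,
                                 0, 5, 0), 2, byrow = TRUE),
                        gene_ids = c("A", "B", "C"))
  tb <- build_token_batch(counts, g, cfg)
  expect_equal(tb$token_genes[1, 1], 0L)   # CLS sentinel
  expect_equal(sum(tb$mask[1, ]), 4)       # CLS + 3 genes
  expect_equal(sum(tb$mask[2, ]), 2)       # CLS + 1 gene
  expect_true(all(is.na(tb$token_genes[2, 3:4])))
  # distance matrix of cell 1 covers CLS + genes, CLS bucket reserved
  f <- tb$features[[1]]
  expect_equal(dim(f$dist_idx), c(4, 4))
  expect_true(all(f$dist_idx[1, ] == cfg$D_max + 3L))
})

test_that("cell coordinates have the configured length (2048 by default)", {
  g <- chain_graph()
  params_big <- init_cmm_params(model_config(n_layers = 1), 3, seed = 1)
  co <- encode_cell(c(1, 2, 3), g, params_big, model_config(n_layers = 1))
  expect_length(as.numeric(co), 2048)
  expect_true(all(is.finite(co)))
})

test_that("encoding is deterministic and permutation-invariant", {
  cfg <- small_config()
  G <- 15
  g <- random_digraph(G, 0.2, seed = 2)
  cell <- random_cell(G, seed = 3)
  params <- init_cmm_params(cfg, G, seed = 4)
  c1 <- encode_cell(cell, g, params, cfg)
  c2 <- encode_cell(cell, g, params, cfg)
  expect_identical(as.numeric(c1), as.numeric(c2))

  # permute token order (keeping CLS first) with consistent features:
  # coordinate must be unchanged up to numerical noise
  cn <- log1p(cfg$L * cell / sum(cell))
  feat <- ns$token_features(cell, cn, g, cfg)
  n <- feat$n_tokens
  set.seed(9)
  perm <- c(1L, 1L + sample(n - 1L))
  pfeat <- list(genes = feat$genes[perm[-1] - 1L], n_tokens = n,
                xnorm = feat$xnorm[perm],
                deg_in = feat$deg_in[perm], deg_out = feat$deg_out[perm],
                dist_idx = feat$dist_idx[perm, perm])
  f1 <- ns$encode_forward(feat, params, cfg)
  f2 <- ns$encode_forward(pfeat, params, cfg)
  rel <- sqrt(sum((f1$coord - f2$coord)^2)) /
    max(sqrt(sum(f1$coord^2)), 1e-12)
  expect_lt(rel, 1e-5)
})

test_that("padded tokens never change real-token outputs", {
  cfg <- small_config()
  G <- 12
  g <- random_digraph(G, 0.25, seed = 5)
  cell <- random_cell(G, seed = 6)
  params <- init_cmm_params(cfg, G, seed = 7)
  cn <- log1p(cfg$L * cell / sum(cell))
  feat <- ns$token_features(cell, cn, g, cfg)
  n <- feat$n_tokens
  fwd <- ns$encode_forward(feat, params, cfg)

  n_pad <- 3L
  pfeat <- list(genes = c(feat$genes, rep(feat$genes[1], n_pad)),
                n_tokens = n + n_pad,
                xnorm = c(feat$xnorm, rep(1, n_pad)),
                deg_in = c(feat$deg_in, rep(1L, n_pad)),
                deg_out = c(feat$deg_out, rep(1L, n_pad)),
                dist_idx = matrix(cfg$D_max + 2L, n + n_pad, n + n_pad))
  pfeat$dist_idx[seq_len(n), seq_len(n)] <- feat$dist_idx
  mask <- c(rep(TRUE, n), rep(FALSE, n_pad))
  pfwd <- ns$encode_forward(pfeat, params, cfg, mask = mask)
  expect_lt(max(abs(pfwd$h_final[seq_len(n), ] - fwd$h_final)), 1e-6)
  expect_lt(max(abs(pfwd$coord - fwd$coord)), 1e-6)
})

test_that("attention rows are normalized and reduce to uniform for constant logits", {
  cfg <- small_config()
  n <- 6
  W <- 2 * cfg$H
  params <- init_cmm_params(cfg, 10, seed = 3)
  lp <- params$layers[[1]]
  states <- matrix(rnorm(n * W), n, W)
  dist_idx <- matrix(1L, n, n)
  out <- genegraph_attention_layer(states, rep(1L, n), rep(1L, n),
                                   dist_idx, lp, params, cfg,
                                   return_attention = TRUE)
  for (P in attr(out, "attention"))
    expect_equal(rowSums(P), rep(1, n), tolerance = 1e-6)

  # identical tokens and a constant bias table give exactly uniform rows
  lp0 <- lp
  lp0$bias[] <- 0
  same <- matrix(rep(rnorm(W), each = n), n, W)
  out2 <- genegraph_attention_layer(same, rep(1L, n), rep(1L, n),
                                    dist_idx, lp0, params, cfg,
                                    return_attention = TRUE)
  for (P in attr(out2, "attention"))
    expect_equal(P, matrix(1 / n, n, n), tolerance = 1e-6)

  # equal graph distances receive identical bias terms: with tokens
  # varying, rows still sum to 1 and bias enters through the lookup only
  expect_error(genegraph_attention_layer(states[, 1:3], rep(1L, n),
                                         rep(1L, n), dist_idx, lp,
                                         params, cfg),
               "2H")
})

test_that("with a fully connected graph the layer matches a plain transformer", {
  # uniform degrees + constant bias table: graph terms are constant,
  # so the layer must equal an independently coded standard pre-norm
  # transformer layer up to the constant centrality shift
  cfg <- small_config()
  G <- 9
  fc <- make_variant(random_digraph(G, 0.2, seed = 11), "fully_connected")
  cell <- rep(2, G)
  params <- init_cmm_params(cfg, G, seed = 12)
  lp <- params$layers[[1]]
  lp$bias[] <- 0.37          # constant over all distance buckets
  params$layers[[1]] <- lp

  cn <- log1p(cfg$L * cell / sum(cell))
  feat <- ns$token_features(cell, cn, fc, cfg)
  n <- feat$n_tokens
  expect_true(all(feat$deg_in[-1] == feat$deg_in[2]))  # uniform degrees

  h0 <- ns$input_embedding(feat, params)
  got <- ns$layer_fwd(h0, lp, params, feat, rep(TRUE, n), cfg)$h

  # independent plain-attention oracle (base R, no package internals)
  Zc <- params$z_in[feat$deg_in, ] + params$z_out[feat$deg_out, ]
  x0 <- h0 + Zc
  ln <- function(x, g, b) {
    mu <- rowMeans(x); v <- rowMeans((x - mu)^2)
    ((x - mu) / sqrt(v + 1e-5)) * rep(g, each = nrow(x)) +
      rep(b, each = nrow(x))
  }
  gelu <- function(x) x * pnorm(x)
  l1 <- ln(x0, lp$ln1_g, lp$ln1_b)
  x1 <- x0 + gelu(l1 %*% lp$Wm1 + rep(lp$bm1, each = n)) %*% lp$Wm2 +
    rep(lp$bm2, each = n)
  l2 <- ln(x1, lp$ln2_g, lp$ln2_b)
  D <- cfg$D
  O <- matrix(0, n, 2 * cfg$H)
  for (i in seq_len(cfg$n_heads)) {
    cols <- ((i - 1) * D + 1):(i * D)
    Q <- l2 %*% lp$Wq; K <- l2 %*% lp$Wk; V <- l2 %*% lp$Wv
    S <- Q[, cols] %*% t(K[, cols]) / sqrt(D) + 0.37
    P <- exp(S - apply(S, 1, max))
    P <- P / rowSums(P)
    O[, cols] <- P %*% V[, cols]
  }
  want <- x1 + O %*% lp$Wo + rep(lp$bo, each = n)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("compiled and reference sublayers are numerically identical", {
  cfg <- small_config()
  G <- 14
  g <- random_digraph(G, 0.25, seed = 21)
  cell <- random_cell(G, seed = 22)
  params <- init_cmm_params(cfg, G, seed = 23)
  cn <- log1p(cfg$L * cell / sum(cell))
  feat <- ns$token_features(cell, cn, g, cfg)
  dco <- rnorm(cfg$coordinate_dim)
  res <- lapply(c("cpp", "r"), function(be) {
    withr::local_options(drivergraph.backend = be)
    fwd <- ns$encode_forward(feat, params, cfg)
    list(coord = fwd$coord,
         grads = ns$encode_backward(fwd, dco, feat, params, cfg))
  })
  expect_equal(res[[1]]$coord, res[[2]]$coord, tolerance = 1e-12)
  expect_equal(res[[1]]$grads, res[[2]]$grads, tolerance = 1e-10)
})

test_that("analytic encoder gradients match finite differences", {
  cfg <- small_config()
  G <- 10
  g <- random_digraph(G, 0.25, seed = 31)
  cell <- random_cell(G, seed = 32)
  params <- init_cmm_params(cfg, G, seed = 33)
  cn <- log1p(cfg$L * cell / sum(cell))
  feat <- ns$token_features(cell, cn, g, cfg)
  target <- rnorm(cfg$coordinate_dim)
  obj <- function(p) {
    sum((ns$encode_forward(feat, p, cfg)$coord - target)^2)
  }
  fwd <- ns$encode_forward(feat, params, cfg)
  grads <- ns$encode_backward(fwd, 2 * (fwd$coord - target), feat,
                              params, cfg)
  # directional derivative along a random direction in parameter space
  set.seed(34)
  dir <- ns$tree_map(params, function(x) {
    d <- rnorm(length(x))
    if (!is.null(dim(x))) dim(d) <- dim(x)
    d
  })
  dot <- 0
  acc <- function(a, b) {
    if (is.list(a)) mapply(acc, a, b)
    else dot <<- dot + sum(a * b)
    invisible(NULL)
  }
  acc(grads, dir)
  eps <- 1e-5
  up <- ns$tree_map2(params, dir, function(x, d) x + eps * d)
  dn <- ns$tree_map2(params, dir, function(x, d) x - eps * d)
  numeric_dd <- (obj(up) - obj(dn)) / (2 * eps)
  expect_equal(dot, numeric_dd, tolerance = 1e-6)
})

test_that("post-norm layer ordering is available and differs from pre-norm", {
  G <- 8
  g <- random_digraph(G, 0.3, seed = 41)
  cell <- random_cell(G, seed = 42)
  pre <- small_config()
  post <- small_config(pre_norm = FALSE)
  p1 <- init_cmm_params(pre, G, seed = 43)
  c_pre <- encode_cell(cell, g, p1, pre)
  c_post <- encode_cell(cell, g, p1, post)
  expect_false(isTRUE(all.equal(as.numeric(c_pre), as.numeric(c_post))))
})
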