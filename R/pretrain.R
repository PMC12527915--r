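# Downsampling-reconstruction pretraining: a binomially thinned profile
# is encoded to a cell coordinate, and a two-layer MLP decoder must
# recover the cell's original expression gene by gene from
# (coordinate ++ gene-name embedding).

#' Initialize decoder parameters
#'
#' Two linear layers with a GELU in between. The input is the
#' concatenation of a cell coordinate and one gene-name embedding; the
#' output is the predicted expression of that gene.
#'
#' @param config A [model_config].
#' @param seed Integer seed.
#' @return A `decoder_params` list.
#' @export
init_decoder_params <- function(config, seed = 1) {
  set.seed(as.integer(seed))
  d_in <- config$coordinate_dim + config$H
  structure(list(
    Wd1 = rmat(d_in, config$decoder_hidden),
    bd1 = rep(0, config$decoder_hidden),
    Wd2 = rmat(config$decoder_hidden, 1L),
    bd2 = 0
  ), class = "decoder_params")
}

decoder_fwd <- function(coord, gene_idx, cmm_params, decoder_params) {
  E <- cmm_params$name_emb[gene_idx + 1L, , drop = FALSE]
  n <- length(gene_idx)
  In <- cbind(matrix(coord, n, length(coord), byrow = TRUE), E)
  m1 <- In %*% decoder_params$Wd1 + rep(decoder_params$bd1, each = n)
  a1 <- gelu_fwd(m1)
  out <- drop(a1 %*% decoder_params$Wd2) + decoder_params$bd2
  list(out = out, In = In, m1 = m1, a1 = a1)
}

# returns gradients wrt decoder params, the coordinate and the queried
# name-embedding rows
decoder_bwd <- function(dout, cache, gene_idx, config, decoder_params) {
  dout <- matrix(dout, ncol = 1)
  dWd2 <- crossprod(cache$a1, dout)
  dbd2 <- sum(dout)
  da1 <- tcrossprod(dout, decoder_params$Wd2)
  dm1 <- gelu_bwd(cache$m1, da1)
  dWd1 <- crossprod(cache$In, dm1)
  dbd1 <- colSums(dm1)
  dIn <- tcrossprod(dm1, decoder_params$Wd1)
  C <- config$coordinate_dim
  list(Wd1 = dWd1, bd1 = dbd1, Wd2 = dWd2, bd2 = dbd2,
       dcoord = colSums(dIn[, seq_len(C), drop = FALSE]),
       dname = dIn[, C + seq_len(config$H), drop = FALSE])
}

#' Decode an expression profile from a cell coordinate
#'
#' For each queried gene, the decoder MLP maps the concatenation of the
#' cell coordinate and that gene's name embedding to one predicted
#' (shifted-log normalized) expression value.
#'
#' @param coordinate Numeric cell coordinate of length
#'   `coordinate_dim`.
#' @param gene_indices Integer gene indices (1-based into the
#'   vocabulary).
#' @param cmm_params Encoder parameters (for the shared name-embedding
#'   table).
#' @param decoder_params Decoder parameters.
#' @param config A [model_config].
#' @return Numeric vector, one predicted value per queried gene.
#' @export
decode_profile <- function(coordinate, gene_indices, cmm_params,
                           decoder_params, config) {
  gene_indices <- as.integer(gene_indices)
  if (any(gene_indices < 1) || any(gene_indices > cmm_params$n_genes))
    stop("gene index out of vocabulary range")
  if (length(coordinate) != config$coordinate_dim)
    stop("coordinate length does not match config")
  decoder_fwd(coordinate, gene_indices, cmm_params, decoder_params)$out
}

#' Reconstruction loss
#'
#' Mean over cells of the squared 2-norm of (predicted - target) over
#' the queried genes.
#'
#' @param predicted Numeric matrix (cells x queried genes) or vector for
#'   a single cell.
#' @param target Matrix or vector of the same shape, on the normalized
#'   expression scale.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(predicted, target) {
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  if (is.null(dim(target))) target <- matrix(target, nrow = 1)
  if (!all(dim(predicted) == dim(target)))
    stop("predicted/target shape mismatch")
  r <- predicted - target
  mean(rowSums(r * r))
}

# Query set for the decoder: the full vocabulary when it fits in the
# training token budget, otherwise the original profile's non-zero
# genes plus an equal-sized random sample of its zero genes.
decoder_query_genes <- function(cell_raw, config) {
  G <- length(cell_raw)
  if (G <= config$max_train_genes) return(seq_len(G))
  nz <- which(cell_raw > 0)
  z <- which(cell_raw == 0)
  sort(c(nz, sample(z, min(length(z), length(nz)))))
}

#' Pretrain the encoder by downsampling reconstruction
#'
#' Each step draws a downsampling rate r uniformly from
#' `rate_range = [1, 20)` per cell, thins the counts binomially, encodes
#' the thinned profile, decodes the queried genes and minimizes the
#' reconstruction loss against the cell's original profile. Both the
#' encoder and the decoder are optimized (Adam with linear warmup over
#' the first 5\% of steps). By default the reconstruction target is the
#' shifted-log normalized original profile; `target = "raw"` restores
#' literal raw-count targets.
#'
#' @param counts A [cell_counts] object.
#' @param graph A [gene_graph] over the same vocabulary.
#' @param config A [model_config].
#' @param epochs Training epochs (0 = return the initialization with an
#'   epoch-0 evaluation).
#' @param batch_size Cells per Adam step.
#' @param lr Peak learning rate.
#' @param seed Seed controlling initialization, splits, downsampling and
#'   shuffling; identical seeds give identical reports.
#' @param holdout_frac Fraction of cells held out for evaluation, in
#'   \[0, 0.5\].
#' @param rate_range Downsampling-rate range (uniform draw).
#' @param lr_decay Multiplicative learning-rate decay applied once per
#'   epoch (default 1 = constant rate after warmup).
#' @param target `"normalized"` (default) or `"raw"` reconstruction
#'   target.
#' @param verbose Print per-epoch losses.
#' @return List with `cmm` (encoder params), `decoder` (decoder params)
#'   and `report` (per-epoch mean training loss, held-out loss, held-out
#'   per-cell Pearson correlation and the config snapshot).
#' @export
pretrain <- function(counts, graph, config, epochs = 3, batch_size = 32,
                     lr = 1e-3, seed = 1, holdout_frac = 0.1,
                     rate_range = c(1, 20), lr_decay = 1,
                     target = c("normalized", "raw"),
                     verbose = FALSE) {
  stopifnot(inherits(counts, "cell_counts"), inherits(graph, "gene_graph"))
  target <- match.arg(target)
  if (holdout_frac < 0 || holdout_frac > 0.5)
    stop("holdout_frac must be in [0, 0.5]")
  N <- nrow(counts$counts)
  if (N < 2) stop("need at least 2 cells")
  G <- length(counts$gene_ids)
  if (!identical(counts$gene_ids, graph$gene_ids))
    stop("counts and graph vocabularies differ")

  set.seed(as.integer(seed))
  norm <- shifted_log_normalize(counts, config$L)
  params <- init_cmm_params(config, G, seed = seed,
                            expr_center = mean(norm$values[norm$values > 0]))
  dec <- init_decoder_params(config, seed = seed + 1L)
  targets <- if (target == "normalized") norm$values else counts$counts

  n_hold <- floor(holdout_frac * N)
  hold <- if (n_hold > 0) sort(sample(N, n_hold)) else integer(0)
  train_idx <- setdiff(seq_len(N), hold)

  opt <- adam_init(list(cmm = params, dec = dec))
  total_steps <- max(1, epochs * ceiling(length(train_idx) / batch_size))
  warmup <- max(1, ceiling(0.05 * total_steps))
  step <- 0L

  one_cell_loss <- function(i, params, dec, rate, with_grad = FALSE,
                            ds_seed = 0L) {
    raw <- counts$counts[i, ]
    thinned <- raw
    if (rate > 1) {
      nz <- which(raw > 0)
      thinned[nz] <- stats::rbinom(length(nz), as.integer(raw[nz]),
                                   1 / rate)
    }
    if (sum(thinned) == 0) return(NULL)   # fully thinned away; skip
    cn <- log1p(config$L * thinned / sum(thinned))
    feat <- token_features(thinned, cn, graph, config, training = TRUE,
                           seed = ds_seed)
    fwd <- encode_forward(feat, params, config)
    q <- decoder_query_genes(raw, config)
    dfwd <- decoder_fwd(fwd$coord, q, params, dec)
    resid <- dfwd$out - targets[i, q]
    loss <- sum(resid * resid)
    if (!with_grad)
      return(list(loss = loss, pred = dfwd$out, q = q))
    dout <- 2 * resid
    db <- decoder_bwd(dout, dfwd, q, config, dec)
    g_cmm <- encode_backward(fwd, db$dcoord, feat, params, config)
    g_cmm$name_emb <- scatter_add_rows(g_cmm$name_emb, q + 1L, db$dname)
    list(loss = loss,
         grads = list(cmm = g_cmm,
                      dec = list(Wd1 = db$Wd1, bd1 = db$bd1,
                                 Wd2 = db$Wd2, bd2 = db$bd2)))
  }

  eval_holdout <- function(params, dec, epoch) {
    if (length(hold) == 0)
      return(list(loss = NA_real_, pearson = NA_real_))
    set.seed(as.integer(seed) + 7919L * (epoch + 1L))
    losses <- numeric(0); cors <- numeric(0)
    for (i in hold) {
      rate <- stats::runif(1, rate_range[1], rate_range[2])
      r <- one_cell_loss(i, params, dec, rate, ds_seed = seed + i)
      if (is.null(r)) next
      losses <- c(losses, r$loss)
      if (stats::sd(r$pred) > 0 && stats::sd(targets[i, r$q]) > 0)
        cors <- c(cors, stats::cor(r$pred, targets[i, r$q]))
    }
    list(loss = mean(losses), pearson = mean(cors))
  }

  # epoch-0 evaluation: held-out metrics plus the pre-training loss on
  # a seeded subsample of training cells (the reference point for the
  # loss-halving property)
  eval_train0 <- function(params, dec) {
    set.seed(as.integer(seed) + 557L)
    idx <- if (length(train_idx) > 256) sort(sample(train_idx, 256))
           else train_idx
    rates <- stats::runif(length(idx), rate_range[1], rate_range[2])
    losses <- numeric(0)
    for (k in seq_along(idx)) {
      r <- one_cell_loss(idx[k], params, dec, rates[k],
                         ds_seed = seed + idx[k])
      if (!is.null(r)) losses <- c(losses, r$loss)
    }
    mean(losses)
  }
  report <- list(epoch = integer(0), train_loss = numeric(0),
                 holdout_loss = numeric(0), holdout_pearson = numeric(0))
  ev0 <- eval_holdout(params, dec, 0L)
  report$epoch <- 0L
  report$train_loss <- eval_train0(params, dec)
  report$holdout_loss <- ev0$loss
  report$holdout_pearson <- ev0$pearson

  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      set.seed(as.integer(seed) + 104729L * ep)
      order_idx <- sample(train_idx)
      rates <- stats::runif(length(order_idx), rate_range[1],
                            rate_range[2])
      ep_losses <- numeric(0)
      batches <- split(seq_along(order_idx),
                       ceiling(seq_along(order_idx) / batch_size))
      for (b in batches) {
        acc <- NULL; bl <- 0; nb <- 0L
        for (k in b) {
          r <- one_cell_loss(order_idx[k], params, dec, rates[k],
                             with_grad = TRUE,
                             ds_seed = seed + 31L * ep + order_idx[k])
          if (is.null(r)) next
          acc <- if (is.null(acc)) r$grads else tree_add(acc, r$grads)
          bl <- bl + r$loss; nb <- nb + 1L
        }
        if (nb == 0L) next
        acc <- tree_map(acc, function(x) x / nb)
        step <- step + 1L
        lr_t <- lr * lr_decay^(ep - 1) * min(1, step / warmup)
        upd <- adam_step(list(cmm = params, dec = dec), acc, opt, lr_t)
        params <- upd$params$cmm; dec <- upd$params$dec
        opt <- upd$state
        ep_losses <- c(ep_losses, bl / nb)
      }
      if (any(!is.finite(ep_losses)))
        stop("pretraining diverged: non-finite loss at epoch ", ep)
      ev <- eval_holdout(params, dec, ep)
      report$epoch <- c(report$epoch, ep)
      report$train_loss <- c(report$train_loss, mean(ep_losses))
      report$holdout_loss <- c(report$holdout_loss, ev$loss)
      report$holdout_pearson <- c(report$holdout_pearson, ev$pearson)
      if (verbose)
        message(sprintf("epoch %d: train %.3f holdout %.3f (r = %.3f)",
                        ep, mean(ep_losses), ev$loss, ev$pearson))
    }
  }
  list(cmm = params, decoder = dec,
       report = c(report, list(seed = seed, holdout_cells = hold,
                               config = config, target = target)))
}
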