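# Driver-gene predictor: a two-layer MLP over the concatenated source
# and target cell coordinates, trained with cross-entropy over the
# candidate (perturbation-pool) genes and fine-tuned jointly with the
# encoder. Classifier inputs are stabilized before the MLP: frozen
# feature variants standardize with training-set statistics, while the
# jointly trained model applies a parameter-free layer normalization
# (coordinates drift during fine-tuning, so fixed statistics cannot).

#' Initialize driver-gene predictor parameters
#'
#' @param config A [model_config].
#' @param candidates Character vector of candidate driver genes (the
#'   classifier's classes), length K >= 2.
#' @param input_dim Input width (2 x coordinate_dim for coordinate
#'   input; 2 x G for the no-CMM expression variant).
#' @param hidden Hidden width (default `coordinate_dim`); `0` gives a
#'   single linear layer (multinomial logistic regression, the no-DGP
#'   variant).
#' @param input_ln Apply parameter-free layer normalization to the
#'   input row (used by the jointly fine-tuned model).
#' @param center,scale Optional per-feature standardization vectors
#'   (training-set statistics; used by the frozen-feature variants).
#' @param seed Integer seed.
#' @return A `dgp_params` list.
#' @export
init_dgp_params <- function(config, candidates, input_dim = NULL,
                            hidden = NULL, input_ln = FALSE,
                            center = NULL, scale = NULL, seed = 1) {
  K <- length(candidates)
  if (K < 2) stop("need at least 2 candidate genes")
  if (is.null(input_dim)) input_dim <- 2L * config$coordinate_dim
  if (is.null(hidden)) hidden <- config$coordinate_dim
  set.seed(as.integer(seed))
  # the output layer starts at zero so the classifier begins exactly at
  # the uniform distribution (CE = log K). With a random output layer,
  # joint training finds a shortcut: collapsing the encoder's coordinate
  # variation drives the predictions to the prior and the loss to log K,
  # after which no signal remains. Zero output weights remove that
  # incentive; the head first aligns with the labels, then passes
  # informative gradients to the encoder.
  if (hidden > 0) {
    p <- list(W1 = rmat(input_dim, hidden), b1 = rep(0, hidden),
              W2 = matrix(0, hidden, K), b2 = rep(0, K))
  } else {
    p <- list(W2 = matrix(0, input_dim, K), b2 = rep(0, K))
  }
  p$candidates <- candidates
  p$input_ln <- isTRUE(input_ln)
  p$center <- center
  p$scale <- scale
  structure(p, class = "dgp_params")
}

# forward through optional standardization / input layer norm, then the
# MLP (or single linear layer); cache carries what backward needs
dgp_fwd <- function(z, p) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (!is.null(p$center))
    z <- sweep(sweep(z, 2, p$center), 2, pmax(p$scale, 1e-8), "/")
  ln <- NULL
  if (isTRUE(p$input_ln)) {
    ln <- layernorm_fwd(z, rep(1, ncol(z)), rep(0, ncol(z)))
    z <- ln$y
  }
  n <- nrow(z)
  if (!is.null(p$W1)) {
    m1 <- z %*% p$W1 + rep(p$b1, each = n)
    a1 <- gelu_fwd(m1)
    logits <- a1 %*% p$W2 + rep(p$b2, each = n)
    list(logits = logits, z = z, m1 = m1, a1 = a1, ln = ln)
  } else {
    list(logits = z %*% p$W2 + rep(p$b2, each = n), z = z, ln = ln)
  }
}

dgp_bwd <- function(dlogits, cache, p) {
  if (!is.null(p$W1)) {
    dW2 <- crossprod(cache$a1, dlogits)
    db2 <- colSums(dlogits)
    da1 <- tcrossprod(dlogits, p$W2)
    dm1 <- gelu_bwd(cache$m1, da1)
    dW1 <- crossprod(cache$z, dm1)
    db1 <- colSums(dm1)
    dz <- tcrossprod(dm1, p$W1)
    grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  } else {
    grads <- list(W2 = crossprod(cache$z, dlogits),
                  b2 = colSums(dlogits))
    dz <- tcrossprod(dlogits, p$W2)
  }
  if (!is.null(cache$ln))
    dz <- layernorm_bwd(dz, cache$ln, rep(1, ncol(dz)))$dx
  if (!is.null(p$center))   # chain through the fixed standardization
    dz <- sweep(dz, 2, pmax(p$scale, 1e-8), "/")
  list(grads = grads, dz = dz)
}

#' Cross-entropy driver loss
#'
#' `-log softmax(logits)[label]`: the negative log probability assigned
#' to the true driver.
#'
#' @param logits Numeric vector of K candidate logits.
#' @param label Integer index of the true driver in the candidate set.
#' @return Non-negative scalar.
#' @export
driver_loss <- function(logits, label) {
  label <- as.integer(label)
  if (label < 1 || label > length(logits)) stop("label out of range")
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[label]
}

#' Predict per-candidate driver likelihoods for one cell pair
#'
#' Encodes the source and target cells, concatenates their coordinates
#' and applies the classifier; the softmax output is the likelihood
#' score of each candidate gene being the driver of the transition.
#'
#' @param src,tgt Raw count vectors for the source and target cell.
#' @param graph A [gene_graph].
#' @param cmm_params Encoder parameters.
#' @param dgp_params Classifier parameters (coordinate input).
#' @param config A [model_config].
#' @return A `likelihood_vector`: named numeric vector of probabilities
#'   summing to one.
#' @export
predict_likelihoods <- function(src, tgt, graph, cmm_params, dgp_params,
                                config) {
  z <- c(encode_cell(src, graph, cmm_params, config),
         encode_cell(tgt, graph, cmm_params, config))
  expected <- if (!is.null(dgp_params$W1)) nrow(dgp_params$W1)
              else nrow(dgp_params$W2)
  if (length(z) != expected)
    stop("classifier input width does not match the candidate-set params")
  p <- drop(softmax_rows(dgp_fwd(z, dgp_params)$logits))
  structure(stats::setNames(p, dgp_params$candidates),
            class = "likelihood_vector")
}

#' Rank candidates by likelihood
#'
#' Dense ranks by descending probability; ties are broken by ascending
#' candidate index, so the output is always a permutation of 1..K.
#'
#' @param likelihoods Numeric vector of candidate probabilities.
#' @return Integer vector of ranks (1 = most likely), named like the
#'   input.
#' @export
rank_candidates <- function(likelihoods) {
  o <- order(-as.numeric(likelihoods), seq_along(likelihoods))
  r <- integer(length(o))
  r[o] <- seq_along(o)
  stats::setNames(r, names(likelihoods))
}

validate_pairs <- function(pairs, counts) {
  need <- c("source_id", "target_id", "driver", "split")
  if (!all(need %in% names(pairs)))
    stop("pairs needs columns: ", paste(need, collapse = ", "))
  if (!all(pairs$split %in% c("train", "test")))
    stop("split must be 'train' or 'test'")
  ids <- c(pairs$source_id, pairs$target_id)
  if (!all(ids %in% counts$cell_ids))
    stop("pair cell id(s) missing from the count matrix")
  key <- paste(pairs$source_id, pairs$target_id)
  leak <- intersect(key[pairs$split == "train"],
                    key[pairs$split == "test"])
  if (length(leak) > 0)
    stop("pair(s) present in both train and test splits: ",
         paste(utils::head(leak, 3), collapse = "; "))
  invisible(pairs)
}

# Precompute per-cell token features for every cell referenced in the
# pairs table. With G <= max_train_genes the training-time gene sample
# is the full non-zero set, so features are fixed across epochs.
pair_cell_features <- function(cells, counts, graph, config, seed) {
  norm <- shifted_log_normalize(counts, config$L)
  idx <- match(cells, counts$cell_ids)
  feats <- lapply(seq_along(cells), function(k) {
    i <- idx[k]
    token_features(counts$counts[i, ], norm$values[i, ], graph, config,
                   training = TRUE, seed = seed + i)
  })
  names(feats) <- cells
  feats
}

#' Fine-tune the encoder and driver-gene predictor
#'
#' Minimizes the mean cross-entropy of the true driver over the training
#' pairs (Adam, 5\% linear warmup). In the default `"full"` variant both
#' the encoder and the classifier are updated (set `freeze_cmm = TRUE`
#' to train the head only). The `"no_cmm"` ablation feeds concatenated
#' shifted-log expression vectors straight to the classifier MLP;
#' `"no_dgp"` trains a multinomial logistic regression on frozen
#' pretrained coordinates.
#'
#' @param pairs Data frame with columns `source_id`, `target_id`,
#'   `driver`, `split` (`"train"`/`"test"`).
#' @param counts A [cell_counts] containing all referenced cells.
#' @param graph A [gene_graph].
#' @param cmm_params Initial encoder parameters (typically pretrained;
#'   ignored by `"no_cmm"`).
#' @param config A [model_config].
#' @param epochs,batch_size,lr Optimization settings.
#' @param seed Integer seed; identical seeds give identical results.
#' @param freeze_cmm Keep encoder parameters fixed during training.
#' @param head_warmup_epochs Epochs of head-only training on the frozen
#'   initial coordinates before joint optimization begins (cheap: the
#'   coordinates are computed once and cached). Warm-starting the
#'   classifier this way gives the encoder label-informative gradients
#'   from the first joint step; starting both cold makes the easiest
#'   descent direction a collapse of the coordinate variation toward
#'   the uniform-output point.
#' @param joint_lr Learning rate of the joint phase (default `lr / 10`).
#'   The warm-started classifier is sensitive to coordinate drift, so
#'   the joint phase moves more slowly than the head-only phase.
#' @param variant `"full"`, `"no_cmm"` or `"no_dgp"`.
#' @param verbose Print per-epoch progress.
#' @return A `driver_model` list: `variant`, `cmm`, `dgp`, `config`,
#'   `candidates` and a `report` with per-epoch train loss and final
#'   train/test top-1/top-5 accuracies.
#' @export
finetune <- function(pairs, counts, graph, cmm_params, config,
                     epochs = 5, batch_size = 16, lr = 1e-3, seed = 1,
                     freeze_cmm = FALSE, head_warmup_epochs = 12,
                     joint_lr = NULL,
                     variant = c("full", "no_cmm", "no_dgp"),
                     verbose = FALSE) {
  variant <- match.arg(variant)
  validate_pairs(pairs, counts)
  train <- pairs[pairs$split == "train", , drop = FALSE]
  if (nrow(train) == 0) stop("train split is empty")
  candidates <- sort(unique(train$driver))
  if (!all(pairs$driver %in% candidates))
    warning("test split contains driver(s) absent from training")
  labels_all <- match(pairs$driver, candidates)

  cells <- unique(c(pairs$source_id, pairs$target_id))
  cell_idx <- match(cells, counts$cell_ids)
  train_cells <- unique(c(train$source_id, train$target_id))

  if (variant == "no_cmm") {
    norm <- shifted_log_normalize(counts, config$L)
    expr <- norm$values[cell_idx, , drop = FALSE]
    rownames(expr) <- cells
    tr_expr <- expr[train_cells, , drop = FALSE]
    dgp <- init_dgp_params(config, candidates,
                           input_dim = 2L * ncol(expr),
                           hidden = config$coordinate_dim,
                           center = rep(colMeans(tr_expr), 2),
                           scale = rep(apply(tr_expr, 2, stats::sd), 2),
                           seed = seed)
    fit <- fit_head_on_features(expr, pairs, candidates, dgp, epochs,
                                batch_size, lr, seed, verbose)
    model <- structure(list(variant = variant, cmm = NULL, dgp = fit$dgp,
                            config = config, candidates = candidates,
                            report = fit$report),
                       class = "driver_model")
    model$report <- c(model$report,
                      final_accuracy_report(model, pairs, counts, graph))
    return(model)
  }

  feats <- pair_cell_features(cells, counts, graph, config, seed)

  if (variant == "no_dgp") {
    coords <- t(vapply(feats, function(f)
      encode_forward(f, cmm_params, config)$coord,
      numeric(config$coordinate_dim)))
    rownames(coords) <- cells
    tr_co <- coords[train_cells, , drop = FALSE]
    dgp <- init_dgp_params(config, candidates,
                           input_dim = 2L * config$coordinate_dim,
                           hidden = 0L,
                           center = rep(colMeans(tr_co), 2),
                           scale = rep(apply(tr_co, 2, stats::sd), 2),
                           seed = seed)
    fit <- fit_head_on_features(coords, pairs, candidates, dgp, epochs,
                                batch_size, lr, seed, verbose)
    model <- structure(list(variant = variant, cmm = cmm_params,
                            dgp = fit$dgp, config = config,
                            candidates = candidates, report = fit$report),
                       class = "driver_model")
    model$report <- c(model$report,
                      final_accuracy_report(model, pairs, counts, graph))
    return(model)
  }

  # full model: joint training of encoder and classifier. Classifier
  # inputs are centred per dimension with statistics of the initial
  # (pretrained) coordinates over the training cells; the fixed affine
  # transform removes the large cell-independent component of the
  # coordinates, which otherwise dominates early training. One scalar
  # scale is used for all dimensions: per-dimension scales would blow
  # up gradients through dimensions the encoder leaves near-constant.
  init_coords <- t(vapply(feats, function(f)
    encode_forward(f, cmm_params, config)$coord,
    numeric(config$coordinate_dim)))
  rownames(init_coords) <- cells
  tr_co <- init_coords[train_cells, , drop = FALSE]
  co_center <- colMeans(tr_co)
  co_scale <- sqrt(mean(apply(tr_co, 2, stats::var)))
  dgp <- init_dgp_params(config, candidates,
                         center = rep(co_center, 2),
                         scale = rep(co_scale, 2L * config$coordinate_dim),
                         input_ln = TRUE, seed = seed)

  # phase 1: head-only warm start (linear probe) on the cached frozen
  # coordinates; with freeze_cmm this is the whole fit
  warmup_report <- NULL
  head_epochs <- if (freeze_cmm) epochs else head_warmup_epochs
  if (head_epochs > 0) {
    fit <- fit_head_on_features(init_coords, pairs, candidates, dgp,
                                head_epochs, batch_size, lr,
                                seed + 13L, verbose = FALSE)
    dgp <- fit$dgp
    warmup_report <- fit$report
    if (verbose)
      message(sprintf("head warm start: CE %.3f -> %.3f",
                      warmup_report$train_loss[1],
                      utils::tail(warmup_report$train_loss, 1)))
  }
  if (freeze_cmm) {
    model <- structure(list(variant = variant, cmm = cmm_params,
                            dgp = dgp, config = config,
                            candidates = candidates,
                            report = list(warmup = warmup_report)),
                       class = "driver_model")
    model$report <- c(model$report,
                      final_accuracy_report(model, pairs, counts, graph))
    return(model)
  }

  if (is.null(joint_lr)) joint_lr <- lr / 10
  dgp_learn <- dgp[c("W1", "b1", "W2", "b2")]
  params <- list(cmm = cmm_params, dgp = dgp_learn)
  opt <- adam_init(params)
  tr_rows <- which(pairs$split == "train")
  total_steps <- max(1, epochs * ceiling(length(tr_rows) / batch_size))
  warmup <- max(1, ceiling(0.05 * total_steps))
  step <- 0L
  report <- list(epoch = integer(0), train_loss = numeric(0))

  for (ep in seq_len(epochs)) {
    set.seed(as.integer(seed) + 2309L * ep)
    order_rows <- sample(tr_rows)
    batches <- split(order_rows, ceiling(seq_along(order_rows) / batch_size))
    ep_loss <- 0; n_seen <- 0L
    for (b in batches) {
      cmm_cur <- params$cmm
      bcells <- unique(c(pairs$source_id[b], pairs$target_id[b]))
      fwds <- lapply(bcells, function(cl)
        encode_forward(feats[[cl]], cmm_cur, config))
      names(fwds) <- bcells
      Z <- t(vapply(seq_along(b), function(j)
        c(fwds[[pairs$source_id[b[j]]]]$coord,
          fwds[[pairs$target_id[b[j]]]]$coord),
        numeric(2L * config$coordinate_dim)))
      fw <- dgp_fwd(Z, dgp)
      probs <- softmax_rows(fw$logits)
      lab <- labels_all[b]
      losses <- -log(pmax(probs[cbind(seq_along(b), lab)], 1e-300))
      dlogits <- probs
      dlogits[cbind(seq_along(b), lab)] <-
        dlogits[cbind(seq_along(b), lab)] - 1
      dlogits <- dlogits / length(b)
      hb <- dgp_bwd(dlogits, fw, dgp)
      grads <- list(dgp = hb$grads)
      {
        C <- config$coordinate_dim
        dcoord <- lapply(stats::setNames(bcells, bcells),
                         function(cl) numeric(C))
        for (j in seq_along(b)) {
          sid <- pairs$source_id[b[j]]; tid <- pairs$target_id[b[j]]
          dcoord[[sid]] <- dcoord[[sid]] + hb$dz[j, seq_len(C)]
          dcoord[[tid]] <- dcoord[[tid]] + hb$dz[j, C + seq_len(C)]
        }
        g_cmm <- NULL
        for (cl in bcells) {
          g <- encode_backward(fwds[[cl]], dcoord[[cl]], feats[[cl]],
                               cmm_cur, config)
          g_cmm <- if (is.null(g_cmm)) g else tree_add(g_cmm, g)
        }
        grads$cmm <- g_cmm
      }
      step <- step + 1L
      lr_t <- joint_lr * min(1, step / warmup)
      grads <- clip_grad_tree(grads)
      upd <- adam_step(params, grads, opt, lr_t)
      params <- upd$params; opt <- upd$state
      dgp[c("W1", "b1", "W2", "b2")] <- params$dgp
      ep_loss <- ep_loss + sum(losses); n_seen <- n_seen + length(b)
    }
    if (!is.finite(ep_loss))
      stop("fine-tuning diverged: non-finite loss at epoch ", ep)
    report$epoch <- c(report$epoch, ep)
    report$train_loss <- c(report$train_loss, ep_loss / n_seen)
    if (verbose)
      message(sprintf("epoch %d: train CE %.3f", ep, ep_loss / n_seen))
  }

  report$warmup <- warmup_report
  model <- structure(list(variant = variant, cmm = params$cmm, dgp = dgp,
                          config = config, candidates = candidates,
                          report = report),
                     class = "driver_model")
  model$report <- c(model$report,
                    final_accuracy_report(model, pairs, counts, graph))
  model
}

# global L2 gradient clipping: rescale the whole gradient tree when its
# norm exceeds `max_norm` (stabilizes joint fine-tuning)
clip_grad_tree <- function(grads, max_norm = 5) {
  total <- 0
  acc <- function(x) {
    if (is.list(x)) lapply(x, acc) else total <<- total + sum(x * x)
    invisible(NULL)
  }
  acc(grads)
  nrm <- sqrt(total)
  if (is.finite(nrm) && nrm > max_norm)
    grads <- tree_map(grads, function(x) x * (max_norm / nrm))
  grads
}

# shared Adam loop for classifier heads over fixed per-cell feature rows
fit_head_on_features <- function(features, pairs, candidates, dgp,
                                 epochs, batch_size, lr, seed, verbose) {
  labels_all <- match(pairs$driver, candidates)
  tr_rows <- which(pairs$split == "train")
  learn <- dgp[intersect(c("W1", "b1", "W2", "b2"), names(dgp))]
  opt <- adam_init(learn)
  total_steps <- max(1, epochs * ceiling(length(tr_rows) / batch_size))
  warmup <- max(1, ceiling(0.05 * total_steps))
  step <- 0L
  report <- list(epoch = integer(0), train_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    set.seed(as.integer(seed) + 2309L * ep)
    order_rows <- sample(tr_rows)
    batches <- split(order_rows, ceiling(seq_along(order_rows) / batch_size))
    ep_loss <- 0; n_seen <- 0L
    for (b in batches) {
      Z <- cbind(features[pairs$source_id[b], , drop = FALSE],
                 features[pairs$target_id[b], , drop = FALSE])
      fw <- dgp_fwd(Z, dgp)
      probs <- softmax_rows(fw$logits)
      lab <- labels_all[b]
      losses <- -log(pmax(probs[cbind(seq_along(b), lab)], 1e-300))
      dlogits <- probs
      dlogits[cbind(seq_along(b), lab)] <-
        dlogits[cbind(seq_along(b), lab)] - 1
      dlogits <- dlogits / length(b)
      hb <- dgp_bwd(dlogits, fw, dgp)
      step <- step + 1L
      lr_t <- lr * min(1, step / warmup)
      upd <- adam_step(learn, clip_grad_tree(hb$grads), opt, lr_t)
      learn <- upd$params; opt <- upd$state
      dgp[names(learn)] <- learn
      ep_loss <- ep_loss + sum(losses); n_seen <- n_seen + length(b)
    }
    report$epoch <- c(report$epoch, ep)
    report$train_loss <- c(report$train_loss, ep_loss / n_seen)
    if (verbose)
      message(sprintf("epoch %d: train CE %.3f", ep, ep_loss / n_seen))
  }
  list(dgp = dgp, report = report)
}

#' Predict likelihoods for a table of pairs
#'
#' Applies a trained `driver_model` to every row of a pairs table and
#' returns the matrix of per-candidate probabilities.
#'
#' @param model A `driver_model` from [finetune()].
#' @param pairs Pairs data frame (columns `source_id`, `target_id`).
#' @param counts A [cell_counts].
#' @param graph A [gene_graph].
#' @param mask_driver If `TRUE`, set the true driver's count to zero in
#'   both cells before encoding (requires a `driver` column).
#' @return Numeric matrix, pairs x candidates, rows summing to one.
#' @export
predict_pairs <- function(model, pairs, counts, graph,
                          mask_driver = FALSE) {
  stopifnot(inherits(model, "driver_model"))
  config <- model$config
  cts <- counts$counts
  if (mask_driver) {
    bad <- setdiff(unique(pairs$driver), counts$gene_ids)
    if (length(bad) > 0)
      stop("driver(s) not in vocabulary: ", paste(bad, collapse = ", "))
  }
  if (model$variant == "no_cmm") {
    Zrows <- function(j) {
      si <- match(pairs$source_id[j], counts$cell_ids)
      ti <- match(pairs$target_id[j], counts$cell_ids)
      s <- cts[si, ]; t <- cts[ti, ]
      if (mask_driver) {
        g <- match(pairs$driver[j], counts$gene_ids)
        s[g] <- 0; t[g] <- 0
      }
      c(log1p(config$L * s / sum(s)), log1p(config$L * t / sum(t)))
    }
    Z <- t(vapply(seq_len(nrow(pairs)), Zrows, numeric(2L * ncol(cts))))
  } else {
    coord_cache <- new.env(parent = emptyenv())
    get_coord <- function(cell_id, masked_gene = NA) {
      key <- if (is.na(masked_gene)) cell_id
             else paste0(cell_id, "#", masked_gene)
      if (!is.null(coord_cache[[key]])) return(coord_cache[[key]])
      x <- cts[match(cell_id, counts$cell_ids), ]
      if (!is.na(masked_gene)) x[masked_gene] <- 0
      co <- as.numeric(encode_cell(x, graph, model$cmm, config))
      coord_cache[[key]] <- co
      co
    }
    Z <- t(vapply(seq_len(nrow(pairs)), function(j) {
      mg <- if (mask_driver) match(pairs$driver[j], counts$gene_ids)
            else NA
      c(get_coord(pairs$source_id[j], mg),
        get_coord(pairs$target_id[j], mg))
    }, numeric(2L * config$coordinate_dim)))
  }
  P <- softmax_rows(dgp_fwd(Z, model$dgp)$logits)
  dimnames(P) <- list(NULL, model$candidates)
  P
}

#' Ablation-mode prediction for one cell pair
#'
#' * `no_cmm`: classifier MLP on concatenated shifted-log expression
#'   vectors (requires a model trained with `variant = "no_cmm"`).
#' * `no_dgp`: multinomial logistic regression on concatenated frozen
#'   coordinates (model trained with `variant = "no_dgp"`).
#' * `masked_driver`: standard full-model prediction after zeroing the
#'   given driver's count in both cells.
#'
#' @param variant `"no_cmm"`, `"no_dgp"` or `"masked_driver"`.
#' @param model A matching `driver_model`.
#' @param src,tgt Raw count vectors.
#' @param graph A [gene_graph].
#' @param driver Driver gene id to mask (`masked_driver` only).
#' @return A `likelihood_vector`.
#' @export
ablation_predict <- function(variant = c("no_cmm", "no_dgp",
                                         "masked_driver"),
                             model, src, tgt, graph, driver = NULL) {
  variant <- match.arg(variant)
  config <- model$config
  if (variant == "masked_driver") {
    if (model$variant != "full")
      stop("masked_driver needs a model trained with variant = 'full'")
    if (is.null(driver)) stop("masked_driver needs the driver gene id")
    g <- match(driver, graph$gene_ids)
    if (is.na(g)) stop("driver not in vocabulary: ", driver)
    src[g] <- 0; tgt[g] <- 0
    return(predict_likelihoods(src, tgt, graph, model$cmm, model$dgp,
                               config))
  }
  if (model$variant != variant)
    stop("model was trained with variant '", model$variant, "'")
  if (variant == "no_cmm") {
    z <- c(log1p(config$L * src / sum(src)),
           log1p(config$L * tgt / sum(tgt)))
    p <- drop(softmax_rows(dgp_fwd(z, model$dgp)$logits))
  } else {
    z <- c(encode_cell(src, graph, model$cmm, config),
           encode_cell(tgt, graph, model$cmm, config))
    p <- drop(softmax_rows(dgp_fwd(z, model$dgp)$logits))
  }
  structure(stats::setNames(p, model$candidates),
            class = "likelihood_vector")
}

# train accuracy is reported on a subsample of at most 600 pairs; the
# test split is always evaluated in full
final_accuracy_report <- function(model, pairs, counts, graph) {
  out <- list()
  for (sp in c("train", "test")) {
    sub <- pairs[pairs$split == sp, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (sp == "train" && nrow(sub) > 600) {
      set.seed(104651L)
      sub <- sub[sort(sample(nrow(sub), 600)), , drop = FALSE]
    }
    P <- predict_pairs(model, sub, counts, graph)
    lab <- match(sub$driver, model$candidates)
    ranks <- t(apply(P, 1, function(p) rank_candidates(p)))
    rr <- ranks[cbind(seq_len(nrow(sub)), lab)]
    out[[paste0(sp, "_top1")]] <- mean(rr <= 1)
    out[[paste0(sp, "_top5")]] <- mean(rr <= 5)
  }
  out
}

#' @export
print.driver_model <- function(x, ...) {
  cat(sprintf("driver_model (%s): %d candidates, coordinate_dim = %d\n",
              x$variant, length(x$candidates), x$config$coordinate_dim))
  if (!is.null(x$report$test_top1))
    cat(sprintf("  test top-1 %.3f, top-5 %.3f\n",
                x$report$test_top1, x$report$test_top5))
  invisible(x)
}
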