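ns <- asNamespace("drivergraph")

test_that("driver loss matches closed forms", {
  expect_equal(driver_loss(rep(0.3, 4), 2), log(4))
  expect_equal(driver_loss(c(1, 0, -1), 1),
               -log(exp(1) / (exp(1) + 1 + exp(-1))))
  expect_equal(driver_loss(c(1, 0, -1), 1), 0.4076, tolerance = 1e-4)
  # saturating logit for the true class drives the loss to zero
  expect_lt(driver_loss(c(50, 0, 0), 1), 1e-20)
  expect_error(driver_loss(c(0, 0), 3), "range")
})

test_that("likelihood vectors are normalized and ranked deterministically", {
  cfg <- small_config()
  G <- 10
  g <- random_digraph(G, 0.3, seed = 1)
  params <- init_cmm_params(cfg, G, seed = 2)
  dgp <- init_dgp_params(cfg, paste0("n", 1:4), seed = 3)
  src <- random_cell(G, seed = 4)
  tgt <- random_cell(G, seed = 5)
  # the output layer initializes at zero: exactly uniform predictions
  p0 <- predict_likelihoods(src, tgt, g, params, dgp, cfg)
  expect_equal(as.numeric(p0), rep(0.25, 4))
  # with nonzero output weights: normalized, and order-sensitive
  set.seed(40)
  dgp$W2 <- matrix(rnorm(length(dgp$W2), sd = 0.1), nrow(dgp$W2))
  p <- predict_likelihoods(src, tgt, g, params, dgp, cfg)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # concatenation order matters: swapping src and tgt changes the output
  psw <- predict_likelihoods(tgt, src, g, params, dgp, cfg)
  expect_false(isTRUE(all.equal(as.numeric(p), as.numeric(psw))))

  expect_equal(unname(rank_candidates(c(0.5, 0.3, 0.2))), c(1L, 2L, 3L))
  expect_equal(unname(rank_candidates(c(0.3, 0.5, 0.2))[2]), 1L)
  expect_equal(unname(rank_candidates(rep(0.25, 4))), 1:4)
  set.seed(6)
  expect_setequal(rank_candidates(runif(9)), 1:9)
})

test_that("pair validation rejects leakage and missing cells", {
  counts <- toy_counts()
  pairs <- data.frame(source_id = c("c1", "c1"), target_id = c("c2", "c2"),
                      driver = c("gA", "gA"),
                      split = c("train", "test"),
                      stringsAsFactors = FALSE)
  expect_error(ns$validate_pairs(pairs, counts), "both train and test")
  pairs2 <- data.frame(source_id = "cX", target_id = "c2", driver = "gA",
                       split = "train", stringsAsFactors = FALSE)
  expect_error(ns$validate_pairs(pairs2, counts), "missing")
})

test_that("the no-DGP head is affine in the coordinates", {
  cfg <- small_config(coordinate_dim = 5)
  dgp <- init_dgp_params(cfg, c("a", "b", "c"), input_dim = 10,
                         hidden = 0L, seed = 7)
  set.seed(42)
  dgp$W2 <- matrix(rnorm(length(dgp$W2), sd = 0.2), nrow(dgp$W2))
  z1 <- rnorm(10); z2 <- rnorm(10)
  l <- function(z) ns$dgp_fwd(z, dgp)$logits
  # affinity: l(az1 + (1-a)z2) = a l(z1) + (1-a) l(z2), checked at 3 points
  for (a in c(0.2, 0.5, 0.9))
    expect_equal(l(a * z1 + (1 - a) * z2),
                 a * l(z1) + (1 - a) * l(z2), tolerance = 1e-10)
  # and it matches the explicit linear model
  expect_equal(drop(l(z1)), drop(z1 %*% dgp$W2 + dgp$b2))
})

test_that("classifier-head gradients match finite differences", {
  cfg <- small_config(coordinate_dim = 4)
  dgp <- init_dgp_params(cfg, c("a", "b", "c"), input_dim = 8,
                         hidden = 6, input_ln = TRUE, seed = 8)
  set.seed(41)
  dgp$W2 <- matrix(rnorm(length(dgp$W2), sd = 0.3), nrow(dgp$W2))
  z <- matrix(rnorm(16), 2, 8)
  lab <- c(2L, 3L)
  loss_of <- function(p) {
    fw <- ns$dgp_fwd(z, p)
    pr <- ns$softmax_rows(fw$logits)
    -mean(log(pr[cbind(1:2, lab)]))
  }
  fw <- ns$dgp_fwd(z, dgp)
  pr <- ns$softmax_rows(fw$logits)
  dl <- pr
  dl[cbind(1:2, lab)] <- dl[cbind(1:2, lab)] - 1
  hb <- ns$dgp_bwd(dl / 2, fw, dgp)
  eps <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2")) {
    idx <- seq_len(min(5, length(dgp[[nm]])))
    for (i in idx) {
      p2 <- dgp; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- dgp; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
      expect_equal(hb$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("fine-tuning on a small task learns, reproduces, and guards splits", {
  cfg <- small_config(coordinate_dim = 16)
  sc <- sim_config(n_genes = 40, n_states = 2, n_drivers = 4,
                   cells_per_condition = 10, controls_per_state = 20,
                   density = 0.05, seed = 2)
  ds <- build_pair_dataset(sc, "in_domain")
  params <- init_cmm_params(cfg, 40, seed = 3)
  m1 <- finetune(ds$pairs, ds$counts, ds$graph, params, cfg, epochs = 4,
                 batch_size = 8, lr = 2e-3, seed = 4)
  m2 <- finetune(ds$pairs, ds$counts, ds$graph, params, cfg, epochs = 4,
                 batch_size = 8, lr = 2e-3, seed = 4)
  expect_identical(m1$report$train_loss, m2$report$train_loss)
  expect_identical(m1$report$test_top1, m2$report$test_top1)
  expect_equal(sort(m1$candidates), m1$candidates)
  expect_true(m1$report$test_top5 >= m1$report$test_top1)
  # loss decreases from the uniform start
  expect_lt(tail(m1$report$train_loss, 1), log(4))

  # freezing the encoder still trains and reports
  mf <- finetune(ds$pairs, ds$counts, ds$graph, params, cfg, epochs = 1,
                 batch_size = 8, lr = 1e-3, seed = 5, freeze_cmm = TRUE)
  expect_equal(mf$cmm$name_emb, params$name_emb)
  expect_true(is.finite(mf$report$test_top1))
})

test_that("ablation variants train and predict normalized likelihoods", {
  cfg <- small_config(coordinate_dim = 16)
  sc <- sim_config(n_genes = 40, n_states = 2, n_drivers = 4,
                   cells_per_condition = 8, controls_per_state = 15,
                   density = 0.05, seed = 6)
  ds <- build_pair_dataset(sc, "in_domain")
  params <- init_cmm_params(cfg, 40, seed = 7)

  nc <- finetune(ds$pairs, ds$counts, ds$graph, NULL, cfg, epochs = 2,
                 batch_size = 8, seed = 8, variant = "no_cmm")
  nd <- finetune(ds$pairs, ds$counts, ds$graph, params, cfg, epochs = 2,
                 batch_size = 8, seed = 9, variant = "no_dgp")
  fu <- finetune(ds$pairs, ds$counts, ds$graph, params, cfg, epochs = 1,
                 batch_size = 8, seed = 10)

  i <- which(ds$pairs$split == "test")[1]
  src <- ds$counts$counts[match(ds$pairs$source_id[i], ds$counts$cell_ids), ]
  tgt <- ds$counts$counts[match(ds$pairs$target_id[i], ds$counts$cell_ids), ]
  for (x in list(ablation_predict("no_cmm", nc, src, tgt, ds$graph),
                 ablation_predict("no_dgp", nd, src, tgt, ds$graph),
                 ablation_predict("masked_driver", fu, src, tgt, ds$graph,
                                  driver = ds$pairs$driver[i]))) {
    expect_equal(sum(x), 1, tolerance = 1e-6)
    expect_length(x, 4)
  }
  expect_error(ablation_predict("no_cmm", fu, src, tgt, ds$graph),
               "variant")
  expect_error(ablation_predict("masked_driver", fu, src, tgt, ds$graph),
               "driver")
})
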