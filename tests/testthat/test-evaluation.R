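make_probs <- function(n, K, true_idx, strength = 0.8, seed = 1) {
  set.seed(seed)
  P <- matrix(runif(n * K), n, K)
  P[cbind(seq_len(n), true_idx)] <- P[cbind(seq_len(n), true_idx)] +
    strength * K
  P <- P / rowSums(P)
  colnames(P) <- paste0("g", seq_len(K))
  P
}

test_that("a perfect predictor scores 1 on every metric", {
  K <- 6; n <- 30
  lab <- rep(1:K, 5)
  P <- matrix(1e-6, n, K)
  P[cbind(1:n, lab)] <- 1
  P <- P / rowSums(P)
  colnames(P) <- paste0("g", 1:K)
  m <- classification_metrics(P, lab)
  expect_equal(m$top_1, 1)
  expect_equal(m$top_5, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$auroc, 1)
  expect_true(all(m$ranks == 1))
})

test_that("top-5 dominates top-1 and ranks stay within bounds", {
  K <- 10; n <- 200
  lab <- sample(1:K, n, replace = TRUE)
  P <- make_probs(n, K, lab, strength = 0.15, seed = 2)
  m <- classification_metrics(P, lab)
  expect_gte(m$top_5, m$top_1)
  expect_true(all(m$ranks >= 1 & m$ranks <= K))
  expect_true(m$top_1 >= 0 && m$top_1 <= 1)
})

test_that("a uniform random predictor matches its analytic expectations", {
  K <- 20; n <- 10000
  set.seed(3)
  lab <- sample(1:K, n, replace = TRUE)
  P <- matrix(runif(n * K), n, K)
  P <- P / rowSums(P)
  colnames(P) <- paste0("g", 1:K)
  m <- classification_metrics(P, lab)
  se1 <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(m$top_1 - 0.05), 3 * se1)
  # mean rank of the true label ~ (K + 1) / 2 = 10.5
  se_rank <- sqrt((K^2 - 1) / 12 / n)
  expect_lt(abs(m$rank_mean - 10.5), 3 * se_rank)
  expect_equal(m$auroc, 0.5, tolerance = 0.02)
})

test_that("classes absent from the labels are excluded with a warning", {
  K <- 5
  lab <- c(1, 1, 2, 2)
  P <- make_probs(4, K, lab, seed = 4)
  expect_warning(m <- classification_metrics(P, lab), "absent")
  expect_equal(nrow(m$per_gene), 2)
})

test_that("dual-perturbation ranks are order-invariant", {
  K <- 8
  P <- make_probs(5, K, rep(1, 5), seed = 5)
  r12 <- rank_metrics(P, labels = rep(3, 5), second_labels = rep(7, 5))
  r21 <- rank_metrics(P, labels = rep(7, 5), second_labels = rep(3, 5))
  expect_equal(r12$rank_perturbation1, r21$rank_perturbation1)
  expect_equal(r12$rank_perturbation2, r21$rank_perturbation2)
  expect_true(all(r12$rank_perturbation1 <= r12$rank_perturbation2))
  # perfect predictor: all ranks 1
  lab <- sample(1:K, 5, replace = TRUE)
  Pp <- matrix(0, 5, K); Pp[cbind(1:5, lab)] <- 1
  colnames(Pp) <- paste0("g", 1:K)
  expect_true(all(rank_metrics(Pp, lab)$ranks == 1))
})

test_that("LISI hits its anchors and is rotation invariant", {
  # single label: all zeros, with a warning
  set.seed(6)
  X <- matrix(rnorm(80), 40, 2)
  expect_warning(z <- lisi(X, rep("a", 40), perplexity = 10), "single")
  expect_true(all(z == 0))

  # separated labels: near 0
  Xs <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60) + 50, 30, 2))
  s <- lisi(Xs, rep(c("a", "b"), each = 30), perplexity = 10)
  expect_lt(mean(s), 0.05)

  # balanced two-label perfect interleaving on a line: near 1
  n <- 200
  Xi <- cbind(seq_len(n), 0)
  li <- rep(c("a", "b"), n / 2)
  si <- lisi(Xi, li, perplexity = 30)
  expect_gt(mean(si), 0.95)
  expect_true(all(si >= 0 & si <= 1))

  # rigid rotation leaves every score unchanged
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  s2 <- lisi(Xs %*% R, rep(c("a", "b"), each = 30), perplexity = 10)
  expect_equal(s, s2, tolerance = 1e-8)
})

test_that("transition scores follow the marker-mean formula", {
  src <- matrix(0, 3, 4, dimnames = list(NULL, c("m1", "m2", "x", "y")))
  tgt <- src
  tgt[, "m1"] <- 0.5; tgt[, "m2"] <- 1.5
  sets <- list(up = c("m1", "m2"))
  cts <- transition_score(src, tgt, sets)
  expect_equal(unname(cts[, "up"]), rep(1, 3))
  # zero when target equals source
  expect_true(all(transition_score(src, src, sets) == 0))
  # adding a constant to target markers adds it to the score
  tgt2 <- tgt; tgt2[, c("m1", "m2")] <- tgt2[, c("m1", "m2")] + 2
  expect_equal(transition_score(src, tgt2, sets),
               transition_score(src, tgt, sets) + 2)
  # antisymmetry under src/tgt swap
  expect_equal(transition_score(tgt, src, sets),
               -transition_score(src, tgt, sets))
  expect_error(transition_score(src, tgt, list(bad = "zz")), "vocabulary")
  expect_error(transition_score(src, tgt, list(empty = character(0))),
               "empty")
})

test_that("prediction scores average member likelihoods", {
  P <- matrix(c(0.2, 0.4, 0.4,
                0.1, 0.6, 0.3), 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  ps <- prediction_score(P, list(ab = c("a", "b"), solo = "c"))
  expect_equal(unname(ps[, "ab"]), c(0.3, 0.35))
  expect_equal(unname(ps[, "solo"]), c(0.4, 0.3))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_error(prediction_score(P, list(bad = c("a", "zz"))), "absent")
})

test_that("the hand-rolled rank-sum test matches wilcox.test", {
  ns <- asNamespace("drivergraph")
  set.seed(7)
  a <- matrix(c(rnorm(40), rnorm(40, 1)), ncol = 2)
  b <- matrix(c(rnorm(60), rnorm(60)), ncol = 2)
  p <- ns$rank_sum_test(a, b)
  for (j in 1:2) {
    ref <- stats::wilcox.test(a[, j], b[, j], correct = FALSE,
                              exact = FALSE)$p.value
    expect_equal(p[j], ref, tolerance = 1e-10)
  }
  # ties handled via the correction term
  at <- matrix(rep(c(1, 2, 2, 3), 5), ncol = 1)
  bt <- matrix(rep(c(2, 2, 3, 4), 5), ncol = 1)
  ref <- suppressWarnings(stats::wilcox.test(at[, 1], bt[, 1],
                                             correct = FALSE,
                                             exact = FALSE)$p.value)
  expect_equal(ns$rank_sum_test(at, bt), ref, tolerance = 1e-10)
})

test_that("DGE baseline ranks a strongly shifted gene first", {
  set.seed(8)
  G <- 30
  gene_ids <- sprintf("g%02d", 1:G)
  src <- cell_counts(matrix(rpois(150 * G, 5), 150, G),
                     gene_ids = gene_ids)
  tgt_counts <- matrix(rpois(150 * G, 5), 150, G)
  tgt_counts[, 7] <- rpois(150, 60)   # one gene strongly up
  tgt <- cell_counts(tgt_counts, gene_ids = gene_ids)
  res <- suppressWarnings(
    dge_baseline_ranking(src, tgt, n_cluster_range = c(2, 40),
                         alpha = 0.05, seed = 1))
  informative <- Filter(function(df) nrow(df) >= 3, res$rankings)
  expect_gt(length(informative), 0)
  top_hits <- vapply(informative, function(df) df$gene[1], character(1))
  expect_gt(mean(top_hits == "g07"), 0.5)
  for (df in res$rankings) {
    expect_true(all(df$padj < 0.05))
    expect_true(all(diff(abs(df$logfc)) <= 1e-12))
  }
  # identical groups: (almost) nothing significant
  src2 <- cell_counts(matrix(rpois(100 * G, 5), 100, G),
                      gene_ids = gene_ids)
  tgt2 <- cell_counts(matrix(rpois(100 * G, 5), 100, G),
                      gene_ids = gene_ids)
  res2 <- suppressWarnings(
    dge_baseline_ranking(src2, tgt2, n_cluster_range = c(2, 40),
                         seed = 2))
  expect_lt(mean(vapply(res2$rankings, nrow, integer(1))), 2)

  # candidate ranks: significant candidates first, others at mid-rank
  ranks <- dge_candidate_ranks(res, tgt$cell_ids[1:3],
                               c("g07", "g01", "g02"))
  expect_equal(unname(ranks[, "g07"]), rep(1, 3))
})

test_that("marker set files round-trip into named lists", {
  tsv <- file.path(withr::local_tempdir(), "sets.tsv")
  writeLines(c("up\tm1", "up\tm2", "down\tm3"), tsv)
  sets <- read_marker_sets(tsv)
  expect_setequal(names(sets), c("up", "down"))
  expect_setequal(sets$up, c("m1", "m2"))
  expect_identical(sets$down, "m3")
})
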