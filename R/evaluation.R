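# Evaluation: multiclass classification metrics, rank statistics,
# neighborhood label mixing (LISI), marker-set transition scores,
# likelihood-score aggregation, and the differential-expression ranking
# baseline.

#' Classification metrics for driver prediction
#'
#' Top-k accuracy is the fraction of pairs whose true driver ranks
#' within the top k likelihoods; macro-F1 is computed over top-1
#' predicted classes; AUROC is the macro average of one-vs-rest AUROCs
#' using the predicted probabilities. Classes without both a positive
#' and a negative example are excluded from the AUROC average (and
#' classes absent from the labels from both macro averages), with a
#' warning.
#'
#' @param predictions Numeric matrix, pairs x candidates (rows are
#'   probability vectors); column names are the candidate ids.
#' @param labels Character vector of true drivers (or integer column
#'   indices).
#' @return A `metric_report` list: `top_1`, `top_5`, `macro_f1`,
#'   `auroc`, `per_gene` accuracy table, `rank_mean`, `rank_median`,
#'   `ranks`, `n`.
#' @export
classification_metrics <- function(predictions, labels) {
  P <- as.matrix(predictions)
  K <- ncol(P); n <- nrow(P)
  if (n < 1) stop("need at least one pair")
  cand <- colnames(P)
  if (is.character(labels)) {
    lab <- match(labels, cand)
    if (anyNA(lab)) stop("label(s) outside the candidate set")
  } else lab <- as.integer(labels)
  ranks <- t(apply(P, 1, rank_candidates))
  true_rank <- ranks[cbind(seq_len(n), lab)]
  pred1 <- apply(ranks, 1, which.min)

  present <- sort(unique(lab))
  if (length(present) < K)
    warning(sprintf("%d class(es) absent from labels; excluded from macro averages",
                    K - length(present)))
  f1 <- vapply(present, function(k) {
    tp <- sum(pred1 == k & lab == k)
    fp <- sum(pred1 == k & lab != k)
    fn <- sum(pred1 != k & lab == k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))

  aucs <- vapply(present, function(k) {
    y <- as.integer(lab == k)
    if (sum(y) == 0 || sum(y) == n) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = P[, k],
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  }, numeric(1))
  if (anyNA(aucs))
    warning("class(es) without both positives and negatives excluded from AUROC")

  per_gene <- data.frame(
    gene = cand[present],
    n = as.integer(table(factor(lab, levels = present))),
    top1 = vapply(present, function(k) mean(true_rank[lab == k] <= 1),
                  numeric(1)))
  structure(list(top_1 = mean(true_rank <= 1),
                 top_5 = mean(true_rank <= min(5, K)),
                 macro_f1 = mean(f1),
                 auroc = mean(aucs, na.rm = TRUE),
                 per_gene = per_gene,
                 rank_mean = mean(true_rank),
                 rank_median = stats::median(true_rank),
                 ranks = true_rank, n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (n = %d): top-1 %.3f, top-5 %.3f, macro-F1 %.3f, AUROC %.3f\n",
              x$n, x$top_1, x$top_5, x$macro_f1, x$auroc))
  cat(sprintf("  true-driver rank: mean %.2f, median %g\n",
              x$rank_mean, x$rank_median))
  invisible(x)
}

#' Rank statistics of true drivers
#'
#' Per pair, the rank of each true driver among the candidates. With a
#' second driver (dual perturbations), "perturbation 1" is defined as
#' the better-ranked of the two and "perturbation 2" as the worse,
#' regardless of input order.
#'
#' @param predictions Probability matrix, pairs x candidates.
#' @param labels True drivers (character or index).
#' @param second_labels Optional second drivers for dual perturbations.
#' @return List with `ranks` (first/only driver), and for dual input
#'   `rank_perturbation1`/`rank_perturbation2`, plus means and medians.
#' @export
rank_metrics <- function(predictions, labels, second_labels = NULL) {
  P <- as.matrix(predictions)
  n <- nrow(P)
  to_idx <- function(l) {
    if (is.character(l)) {
      i <- match(l, colnames(P))
      if (anyNA(i)) stop("label(s) outside the candidate set")
      i
    } else as.integer(l)
  }
  lab <- to_idx(labels)
  ranks <- t(apply(P, 1, rank_candidates))
  r1 <- ranks[cbind(seq_len(n), lab)]
  out <- list(ranks = r1, rank_mean = mean(r1),
              rank_median = stats::median(r1))
  if (!is.null(second_labels)) {
    lab2 <- to_idx(second_labels)
    r2 <- ranks[cbind(seq_len(n), lab2)]
    out$rank_perturbation1 <- pmin(r1, r2)
    out$rank_perturbation2 <- pmax(r1, r2)
    out$mean_perturbation1 <- mean(out$rank_perturbation1)
    out$mean_perturbation2 <- mean(out$rank_perturbation2)
  }
  out
}

#' Local inverse Simpson index of label mixing
#'
#' For each cell, neighbor weights are set by a Gaussian kernel whose
#' bandwidth is tuned so the neighborhood perplexity matches
#' `perplexity`; the weighted label distribution's inverse Simpson
#' index lambda (in \[1, n_labels\]) is then rescaled to
#' `(lambda - 1) / (n_labels - 1)`, so 0 means every neighborhood is
#' single-label (perfectly separated) and 1 means perfect mixing.
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param labels Vector of labels, one per cell.
#' @param perplexity Effective neighborhood size (default 30); must be
#'   smaller than the number of cells.
#' @return Numeric vector of per-cell scores in \[0, 1\].
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  X <- as.matrix(embedding)
  n <- nrow(X)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per cell required")
  if (n <= perplexity) stop("need more cells than the perplexity")
  ulab <- unique(labels)
  L <- length(ulab)
  if (L == 1) {
    warning("single global label: all LISI scores are 0")
    return(rep(0, n))
  }
  lab_i <- match(labels, ulab)
  D2 <- as.matrix(stats::dist(X))^2
  k_use <- min(n - 1, max(3 * perplexity, perplexity + 2))
  target <- log(perplexity)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    o <- order(d)[seq_len(k_use)]
    di <- d[o]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { hh <- 0 } else {
        p <- w / sw
        hh <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(hh - target) < 1e-5) break
      if (hh > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p <- w / sum(w)
    mass <- vapply(seq_len(L), function(l)
      sum(p[lab_i[-i][o] == l]), numeric(1))
    lambda <- 1 / sum(mass^2)
    scores[i] <- (lambda - 1) / (L - 1)
  }
  pmin(pmax(scores, 0), 1)
}

#' Marker-set transition scores
#'
#' For marker set i and pair j, the transition score is the mean over
#' the set's markers of (target minus source) normalized expression. It
#' is linear in the target expression and antisymmetric under swapping
#' source and target.
#'
#' @param src,tgt Normalized expression matrices (pairs x genes), rows
#'   aligned (row j of each is pair j).
#' @param sets Named list of marker gene id vectors.
#' @return Numeric matrix, pairs x sets.
#' @export
transition_score <- function(src, tgt, sets) {
  if (inherits(src, "normalized_matrix")) src <- src$values
  if (inherits(tgt, "normalized_matrix")) tgt <- tgt$values
  if (!all(dim(src) == dim(tgt))) stop("src/tgt shape mismatch")
  if (length(sets) == 0) stop("need at least one marker set")
  out <- vapply(sets, function(markers) {
    if (length(markers) == 0) stop("empty marker set")
    idx <- match(markers, colnames(src))
    if (anyNA(idx)) stop("marker(s) outside the vocabulary: ",
                         paste(markers[is.na(idx)], collapse = ", "))
    rowMeans(tgt[, idx, drop = FALSE] - src[, idx, drop = FALSE])
  }, numeric(nrow(src)))
  out <- matrix(out, nrow = nrow(src),
                dimnames = list(rownames(src), names(sets)))
  out
}

#' Prediction scores from likelihood vectors
#'
#' Aggregates likelihood scores over curated driver sets: the
#' prediction score of transition type i for pair j is the mean of the
#' member genes' predicted likelihoods.
#'
#' @param likelihoods Probability matrix, pairs x candidates (columns
#'   named by candidate gene).
#' @param driver_sets Named list of candidate gene id vectors.
#' @return Numeric matrix, pairs x sets, entries in \[0, 1\].
#' @export
prediction_score <- function(likelihoods, driver_sets) {
  P <- as.matrix(likelihoods)
  out <- vapply(driver_sets, function(set) {
    idx <- match(set, colnames(P))
    if (anyNA(idx))
      stop("driver set member(s) absent from candidates: ",
           paste(set[is.na(idx)], collapse = ", "))
    rowMeans(P[, idx, drop = FALSE])
  }, numeric(nrow(P)))
  matrix(out, nrow = nrow(P),
         dimnames = list(rownames(P), names(driver_sets)))
}

# Vectorized two-sided Wilcoxon rank-sum test (normal approximation
# with tie correction), one test per column.
rank_sum_test <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  vapply(seq_len(ncol(a)), function(j) {
    x <- c(a[, j], b[, j])
    r <- rank(x)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(x)
    n <- n1 + n2
    sig2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (W - mu) / sqrt(sig2)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
}

#' Differential-expression ranking baseline
#'
#' The standard alternative to model-based driver ranking: target cells
#' are normalized, log-transformed and clustered (Leiden communities on
#' a k-nearest-neighbour graph, resolution tuned so the cluster count
#' lands in `n_cluster_range`); each cluster is compared with the
#' pooled source cells by a per-gene two-sided Wilcoxon rank-sum test;
#' genes significant at `alpha` after Benjamini-Hochberg correction are
#' ranked by decreasing absolute log fold change.
#'
#' @param src_cells,tgt_cells [cell_counts] objects for the source
#'   (reference) and target groups.
#' @param n_cluster_range Admissible cluster-count range (default
#'   c(20, 40)); if the resolution search cannot land inside it, a
#'   warning is emitted and the achieved count is used.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param knn Neighbours for the clustering graph (default 15).
#' @param L Normalization scale.
#' @param seed Clustering seed.
#' @return List with `clusters` (per target cell), and `rankings`: per
#'   cluster a data frame (`gene`, `logfc`, `pvalue`, `padj`) of the
#'   significant genes, ordered by `abs(logfc)` descending.
#' @export
dge_baseline_ranking <- function(src_cells, tgt_cells,
                                 n_cluster_range = c(20, 40),
                                 alpha = 0.05, knn = 15, L = 1e4,
                                 seed = 1) {
  stopifnot(inherits(src_cells, "cell_counts"),
            inherits(tgt_cells, "cell_counts"))
  src_norm <- shifted_log_normalize(src_cells, L)$values
  tgt_norm <- shifted_log_normalize(tgt_cells, L)$values
  n <- nrow(tgt_norm)

  # kNN graph on the top principal components of the target cells
  set.seed(as.integer(seed))
  npc <- min(30, ncol(tgt_norm) - 1, n - 1)
  pc <- stats::prcomp(tgt_norm, rank. = npc)$x
  k <- min(knn, n - 1)
  D <- as.matrix(stats::dist(pc))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  und <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(und, directed = FALSE)

  cluster_at <- function(res) {
    set.seed(as.integer(seed))
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res))
  }
  lo <- 0.1; hi <- 50
  memb <- NULL
  for (iter in 1:30) {
    mid <- sqrt(lo * hi)
    memb <- cluster_at(mid)
    nc <- length(unique(memb))
    if (nc < n_cluster_range[1]) lo <- mid
    else if (nc > n_cluster_range[2]) hi <- mid
    else break
  }
  nc <- length(unique(memb))
  if (nc < n_cluster_range[1] || nc > n_cluster_range[2])
    warning(sprintf("achieved %d clusters, outside [%d, %d]; proceeding",
                    nc, n_cluster_range[1], n_cluster_range[2]))

  rankings <- lapply(sort(unique(memb)), function(cl) {
    tc <- tgt_norm[memb == cl, , drop = FALSE]
    p <- rank_sum_test(tc, src_norm)
    padj <- stats::p.adjust(p, method = "BH")
    logfc <- colMeans(tc) - colMeans(src_norm)
    sig <- which(padj < alpha)
    df <- data.frame(gene = colnames(tgt_norm)[sig], logfc = logfc[sig],
                     pvalue = p[sig], padj = padj[sig],
                     stringsAsFactors = FALSE)
    df[order(-abs(df$logfc)), , drop = FALSE]
  })
  names(rankings) <- paste0("cluster", sort(unique(memb)))
  list(clusters = stats::setNames(as.integer(memb), tgt_cells$cell_ids),
       rankings = rankings, n_clusters = nc)
}

#' Candidate ranks implied by the DGE baseline
#'
#' For each target cell, ranks the candidate genes by its cluster's
#' DGE ordering: significant candidates first (by decreasing
#' `abs(logfc)`), then all non-significant candidates at their shared
#' mid-rank.
#'
#' @param dge Result of [dge_baseline_ranking()].
#' @param target_ids Target cell ids (must be in `dge$clusters`).
#' @param candidates Candidate gene ids.
#' @return Integer-ish matrix, cells x candidates, of dense ranks.
#' @export
dge_candidate_ranks <- function(dge, target_ids, candidates) {
  K <- length(candidates)
  cl <- dge$clusters[target_ids]
  if (anyNA(cl)) stop("target id(s) missing from the DGE clustering")
  per_cluster <- lapply(dge$rankings, function(df) {
    hit <- match(candidates, df$gene)
    r <- numeric(K)
    sig <- which(!is.na(hit))
    sig <- sig[order(hit[sig])]
    r[sig] <- seq_along(sig)
    rest <- which(is.na(hit))
    r[rest] <- length(sig) + (length(rest) + 1) / 2
    r
  })
  out <- t(vapply(paste0("cluster", cl), function(key) per_cluster[[key]],
                  numeric(K)))
  dimnames(out) <- list(target_ids, candidates)
  out
}

#' Read marker sets from TSV
#'
#' Two-column TSV (`set` and `gene`, no header) listing the member
#' genes of each marker or driver set, as consumed by
#' [transition_score()] and [prediction_score()].
#'
#' @param path Path to the TSV.
#' @return Named list of character vectors.
#' @export
read_marker_sets <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("marker set file needs two columns: ", path)
  split(as.character(df[[2]]), df[[1]])
}
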