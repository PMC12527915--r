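# Shared fixtures, built in code. The small config keeps the encoder
# cheap; tests that need trained models use the cached pipeline in
# helper-pipeline.R.

small_config <- function(...) {
  args <- utils::modifyList(
    list(H = 8, n_layers = 2, n_heads = 4, coordinate_dim = 6,
         D_max = 3, degree_cap = 5, mlp_hidden = 10, decoder_hidden = 7),
    list(...))
  do.call(model_config, args)
}

# desk-scale training configuration used by the acceptance pipeline
desk_config <- function(...) {
  args <- utils::modifyList(
    list(H = 64, n_layers = 2, n_heads = 4, coordinate_dim = 128,
         mlp_hidden = 128),
    list(...))
  do.call(model_config, args)
}

toy_counts <- function() {
  cell_counts(matrix(c(1, 0, 3,
                       0, 2, 0,
                       4, 1, 2), nrow = 3, byrow = TRUE),
              cell_ids = c("c1", "c2", "c3"),
              gene_ids = c("gA", "gB", "gC"))
}

chain_graph <- function() {
  # A -> B -> C
  gene_graph(c("A", "B", "C"), rbind(c(1L, 2L), c(2L, 3L)))
}

random_cell <- function(G, seed = 1, lambda = 3) {
  set.seed(seed)
  x <- stats::rpois(G, lambda)
  if (all(x == 0)) x[1] <- 1
  x
}

# Floyd-Warshall oracle with the same clipping and sentinel rules as
# shortest_path_buckets; used as the independent distance reference.
fw_bucket_oracle <- function(graph, subset, D_max) {
  G <- length(graph$gene_ids)
  INF <- Inf
  d <- matrix(INF, G, G)
  if (nrow(graph$edges) > 0)
    d[graph$edges] <- 1
  diag(d) <- 0   # a zero-length path always beats a self-loop
  for (k in seq_len(G))
    for (i in seq_len(G)) {
      if (!is.finite(d[i, k])) next
      alt <- d[i, k] + d[k, ]
      upd <- alt < d[i, ]
      d[i, upd] <- alt[upd]
    }
  out <- d[subset, subset, drop = FALSE]
  unreach <- as.integer(D_max + 1)
  out[is.infinite(out)] <- unreach
  out[out > D_max & out != unreach] <- D_max
  out <- matrix(as.integer(out), nrow = length(subset))
  attr(out, "unreachable") <- unreach
  out
}

random_digraph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  pairs <- which(matrix(stats::runif(n_nodes^2) < p_edge, n_nodes),
                 arr.ind = TRUE)
  gene_graph(paste0("n", seq_len(n_nodes)), pairs)
}
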