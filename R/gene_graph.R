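#' Construct a directed gene graph
#'
#' A directed, unweighted gene-gene prior (e.g. the union of a regulatory
#' and a signalling network). Self-loops are allowed; parallel edges are
#' collapsed. Genes without any edge are kept as isolated nodes so the
#' graph vocabulary can cover the full expression vocabulary.
#'
#' @param gene_ids Ordered unique character vector of node names.
#' @param edges Two-column integer matrix of (source index, target index)
#'   pairs, or a zero-row matrix for an edgeless graph.
#' @return An object of class `gene_graph` with fields `gene_ids`,
#'   `edges` (deduplicated, row-sorted) and a cached `igraph` handle.
#' @export
gene_graph <- function(gene_ids, edges) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in graph")
  G <- length(gene_ids)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1) || any(edges > G))
      stop("edge endpoint outside gene vocabulary")
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  ig <- igraph::make_empty_graph(n = G, directed = TRUE)
  if (nrow(edges) > 0)
    ig <- igraph::add_edges(ig, t(edges))
  structure(list(gene_ids = gene_ids, edges = edges, ig = ig),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d genes, %d directed edges\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a gene graph
#' @param graph A [gene_graph].
#' @return Integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Load a directed edge list from TSV
#'
#' @param path Two-column TSV of gene symbols (source, target), no
#'   header.
#' @param vocabulary Character vector fixing the node set (edges touching
#'   unknown genes are dropped, with a message giving the count), or
#'   `"infer"` to take the node set from the file.
#' @return A [gene_graph].
#' @export
load_edge_list <- function(path, vocabulary = "infer") {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty edge list: ", path)
  if (ncol(df) < 2) stop("edge list needs two columns: ", path)
  src <- as.character(df[[1]]); tgt <- as.character(df[[2]])
  if (identical(vocabulary, "infer")) {
    vocab <- sort(unique(c(src, tgt)))
  } else {
    vocab <- as.character(vocabulary)
    keep <- src %in% vocab & tgt %in% vocab
    if (any(!keep))
      message(sprintf("dropped %d edge(s) touching genes outside the vocabulary",
                      sum(!keep)))
    src <- src[keep]; tgt <- tgt[keep]
  }
  edges <- cbind(match(src, vocab), match(tgt, vocab))
  gene_graph(vocab, edges)
}

#' Write a gene graph as an edge-list TSV
#' @param graph A [gene_graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(
    data.frame(source = graph$gene_ids[graph$edges[, 1]],
               target = graph$gene_ids[graph$edges[, 2]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Union of directed gene graphs
#'
#' Two genes are linked in the union iff they are linked in any of the
#' input graphs; the node set is the union of node sets.
#'
#' @param graphs List of [gene_graph] objects.
#' @return A [gene_graph].
#' @export
union_graphs <- function(graphs) {
  if (length(graphs) == 0) stop("need at least one graph")
  stopifnot(all(vapply(graphs, inherits, logical(1), "gene_graph")))
  vocab <- sort(unique(unlist(lapply(graphs, `[[`, "gene_ids"))))
  edges <- do.call(rbind, lapply(graphs, function(g) {
    if (nrow(g$edges) == 0) return(matrix(integer(), ncol = 2))
    cbind(match(g$gene_ids[g$edges[, 1]], vocab),
          match(g$gene_ids[g$edges[, 2]], vocab))
  }))
  gene_graph(vocab, edges)
}

#' Cell-specific subgraph
#'
#' Removes the gene nodes whose raw count is zero in the given cell and
#' every edge incident to them, leaving the induced subgraph on the
#' cell's expressed genes (expressed genes absent from the prior remain
#' as isolated nodes).
#'
#' @param graph A [gene_graph] whose vocabulary matches the cell's genes.
#' @param cell Numeric count vector for one cell, aligned with
#'   `graph$gene_ids` (names, if present, are checked).
#' @return A [gene_graph] over the expressed genes.
#' @export
cell_specific_subgraph <- function(graph, cell) {
  stopifnot(inherits(graph, "gene_graph"))
  if (!is.null(names(cell))) {
    if (!setequal(names(cell), graph$gene_ids))
      stop("cell gene ids do not match the graph vocabulary")
    cell <- cell[graph$gene_ids]
  } else if (length(cell) != length(graph$gene_ids)) {
    stop("cell vector length does not match the graph vocabulary")
  }
  keep <- which(cell > 0)
  if (length(keep) == 0) stop("cell has no non-zero gene")
  keep_set <- logical(length(graph$gene_ids))
  keep_set[keep] <- TRUE
  e <- graph$edges
  if (nrow(e) > 0) {
    e <- e[keep_set[e[, 1]] & keep_set[e[, 2]], , drop = FALSE]
    remap <- integer(length(graph$gene_ids))
    remap[keep] <- seq_along(keep)
    e <- cbind(remap[e[, 1]], remap[e[, 2]])
  }
  gene_graph(graph$gene_ids[keep], e)
}

#' In- and out-degree table
#'
#' Self-loops count once towards both the in- and the out-degree.
#'
#' @param graph A [gene_graph].
#' @return A data.frame with columns `gene_id`, `in_degree`,
#'   `out_degree`; column sums both equal the edge count.
#' @export
compute_degrees <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  G <- length(graph$gene_ids)
  ind <- integer(G); outd <- integer(G)
  if (nrow(graph$edges) > 0) {
    t_in <- tabulate(graph$edges[, 2], nbins = G)
    t_out <- tabulate(graph$edges[, 1], nbins = G)
    ind <- t_in; outd <- t_out
  }
  data.frame(gene_id = graph$gene_ids, in_degree = ind, out_degree = outd,
             stringsAsFactors = FALSE)
}

#' Shortest-path distance buckets
#'
#' Directed BFS distances between all pairs of a gene subset, computed
#' over the full graph (paths may pass through genes outside the
#' subset), clipped at `D_max`. Reachable pairs further than `D_max`
#' fall in the `D_max` bucket; unreachable pairs get the sentinel bucket
#' `D_max + 1`. The diagonal is zero. The matrix is generally
#' asymmetric.
#'
#' @param graph A [gene_graph].
#' @param subset Integer indices (into `graph$gene_ids`) or gene ids.
#' @param D_max Distance cap (>= 1), default 8.
#' @return Integer matrix with `attr(, "unreachable")` giving the
#'   sentinel value `D_max + 1`.
#' @export
shortest_path_buckets <- function(graph, subset, D_max = 8) {
  stopifnot(inherits(graph, "gene_graph"))
  if (length(subset) == 0) stop("empty gene subset")
  if (!is.numeric(D_max) || D_max < 1) stop("D_max must be >= 1")
  if (is.character(subset)) {
    idx <- match(subset, graph$gene_ids)
    if (anyNA(idx)) stop("subset gene(s) not in graph vocabulary")
  } else {
    idx <- as.integer(subset)
    if (any(idx < 1) || any(idx > length(graph$gene_ids)))
      stop("subset index out of range")
  }
  d <- igraph::distances(graph$ig, v = idx, to = idx, mode = "out",
                         algorithm = "unweighted")
  unreach <- as.integer(D_max + 1)
  d[is.infinite(d)] <- unreach
  d[d > D_max & d != unreach] <- as.integer(D_max)
  d <- matrix(as.integer(d), nrow = length(idx),
              dimnames = list(graph$gene_ids[idx], graph$gene_ids[idx]))
  attr(d, "unreachable") <- unreach
  d
}

#' Graph variants for ablation studies
#'
#' * `fully_connected`: every ordered pair of genes, self-loops
#'   included, is an edge.
#' * `sparsified`: a uniform random subsample of `round(fraction * E)`
#'   of the original edges, without replacement.
#' * `randomized`: same node count and edge count, with the original
#'   self-loops preserved and the remaining edges placed uniformly at
#'   random among non-loop ordered pairs.
#'
#' @param graph A [gene_graph].
#' @param kind One of `"fully_connected"`, `"sparsified"`,
#'   `"randomized"`.
#' @param fraction Edge fraction in (0, 1); `sparsified` only.
#' @param seed Integer seed (sparsified/randomized).
#' @return A [gene_graph] on the same vocabulary.
#' @export
make_variant <- function(graph, kind = c("fully_connected", "sparsified",
                                         "randomized"),
                         fraction = NULL, seed = 1) {
  stopifnot(inherits(graph, "gene_graph"))
  kind <- match.arg(kind)
  G <- length(graph$gene_ids)
  if (kind == "fully_connected") {
    edges <- cbind(rep(seq_len(G), each = G), rep(seq_len(G), times = G))
    return(gene_graph(graph$gene_ids, edges))
  }
  set.seed(as.integer(seed))
  if (kind == "sparsified") {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1)
      stop("sparsified variant needs fraction in (0, 1)")
    keep <- sample(nrow(graph$edges), round(fraction * nrow(graph$edges)))
    return(gene_graph(graph$gene_ids, graph$edges[keep, , drop = FALSE]))
  }
  # randomized: preserve node count, edge count and self-loops
  loops <- graph$edges[graph$edges[, 1] == graph$edges[, 2], , drop = FALSE]
  n_other <- nrow(graph$edges) - nrow(loops)
  # sample ordered non-loop pairs without replacement via linear indices
  pool <- as.numeric(G) * (G - 1)
  if (n_other > pool) stop("edge count exceeds available ordered pairs")
  lin <- sample(pool, n_other)
  src <- ((lin - 1) %/% (G - 1)) + 1
  off <- ((lin - 1) %% (G - 1)) + 1
  tgt <- ifelse(off >= src, off + 1, off)
  gene_graph(graph$gene_ids, rbind(loops, cbind(src, tgt)))
}
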