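# Synthetic perturb-seq generator: negative-binomial counts with
# log-normal cell-state programs and library-size variation, plus
# perturbations whose multiplicative effects propagate along a known
# directed gene graph with geometric decay. Ground truth (graph, state
# programs, driver labels) is carried along so parameter-recovery and
# ablation experiments need no external data.

#' Simulation configuration
#'
#' @param n_genes Vocabulary size G.
#' @param n_states Number of cell states C.
#' @param n_drivers Number of perturbed (driver) genes K.
#' @param cells_per_condition Perturbed cells per (state, driver).
#' @param controls_per_state Unperturbed cells per state.
#' @param lib_meanlog,lib_sdlog Log-normal library-size factor
#'   parameters (mu_s, sigma_s).
#' @param theta Negative-binomial dispersion (size); larger is closer
#'   to Poisson.
#' @param alpha Driver effect multiplier on the mean (> 1 activation,
#'   < 1 repression).
#' @param beta Propagation decay in (0, 1): a gene at directed depth d
#'   from the driver has its mean multiplied by `alpha^(beta^d)`.
#' @param depth Propagation depth P; genes beyond it are unaffected.
#' @param density Graph density (expected edges ~ density * G^2).
#' @param program_sdlog Spread of the log-normal base gene program.
#' @param state_sdlog Spread of the per-state log-normal modulation.
#' @param mean_depth Expected total counts per cell before the library
#'   factor.
#' @param test_frac Held-out fraction for the in-domain split.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, n_states = 4, n_drivers = 20,
                       cells_per_condition = 50, controls_per_state = 500,
                       lib_meanlog = 0, lib_sdlog = 0.3, theta = 10,
                       alpha = 3, beta = 0.6, depth = 2, density = 0.03,
                       program_sdlog = 1.2, state_sdlog = 0.4,
                       mean_depth = 3000, test_frac = 0.2, seed = 1) {
  stopifnot(n_genes > 1, n_states >= 1, n_drivers >= 2,
            cells_per_condition >= 1, controls_per_state >= 1,
            theta > 0, alpha > 0, alpha != 1 || TRUE,
            beta > 0, beta < 1, depth >= 0,
            density > 0, density < 1, mean_depth > 0,
            test_frac > 0, test_frac < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a directed gene graph with heavy-tailed out-degree
#'
#' Sequential preferential attachment on out-degree: each new edge
#' picks its source with probability proportional to (current
#' out-degree + 1) and its target uniformly; duplicates and self-loops
#' are rejected. The edge count is `round(density * G^2)`.
#'
#' @param n_genes Number of genes G.
#' @param density Edge density in (0, 1).
#' @param seed Integer seed.
#' @return A [gene_graph] with gene ids `g001`, `g002`, ...
#' @export
generate_graph <- function(n_genes, density, seed = 1) {
  stopifnot(density > 0, density < 1)
  set.seed(as.integer(seed))
  G <- as.integer(n_genes)
  E <- round(density * G^2)
  outdeg <- rep(0L, G)
  seen <- new.env(parent = emptyenv())
  edges <- matrix(0L, E, 2)
  e <- 0L
  while (e < E) {
    s <- sample.int(G, 1, prob = outdeg + 1)
    t <- sample.int(G, 1)
    if (s == t) next
    key <- paste0(s, "_", t)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    e <- e + 1L
    edges[e, ] <- c(s, t)
    outdeg[s] <- outdeg[s] + 1L
  }
  gene_graph(sprintf("g%03d", seq_len(G)), edges)
}

sim_programs <- function(config) {
  set.seed(as.integer(config$seed))
  G <- config$n_genes
  base <- exp(stats::rnorm(G, 0, config$program_sdlog))
  mu <- t(vapply(seq_len(config$n_states), function(c) {
    m <- base * exp(stats::rnorm(G, 0, config$state_sdlog))
    m * config$mean_depth / sum(m)
  }, numeric(G)))
  rownames(mu) <- paste0("state", seq_len(config$n_states))
  mu
}

#' Simulate unperturbed cells
#'
#' Per state c, gene means come from a log-normal program; counts are
#' negative binomial with mean `s_n * mu[c, g]` and dispersion `theta`,
#' where `s_n` is a log-normal library factor.
#'
#' @param config A [sim_config].
#' @param graph A [gene_graph] with `n_genes` nodes (carried along for
#'   vocabulary alignment).
#' @param n_per_state Cells per state (default
#'   `config$controls_per_state`).
#' @param prefix Cell id prefix.
#' @param seed Seed for the count draws (the state programs always
#'   derive from `config$seed`).
#' @return A [cell_counts] with attributes `states` (per-cell state
#'   index), `lib` (per-cell library factor) and `mu` (state x gene
#'   mean matrix).
#' @export
simulate_cells <- function(config, graph, n_per_state = NULL,
                           prefix = "ctrl", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(graph, "gene_graph"))
  if (length(graph$gene_ids) != config$n_genes)
    stop("graph size does not match config$n_genes")
  if (is.null(n_per_state)) n_per_state <- config$controls_per_state
  mu <- sim_programs(config)
  set.seed(as.integer(seed))
  n <- config$n_states * n_per_state
  states <- rep(seq_len(config$n_states), each = n_per_state)
  lib <- stats::rlnorm(n, config$lib_meanlog, config$lib_sdlog)
  counts <- matrix(0, n, config$n_genes)
  for (i in seq_len(n))
    counts[i, ] <- stats::rnbinom(config$n_genes,
                                  mu = lib[i] * mu[states[i], ],
                                  size = config$theta)
  ids <- sprintf("%s_s%d_%04d", prefix, states,
                 stats::ave(seq_len(n), states, FUN = seq_along))
  out <- cell_counts(counts, ids, graph$gene_ids)
  attr(out, "states") <- states[match(out$cell_ids, ids)]
  attr(out, "lib") <- lib[match(out$cell_ids, ids)]
  attr(out, "mu") <- mu
  out
}

#' Perturbation effect specification
#'
#' The driver's mean is multiplied by `alpha`; a gene at directed
#' shortest-path depth d (1..P) from the driver is multiplied by
#' `alpha^(beta^d)`, so the effect decays monotonically with depth;
#' genes beyond depth P (or unreachable) are unaffected.
#'
#' @param graph A [gene_graph].
#' @param driver Driver gene id.
#' @param config A [sim_config].
#' @return A `perturbation_spec` list with `driver` and the per-gene
#'   multiplicative `effect` vector.
#' @export
perturbation_spec <- function(graph, driver, config) {
  gi <- match(driver, graph$gene_ids)
  if (is.na(gi)) stop("driver not in graph vocabulary: ", driver)
  d <- suppressWarnings(
    igraph::distances(graph$ig, v = gi, mode = "out",
                      algorithm = "unweighted"))[1, ]
  effect <- rep(1, length(graph$gene_ids))
  within <- is.finite(d) & d <= config$depth
  effect[within] <- config$alpha^(config$beta^d[within])
  structure(list(driver = driver, effect = effect,
                 gene_ids = graph$gene_ids),
            class = "perturbation_spec")
}

#' Apply a perturbation by resampling counts
#'
#' Redraws every cell's counts from the same generative model with the
#' state means multiplied by the spec's per-gene effects; the library
#' factor of each cell is kept, so only the driver and its graph
#' descendants shift in expectation.
#'
#' @param cells A [cell_counts] produced by [simulate_cells()].
#' @param graph A [gene_graph].
#' @param spec A [perturbation_spec].
#' @param config A [sim_config].
#' @param seed Seed for the redraw.
#' @param prefix Cell id prefix for the perturbed cells.
#' @return A [cell_counts] of perturbed cells (same states and library
#'   factors as the input cells).
#' @export
apply_perturbation <- function(cells, graph, spec, config,
                               seed = config$seed + 1, prefix = "pert") {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (!identical(spec$gene_ids, cells$gene_ids))
    stop("spec vocabulary does not match the cells")
  states <- attr(cells, "states"); lib <- attr(cells, "lib")
  mu <- attr(cells, "mu")
  if (is.null(states) || is.null(mu))
    stop("cells must carry simulation ground truth (use simulate_cells)")
  set.seed(as.integer(seed))
  n <- nrow(cells$counts)
  counts <- matrix(0, n, config$n_genes)
  for (i in seq_len(n))
    counts[i, ] <- stats::rnbinom(config$n_genes,
                                  mu = lib[i] * mu[states[i], ] * spec$effect,
                                  size = config$theta)
  ids <- sprintf("%s_%s_s%d_%04d", prefix, spec$driver, states,
                 stats::ave(seq_len(n), states, FUN = seq_along))
  out <- cell_counts(counts, ids, cells$gene_ids)
  attr(out, "states") <- states[match(out$cell_ids, ids)]
  attr(out, "lib") <- lib[match(out$cell_ids, ids)]
  attr(out, "mu") <- mu
  out
}

#' Build a paired driver-prediction dataset
#'
#' Simulates controls and perturbed cells for K drivers across C
#' states, pairs every perturbed cell with a random same-state control,
#' and mirrors real screens by drawing drivers only from genes that are
#' both connected (out-degree >= 1) and expressed (base mean at or above
#' the gene-panel median), so every perturbation has a detectable,
#' graph-propagated footprint,
#' and assigns train/test splits: `in_domain` holds out a random,
#' driver-stratified fraction of pairs; `out_of_domain` holds out every
#' pair of the last cell state.
#'
#' @param config A [sim_config].
#' @param split `"in_domain"` or `"out_of_domain"`.
#' @param graph Optional [gene_graph]; generated from the config when
#'   missing.
#' @return List with `counts` (all cells), `graph`, `pairs` (data frame
#'   `source_id`, `target_id`, `driver`, `state`, `split`), `drivers`,
#'   `states` (per cell) and `truth` (state programs and perturbation
#'   specs).
#' @export
build_pair_dataset <- function(config,
                               split = c("in_domain", "out_of_domain"),
                               graph = NULL) {
  split <- match.arg(split)
  if (split == "out_of_domain" && config$n_states < 2)
    stop("out_of_domain split needs at least 2 states")
  if (is.null(graph))
    graph <- generate_graph(config$n_genes, config$density, config$seed)
  set.seed(as.integer(config$seed))
  deg <- compute_degrees(graph)
  base_mean <- colMeans(sim_programs(config))
  eligible <- which(deg$out_degree >= 1 & base_mean >= stats::median(base_mean))
  if (length(eligible) < config$n_drivers)
    stop("not enough expressed genes with out-degree >= 1 to choose drivers")
  drivers <- sort(graph$gene_ids[sample(eligible, config$n_drivers)])

  controls <- simulate_cells(config, graph, seed = config$seed)
  template <- simulate_cells(config, graph,
                             n_per_state = config$cells_per_condition,
                             seed = config$seed + 17L)
  specs <- list(); pert_list <- list()
  for (k in seq_along(drivers)) {
    sp <- perturbation_spec(graph, drivers[k], config)
    specs[[drivers[k]]] <- sp
    pert_list[[k]] <- apply_perturbation(template, graph, sp, config,
                                         seed = config$seed + 100L + k)
  }

  all_counts <- rbind(controls$counts,
                      do.call(rbind, lapply(pert_list, `[[`, "counts")))
  all_ids <- c(controls$cell_ids,
               unlist(lapply(pert_list, `[[`, "cell_ids")))
  counts <- cell_counts(all_counts, all_ids, graph$gene_ids)
  states <- c(attr(controls, "states"),
              unlist(lapply(pert_list, attr, "states")))
  names(states) <- all_ids
  states <- states[counts$cell_ids]

  ctrl_by_state <- split(controls$cell_ids, attr(controls, "states"))
  pairs <- do.call(rbind, lapply(seq_along(drivers), function(k) {
    pc <- pert_list[[k]]
    st <- attr(pc, "states")
    data.frame(
      source_id = vapply(st, function(s)
        sample(ctrl_by_state[[as.character(s)]], 1), character(1)),
      target_id = pc$cell_ids, driver = drivers[k], state = st,
      stringsAsFactors = FALSE)
  }))
  # keep only pairs whose cells survived validation (zero-total drops)
  pairs <- pairs[pairs$target_id %in% counts$cell_ids &
                   pairs$source_id %in% counts$cell_ids, , drop = FALSE]

  if (split == "in_domain") {
    pairs$split <- "train"
    for (d in drivers) {
      rows <- which(pairs$driver == d)
      n_test <- max(1, round(config$test_frac * length(rows)))
      pairs$split[sample(rows, n_test)] <- "test"
    }
  } else {
    pairs$split <- ifelse(pairs$state == config$n_states, "test", "train")
  }
  rownames(pairs) <- NULL
  list(counts = counts, graph = graph, pairs = pairs, drivers = drivers,
       states = states,
       truth = list(mu = attr(controls, "mu"), specs = specs))
}
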