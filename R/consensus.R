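# Order-randomized ensemble: many searches per algorithm under random
# variable orders, edge-frequency tallies, threshold consensus and
# cross-algorithm merging into one robust DAG.

#' Ensemble configuration
#'
#' @param M Runs per algorithm (the reference analysis used 1,000; scale
#'   down for experimentation).
#' @param tau Frequency threshold applied to `count / M`; an edge
#'   "consistently appears" when its frequency reaches `tau` (>=
#'   comparison). Default 0.6.
#' @param merge_rule `"majority_of_algorithms"` (kept when it qualifies
#'   in more than half of the ensembles) or `"intersection"` (all).
#' @param master_seed Seed for the stream of per-run variable orders.
#' @return Object of class `consensus_config`.
#' @export
consensus_config <- function(M = 1000L, tau = 0.6,
                             merge_rule = c("majority_of_algorithms",
                                            "intersection"),
                             master_seed = 1L) {
  merge_rule <- match.arg(merge_rule)
  stopifnot(M >= 1, tau > 0, tau <= 1)
  structure(list(M = as.integer(M), tau = tau, merge_rule = merge_rule,
                 master_seed = as.integer(master_seed)),
            class = "consensus_config")
}

#' Run one algorithm M times under random variable orders
#'
#' Each run draws a fresh permutation from the master seed's stream; a
#' directed tally increments when the run outputs tail -> arrow for the
#' ordered pair, any other surviving edge (undirected or circle-marked)
#' increments the undirected tally. A failed run aborts the ensemble —
#' no silent partial tallies.
#'
#' @param x An [rd_dataset] or CI engine (the correlation matrix is
#'   computed once and shared across runs).
#' @param algo `"pc_original"`, `"pc_stable"`, `"pc_parallel"` or
#'   `"fci"`.
#' @param bk A [background_knowledge].
#' @param cfg A [consensus_config].
#' @param alpha CI-test level passed to each run.
#' @param keep_graphs Retain the individual run graphs (for audit).
#' @return Object of class `edge_frequency_table`: `algorithm`, `M`,
#'   `counts` (VxV directed tallies), `undirected_counts` (upper
#'   triangle), `seeds`, `nodes`.
#' @export
randomized_runs <- function(x, algo, bk = background_knowledge(),
                            cfg = consensus_config(), alpha = 0.05,
                            keep_graphs = FALSE) {
  stopifnot(algo %in% c("pc_original", "pc_stable", "pc_parallel", "fci"))
  engine <- as_engine(x, alpha)
  nodes <- engine$nodes
  V <- length(nodes)
  set.seed(cfg$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$M)
  counts <- matrix(0L, V, V, dimnames = list(nodes, nodes))
  und <- matrix(0L, V, V, dimnames = list(nodes, nodes))
  graphs <- if (keep_graphs) vector("list", cfg$M) else NULL
  for (m in seq_len(cfg$M)) {
    set.seed(seeds[m])
    ord <- sample(nodes)
    scfg <- search_config(alpha = alpha, variant = algo,
                          variable_order = ord)
    g <- if (algo == "fci") run_fci(engine, scfg, bk)
         else run_pc(engine, scfg, bk)
    am <- g$amat
    dirs <- (am == MARK_ARROW) & (t(am) == MARK_TAIL)
    counts <- counts + dirs
    other <- (am != 0L) & !dirs & !t(dirs) & upper.tri(am)
    und <- und + other
    if (keep_graphs) graphs[[m]] <- g
  }
  structure(list(algorithm = algo, M = cfg$M, counts = counts,
                 undirected_counts = und, seeds = seeds, nodes = nodes,
                 graphs = graphs),
            class = "edge_frequency_table")
}

#' @export
print.edge_frequency_table <- function(x, ...) {
  cat("<edge_frequency_table> ", x$algorithm, ", M=", x$M, ", ",
      sum(x$counts > 0) + sum(x$undirected_counts > 0),
      " pairs ever seen\n", sep = "")
  invisible(x)
}

#' Per-edge frequency report
#'
#' Sorted listing of every tallied edge for audit and plotting.
#'
#' @param table An `edge_frequency_table`.
#' @return data.frame `from`, `to`, `direction` (`"->"` or `"--"`),
#'   `count`, `M`, `frequency`, sorted by decreasing frequency then
#'   lexicographically.
#' @export
stability_profile <- function(table) {
  nodes <- table$nodes
  rows <- list()
  idx <- which(table$counts > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    rows[[length(rows) + 1L]] <- data.frame(
      from = nodes[idx[r, 1]], to = nodes[idx[r, 2]], direction = "->",
      count = table$counts[idx[r, 1], idx[r, 2]], M = table$M,
      stringsAsFactors = FALSE)
  }
  idx <- which(table$undirected_counts > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    rows[[length(rows) + 1L]] <- data.frame(
      from = nodes[idx[r, 1]], to = nodes[idx[r, 2]], direction = "--",
      count = table$undirected_counts[idx[r, 1], idx[r, 2]], M = table$M,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(from = character(), to = character(),
                      direction = character(), count = integer(),
                      M = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$frequency <- out$count / out$M
  out[order(-out$frequency, out$from, out$to), , drop = FALSE]
}

#' Merge ensemble tallies into one consensus graph
#'
#' Within each algorithm an unordered pair qualifies when its total
#' support across the M runs -- directed occurrences in either
#' direction plus undirected/circle occurrences -- reaches `tau` (>=
#' comparison); the algorithm commits to a direction only when that
#' direction alone was output in at least `tau` of the runs -- an
#' unstable 50/50 direction split is evidence about presence, not
#' orientation, and committing to its majority would seed spurious
#' cycles. Algorithms are then merged by the configured rule, the
#' consensus outcome being the modal vote among qualifying algorithms
#' (ties to undirected). Undirected consensus edges remain in
#' the output graph and are additionally listed in attribute
#' `undirected_leftovers`; any directed cycle is repaired by
#' iteratively deleting, within each cycle, the edge with the lowest
#' mean directed frequency.
#'
#' @param tables List of `edge_frequency_table`s over one node set.
#' @param cfg A [consensus_config].
#' @return A [mixed_graph] of kind `"dag"` (its directed view is
#'   acyclic; undirected edges may remain).
#' @export
consensus_graph <- function(tables, cfg = consensus_config()) {
  if (inherits(tables, "edge_frequency_table")) tables <- list(tables)
  nodes <- tables[[1]]$nodes
  for (tb in tables) if (!identical(tb$nodes, nodes))
    stop("edge-frequency tables disagree on the node set")
  V <- length(nodes)
  n_alg <- length(tables)
  need <- if (cfg$merge_rule == "intersection") n_alg else floor(n_alg / 2) + 1L
  dir_votes <- matrix(0L, V, V)      # algorithm votes for i -> j
  und_votes <- matrix(0L, V, V)      # votes for i -- j (upper triangle)
  freq_sum <- matrix(0, V, V)        # directed frequency accumulator
  for (tb in tables) {
    f <- tb$counts / tb$M
    freq_sum <- freq_sum + f
    u <- (tb$undirected_counts + t(tb$undirected_counts)) / tb$M
    for (i in seq_len(V)) for (j in seq_len(V)) {
      if (j <= i) next
      if (f[i, j] + f[j, i] + u[i, j] < cfg$tau) next
      # direction committed only at >= tau for that direction alone
      if (f[i, j] >= cfg$tau && f[i, j] > f[j, i])
        dir_votes[i, j] <- dir_votes[i, j] + 1L
      else if (f[j, i] >= cfg$tau && f[j, i] > f[i, j])
        dir_votes[j, i] <- dir_votes[j, i] + 1L
      else und_votes[i, j] <- und_votes[i, j] + 1L
    }
  }
  g <- mixed_graph(nodes, kind = "dag")
  leftovers <- list()
  for (i in seq_len(V)) for (j in seq_len(V)) {
    if (j <= i) next
    votes <- dir_votes[i, j] + dir_votes[j, i] + und_votes[i, j]
    if (votes < need) next
    if (dir_votes[i, j] > dir_votes[j, i] &&
        dir_votes[i, j] > und_votes[i, j]) {
      g <- add_directed_edge(g, nodes[i], nodes[j])
    } else if (dir_votes[j, i] > dir_votes[i, j] &&
               dir_votes[j, i] > und_votes[i, j]) {
      g <- add_directed_edge(g, nodes[j], nodes[i])
    } else {
      g <- add_undirected_edge(g, nodes[i], nodes[j])
      leftovers[[length(leftovers) + 1L]] <-
        data.frame(a = nodes[i], b = nodes[j], stringsAsFactors = FALSE)
    }
  }
  # cycle repair: delete the lowest-mean-frequency edge inside each cycle
  mean_freq <- freq_sum / n_alg
  repeat {
    A <- dag_view(g)
    if (!has_cycle_adj(A)) break
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    comp <- igraph::components(ig, mode = "strong")
    cyc <- which(comp$csize > 1)[1]
    members <- which(comp$membership == cyc)
    worst <- NULL; worst_f <- Inf
    for (i in members) for (j in members) {
      if (A[i, j] == 1L && mean_freq[i, j] < worst_f) {
        worst <- c(i, j); worst_f <- mean_freq[i, j]
      }
    }
    g$amat[worst[1], worst[2]] <- MARK_NONE
    g$amat[worst[2], worst[1]] <- MARK_NONE
  }
  attr(g, "undirected_leftovers") <-
    if (length(leftovers) > 0L) do.call(rbind, leftovers)
    else data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  validate_graph(g)
  g
}
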