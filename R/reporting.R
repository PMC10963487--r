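# Reporting: stratified detection-rate tables, local causal
# neighborhoods around a target node, pathway enumeration, and
# upstream/downstream (ancestor/descendant) sets.

#' Stratified detection rates for a binary outcome
#'
#' One row per level of each stratifying variable plus an overall row.
#' Rates are percentages with two decimals, rounded half-up, matching
#' the display convention of descriptive survey tables.
#'
#' @param d An [rd_dataset] (encoded; outcome coded 0/1).
#' @param outcome Name of the binary outcome variable.
#' @param strata Character vector of stratifying variable names (may be
#'   empty for the overall rate only).
#' @return data.frame with `stratum`, `level`, `n_total`, `n_positive`,
#'   `rate` (percent, 2 decimals; `NA` and flagged when a stratum is
#'   empty — empty strata are reported, not dropped).
#' @export
detection_rates <- function(d, outcome, strata = character()) {
  m <- meta_by_name(d, outcome)
  if (m$var_type != "binary")
    stop("outcome '", outcome, "' is not binary")
  y <- as.numeric(d$values[, outcome])
  rows <- list()
  add_row <- function(stratum, level, idx) {
    nt <- sum(!is.na(y[idx]))
    np <- sum(y[idx] == 1, na.rm = TRUE)
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum = stratum, level = level, n_total = nt, n_positive = np,
      rate = if (nt > 0) round_half_up(100 * np / nt, 2L) else NA_real_,
      stringsAsFactors = FALSE)
  }
  add_row("overall", "all", seq_len(d$n))
  for (s in strata) {
    sm <- meta_by_name(d, s)
    x <- d$values[, s]
    if (sm$var_type == "continuous")
      stop("stratum '", s, "' is continuous; stratify on discrete variables")
    for (k in seq_along(sm$level_order)) {
      code <- k - 1L
      idx <- which(!is.na(x) & (x == code | x == sm$level_order[k]))
      add_row(s, sm$level_order[k], idx)
    }
  }
  do.call(rbind, rows)
}

#' Rate from a printed numerator/denominator pair
#'
#' The same two-decimal half-up convention used by [detection_rates],
#' exposed for recomputing published table entries.
#'
#' @param n_positive,n_total Counts.
#' @return Percentage with two decimals.
#' @export
rate_percent <- function(n_positive, n_total) {
  stopifnot(n_total > 0, n_positive <= n_total)
  round_half_up(100 * n_positive / n_total, 2L)
}

#' Local causal neighborhood of a target node
#'
#' Induced subgraph on all nodes within undirected graph distance
#' `steps` of the target (edge direction is ignored for the distance, so
#' both parents and children at each step are included); edge marks are
#' preserved.
#'
#' @param g A [mixed_graph].
#' @param target Node name.
#' @param steps Maximum distance (default 2: direct plus secondary
#'   neighbors).
#' @return The induced [mixed_graph].
#' @export
local_neighborhood <- function(g, target, steps = 2L) {
  ti <- match(target, g$nodes)
  if (is.na(ti)) stop("unknown target node: ", target)
  stopifnot(steps >= 1L)
  ig <- as_igraph_skeleton(g)
  dist <- igraph::distances(ig, v = ti)[1, ]
  keep <- which(dist <= steps)
  sub <- mixed_graph(g$nodes[keep], kind = g$kind)
  sub$amat <- g$amat[keep, keep, drop = FALSE]
  sub
}

#' Enumerate directed pathways into a target
#'
#' All directed (tail -> arrow) paths ending at the target with at most
#' `max_len` edges, deduplicated and sorted by (length, lexicographic
#' node sequence) so output is exactly reproducible. When a
#' [weighted_digraph] is supplied each traversed edge is annotated with
#' its risk/protective polarity.
#'
#' @param g A [mixed_graph] whose DAG view is acyclic.
#' @param target Node name.
#' @param max_len Maximum number of edges per pathway (default 6).
#' @param weights Optional thresholded [weighted_digraph] for polarity
#'   annotation.
#' @return List of `causal_pathway` objects (`nodes`, `polarity`).
#' @export
enumerate_pathways <- function(g, target, max_len = 6L, weights = NULL) {
  ti <- match(target, g$nodes)
  if (is.na(ti)) stop("unknown target node: ", target)
  A <- dag_view(g)
  if (has_cycle_adj(A))
    stop("pathway semantics require an acyclic graph")
  # depth-first walk backwards from the target
  paths <- list()
  walk <- function(path) {
    head <- path[1]
    pa <- which(A[, head] == 1L)
    for (p in pa) {
      if (p %in% path) next
      newp <- c(p, path)
      paths[[length(paths) + 1L]] <<- newp
      if (length(newp) - 1L < max_len) walk(newp)
    }
  }
  walk(ti)
  if (length(paths) == 0L) return(list())
  key <- vapply(paths, function(p) paste(g$nodes[p], collapse = "\r"),
                character(1))
  ordc <- order(lengths(paths), key)
  paths <- paths[ordc]
  lapply(paths, function(p) {
    nodes <- g$nodes[p]
    pol <- NULL
    if (!is.null(weights)) {
      pol <- vapply(seq_len(length(nodes) - 1L), function(i) {
        w <- weights$A[nodes[i], nodes[i + 1L]]
        if (w > 0) "risk" else if (w < 0) "protective" else NA_character_
      }, character(1))
    }
    structure(list(nodes = nodes, polarity = pol), class = "causal_pathway")
  })
}

#' @export
print.causal_pathway <- function(x, ...) {
  cat(paste(x$nodes, collapse = " -> "))
  if (!is.null(x$polarity))
    cat("   [", paste(x$polarity, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Upstream and downstream sets of a node
#'
#' Transitive closure over the DAG view in both directions: ancestors
#' act as forerunners of the node, descendants are those it can
#' influence.
#'
#' @param g A [mixed_graph].
#' @param node Node name.
#' @return List `upstream` (ancestor names), `downstream` (descendant
#'   names).
#' @export
upstream_downstream <- function(g, node) {
  ni <- match(node, g$nodes)
  if (is.na(ni)) stop("unknown node: ", node)
  ig <- as_igraph_directed(g)
  up <- igraph::subcomponent(ig, ni, mode = "in")
  down <- igraph::subcomponent(ig, ni, mode = "out")
  list(upstream = setdiff(g$nodes[as.integer(up)], node),
       downstream = setdiff(g$nodes[as.integer(down)], node))
}
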