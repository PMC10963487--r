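# Structural-causal-model survey simulator.
#
# Ground truth is a weighted DAG with Gaussian noise; ordinal and binary
# variables arise by thresholding a latent continuous value, and the
# DISCRETIZED code (not the latent) feeds children, so downstream
# structure recovery is tested under the same coarsening a real survey
# imposes.

#' Construct a structural-causal-model specification
#'
#' @param graph A [mixed_graph] of kind `"dag"`; ground-truth structure.
#' @param weights Named numeric vector of signed linear coefficients,
#'   names `"parent->child"`, keyed exactly by the DAG's edges.
#' @param noise_sd Named numeric vector (one positive entry per node).
#' @param thresholds Named list: for each discrete node, a strictly
#'   increasing numeric vector of cut points on its latent scale; a node
#'   with k cut points yields k+1 ordinal codes 0..k.
#' @param tiers Named character vector, one of `"exogenous_fixed"`,
#'   `"exogenous_covid"`, `"endogenous"` per node. No edge may point
#'   into an exogenous node.
#' @param levels Optional named list of level labels for discrete nodes
#'   (defaults to `"0"`, `"1"`, ...).
#' @return Object of class `scm_spec`.
#' @export
scm_spec <- function(graph, weights, noise_sd, thresholds = list(),
                     tiers = NULL, levels = list()) {
  validate_graph(graph)
  if (!identical(graph$kind, "dag")) stop("spec graph must have kind 'dag'")
  nodes <- graph$nodes
  A <- dag_view(graph)
  ekeys <- edge_keys(A)
  if (!setequal(names(weights), ekeys))
    stop("weights must be keyed exactly by the DAG's edges; mismatch: ",
         paste(c(setdiff(ekeys, names(weights)),
                 setdiff(names(weights), ekeys)), collapse = ", "))
  if (!setequal(names(noise_sd), nodes) || any(noise_sd <= 0))
    stop("noise_sd needs one positive entry per node")
  for (nm in names(thresholds)) {
    th <- thresholds[[nm]]
    if (length(th) > 0L && any(diff(th) <= 0))
      stop("thresholds for '", nm, "' must be strictly increasing")
  }
  if (is.null(tiers)) tiers <- stats::setNames(rep("endogenous", length(nodes)), nodes)
  if (!setequal(names(tiers), nodes)) stop("tiers must cover every node")
  exo <- names(tiers)[tiers != "endogenous"]
  for (nm in exo) {
    if (any(A[, nm] != 0L))
      stop("edge points into exogenous node '", nm, "'")
  }
  structure(list(graph = graph, weights = weights,
                 noise_sd = noise_sd[nodes], thresholds = thresholds,
                 tiers = tiers[nodes], levels = levels),
            class = "scm_spec")
}

edge_keys <- function(A) {
  idx <- which(A != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(character())
  paste0(rownames(A)[idx[, 1]], "->", colnames(A)[idx[, 2]])
}

#' @export
print.scm_spec <- function(x, ...) {
  cat("<scm_spec> ", length(x$graph$nodes), " nodes, ",
      length(x$weights), " weighted edges, ",
      sum(x$tiers != "endogenous"), " exogenous\n", sep = "")
  invisible(x)
}

# deterministic per-node substream: adding a node never perturbs the
# draws of existing nodes
node_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1073741789
  as.integer((h + as.numeric(seed) * 7919) %% 2147483629)
}

#' Sample a survey dataset from an SCM specification
#'
#' Ancestral sampling in topological order:
#' `latent(v) = sum_parents w * value(parent) + N(0, noise_sd_v)`, where
#' `value(parent)` is the parent's discretized code if the parent is
#' ordinal/binary. Discrete nodes are then coded by counting thresholds
#' below the latent. With `nonlinear = TRUE` the summed parent
#' contribution passes through `tanh` before noise is added.
#'
#' @param spec An [scm_spec].
#' @param n Sample size (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param nonlinear Apply the fixed smooth monotone transform.
#' @return An [rd_dataset]; discrete columns hold 0-based codes, and the
#'   metadata carries the level labels, so [encode_ordinal] is a no-op on
#'   simulator output.
#' @export
sample_scm <- function(spec, n, seed = 1L, nonlinear = FALSE) {
  stopifnot(inherits(spec, "scm_spec"), n >= 1)
  nodes <- spec$graph$nodes
  A <- dag_view(spec$graph)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  topo <- nodes[as.integer(igraph::topo_sort(ig, mode = "out"))]
  vals <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in topo) {
    pa <- nodes[A[, v] != 0L]
    contrib <- numeric(n)
    for (p in pa) contrib <- contrib + spec$weights[[paste0(p, "->", v)]] * vals[, p]
    if (nonlinear && length(pa) > 0L) contrib <- tanh(contrib)
    set.seed(node_seed(seed, v))
    latent <- contrib + stats::rnorm(n, 0, spec$noise_sd[[v]])
    th <- spec$thresholds[[v]]
    if (is.null(th) || length(th) == 0L) {
      vals[, v] <- latent
    } else {
      vals[, v] <- as.numeric(rowSums(outer(latent, th, `>`)))
    }
  }
  meta <- lapply(nodes, function(v) {
    th <- spec$thresholds[[v]]
    if (is.null(th) || length(th) == 0L) {
      variable_meta(v, "continuous", spec$tiers[[v]])
    } else {
      k <- length(th) + 1L
      lv <- spec$levels[[v]]
      if (is.null(lv)) lv <- as.character(seq_len(k) - 1L)
      variable_meta(v, if (k == 2L) "binary" else "ordinal",
                    spec$tiers[[v]], lv)
    }
  })
  d <- rd_dataset(vals, meta)
  attr(d, "pre_encoded") <- TRUE
  d
}

#' Inject missing values into a dataset (corruption for preprocessing tests)
#'
#' Kept separate from [sample_scm] so the generator itself always emits
#' complete data.
#'
#' @param d An [rd_dataset].
#' @param rate Fraction of cells set to `NA` uniformly at random.
#' @param seed Integer seed.
#' @param blank_blocks Optional list of `list(vars=, rows=)` entries that
#'   blank whole variable blocks for the given rows (emulating absent
#'   caregiver questionnaires).
#' @return The corrupted dataset.
#' @export
inject_missing <- function(d, rate = 0, seed = 1L, blank_blocks = NULL) {
  set.seed(seed)
  v <- d$values
  if (rate > 0) {
    mask <- matrix(stats::runif(length(v)) < rate, nrow(v))
    v[mask] <- NA_real_
  }
  for (bl in blank_blocks) {
    v[bl$rows, bl$vars] <- NA_real_
  }
  d$values <- v
  d
}

#' Per-variable marginal summary
#'
#' For each discrete variable, level counts and percentages; for each
#' continuous variable, mean and standard deviation. Percentages use two
#' decimals, rounded half-up, as survey tables print them.
#'
#' @param d An [rd_dataset].
#' @return data.frame with columns `variable`, `level`, `count`,
#'   `percent`, `mean`, `sd`.
#' @export
marginal_report <- function(d) {
  rows <- list()
  for (m in d$meta) {
    x <- d$values[, m$name]
    x <- x[!is.na(x)]
    if (m$var_type == "continuous") {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = m$name, level = NA_character_, count = length(x),
        percent = NA_real_, mean = mean(x), sd = stats::sd(x),
        stringsAsFactors = FALSE)
    } else {
      for (k in seq_along(m$level_order)) {
        cnt <- sum(x == k - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = m$name, level = m$level_order[k], count = cnt,
          percent = round_half_up(100 * cnt / length(x), 2L),
          mean = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# ---------------------------------------------------------------------------
# YAML serialization of specs ------------------------------------------------

#' Serialize an SCM spec to YAML
#' @param spec An [scm_spec]. @param path Output file.
#' @export
write_scm_spec <- function(spec, path) {
  e <- graph_edges(spec$graph)
  obj <- list(
    nodes = lapply(spec$graph$nodes, function(v) {
      list(name = v, tier = unname(spec$tiers[[v]]),
           noise_sd = unname(spec$noise_sd[[v]]),
           thresholds = as.list(spec$thresholds[[v]]),
           levels = as.list(spec$levels[[v]]))
    }),
    edges = lapply(seq_len(nrow(e)), function(i) {
      key <- paste0(e$a[i], "->", e$b[i])
      if (!key %in% names(spec$weights)) key <- paste0(e$b[i], "->", e$a[i])
      p <- strsplit(key, "->", fixed = TRUE)[[1]]
      list(from = p[1], to = p[2], weight = unname(spec$weights[[key]]))
    }))
  yaml::write_yaml(obj, path)
}

#' Read an SCM spec from YAML written by [write_scm_spec]
#' @param path Input file.
#' @return An [scm_spec].
#' @export
read_scm_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  nodes <- vapply(obj$nodes, `[[`, character(1), "name")
  g <- mixed_graph(nodes, kind = "dag")
  w <- numeric(0)
  for (e in obj$edges) {
    g <- add_directed_edge(g, e$from, e$to)
    w[paste0(e$from, "->", e$to)] <- e$weight
  }
  scm_spec(
    g, w,
    noise_sd = stats::setNames(vapply(obj$nodes, `[[`, numeric(1), "noise_sd"), nodes),
    thresholds = stats::setNames(
      lapply(obj$nodes, function(x) as.numeric(unlist(x$thresholds))), nodes),
    tiers = stats::setNames(vapply(obj$nodes, `[[`, character(1), "tier"), nodes),
    levels = stats::setNames(
      lapply(obj$nodes, function(x) as.character(unlist(x$levels))), nodes))
}
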