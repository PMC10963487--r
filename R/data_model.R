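# Core data containers: variable metadata, datasets, mixed graphs,
# graph comparison and serialization.

#' Variable metadata
#'
#' Describes one survey variable: its measurement type, its exogeneity
#' tier (used to forbid incoming causal arrows during search), and, for
#' discrete variables, the authoritative order of its levels.
#'
#' @param name Variable name (unique within a dataset).
#' @param var_type One of `"continuous"`, `"ordinal"`, `"binary"`.
#' @param tier One of `"exogenous_fixed"` (intrinsic attributes such as
#'   gender or school grade), `"exogenous_covid"` (pandemic-period
#'   behavioral-change indicators), `"endogenous"`.
#' @param level_order Character vector of category labels in increasing
#'   order; required for ordinal/binary variables, must be empty for
#'   continuous ones.
#' @return An object of class `variable_meta`.
#' @export
variable_meta <- function(name, var_type = c("continuous", "ordinal", "binary"),
                          tier = c("endogenous", "exogenous_fixed", "exogenous_covid"),
                          level_order = character()) {
  var_type <- match.arg(var_type)
  tier <- match.arg(tier)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  level_order <- as.character(level_order)
  if (var_type == "continuous" && length(level_order) > 0L)
    stop("continuous variable '", name, "' must not declare level_order")
  if (var_type != "continuous" && length(level_order) == 0L)
    stop("discrete variable '", name, "' requires a non-empty level_order")
  if (var_type == "binary" && length(level_order) != 2L)
    stop("binary variable '", name, "' must have exactly 2 levels")
  if (anyDuplicated(level_order))
    stop("duplicate levels in level_order of '", name, "'")
  structure(list(name = name, var_type = var_type, tier = tier,
                 level_order = level_order),
            class = "variable_meta")
}

#' Construct a dataset
#'
#' The single container flowing through the pipeline: a numeric matrix
#' of N participants by V variables plus per-variable metadata.
#' Character/factor columns are permitted before ordinal encoding;
#' missing cells are permitted before preprocessing.
#'
#' @param values Matrix or data.frame, N x V. Numeric after
#'   [encode_ordinal]; before encoding, discrete columns may still hold
#'   character level labels (the matrix is then character-mode).
#' @param meta List of [variable_meta] objects, length V, in column order.
#' @return An object of class `rd_dataset` with elements `values`
#'   (matrix), `meta`, `n`.
#' @export
rd_dataset <- function(values, meta) {
  if (is.data.frame(values)) {
    values <- if (all(vapply(values, is.numeric, logical(1))))
      as.matrix(values) else as.matrix(as.data.frame(lapply(values, as.character),
                                                     stringsAsFactors = FALSE))
  }
  if (!is.matrix(values)) stop("values must be a matrix or data.frame")
  if (!all(vapply(meta, inherits, logical(1), "variable_meta")))
    stop("meta must be a list of variable_meta objects")
  nms <- vapply(meta, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (ncol(values) != length(meta))
    stop("column count (", ncol(values), ") != metadata length (", length(meta), ")")
  colnames(values) <- nms
  structure(list(values = values, meta = meta, n = nrow(values)),
            class = "rd_dataset")
}

#' @export
print.rd_dataset <- function(x, ...) {
  cat("<rd_dataset> ", x$n, " samples x ", length(x$meta), " variables\n", sep = "")
  tiers <- vapply(x$meta, `[[`, character(1), "tier")
  cat("  tiers: ", paste(sprintf("%s=%d", names(table(tiers)), table(tiers)),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

var_names <- function(d) vapply(d$meta, `[[`, character(1), "name")
var_types <- function(d) vapply(d$meta, `[[`, character(1), "var_type")
var_tiers <- function(d) vapply(d$meta, `[[`, character(1), "tier")

meta_by_name <- function(d, name) {
  i <- match(name, var_names(d))
  if (is.na(i)) stop("unknown variable: ", name)
  d$meta[[i]]
}

#' Read a dataset from a CSV table and a metadata sheet
#'
#' @param table_path CSV file with a header row; one column per variable.
#' @param meta_path Metadata sheet, either YAML (list of records with
#'   `name`, `var_type`, `tier`, `level_order`) or CSV with those columns
#'   (`level_order` as a `|`-separated string). Every data column must be
#'   listed; columns are reordered to metadata order.
#' @return An [rd_dataset]. Rows containing missing cells are retained
#'   (filtering belongs to preprocessing) but counted in attribute
#'   `n_incomplete`.
#' @export
read_dataset <- function(table_path, meta_path) {
  tab <- utils::read.csv(table_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta <- read_meta_sheet(meta_path)
  nms <- vapply(meta, `[[`, character(1), "name")
  unknown <- setdiff(colnames(tab), nms)
  if (length(unknown) > 0L)
    stop("column(s) absent from metadata: ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(nms, colnames(tab))
  if (length(missing_cols) > 0L)
    stop("metadata lists column(s) absent from the table: ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[, nms, drop = FALSE]
  vt <- vapply(meta, `[[`, character(1), "var_type")
  for (j in seq_along(nms)) {
    col <- tab[[j]]
    if (is.character(col)) col[!is.na(col) & col == ""] <- NA
    if (vt[j] == "continuous" && is.character(col)) {
      conv <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(conv))
      if (length(bad) > 0L)
        stop("non-numeric value '", col[bad[1]], "' in continuous column '",
             nms[j], "' at row ", bad[1])
      col <- conv
    }
    tab[[j]] <- col
  }
  d <- rd_dataset(tab, meta)
  attr(d, "n_incomplete") <- sum(!stats::complete.cases(tab))
  d
}

read_meta_sheet <- function(meta_path) {
  is_yaml <- grepl("\\.(ya?ml)$", meta_path, ignore.case = TRUE)
  if (is_yaml) {
    raw <- yaml::read_yaml(meta_path)
    if (!is.null(raw$variables)) raw <- raw$variables
    lapply(raw, function(r) {
      variable_meta(r$name, r$var_type, r$tier,
                    if (is.null(r$level_order)) character() else unlist(r$level_order))
    })
  } else {
    ms <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    req <- c("name", "var_type", "tier")
    if (!all(req %in% colnames(ms)))
      stop("metadata CSV needs columns: ", paste(req, collapse = ", "))
    lapply(seq_len(nrow(ms)), function(i) {
      raw <- if ("level_order" %in% colnames(ms)) ms$level_order[i] else NA
      lo <- if (!is.na(raw) && nzchar(as.character(raw)))
        strsplit(as.character(raw), "|", fixed = TRUE)[[1]] else character()
      variable_meta(ms$name[i], ms$var_type[i], ms$tier[i], lo)
    })
  }
}

#' Write a dataset back to the CSV pair
#'
#' Inverse of [read_dataset]; numeric codes are written as-is so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param d An [rd_dataset].
#' @param table_path,meta_path Output paths (CSV table, CSV metadata).
#' @export
write_dataset <- function(d, table_path, meta_path = NULL) {
  df <- as.data.frame(d$values)
  # full 17-digit precision so a write -> read round trip is bit-exact
  for (j in seq_along(df)) if (is.numeric(df[[j]]))
    df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, table_path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    ms <- data.frame(
      name = var_names(d), var_type = var_types(d), tier = var_tiers(d),
      level_order = vapply(d$meta, function(m) paste(m$level_order, collapse = "|"),
                           character(1)),
      stringsAsFactors = FALSE)
    utils::write.csv(ms, meta_path, row.names = FALSE)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Mixed graphs ---------------------------------------------------------------

#' Construct a mixed graph
#'
#' One structure serves skeletons, CPDAGs, DAGs and PAGs. Edges carry a
#' mark at each endpoint: tail, arrow, or circle. Internally the graph is
#' a V x V integer matrix `amat` with `amat[i, j]` the mark at `j` on the
#' edge between `i` and `j` (0 = no edge, 1 = tail, 2 = arrow,
#' 3 = circle). A directed edge i -> j has `amat[i, j] == 2` and
#' `amat[j, i] == 1`.
#'
#' @param nodes Character vector of node names.
#' @param edges Optional data.frame with columns `a`, `b`, `mark_at_a`,
#'   `mark_at_b` (marks as `"tail"`, `"arrow"`, `"circle"`).
#' @param kind Label: `"skeleton"`, `"cpdag"`, `"dag"` or `"pag"`.
#' @return An object of class `mixed_graph`.
#' @export
mixed_graph <- function(nodes, edges = NULL, kind = "dag") {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  V <- length(nodes)
  amat <- matrix(0L, V, V, dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, amat = amat, kind = kind),
                 class = "mixed_graph")
  if (!is.null(edges) && nrow(edges) > 0L) {
    mk <- c(tail = MARK_TAIL, arrow = MARK_ARROW, circle = MARK_CIRCLE)
    for (i in seq_len(nrow(edges))) {
      g <- set_edge(g, edges$a[i], edges$b[i],
                    mk[[edges$mark_at_a[i]]], mk[[edges$mark_at_b[i]]])
    }
  }
  g
}

set_edge <- function(g, a, b, mark_at_a, mark_at_b) {
  ia <- match(a, g$nodes); ib <- match(b, g$nodes)
  if (is.na(ia) || is.na(ib)) stop("unknown node in edge ", a, " ~ ", b)
  if (ia == ib) stop("self-edge on ", a)
  g$amat[ib, ia] <- as.integer(mark_at_a)   # mark at a
  g$amat[ia, ib] <- as.integer(mark_at_b)   # mark at b
  g
}

#' Add a directed edge a -> b
#' @param g A [mixed_graph]. @param a,b Node names.
#' @export
add_directed_edge <- function(g, a, b) set_edge(g, a, b, MARK_TAIL, MARK_ARROW)

#' Add an undirected edge a - b
#' @param g A [mixed_graph]. @param a,b Node names.
#' @export
add_undirected_edge <- function(g, a, b) set_edge(g, a, b, MARK_TAIL, MARK_TAIL)

has_edge <- function(g, i, j) g$amat[i, j] != 0L

#' List the edges of a mixed graph
#'
#' @param g A [mixed_graph].
#' @return data.frame with one row per unordered pair: `a`, `b`,
#'   `mark_at_a`, `mark_at_b` (mark names). For directed edges the
#'   convention `a -> b` appears as `mark_at_a = "tail"`,
#'   `mark_at_b = "arrow"`.
#' @export
graph_edges <- function(g) {
  V <- length(g$nodes)
  out <- list()
  mknm <- c("tail", "arrow", "circle")
  k <- 0L
  for (i in seq_len(V)) for (j in seq_len(V)) {
    if (j <= i) next
    if (g$amat[i, j] != 0L) {
      k <- k + 1L
      out[[k]] <- data.frame(a = g$nodes[i], b = g$nodes[j],
                             mark_at_a = mknm[g$amat[j, i]],
                             mark_at_b = mknm[g$amat[i, j]],
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(a = character(), b = character(),
                      mark_at_a = character(), mark_at_b = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @export
print.mixed_graph <- function(x, ...) {
  e <- graph_edges(x)
  cat("<mixed_graph kind=", x$kind, "> ", length(x$nodes), " nodes, ",
      nrow(e), " edges\n", sep = "")
  invisible(x)
}

#' Directed (tail -> arrow) adjacency of a mixed graph
#'
#' @param g A [mixed_graph].
#' @return V x V 0/1 matrix; `[i, j] = 1` iff the graph has i -> j with a
#'   tail at i and an arrow at j. Circle or undirected edges do not
#'   appear in the DAG view.
#' @export
dag_view <- function(g) {
  A <- (g$amat == MARK_ARROW) & (t(g$amat) == MARK_TAIL)
  storage.mode(A) <- "integer"
  dimnames(A) <- list(g$nodes, g$nodes)
  A
}

skeleton_matrix <- function(g) {
  S <- g$amat != 0L
  storage.mode(S) <- "integer"
  S
}

#' Is the DAG view of a graph acyclic?
#' @param g A [mixed_graph].
#' @return TRUE iff the tail->arrow edges contain no directed cycle.
#' @export
is_acyclic <- function(g) {
  A <- dag_view(g)
  !has_cycle_adj(A)
}

has_cycle_adj <- function(A) {
  # Kahn's algorithm on a 0/1 adjacency matrix
  V <- nrow(A)
  if (V == 0L) return(FALSE)
  indeg <- colSums(A)
  queue <- which(indeg == 0)
  seen <- 0L
  A <- A > 0
  while (length(queue) > 0L) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    ch <- which(A[v, ])
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
    A[v, ] <- FALSE
  }
  seen < V
}

validate_graph <- function(g) {
  stopifnot(inherits(g, "mixed_graph"))
  am <- g$amat
  if (any(diag(am) != 0L)) stop("self-edges are not allowed")
  if (any((am != 0L) != (t(am) != 0L)))
    stop("inconsistent edge record: mark present at one endpoint only")
  if (identical(g$kind, "dag")) {
    if (any(am == MARK_CIRCLE)) stop("a DAG must not contain circle marks")
    if (!is_acyclic(g)) stop("graph claims kind=dag but contains a directed cycle")
  }
  invisible(g)
}

#' Structural difference between two mixed graphs
#'
#' Compares on the skeleton-plus-orientation convention: an edge present
#' in both graphs but with a different endpoint-mark pair counts once as
#' misoriented; structural Hamming distance is
#' `missing + extra + misoriented`.
#'
#' @param estimated,truth [mixed_graph]s over the same node set.
#' @return List of class `graph_delta` with `shd`, `missing_edges`,
#'   `extra_edges`, `misoriented_edges`.
#' @export
structural_delta <- function(estimated, truth) {
  if (!setequal(estimated$nodes, truth$nodes))
    stop("node sets differ")
  # align node order
  perm <- match(truth$nodes, estimated$nodes)
  ae <- estimated$amat[perm, perm, drop = FALSE]
  at <- truth$amat
  in_e <- ae != 0L
  in_t <- at != 0L
  up <- upper.tri(ae)
  missing <- sum(in_t[up] & !in_e[up])
  extra <- sum(in_e[up] & !in_t[up])
  both <- in_e & in_t & up
  # marks must match at both endpoints; compare the full mark pair
  mis <- 0L
  idx <- which(both, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (ae[i, j] != at[i, j] || ae[j, i] != at[j, i]) mis <- mis + 1L
    }
  }
  structure(list(shd = missing + extra + mis,
                 missing_edges = missing, extra_edges = extra,
                 misoriented_edges = mis),
            class = "graph_delta")
}

#' @export
print.graph_delta <- function(x, ...) {
  cat("<graph_delta> shd=", x$shd, " (missing=", x$missing_edges,
      ", extra=", x$extra_edges, ", misoriented=", x$misoriented_edges, ")\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Graph serialization --------------------------------------------------------

#' Write a mixed graph to disk
#'
#' @param g A [mixed_graph].
#' @param path Output file.
#' @param format `"dot"`, `"graphml"` or `"adjacency_csv"`. DOT and
#'   GraphML carry the endpoint marks as edge attributes. The adjacency
#'   CSV encodes tail->arrow as 1 in cell `[from, to]`, an undirected
#'   edge as 1 in both cells, and a circle endpoint as the sentinel 2 at
#'   that endpoint's cell (documented in the header comment). Node order
#'   is the graph's node order, making output byte-stable.
#' @export
write_graph <- function(g, path, format = c("adjacency_csv", "dot", "graphml")) {
  format <- match.arg(format)
  validate_graph(g)
  e <- graph_edges(g)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "adjacency_csv") {
    V <- length(g$nodes)
    M <- matrix(0L, V, V, dimnames = list(g$nodes, g$nodes))
    if (nrow(e) > 0L) for (r in seq_len(nrow(e))) {
      i <- match(e$a[r], g$nodes); j <- match(e$b[r], g$nodes)
      ma <- e$mark_at_a[r]; mb <- e$mark_at_b[r]
      if (ma == "tail" && mb == "arrow") M[i, j] <- 1L
      else if (ma == "arrow" && mb == "tail") M[j, i] <- 1L
      else if (ma == "tail" && mb == "tail") { M[i, j] <- 1L; M[j, i] <- 1L }
      else {
        # circle or arrow-arrow endpoints: sentinel 2 at each non-tail-arrow cell
        M[i, j] <- if (mb == "arrow") 1L else 2L
        M[j, i] <- if (ma == "arrow") 1L else 2L
      }
    }
    writeLines(paste0("# adjacency: [from,to]=1 means from->to; ",
                      "1 in both cells = undirected; 2 = circle/uncertain endpoint; ",
                      "kind=", g$kind), con)
    utils::write.csv(as.data.frame(M), con, row.names = TRUE)
  } else if (format == "dot") {
    writeLines(c(sprintf("digraph \"%s\" {", g$kind),
                 sprintf("  \"%s\";", g$nodes)), con)
    if (nrow(e) > 0L) for (r in seq_len(nrow(e))) {
      arrow_head <- c(tail = "none", arrow = "normal", circle = "odot")
      writeLines(sprintf(
        "  \"%s\" -> \"%s\" [dir=both, arrowtail=%s, arrowhead=%s, mark_at_a=%s, mark_at_b=%s];",
        e$a[r], e$b[r], arrow_head[[e$mark_at_a[r]]], arrow_head[[e$mark_at_b[r]]],
        e$mark_at_a[r], e$mark_at_b[r]), con)
    }
    writeLines("}", con)
  } else {
    writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
                 '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
                 '  <key id="ma" for="edge" attr.name="mark_at_a" attr.type="string"/>',
                 '  <key id="mb" for="edge" attr.name="mark_at_b" attr.type="string"/>',
                 sprintf('  <graph id="%s" edgedefault="undirected">', g$kind),
                 sprintf('    <node id="%s"/>', g$nodes)), con)
    if (nrow(e) > 0L) for (r in seq_len(nrow(e))) {
      writeLines(sprintf(
        '    <edge source="%s" target="%s"><data key="ma">%s</data><data key="mb">%s</data></edge>',
        e$a[r], e$b[r], e$mark_at_a[r], e$mark_at_b[r]), con)
    }
    writeLines(c("  </graph>", "</graphml>"), con)
  }
  invisible(NULL)
}

#' Read a mixed graph from an adjacency CSV written by [write_graph]
#' @param path File path.
#' @param kind Graph kind label for the result.
#' @return A [mixed_graph].
#' @export
read_adjacency_csv <- function(path, kind = "dag") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  M <- as.matrix(utils::read.csv(text = paste(lines, collapse = "\n"),
                                 row.names = 1, check.names = FALSE))
  nodes <- rownames(M)
  g <- mixed_graph(nodes, kind = kind)
  V <- length(nodes)
  for (i in seq_len(V)) for (j in seq_len(V)) {
    if (j <= i) next
    a <- M[i, j]; b <- M[j, i]
    if (a == 0 && b == 0) next
    if (a == 1 && b == 0) g <- add_directed_edge(g, nodes[i], nodes[j])
    else if (a == 0 && b == 1) g <- add_directed_edge(g, nodes[j], nodes[i])
    else if (a == 1 && b == 1) g <- add_undirected_edge(g, nodes[i], nodes[j])
    else {
      mk_at_j <- if (a == 1) MARK_ARROW else MARK_CIRCLE
      mk_at_i <- if (b == 1) MARK_ARROW else MARK_CIRCLE
      g <- set_edge(g, nodes[i], nodes[j], mk_at_i, mk_at_j)
    }
  }
  g
}

# igraph conversion for reachability-style queries -----------------------------
as_igraph_directed <- function(g) {
  igraph::graph_from_adjacency_matrix(dag_view(g), mode = "directed")
}

as_igraph_skeleton <- function(g) {
  igraph::graph_from_adjacency_matrix(skeleton_matrix(g), mode = "undirected")
}
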