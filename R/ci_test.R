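# Fisher-z conditional-independence testing on partial correlations,
# plus a d-separation oracle engine used to validate search logic
# independently of statistical error.

#' Sample partial correlation via correlation-matrix inversion
#'
#' `r = -Omega[x,y] / sqrt(Omega[x,x] * Omega[y,y])` where `Omega` is
#' the inverse of the correlation submatrix over `{x, y} union s`. One
#' correlation matrix per dataset is cached by the search code; this
#' user-facing form recomputes it.
#'
#' @param d An [rd_dataset] (numeric, no missing values).
#' @param x,y Variable names, distinct, not in `s`.
#' @param s Character vector of conditioning variable names.
#' @return The partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(d, x, y, s = character()) {
  C <- stats::cor(d$values)
  partial_correlation_from_cor(C, d$n, x, y, s)
}

partial_correlation_from_cor <- function(C, n, x, y, s = character()) {
  if (x == y) stop("collinearity: x and y are the same variable")
  if (x %in% s || y %in% s) stop("x and y must not appear in the conditioning set")
  if (n <= length(s) + 3)
    stop("sample size ", n, " too small for |S| = ", length(s))
  vars <- c(x, y, s)
  sub <- C[vars, vars, drop = FALSE]
  if (rcond(sub) < 1e-12)
    stop("collinearity: correlation submatrix over {",
         paste(vars, collapse = ", "), "} is singular")
  Om <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(Om) || !all(is.finite(Om)) || Om[1, 1] <= 0 || Om[2, 2] <= 0)
    stop("collinearity: correlation submatrix over {",
         paste(vars, collapse = ", "), "} is singular")
  r <- -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
  max(-1, min(1, r))
}

#' Fisher-z conditional-independence test
#'
#' Transforms the partial correlation `r` of `x` and `y` given `s` to
#' `z = sqrt(n - |S| - 3) * atanh(r)` and compares the two-sided normal
#' tail probability with `alpha`. Independence is declared iff
#' `p > alpha`.
#'
#' @param d An [rd_dataset].
#' @param x,y,s As in [partial_correlation].
#' @param alpha Test level in (0, 1).
#' @return List of class `ci_test_result`: `x`, `y`, `s`, `r`, `z`, `p`,
#'   `n`, `independent`, `saturated` (TRUE when `|r| = 1`, in which case
#'   `p = 0` is returned rather than an infinite statistic).
#' @export
fisher_z_test <- function(d, x, y, s = character(), alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  r <- partial_correlation(d, x, y, s)
  fisher_z_from_r(r, d$n, x, y, s, alpha)
}

fisher_z_from_r <- function(r, n, x, y, s, alpha) {
  df <- n - length(s) - 3
  saturated <- abs(r) >= 1
  if (saturated) {
    z <- sign(r) * Inf
    p <- 0
  } else {
    z <- sqrt(df) * atanh(r)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(x = x, y = y, s = s, r = r,
                 z = if (saturated) sign(r) * .Machine$double.xmax else z,
                 p = p, n = n, independent = p > alpha, saturated = saturated),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(sprintf("CI test %s _||_ %s | {%s}: r=%.4f z=%.3f p=%.4g -> %s\n",
              x$x, x$y, paste(x$s, collapse = ","), x$r,
              min(x$z, 1e308), x$p,
              if (x$independent) "independent" else "dependent"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CI engines: a uniform interface the search algorithms consume --------------

#' Fisher-z engine over a dataset
#'
#' Caches the correlation matrix once; every test is then a small
#' submatrix inversion, which is what makes the order-randomized
#' ensemble affordable.
#'
#' @param d An [rd_dataset], preprocessed (numeric, complete).
#' @param alpha Test level.
#' @return A CI engine for [run_pc]/[run_fci].
#' @export
ci_engine_fisherz <- function(d, alpha = 0.05) {
  if (!is.numeric(d$values)) stop("fisher-z engine needs an encoded dataset")
  if (anyNA(d$values)) stop("fisher-z engine needs complete data")
  structure(list(kind = "fisherz", C = stats::cor(d$values), n = d$n,
                 alpha = alpha, nodes = var_names(d)),
            class = c("ci_engine_fisherz", "ci_engine"))
}

#' d-separation oracle engine over a known DAG
#'
#' Substitutes graphical d-separation for the statistical test, so that
#' algorithmic soundness can be checked in isolation from sampling
#' error.
#'
#' @param true_graph A [mixed_graph] of kind `"dag"`.
#' @return A CI engine: p-value 1 when the pair is d-separated given the
#'   conditioning set, 0 otherwise.
#' @export
ci_engine_dsep <- function(true_graph) {
  validate_graph(true_graph)
  structure(list(kind = "dsep", graph = true_graph, alpha = 0.5,
                 n = Inf, nodes = true_graph$nodes),
            class = c("ci_engine_dsep", "ci_engine"))
}

ci_test_engine <- function(engine, x, y, s) UseMethod("ci_test_engine")

#' @export
ci_test_engine.ci_engine_fisherz <- function(engine, x, y, s) {
  r <- partial_correlation_from_cor(engine$C, engine$n, x, y, s)
  fisher_z_from_r(r, engine$n, x, y, s, engine$alpha)
}

#' @export
ci_test_engine.ci_engine_dsep <- function(engine, x, y, s) {
  sep <- d_separated(engine$graph, x, y, s)
  structure(list(x = x, y = y, s = s, r = if (sep) 0 else NA_real_,
                 z = NA_real_, p = as.numeric(sep), n = Inf,
                 independent = sep, saturated = FALSE),
            class = "ci_test_result")
}

#' d-separation in a DAG
#'
#' Moralization route: restrict to the ancestral subgraph of
#' `{x, y} union s`, marry co-parents, drop directions, delete `s`, and
#' test whether `x` and `y` remain connected.
#'
#' @param g A [mixed_graph] of kind `"dag"`.
#' @param x,y Node names.
#' @param s Character vector of conditioning node names.
#' @return TRUE iff `x` and `y` are d-separated given `s`.
#' @export
d_separated <- function(g, x, y, s = character()) {
  if (x %in% s || y %in% s)
    stop("conditioning set must not contain x or y")
  A <- dag_view(g)
  nodes <- g$nodes
  ix <- match(c(x, y, s), nodes)
  if (anyNA(ix)) stop("unknown node(s): ",
                      paste(c(x, y, s)[is.na(ix)], collapse = ", "))
  # ancestors of {x, y} union s (including themselves)
  anc <- ix
  frontier <- ix
  Alog <- A > 0
  while (length(frontier) > 0L) {
    pa <- which(rowSums(Alog[, frontier, drop = FALSE]) > 0)
    new <- setdiff(pa, anc)
    anc <- c(anc, new)
    frontier <- new
  }
  anc <- sort(anc)
  Asub <- Alog[anc, anc, drop = FALSE]
  # moralize: undirect and marry parents of each node
  U <- Asub | t(Asub)
  for (v in seq_len(nrow(Asub))) {
    pa <- which(Asub[, v])
    if (length(pa) > 1L) U[pa, pa] <- TRUE
  }
  diag(U) <- FALSE
  keep <- !(nodes[anc] %in% s)
  U <- U[keep, keep, drop = FALSE]
  kept_names <- nodes[anc][keep]
  # plain BFS connectivity (this is the oracle's hot path)
  src <- match(x, kept_names); dst <- match(y, kept_names)
  reach <- rep(FALSE, nrow(U)); reach[src] <- TRUE
  frontier <- src
  while (length(frontier) > 0L && !reach[dst]) {
    nxt <- which(colSums(U[frontier, , drop = FALSE]) > 0 & !reach)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  !reach[dst]
}
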