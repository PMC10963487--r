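# Graph-autoencoder structure learner: a NOTEARS-style generalization
# in which a shared per-variable encoder/decoder pair handles nonlinear
# relations and the learned signed adjacency separates risk (positive)
# from protective (negative) influences.

#' Graph-autoencoder configuration
#'
#' @param hidden_sizes Number of curvature basis functions in the
#'   shared scalar encoder and decoder, `c(encoder, decoder)`; default
#'   `c(8, 4)`.
#' @param sparsity_weight L1 penalty `lambda` on the adjacency.
#' @param weight_decay L2 penalty on the curvature readouts; keeps the
#'   nonlinear corrections small unless the data demand them, so the
#'   adjacency keeps the scale of the data.
#' @param omega Edge threshold for [threshold_weights].
#' @param max_outer_iters,inner_iters Augmented-Lagrangian outer loop
#'   cap and L-BFGS-B iteration cap per subproblem solve.
#' @param rho_init,rho_max,gamma Penalty start, cap and growth factor
#'   (rho multiplies by `gamma` whenever h(A) fails to shrink by 4x).
#' @param h_tol Convergence tolerance on the acyclicity value.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `gae_config`.
#' @export
gae_config <- function(hidden_sizes = c(8L, 4L), sparsity_weight = 0.01,
                       weight_decay = 1,
                       omega = 0.3, max_outer_iters = 20L,
                       inner_iters = 200L, rho_init = 1, rho_max = 1e16,
                       gamma = 10, h_tol = 1e-8, seed = 1L) {
  stopifnot(length(hidden_sizes) == 2L, rho_init <= rho_max, h_tol > 0,
            omega > 0, sparsity_weight >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 sparsity_weight = sparsity_weight,
                 weight_decay = weight_decay, omega = omega,
                 max_outer_iters = as.integer(max_outer_iters),
                 inner_iters = as.integer(inner_iters),
                 rho_init = rho_init, rho_max = rho_max, gamma = gamma,
                 h_tol = h_tol, seed = as.integer(seed)),
            class = "gae_config")
}

#' NOTEARS acyclicity value
#'
#' `h(A) = trace(expm(A o A)) - d` with `o` the elementwise product;
#' zero exactly when the support of `A` is acyclic, positive otherwise.
#'
#' @param A Square numeric matrix.
#' @return Non-negative scalar.
#' @export
acyclicity <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be square")
  E <- as.matrix(Matrix::expm(Matrix::Matrix(A * A)))
  sum(diag(E)) - nrow(A)
}

#' Weighted directed graph (signed adjacency)
#'
#' @param A V x V numeric matrix, `A[i, j]` the weight of i -> j; zero
#'   diagonal.
#' @param nodes Node names.
#' @param threshold_applied The omega used by [threshold_weights], or
#'   `NULL` for a raw (unthresholded) estimate.
#' @return Object of class `weighted_digraph`.
#' @export
weighted_digraph <- function(A, nodes, threshold_applied = NULL) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), nrow(A) == length(nodes))
  if (any(diag(A) != 0)) stop("diagonal must be zero")
  dimnames(A) <- list(nodes, nodes)
  structure(list(A = A, nodes = nodes,
                 threshold_applied = threshold_applied),
            class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  cat("<weighted_digraph> ", length(x$nodes), " nodes, ",
      sum(x$A != 0), " nonzero weights",
      if (!is.null(x$threshold_applied))
        paste0(" (thresholded at ", x$threshold_applied, ")") else
          " (unthresholded)", "\n", sep = "")
  invisible(x)
}

#' Fit the graph autoencoder
#'
#' Minimizes the reconstruction loss of a per-variable autoencoder with
#' adjacency-weighted message passing, plus an L1 penalty on the
#' adjacency, subject to `acyclicity(A) <= h_tol` via an augmented
#' Lagrangian whose penalty grows while h fails to shrink. Optimization
#' is full-batch and deterministic given the seed. Background knowledge
#' enters as a hard mask: forbidden entries of A are pinned to zero.
#'
#' The shared scalar encoder and decoder are residual maps
#' `f(u) = u + sum_k w_k phi_k(u)` over a fixed bank of tanh curvature
#' bases with `phi(0) = 0` and `phi'(0) = 0`; only the readout weights
#' (and the adjacency) are trained. With the readouts at zero the model
#' is exactly the linear NOTEARS model, so the adjacency is identified
#' on the scale of the standardized data and its signs carry the
#' risk/protective semantics; the curvature terms let the maps bend to
#' accommodate nonlinear (e.g. discretized-ordinal) relations.
#'
#' @param d An [rd_dataset], preprocessed and standardized.
#' @param cfg A [gae_config].
#' @param bk Optional [background_knowledge]; forbidden entries masked.
#' @return A [weighted_digraph] (unthresholded), with attribute
#'   `diagnostics`: `h` (final acyclicity), `converged`, `n_outer`,
#'   `loss_trace`. Non-convergence returns the best iterate flagged, it
#'   is not an error.
#' @export
gae_fit <- function(d, cfg = gae_config(), bk = NULL) {
  X <- d$values
  if (!is.numeric(X) || anyNA(X)) stop("gae_fit needs encoded, complete data")
  nodes <- var_names(d)
  V <- length(nodes)
  VV <- V * V
  # background knowledge enters as a hard mask on A: forbidden entries
  # (and the diagonal) are pinned to zero through the box constraints
  mask <- matrix(1, V, V); diag(mask) <- 0
  if (!is.null(bk)) {
    for (e in intersect(bk$forbidden_into, nodes))
      mask[, match(e, nodes)] <- 0
    fe <- bk$forbidden_edges
    if (!is.null(fe)) for (r in seq_len(nrow(fe)))
      mask[match(fe[r, 1], nodes), match(fe[r, 2], nodes)] <- 0
  }
  h1 <- cfg$hidden_sizes[1]; h3 <- cfg$hidden_sizes[2]
  set.seed(cfg$seed)
  # fixed ridge directions/offsets of the curvature bases; readouts and
  # the adjacency start at zero, i.e. exactly the linear model
  W1 <- stats::runif(h1, 0.4, 1.2) * sample(c(-1, 1), h1, TRUE)
  b1 <- stats::rnorm(h1, 0, 1)
  W3 <- stats::runif(h3, 0.4, 1.2) * sample(c(-1, 1), h3, TRUE)
  b3 <- stats::rnorm(h3, 0, 1)
  # detrend each ridge function against the pooled data so the bases
  # are empirically uncorrelated with their input (they contribute
  # curvature only, never average linear gain)
  Xv <- as.vector(X)
  vx <- stats::var(Xv)
  detrend <- function(W, b) vapply(seq_along(W), function(k)
    stats::cov(tanh(Xv * W[k] + b[k]), Xv) / vx, numeric(1))
  s1 <- detrend(W1, b1)
  s3 <- detrend(W3, b3)
  # encoder bases are a fixed function of the data: evaluate once
  Phi1 <- tanh(outer(Xv, W1) + matrix(b1, length(Xv), h1, byrow = TRUE))
  Phi1 <- sweep(Phi1, 2, tanh(b1)) - outer(Xv, s1)

  npar <- 2L * VV + h1 + h3
  par <- numeric(npar)
  lower <- c(rep(0, 2L * VV), rep(-Inf, h1 + h3))
  upper <- c(ifelse(c(mask, mask) > 0, Inf, 0), rep(Inf, h1 + h3))

  alpha <- 0; rho <- cfg$rho_init
  h_val <- Inf
  loss_trace <- numeric(0)
  converged <- FALSE
  n_outer <- 0L
  # cache: optim calls fn and gr separately on the same parameters
  cache <- new.env(parent = emptyenv())
  evalobj <- function(p, al, rh) {
    key <- c(p, al, rh)
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$res)
    res <- .gae_obj_cpp(p, X, Phi1, W3, b3, s3,
                        cfg$sparsity_weight, cfg$weight_decay, al, rh)
    cache$key <- key; cache$res <- res
    res
  }
  for (outer in seq_len(cfg$max_outer_iters)) {
    h_prev <- h_val
    repeat {
      opt <- stats::optim(par,
                          fn = function(p) evalobj(p, alpha, rho)$value,
                          gr = function(p) evalobj(p, alpha, rho)$grad,
                          method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = cfg$inner_iters,
                                         factr = 1e9))
      A_new <- matrix(opt$par[seq_len(VV)] - opt$par[VV + seq_len(VV)], V, V)
      h_new <- .acyclicity_cpp(A_new)
      if (h_new > 0.25 * h_prev && rho < cfg$rho_max) {
        rho <- min(rho * cfg$gamma, cfg$rho_max)
      } else break
    }
    par <- opt$par
    h_val <- h_new
    alpha <- alpha + rho * h_val
    loss_trace <- c(loss_trace, opt$value)
    n_outer <- outer
    if (h_val <= cfg$h_tol) { converged <- TRUE; break }
    if (rho >= cfg$rho_max) break
  }
  A <- matrix(par[seq_len(VV)] - par[VV + seq_len(VV)], V, V)
  A[mask == 0] <- 0
  g <- weighted_digraph(A, nodes)
  attr(g, "diagnostics") <- list(h = h_val, converged = converged,
                                 n_outer = n_outer,
                                 loss_trace = loss_trace)
  g
}

#' Prune small weights and enforce acyclicity
#'
#' Zeroes entries with `|A[i, j]| < omega`; if any directed cycle
#' survives, the smallest-|weight| edge inside each cycle is removed in
#' turn until the support is acyclic. Idempotent.
#'
#' @param g A [weighted_digraph].
#' @param omega Positive threshold.
#' @return Thresholded [weighted_digraph] with `threshold_applied` set.
#' @export
threshold_weights <- function(g, omega = 0.3) {
  stopifnot(omega > 0)
  A <- g$A
  A[abs(A) < omega] <- 0
  repeat {
    S <- (A != 0) * 1L
    if (!has_cycle_adj(S)) break
    ig <- igraph::graph_from_adjacency_matrix(S, mode = "directed")
    comp <- igraph::components(ig, mode = "strong")
    members <- which(comp$membership == which(comp$csize > 1)[1])
    sub <- abs(A[members, members, drop = FALSE])
    sub[sub == 0] <- Inf
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    A[members[k[1]], members[k[2]]] <- 0
  }
  weighted_digraph(A, g$nodes, threshold_applied = omega)
}

#' Classify edges as risk or protective by weight sign
#'
#' Positive learned weight = risk (amplifying) influence, negative =
#' protective (inhibitory), matching the sign semantics of the signed
#' adjacency. Requires a thresholded graph: labels on sub-threshold
#' noise weights are meaningless.
#'
#' @param g A thresholded [weighted_digraph].
#' @param target Label only edges into this node; `NULL` labels all
#'   edges.
#' @return data.frame `from`, `to`, `weight`, `label` in
#'   `{"risk", "protective"}`.
#' @export
classify_polarity <- function(g, target = NULL) {
  if (is.null(g$threshold_applied))
    stop("classify_polarity needs a thresholded graph; run threshold_weights")
  idx <- which(g$A != 0, arr.ind = TRUE)
  if (!is.null(target)) {
    if (!target %in% g$nodes) stop("unknown target node: ", target)
    idx <- idx[g$nodes[idx[, 2]] == target, , drop = FALSE]
  }
  data.frame(
    from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]],
    weight = g$A[idx],
    label = ifelse(g$A[idx] > 0, "risk", "protective"),
    stringsAsFactors = FALSE)
}

#' Convert a thresholded weighted digraph to a mixed graph
#' @param g A [weighted_digraph].
#' @return A [mixed_graph] of kind `"dag"` over the nonzero support.
#' @export
as_mixed_graph <- function(g) {
  out <- mixed_graph(g$nodes, kind = "dag")
  idx <- which(g$A != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx)))
    out <- add_directed_edge(out, g$nodes[idx[r, 1]], g$nodes[idx[r, 2]])
  out
}
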