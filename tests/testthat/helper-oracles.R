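# Fixture builders and independent oracles used across the suite.
# Oracles deliberately avoid the code paths they validate: the CPDAG
# oracle enumerates skeleton orientations, the reachability oracles use
# boolean matrix powers, the partial-correlation oracle uses regression
# residuals.

# ---- small SCM builders ----------------------------------------------------

two_node_spec <- function(w = 0.8, sd = 1) {
  g <- add_directed_edge(mixed_graph(c("X", "Y"), kind = "dag"), "X", "Y")
  scm_spec(g, c("X->Y" = w), noise_sd = c(X = sd, Y = sd),
           tiers = c(X = "endogenous", Y = "endogenous"))
}

chain_spec <- function(w = 0.9) {
  g <- mixed_graph(c("X", "Y", "Z"), kind = "dag")
  g <- add_directed_edge(g, "X", "Y")
  g <- add_directed_edge(g, "Y", "Z")
  scm_spec(g, c("X->Y" = w, "Y->Z" = w),
           noise_sd = c(X = 1, Y = 1, Z = 1),
           tiers = c(X = "endogenous", Y = "endogenous", Z = "endogenous"))
}

collider_spec <- function(w = 0.9) {
  g <- mixed_graph(c("X", "Y", "Z"), kind = "dag")
  g <- add_directed_edge(g, "X", "Z")
  g <- add_directed_edge(g, "Y", "Z")
  scm_spec(g, c("X->Z" = w, "Y->Z" = w),
           noise_sd = c(X = 1, Y = 1, Z = 1),
           tiers = c(X = "endogenous", Y = "endogenous", Z = "endogenous"))
}

# random continuous linear SEM on V nodes; weights signed in
# [wmin, wmax] by magnitude, upper-triangular support with edge
# probability p
random_sem_spec <- function(V, seed, p = 0.5, wmin = 0.5, wmax = 1.5,
                            max_edges = Inf) {
  set.seed(seed)
  nodes <- paste0("V", seq_len(V))
  g <- mixed_graph(nodes, kind = "dag")
  w <- numeric(0)
  n_e <- 0L
  for (i in seq_len(V - 1)) for (j in seq.int(i + 1, V)) {
    if (n_e < max_edges && stats::runif(1) < p) {
      g <- add_directed_edge(g, nodes[i], nodes[j])
      w[paste0(nodes[i], "->", nodes[j])] <-
        sample(c(-1, 1), 1) * stats::runif(1, wmin, wmax)
      n_e <- n_e + 1L
    }
  }
  scm_spec(g, w, noise_sd = stats::setNames(rep(1, V), nodes),
           tiers = stats::setNames(rep("endogenous", V), nodes))
}

zero_weight_spec <- function(V = 5) {
  nodes <- paste0("V", seq_len(V))
  scm_spec(mixed_graph(nodes, kind = "dag"), numeric(0),
           noise_sd = stats::setNames(rep(1, V), nodes),
           tiers = stats::setNames(rep("endogenous", V), nodes))
}

true_weight_matrix <- function(spec) {
  nodes <- spec$graph$nodes
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in names(spec$weights)) {
    p <- strsplit(k, "->", fixed = TRUE)[[1]]
    W[p[1], p[2]] <- spec$weights[[k]]
  }
  W
}

# ---- CPDAG oracle by enumeration ------------------------------------------

vstructure_key <- function(A) {
  V <- nrow(A)
  keys <- character(0)
  for (z in seq_len(V)) {
    pa <- which(A[, z] == 1L)
    if (length(pa) < 2L) next
    for (a in seq_along(pa)) for (b in seq_along(pa)) {
      if (b <= a) next
      x <- pa[a]; y <- pa[b]
      if (A[x, y] == 1L || A[y, x] == 1L) next
      keys <- c(keys, paste(min(x, y), z, max(x, y)))
    }
  }
  sort(keys)
}

acyclic_adj <- function(A) {
  V <- nrow(A)
  B <- A
  for (k in seq_len(V)) {
    if (any(diag(B) > 0)) return(FALSE)
    B <- (B %*% A > 0) * 1L
  }
  !any(diag(B) > 0)
}

# CPDAG of a DAG by brute force: enumerate every orientation of the
# skeleton, keep the Markov-equivalent ones (same skeleton and
# v-structures), mark an edge directed iff all members agree
cpdag_by_enumeration <- function(g_dag) {
  A <- dag_view(g_dag)
  nodes <- g_dag$nodes
  V <- length(nodes)
  sk <- which((A == 1L | t(A) == 1L) & upper.tri(A), arr.ind = TRUE)
  E <- nrow(sk)
  stopifnot(E <= 16)
  target <- vstructure_key(A)
  seen_ij <- matrix(0L, V, V)
  n_equiv <- 0L
  for (bits in 0:(2^E - 1)) {
    B <- matrix(0L, V, V)
    bb <- bits
    for (e in seq_len(E)) {
      i <- sk[e, 1]; j <- sk[e, 2]
      if (bb %% 2 == 0) B[i, j] <- 1L else B[j, i] <- 1L
      bb <- bb %/% 2
    }
    if (!acyclic_adj(B)) next
    if (!identical(vstructure_key(B), target)) next
    n_equiv <- n_equiv + 1L
    seen_ij <- seen_ij + B
  }
  out <- mixed_graph(nodes, kind = "cpdag")
  for (e in seq_len(E)) {
    i <- sk[e, 1]; j <- sk[e, 2]
    if (seen_ij[i, j] == n_equiv) out <- add_directed_edge(out, nodes[i], nodes[j])
    else if (seen_ij[j, i] == n_equiv) out <- add_directed_edge(out, nodes[j], nodes[i])
    else out <- add_undirected_edge(out, nodes[i], nodes[j])
  }
  out
}

# all DAG extensions of a partially directed graph: enumerate
# orientations of the undirected edges, keep acyclic ones that create
# no v-structure beyond the input's own colliders (used as the oracle
# for Meek-rule checks)
pdag_extensions <- function(g) {
  am <- g$amat
  V <- nrow(am)
  und <- which(am == MARK_TAIL & t(am) == MARK_TAIL & upper.tri(am),
               arr.ind = TRUE)
  E <- nrow(und)
  # directed part: amat[i,j]==ARROW & amat[j,i]==TAIL means i->j
  base <- matrix(0L, V, V, dimnames = dimnames(am))
  dir_idx <- which((am == MARK_ARROW) & (t(am) == MARK_TAIL), arr.ind = TRUE)
  for (r in seq_len(nrow(dir_idx)))
    base[dir_idx[r, 1], dir_idx[r, 2]] <- 1L
  target <- vstructure_key(base)
  out <- list()
  for (bits in 0:(2^E - 1)) {
    B <- base
    bb <- bits
    for (e in seq_len(E)) {
      i <- und[e, 1]; j <- und[e, 2]
      if (bb %% 2 == 0) B[i, j] <- 1L else B[j, i] <- 1L
      bb <- bb %/% 2
    }
    if (!acyclic_adj(B)) next
    if (!identical(vstructure_key(B), target)) next
    out[[length(out) + 1L]] <- B
  }
  out
}

# boolean-matrix transitive closure
closure_oracle <- function(A) {
  V <- nrow(A)
  R <- (A > 0) * 1L
  for (k in seq_len(V)) R <- ((R + R %*% R) > 0) * 1L
  R
}

# regression-residual partial correlation
pcor_by_residuals <- function(X, x, y, s) {
  if (length(s) == 0L) return(stats::cor(X[, x], X[, y]))
  rx <- stats::lm.fit(cbind(1, X[, s, drop = FALSE]), X[, x])$residuals
  ry <- stats::lm.fit(cbind(1, X[, s, drop = FALSE]), X[, y])$residuals
  stats::cor(rx, ry)
}

# convenience: sampled + encoded + standardized pipeline data
std_data <- function(spec, n, seed) {
  standardize(encode_ordinal(sample_scm(spec, n, seed = seed)))$dataset
}

arrowheads_into <- function(g, nodes_forbidden) {
  idx <- match(intersect(nodes_forbidden, g$nodes), g$nodes)
  sum(g$amat[, idx] == 2L)
}
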