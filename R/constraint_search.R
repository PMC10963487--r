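# Constraint-based search: PC (original / stable / parallel) and FCI,
# with tiered background knowledge. The Fisher-z skeleton loop runs in
# compiled code; a generic R loop serves arbitrary CI engines (notably
# the d-separation oracle used to validate the algorithms themselves).

#' Background knowledge for constraint-based search
#'
#' @param forbidden_into Node names that admit no incoming arrowheads
#'   (intrinsic attributes and pandemic-period change indicators).
#' @param forbidden_edges Optional 2-column matrix/data.frame of ordered
#'   pairs (from, to) that may not appear; a pair forbidden in both
#'   directions is removed from the skeleton up front.
#' @return Object of class `background_knowledge`.
#' @export
background_knowledge <- function(forbidden_into = character(),
                                 forbidden_edges = NULL) {
  if (!is.null(forbidden_edges)) {
    forbidden_edges <- as.matrix(forbidden_edges)
    stopifnot(ncol(forbidden_edges) == 2)
  }
  structure(list(forbidden_into = forbidden_into,
                 forbidden_edges = forbidden_edges),
            class = "background_knowledge")
}

#' Derive background knowledge from dataset tiers
#'
#' Variables in tier `exogenous_fixed` or `exogenous_covid` admit no
#' incoming arrowheads.
#'
#' @param d An [rd_dataset].
#' @return A [background_knowledge].
#' @export
bk_from_tiers <- function(d) {
  background_knowledge(forbidden_into = var_names(d)[var_tiers(d) != "endogenous"])
}

#' Search configuration
#'
#' @param alpha CI-test level (default 0.05; report it with any result).
#' @param variant `"pc_original"`, `"pc_stable"`, `"pc_parallel"` or
#'   `"fci"`.
#' @param variable_order Permutation of the variable names giving the
#'   visiting order; `NULL` means metadata order, or a random
#'   permutation when `seed` is set.
#' @param max_cond_size Cap on conditioning-set size in skeleton
#'   discovery (`Inf` = unbounded).
#' @param max_pdsep_size Cap on the subset size searched within
#'   possible-d-sep candidate sets during FCI pruning (default 4; the
#'   full search is exponential in the candidate-set size, and subsets
#'   beyond the skeleton's terminal depth almost never separate an
#'   additional pair). `Inf` restores the exhaustive search.
#' @param seed Integer; draws `variable_order` at random when no
#'   explicit order is given.
#' @return Object of class `search_config`.
#' @export
search_config <- function(alpha = 0.05,
                          variant = c("pc_stable", "pc_original",
                                      "pc_parallel", "fci"),
                          variable_order = NULL, max_cond_size = Inf,
                          max_pdsep_size = 4, seed = NULL) {
  variant <- match.arg(variant)
  structure(list(alpha = alpha, variant = variant,
                 variable_order = variable_order,
                 max_cond_size = max_cond_size,
                 max_pdsep_size = max_pdsep_size, seed = seed),
            class = "search_config")
}

resolve_order <- function(nodes, cfg) {
  ord <- cfg$variable_order
  if (is.null(ord)) {
    if (!is.null(cfg$seed)) {
      set.seed(cfg$seed)
      ord <- sample(nodes)
    } else ord <- nodes
  }
  if (!setequal(ord, nodes) || length(ord) != length(nodes))
    stop("variable_order must be a permutation of the variables")
  ord
}

# sepset map: flat list of length V*V, entry (i-1)*V+j holds the
# 1-based index vector separating nodes i and j (both directions set)
sepset_get <- function(sepsets, i, j, V) sepsets[[(i - 1L) * V + j]]
sepset_set <- function(sepsets, i, j, V, s) {
  sepsets[[(i - 1L) * V + j]] <- s
  sepsets[[(j - 1L) * V + i]] <- s
  sepsets
}

as_engine <- function(x, alpha) {
  if (inherits(x, "ci_engine")) x
  else if (inherits(x, "rd_dataset")) ci_engine_fisherz(x, alpha)
  else stop("expected an rd_dataset or a CI engine")
}

fixed_gap_matrix <- function(nodes, bk) {
  V <- length(nodes)
  G <- matrix(FALSE, V, V)
  fe <- bk$forbidden_edges
  if (!is.null(fe)) for (r in seq_len(nrow(fe))) {
    i <- match(fe[r, 1], nodes); j <- match(fe[r, 2], nodes)
    if (is.na(i) || is.na(j)) stop("forbidden edge names unknown node")
    # removed up front only when forbidden in BOTH directions
    if (!is.null(fe) && any(fe[, 1] == fe[r, 2] & fe[, 2] == fe[r, 1]))
      G[i, j] <- G[j, i] <- TRUE
  }
  G
}

#' PC skeleton discovery
#'
#' Level-wise edge deletion from the complete graph: at depth
#' `l = 0, 1, 2, ...`, each ordered adjacent pair (x, y), visited in
#' `variable_order`, is tested against size-`l` subsets of the adjacency
#' of x (frozen per depth for `pc_stable`/`pc_parallel`, mutating
#' immediately for `pc_original`); the edge is removed on the first
#' independence and the separating set recorded.
#'
#' @param x An [rd_dataset] or a CI engine.
#' @param cfg A [search_config].
#' @param bk A [background_knowledge]; pairs forbidden in both
#'   directions are excluded up front.
#' @return List: `graph` (undirected [mixed_graph], kind `"skeleton"`),
#'   `sepsets`, `n_tests`, `order` (the visiting order used).
#' @export
pc_skeleton <- function(x, cfg = search_config(),
                        bk = background_knowledge()) {
  engine <- as_engine(x, cfg$alpha)
  nodes <- engine$nodes
  V <- length(nodes)
  ord <- resolve_order(nodes, cfg)
  ord_idx <- match(ord, nodes)
  gaps <- fixed_gap_matrix(nodes, bk)
  max_cond <- if (is.infinite(cfg$max_cond_size)) -1L else as.integer(cfg$max_cond_size)
  # the classic FCI sweep mutates adjacencies immediately, like original
  # PC — this is precisely the order sensitivity the ensemble averages out
  variant_code <- switch(cfg$variant, pc_original = 0L, pc_stable = 1L,
                         pc_parallel = 2L, fci = 0L)
  if (inherits(engine, "ci_engine_fisherz")) {
    res <- .pc_skeleton_cpp(engine$C, engine$n, engine$alpha,
                            ord_idx - 1L, variant_code, gaps, max_cond)
    adj <- res$adj
    sepsets <- res$sepsets
    n_tests <- res$n_tests
  } else {
    res <- r_skeleton(engine, ord_idx, variant_code, gaps, max_cond)
    adj <- res$adj
    sepsets <- res$sepsets
    n_tests <- res$n_tests
  }
  g <- mixed_graph(nodes, kind = "skeleton")
  am <- matrix(0L, V, V, dimnames = list(nodes, nodes))
  am[adj] <- MARK_TAIL
  g$amat <- am
  list(graph = g, sepsets = sepsets, n_tests = n_tests, order = ord)
}

# reference R implementation of the same level-wise sweep, generic in
# the CI engine; mirrors the compiled path decision-for-decision
r_skeleton <- function(engine, ord_idx, variant_code, gaps, max_cond) {
  V <- length(engine$nodes)
  adj <- matrix(TRUE, V, V); diag(adj) <- FALSE
  adj[gaps] <- FALSE; adj[t(gaps)] <- FALSE
  sepsets <- vector("list", V * V)
  n_tests <- 0L
  ell <- 0L
  ell_max <- if (max_cond < 0L) V - 2L else max_cond
  while (ell <= ell_max) {
    degs <- rowSums(adj)
    if (!any(degs - 1L >= ell & degs > 0L)) break
    frozen <- adj
    batch <- list()
    for (x in ord_idx) for (y in ord_idx) {
      if (x == y) next
      if (variant_code == 2L) { if (!frozen[x, y]) next } else if (!adj[x, y]) next
      base <- if (variant_code == 0L) adj else frozen
      nbrs <- ord_idx[base[x, ord_idx] & ord_idx != y]
      if (length(nbrs) < ell) next
      combs <- if (ell == 0L) list(integer(0)) else
        utils::combn(seq_along(nbrs), ell, simplify = FALSE)
      for (cb in combs) {
        S <- nbrs[cb]
        res <- ci_test_engine(engine, engine$nodes[x], engine$nodes[y],
                              engine$nodes[S])
        n_tests <- n_tests + 1L
        if (res$independent) {
          if (variant_code == 2L) {
            batch[[length(batch) + 1L]] <- list(x = x, y = y, S = S)
          } else {
            adj[x, y] <- adj[y, x] <- FALSE
            sepsets <- sepset_set(sepsets, x, y, V, S)
          }
          break
        }
      }
    }
    if (variant_code == 2L) for (rm in batch) {
      if (!adj[rm$x, rm$y]) next
      adj[rm$x, rm$y] <- adj[rm$y, rm$x] <- FALSE
      sepsets <- sepset_set(sepsets, rm$x, rm$y, V, rm$S)
    }
    ell <- ell + 1L
  }
  list(adj = adj, sepsets = sepsets, n_tests = n_tests)
}

# ---------------------------------------------------------------------------
# Orientation ----------------------------------------------------------------

arrow_allowed <- function(node, bk) !(node %in% bk$forbidden_into)

edge_dir_allowed <- function(from, to, bk) {
  fe <- bk$forbidden_edges
  if (is.null(fe)) return(TRUE)
  !any(fe[, 1] == from & fe[, 2] == to)
}

#' Orient unshielded colliders
#'
#' For every unshielded triple x - z - y (x, y non-adjacent), orients
#' x -> z <- y iff z is not in sepset(x, y) — unless that would point an
#' arrowhead into a `forbidden_into` node, in which case the triple is
#' left unoriented and the conflict logged in attribute `conflicts`.
#' Conflicting collider demands are resolved first-come in visit order.
#'
#' @param skeleton Undirected [mixed_graph] from [pc_skeleton].
#' @param sepsets Sepset map from the same run.
#' @param bk A [background_knowledge].
#' @param circle_endpoints FCI mode: leave the far endpoints as circles
#'   and record only the arrowheads at the collider.
#' @return Partially directed [mixed_graph].
#' @export
orient_v_structures <- function(skeleton, sepsets, bk = background_knowledge(),
                                circle_endpoints = FALSE) {
  g <- skeleton
  nodes <- g$nodes
  V <- length(nodes)
  am <- g$amat
  if (circle_endpoints) am[am != 0L] <- MARK_CIRCLE
  conflicts <- character()
  for (zi in seq_len(V)) {
    nb <- which(g$amat[zi, ] != 0L)   # neighbors of z
    if (length(nb) < 2L) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (b <= a) next
      xi <- nb[a]; yi <- nb[b]
      if (g$amat[xi, yi] != 0L) next           # shielded
      s <- sepset_get(sepsets, xi, yi, V)
      if (is.null(s)) s <- integer(0)
      if (zi %in% s) next
      if (!arrow_allowed(nodes[zi], bk)) {
        conflicts <- c(conflicts, sprintf(
          "collider %s -> %s <- %s blocked: no arrowheads into %s",
          nodes[xi], nodes[zi], nodes[yi], nodes[zi]))
        next
      }
      # first-come: do not overwrite an arrowhead pointing the other way
      for (wi in c(xi, yi)) {
        if (am[zi, wi] == MARK_ARROW) {
          conflicts <- c(conflicts, sprintf(
            "conflicting collider at %s: edge %s ~ %s already arrow-marked",
            nodes[zi], nodes[wi], nodes[zi]))
        } else {
          am[wi, zi] <- MARK_ARROW
          if (!circle_endpoints) am[zi, wi] <- MARK_TAIL
        }
      }
    }
  }
  g$amat <- am
  g$kind <- if (circle_endpoints) "pag" else "pdag"
  attr(g, "conflicts") <- conflicts
  g
}

# does a directed path b ~> a exist (tail->arrow edges only)?
directed_path_exists <- function(am, from, to) {
  V <- nrow(am)
  A <- (am == MARK_ARROW) & (t(am) == MARK_TAIL)
  reach <- rep(FALSE, V); reach[from] <- TRUE
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ]))))
    nxt <- nxt[!reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
    if (reach[to]) return(TRUE)
  }
  reach[to]
}

# orient i -> j if allowed by background knowledge and acyclicity
try_orient <- function(am, i, j, nodes, bk) {
  if (!arrow_allowed(nodes[j], bk) || !edge_dir_allowed(nodes[i], nodes[j], bk))
    return(list(am = am, done = FALSE))
  if (directed_path_exists(am, j, i)) return(list(am = am, done = FALSE))
  am[i, j] <- MARK_ARROW
  am[j, i] <- MARK_TAIL
  list(am = am, done = TRUE)
}

#' Apply Meek's orientation rules R1-R4 to a fixed point
#'
#' Propagates orientations in a partially directed graph without
#' creating directed cycles or new v-structures, and never pointing an
#' arrowhead into a `forbidden_into` node. Undirected edges incident to
#' a `forbidden_into` node are first oriented away from it (an edge
#' between two such nodes stays undirected).
#'
#' @param g Partially directed [mixed_graph] (marks tail/arrow only).
#' @param bk A [background_knowledge].
#' @return The maximally oriented graph (a CPDAG when the input came
#'   from a faithful skeleton + colliders).
#' @export
apply_meek_rules <- function(g, bk = background_knowledge()) {
  nodes <- g$nodes
  V <- length(nodes)
  am <- g$amat
  # background knowledge: exogenous nodes emit, never receive
  for (ei in match(intersect(bk$forbidden_into, nodes), nodes)) {
    nb <- which(am[ei, ] != 0L)
    for (vi in nb) {
      und <- am[ei, vi] == MARK_TAIL && am[vi, ei] == MARK_TAIL
      if (und && arrow_allowed(nodes[vi], bk)) {
        r <- try_orient(am, ei, vi, nodes, bk)
        am <- r$am
      }
    }
  }
  undirected <- function(i, j) am[i, j] == MARK_TAIL && am[j, i] == MARK_TAIL
  directed <- function(i, j) am[i, j] == MARK_ARROW && am[j, i] == MARK_TAIL
  adjacent <- function(i, j) am[i, j] != 0L
  repeat {
    changed <- FALSE
    for (i in seq_len(V)) for (j in seq_len(V)) {
      if (i == j || !undirected(i, j)) next
      oriented <- FALSE
      # R1: a -> i - j, a and j non-adjacent  =>  i -> j
      for (a in seq_len(V)) {
        if (a == j || !directed(a, i) || adjacent(a, j)) next
        r <- try_orient(am, i, j, nodes, bk)
        if (r$done) { am <- r$am; oriented <- TRUE; break }
      }
      # R2: i -> c -> j with i - j  =>  i -> j
      if (!oriented) for (c in seq_len(V)) {
        if (c == i || c == j) next
        if (directed(i, c) && directed(c, j)) {
          r <- try_orient(am, i, j, nodes, bk)
          if (r$done) { am <- r$am; oriented <- TRUE; break }
        }
      }
      # R3: i - c -> j and i - d -> j, c and d non-adjacent  =>  i -> j
      if (!oriented) {
        cand <- which(vapply(seq_len(V), function(c)
          c != i && c != j && undirected(i, c) && directed(c, j), logical(1)))
        if (length(cand) >= 2L) {
          for (a in seq_along(cand)) {
            for (b in seq_along(cand)) {
              if (b <= a) next
              if (!adjacent(cand[a], cand[b])) {
                r <- try_orient(am, i, j, nodes, bk)
                if (r$done) { am <- r$am; oriented <- TRUE }
                break
              }
            }
            if (oriented) break
          }
        }
      }
      # R4: i - c, c -> d, d -> j, i adjacent to d, c and j non-adjacent
      #     =>  i -> j
      if (!oriented) {
        for (c in seq_len(V)) {
          if (c == i || c == j || !adjacent(i, c) || adjacent(c, j)) next
          for (dd in seq_len(V)) {
            if (dd == i || dd == j || dd == c) next
            if (directed(c, dd) && directed(dd, j) && adjacent(i, dd)) {
              r <- try_orient(am, i, j, nodes, bk)
              if (r$done) { am <- r$am; oriented <- TRUE }
              break
            }
          }
          if (oriented) break
        }
      }
      if (oriented) changed <- TRUE
    }
    if (!changed) break
  }
  g$amat <- am
  g$kind <- "cpdag"
  g
}

#' Run the PC algorithm end to end
#'
#' Skeleton discovery, collider orientation, background-knowledge
#' orientation and Meek refinement. `pc_parallel` returns output
#' identical to `pc_stable` by contract (its per-depth test decisions
#' are computed from the same frozen adjacencies and applied in the same
#' visit order).
#'
#' @param x An [rd_dataset] or a CI engine.
#' @param cfg A [search_config] (any `pc_*` variant).
#' @param bk A [background_knowledge].
#' @return A [mixed_graph] of kind `"cpdag"`, with attributes `sepsets`,
#'   `n_tests`, `order`.
#' @export
run_pc <- function(x, cfg = search_config(), bk = background_knowledge()) {
  if (cfg$variant == "fci") stop("use run_fci for the FCI variant")
  sk <- pc_skeleton(x, cfg, bk)
  g <- orient_v_structures(sk$graph, sk$sepsets, bk)
  g <- apply_meek_rules(g, bk)
  attr(g, "sepsets") <- sk$sepsets
  attr(g, "n_tests") <- sk$n_tests
  attr(g, "order") <- sk$order
  g
}

#' CPDAG of a known DAG
#'
#' The Markov-equivalence-class representative of a DAG: its skeleton
#' with every unshielded-collider arrowhead kept and Meek's rules
#' closed. Serves as the recovery target when a ground-truth DAG is
#' only identifiable up to its equivalence class. With background
#' knowledge, edges out of arrowhead-protected nodes are additionally
#' oriented (as every estimate honoring the same knowledge would), so
#' the target is the maximally oriented PDAG given that knowledge.
#'
#' @param g A [mixed_graph] of kind `"dag"`.
#' @param bk Optional [background_knowledge].
#' @return A [mixed_graph] of kind `"cpdag"`.
#' @export
dag_to_cpdag <- function(g, bk = background_knowledge()) {
  validate_graph(g)
  A <- dag_view(g)
  V <- length(g$nodes)
  am <- matrix(0L, V, V, dimnames = dimnames(A))
  am[(A == 1L) | (t(A) == 1L)] <- MARK_TAIL      # undirected skeleton
  out <- g
  out$amat <- am
  # unshielded colliders of the true DAG keep their arrowheads
  for (z in seq_len(V)) {
    pa <- which(A[, z] == 1L)
    if (length(pa) < 2L) next
    for (a in seq_along(pa)) for (b in seq_along(pa)) {
      if (b <= a) next
      x <- pa[a]; y <- pa[b]
      if (A[x, y] == 1L || A[y, x] == 1L) next
      out$amat[x, z] <- MARK_ARROW; out$amat[z, x] <- MARK_TAIL
      out$amat[y, z] <- MARK_ARROW; out$amat[z, y] <- MARK_TAIL
    }
  }
  # edges leaving arrowhead-protected nodes are identified by the
  # background knowledge itself
  for (e in match(intersect(bk$forbidden_into, g$nodes), g$nodes)) {
    for (v in which(A[e, ] == 1L)) {
      out$amat[e, v] <- MARK_ARROW
      out$amat[v, e] <- MARK_TAIL
    }
  }
  apply_meek_rules(out, bk)
}
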