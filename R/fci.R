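# FCI: possible-d-sep pruning and PAG orientation (collider rule plus
# Zhang's R1-R4). Selection-bias rules R5-R10 are intentionally omitted:
# a school-based cross-sectional survey has no selection structure for
# them to orient; this is a documented limitation.

# Possible-D-SEP(x): nodes v reachable from x along a path on which
# every intermediate vertex is either a collider or part of a triangle
# with its path neighbors.
possible_dsep <- function(g, x_idx) {
  am <- g$amat
  V <- nrow(am)
  adj <- am != 0L
  reached <- matrix(FALSE, V, V)  # state (prev, cur)
  out <- logical(V)
  frontier <- list()
  for (b in which(adj[x_idx, ])) {
    reached[x_idx, b] <- TRUE
    out[b] <- TRUE
    frontier[[length(frontier) + 1L]] <- c(x_idx, b)
  }
  while (length(frontier) > 0L) {
    st <- frontier[[length(frontier)]]
    frontier[[length(frontier)]] <- NULL
    a <- st[1]; b <- st[2]
    for (cc in which(adj[b, ])) {
      if (cc == a || reached[b, cc]) next
      collider_at_b <- am[a, b] == MARK_ARROW && am[cc, b] == MARK_ARROW
      triangle <- adj[a, cc]
      if (collider_at_b || triangle) {
        reached[b, cc] <- TRUE
        out[cc] <- TRUE
        frontier[[length(frontier) + 1L]] <- c(b, cc)
      }
    }
  }
  out[x_idx] <- FALSE
  which(out)
}

#' Possible-d-sep pruning (FCI second skeleton stage)
#'
#' For each remaining edge x ~ y, searches for a separating set among
#' subsets of Possible-D-SEP(x) and Possible-D-SEP(y) (standard
#' reachability definition on the collider-oriented graph). Removals
#' update the sepset map; afterwards all marks are reset to circles and
#' unshielded colliders re-oriented from the updated map.
#'
#' @param g Collider-oriented [mixed_graph] (output of
#'   [orient_v_structures] with `circle_endpoints = TRUE`).
#' @param x An [rd_dataset] or CI engine.
#' @param cfg A [search_config].
#' @param sepsets Sepset map from skeleton discovery.
#' @param bk A [background_knowledge].
#' @return List `graph` (re-oriented, circle marks), `sepsets`.
#' @export
possible_dsep_prune <- function(g, x, cfg, sepsets,
                                bk = background_knowledge()) {
  engine <- as_engine(x, cfg$alpha)
  nodes <- g$nodes
  V <- length(nodes)
  cap <- min(cfg$max_cond_size, if (is.null(cfg$max_pdsep_size)) Inf
                                else cfg$max_pdsep_size)
  max_size <- if (is.infinite(cap)) -1L else as.integer(cap)
  edges <- which(g$amat != 0L & upper.tri(g$amat), arr.ind = TRUE)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    found <- NULL
    for (side in c(i, j)) {
      cand <- setdiff(possible_dsep(g, side), c(i, j))
      if (length(cand) == 0L) next
      found <- find_sepset(engine, i, j, cand, min_size = 1L,
                           max_size = max_size)
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      g$amat[i, j] <- g$amat[j, i] <- MARK_NONE
      sepsets <- sepset_set(sepsets, i, j, V, found)
    }
  }
  # reset marks, re-orient colliders from the updated sepsets
  g$amat[g$amat != 0L] <- MARK_TAIL
  g$kind <- "skeleton"
  g <- orient_v_structures(g, sepsets, bk, circle_endpoints = TRUE)
  list(graph = g, sepsets = sepsets)
}

# search for a separating subset of `cand` (indices); engine-generic
find_sepset <- function(engine, i, j, cand, min_size = 0L, max_size = -1L) {
  if (inherits(engine, "ci_engine_fisherz")) {
    return(.find_sepset_cpp(engine$C, engine$n, engine$alpha, i, j,
                            as.integer(cand), as.integer(min_size),
                            as.integer(max_size)))
  }
  top <- if (max_size < 0L) length(cand) else min(max_size, length(cand))
  if (top < min_size) return(NULL)
  for (k in seq.int(min_size, top)) {
    combs <- if (k == 0L) list(integer(0)) else
      lapply(utils::combn(length(cand), k, simplify = FALSE),
             function(ix) cand[ix])   # combn(x, k) recycles scalar x to 1:x
    for (S in combs) {
      res <- ci_test_engine(engine, engine$nodes[i], engine$nodes[j],
                            engine$nodes[S])
      if (res$independent) return(as.integer(S))
    }
  }
  NULL
}

#' FCI orientation rules (collider rule plus Zhang's R1-R4)
#'
#' Applies, to a fixed point, the four arrowhead/tail completion rules
#' on a circle-marked, collider-oriented graph, never pointing an
#' arrowhead into a `forbidden_into` node. Edges incident to a
#' `forbidden_into` node are first oriented away from it (tail at the
#' exogenous end, arrowhead at the other; an edge between two such
#' nodes keeps its circles).
#'
#' @param g Output graph of [possible_dsep_prune] (or of
#'   [orient_v_structures] with circles when pruning is skipped).
#' @param sepsets Sepset map.
#' @param bk A [background_knowledge].
#' @return A [mixed_graph] of kind `"pag"`.
#' @export
fci_orient <- function(g, sepsets, bk = background_knowledge()) {
  nodes <- g$nodes
  V <- length(nodes)
  am <- g$amat
  adj <- function(i, j) am[i, j] != 0L
  # background knowledge: exogenous ends get tails, the far end an arrow
  for (ei in match(intersect(bk$forbidden_into, nodes), nodes)) {
    for (vi in which(am[ei, ] != 0L)) {
      if (nodes[vi] %in% bk$forbidden_into) next
      am[vi, ei] <- MARK_TAIL
      am[ei, vi] <- MARK_ARROW
    }
  }
  set_arrow <- function(i, j) {          # arrowhead at j on edge i~j
    if (!arrow_allowed(nodes[j], bk)) return(FALSE)
    if (am[i, j] == MARK_ARROW) return(FALSE)
    am[i, j] <<- MARK_ARROW
    TRUE
  }
  repeat {
    changed <- FALSE
    # R1: a*->b o-* c (circle at b on b~c), a,c non-adjacent => b -> c
    for (b in seq_len(V)) for (a in seq_len(V)) {
      if (a == b || am[a, b] != MARK_ARROW) next
      for (cc in seq_len(V)) {
        if (cc == a || cc == b || !adj(b, cc) || adj(a, cc)) next
        if (am[cc, b] == MARK_CIRCLE) {
          if (arrow_allowed(nodes[cc], bk)) {
            am[cc, b] <- MARK_TAIL
            if (am[b, cc] != MARK_ARROW) am[b, cc] <- MARK_ARROW
            changed <- TRUE
          }
        }
      }
    }
    # R2: a -> b *-> c or a *-> b -> c, with circle at c on a~c => a *-> c
    for (a in seq_len(V)) for (cc in seq_len(V)) {
      if (a == cc || am[a, cc] != MARK_CIRCLE) next
      for (b in seq_len(V)) {
        if (b == a || b == cc || !adj(a, b) || !adj(b, cc)) next
        a_to_b <- am[a, b] == MARK_ARROW && am[b, a] == MARK_TAIL
        b_arr_c <- am[b, cc] == MARK_ARROW
        a_arr_b <- am[a, b] == MARK_ARROW
        b_to_c <- am[b, cc] == MARK_ARROW && am[cc, b] == MARK_TAIL
        if ((a_to_b && b_arr_c) || (a_arr_b && b_to_c)) {
          if (set_arrow(a, cc)) changed <- TRUE
          break
        }
      }
    }
    # R3: a*->b<-*c, a,c non-adjacent, a*-o d o-*c, d*-o b => d *-> b
    for (b in seq_len(V)) for (d in seq_len(V)) {
      if (d == b || am[d, b] != MARK_CIRCLE) next
      done <- FALSE
      for (a in seq_len(V)) {
        if (a == b || a == d || am[a, b] != MARK_ARROW ||
            am[a, d] != MARK_CIRCLE) next
        for (cc in seq_len(V)) {
          if (cc %in% c(a, b, d) || adj(a, cc)) next
          if (am[cc, b] == MARK_ARROW && am[cc, d] == MARK_CIRCLE) {
            if (set_arrow(d, b)) changed <- TRUE
            done <- TRUE
            break
          }
        }
        if (done) break
      }
    }
    # R4: discriminating path <d, ..., a, b, c> for the triple (a, b, c)
    # with a circle mark at b
    for (b in seq_len(V)) for (cc in seq_len(V)) {
      if (cc == b || !adj(b, cc)) next
      if (am[cc, b] != MARK_CIRCLE && am[b, cc] != MARK_CIRCLE) next
      for (a in seq_len(V)) {
        if (a == b || a == cc || !adj(a, b) || !adj(a, cc)) next
        # a must be a collider on the path and a parent of c
        if (am[b, a] != MARK_ARROW) next
        if (!(am[a, cc] == MARK_ARROW && am[cc, a] == MARK_TAIL)) next
        d <- find_discriminating_origin(am, a, b, cc)
        if (is.na(d)) next
        s <- sepset_get(sepsets, d, cc, V)
        if (!is.null(s) && b %in% s) {
          # b on every separating path: orient b -> c
          if (arrow_allowed(nodes[cc], bk)) {
            am[cc, b] <- MARK_TAIL
            if (am[b, cc] != MARK_ARROW) am[b, cc] <- MARK_ARROW
            changed <- TRUE
          }
        } else {
          # collider: a <-> b <-> c
          if (set_arrow(a, b)) changed <- TRUE
          if (set_arrow(b, a)) changed <- TRUE
          if (set_arrow(cc, b)) changed <- TRUE
          if (set_arrow(b, cc)) changed <- TRUE
        }
        break
      }
    }
    if (!changed) break
  }
  g$amat <- am
  g$kind <- "pag"
  g
}

# backward search for the far endpoint d of a discriminating path
# <d, q1, ..., a, b, c>: every intermediate vertex is a collider on the
# path and a parent of c; d is not adjacent to c
find_discriminating_origin <- function(am, a, b, cc) {
  V <- nrow(am)
  adj <- am != 0L
  visited <- rep(FALSE, V)
  frontier <- a
  visited[c(a, b, cc)] <- TRUE
  while (length(frontier) > 0L) {
    v <- frontier[[1]]; frontier <- frontier[-1]
    for (t in which(adj[, v])) {
      if (visited[t]) next
      if (am[t, v] != MARK_ARROW) next       # needs arrowhead at v
      if (!adj[t, cc]) return(t)             # found the origin d
      # t must itself be a collider-parent to extend the path
      t_parent_of_c <- am[t, cc] == MARK_ARROW && am[cc, t] == MARK_TAIL
      t_collider <- am[v, t] == MARK_ARROW
      if (t_parent_of_c && t_collider) {
        visited[t] <- TRUE
        frontier <- c(frontier, t)
      }
    }
  }
  NA_integer_
}

#' Run the FCI algorithm end to end
#'
#' PC-style skeleton (order-sensitive sweep, as in the classic
#' algorithm), unshielded-collider orientation with circle endpoints,
#' possible-d-sep pruning with re-orientation, then the completion rules
#' of [fci_orient].
#'
#' @param x An [rd_dataset] or CI engine.
#' @param cfg A [search_config] (variant is forced to `"fci"`).
#' @param bk A [background_knowledge].
#' @return A [mixed_graph] of kind `"pag"` with attributes `sepsets`,
#'   `order`.
#' @export
run_fci <- function(x, cfg = search_config(variant = "fci"),
                    bk = background_knowledge()) {
  cfg$variant <- "fci"
  engine <- as_engine(x, cfg$alpha)
  sk <- pc_skeleton(engine, cfg, bk)
  g <- orient_v_structures(sk$graph, sk$sepsets, bk, circle_endpoints = TRUE)
  pr <- possible_dsep_prune(g, engine, cfg, sk$sepsets, bk)
  g <- fci_orient(pr$graph, pr$sepsets, bk)
  attr(g, "sepsets") <- pr$sepsets
  attr(g, "order") <- sk$order
  g
}
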