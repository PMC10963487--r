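test_that("order-invariant algorithms produce all-or-nothing tallies", {
  spec <- random_sem_spec(5, seed = 51, p = 0.5, wmin = 0.7)
  d <- std_data(spec, 4000, seed = 51)
  tab <- randomized_runs(d, "pc_stable", cfg = consensus_config(M = 20,
                                                               master_seed = 7),
                         alpha = 0.01)
  support <- tab$counts + t(tab$counts) + tab$undirected_counts +
    t(tab$undirected_counts)
  expect_true(all(support %in% c(0L, 20L)))
})

test_that("tallies equal an independent recount of the stored run graphs", {
  spec <- random_sem_spec(5, seed = 52, p = 0.5)
  d <- std_data(spec, 2000, seed = 52)
  tab <- randomized_runs(d, "pc_original",
                         cfg = consensus_config(M = 20, master_seed = 3),
                         alpha = 0.05, keep_graphs = TRUE)
  V <- length(tab$nodes)
  cnt <- matrix(0L, V, V); und <- matrix(0L, V, V)
  for (g in tab$graphs) {
    dirs <- (g$amat == 2L) & (t(g$amat) == 1L)
    cnt <- cnt + dirs
    und <- und + ((g$amat != 0L) & !dirs & !t(dirs) & upper.tri(g$amat))
  }
  expect_equal(unname(tab$counts), unname(cnt))
  expect_equal(unname(tab$undirected_counts), unname(und))

  one <- randomized_runs(d, "pc_original",
                         cfg = consensus_config(M = 1, master_seed = 3),
                         alpha = 0.05, keep_graphs = TRUE)
  expect_true(all((one$counts + one$undirected_counts) %in% c(0L, 1L)))
})

test_that("the ensemble is deterministic given the master seed", {
  spec <- random_sem_spec(5, seed = 53, p = 0.5)
  d <- std_data(spec, 1000, seed = 53)
  t1 <- randomized_runs(d, "pc_original",
                        cfg = consensus_config(M = 8, master_seed = 11))
  t2 <- randomized_runs(d, "pc_original",
                        cfg = consensus_config(M = 8, master_seed = 11))
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$undirected_counts, t2$undirected_counts)
  expect_identical(t1$seeds, t2$seeds)
  expect_identical(consensus_graph(list(t1))$amat,
                   consensus_graph(list(t2))$amat)
})

hand_table <- function(nodes, counts, M, und = NULL) {
  V <- length(nodes)
  cm <- matrix(0L, V, V, dimnames = list(nodes, nodes))
  for (k in seq_along(counts)) {
    p <- strsplit(names(counts)[k], "->", fixed = TRUE)[[1]]
    cm[p[1], p[2]] <- counts[[k]]
  }
  um <- matrix(0L, V, V, dimnames = list(nodes, nodes))
  if (!is.null(und)) for (k in seq_along(und)) {
    p <- strsplit(names(und)[k], "--", fixed = TRUE)[[1]]
    um[p[1], p[2]] <- und[[k]]
  }
  structure(list(algorithm = "hand", M = M, counts = cm,
                 undirected_counts = um, seeds = integer(), nodes = nodes,
                 graphs = NULL),
            class = "edge_frequency_table")
}

test_that("consensus applies the frequency threshold with >= semantics", {
  nodes <- c("X", "Y")
  unan <- hand_table(nodes, c("X->Y" = 1000L), 1000L)
  g <- consensus_graph(list(unan), consensus_config(M = 1000, tau = 0.6))
  expect_equal(dag_view(g)["X", "Y"], 1L)

  # 499/1000 at tau = 0.5: 0.499 < 0.5, excluded
  boundary <- hand_table(nodes, c("X->Y" = 499L), 1000L)
  g2 <- consensus_graph(list(boundary), consensus_config(M = 1000, tau = 0.5))
  expect_equal(nrow(graph_edges(g2)), 0L)
  # exactly 500/1000 qualifies at tau = 0.5
  at <- hand_table(nodes, c("X->Y" = 500L), 1000L)
  g3 <- consensus_graph(list(at), consensus_config(M = 1000, tau = 0.5))
  expect_equal(dag_view(g3)["X", "Y"], 1L)
})

test_that("cycle repair deletes the lowest-frequency edge of each cycle", {
  nodes <- c("a", "b", "c")
  tab <- hand_table(nodes, c("a->b" = 900L, "b->c" = 800L, "c->a" = 610L),
                    1000L)
  g <- consensus_graph(list(tab), consensus_config(M = 1000, tau = 0.6))
  A <- dag_view(g)
  expect_equal(A["a", "b"], 1L)
  expect_equal(A["b", "c"], 1L)
  expect_equal(A["c", "a"], 0L)      # weakest edge of the 3-cycle removed
  expect_true(is_acyclic(g))
})

test_that("raising tau can only shrink the consensus edge set", {
  spec <- random_sem_spec(6, seed = 54, p = 0.5)
  d <- std_data(spec, 2000, seed = 54)
  tab <- randomized_runs(d, "pc_original",
                         cfg = consensus_config(M = 30, master_seed = 5),
                         alpha = 0.05)
  prev <- NULL
  for (tau in c(0.5, 0.6, 0.75, 0.9, 1.0)) {
    g <- consensus_graph(list(tab), consensus_config(M = 30, tau = tau))
    edges <- paste(graph_edges(g)$a, graph_edges(g)$b)
    if (!is.null(prev)) expect_true(all(edges %in% prev))
    prev <- edges
    expect_true(is_acyclic(g))
  }
})

test_that("stability profile conserves the tallies and ranks by frequency", {
  nodes <- c("p", "q", "r")
  tab <- hand_table(nodes, c("p->q" = 12L, "q->r" = 30L), 40L,
                    und = c("p--r" = 7L))
  prof <- stability_profile(tab)
  expect_equal(sum(prof$count), 12L + 30L + 7L)
  expect_equal(prof$count[1], 30L)
  expect_equal(prof$direction[prof$from == "p" & prof$to == "r"], "--")

  empty <- hand_table(nodes, setNames(integer(), character()), 40L)
  expect_equal(nrow(stability_profile(empty)), 0L)
})

test_that("majority merging requires more than half of the algorithms", {
  nodes <- c("X", "Y", "Z")
  t1 <- hand_table(nodes, c("X->Y" = 90L, "Y->Z" = 90L), 100L)
  t2 <- hand_table(nodes, c("X->Y" = 90L), 100L)
  t3 <- hand_table(nodes, c("X->Y" = 5L), 100L)
  g <- consensus_graph(list(t1, t2, t3),
                       consensus_config(M = 100, tau = 0.6,
                                        merge_rule = "majority_of_algorithms"))
  A <- dag_view(g)
  expect_equal(A["X", "Y"], 1L)      # qualifies in 2 of 3
  expect_equal(A["Y", "Z"], 0L)      # qualifies in only 1
  gi <- consensus_graph(list(t1, t2, t3),
                        consensus_config(M = 100, tau = 0.6,
                                         merge_rule = "intersection"))
  expect_equal(nrow(graph_edges(gi)), 0L)
})
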