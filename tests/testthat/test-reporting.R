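binary_outcome_data <- function(n_by_stratum, pos_by_stratum, levels_g) {
  g <- rep(seq_along(n_by_stratum) - 1L, n_by_stratum)
  y <- unlist(lapply(seq_along(n_by_stratum), function(k)
    c(rep(1L, pos_by_stratum[k]), rep(0L, n_by_stratum[k] - pos_by_stratum[k]))))
  rd_dataset(cbind(grp = as.numeric(g), y = as.numeric(y)),
             list(variable_meta("grp", "ordinal", level_order = levels_g),
                  variable_meta("y", "binary", level_order = c("no", "yes"))))
}

test_that("detection rates reproduce printed two-decimal percentages", {
  d <- binary_outcome_data(c(2687L, 2620L), c(667L, 727L),
                           c("male", "female"))
  dr <- detection_rates(d, "y", "grp")
  expect_equal(dr$rate[dr$stratum == "overall"], 26.27)
  expect_equal(dr$rate[dr$level == "male"], 24.82)
  expect_equal(dr$rate[dr$level == "female"], 27.75)
  expect_equal(sum(dr$n_positive[dr$stratum == "grp"]),
               dr$n_positive[dr$stratum == "overall"])

  # zero positives and empty strata are reported, not dropped
  d0 <- binary_outcome_data(c(50L, 0L), c(0L, 0L), c("a", "b"))
  dr0 <- detection_rates(d0, "y", "grp")
  expect_equal(dr0$rate[dr0$level == "a"], 0)
  expect_true(is.na(dr0$rate[dr0$level == "b"]))
  expect_equal(dr0$n_total[dr0$level == "b"], 0L)

  expect_error(detection_rates(d, "grp"), "not binary")
})

test_that("rate_percent rounds half-up at the second decimal", {
  expect_equal(rate_percent(886, 3768), 23.51)
  expect_equal(rate_percent(508, 1539), 33.01)
  expect_equal(rate_percent(1, 16), 6.25)
  # 1/3200 = 0.03125% -> 0.03; 45/8000 = 0.5625% -> 0.56; the half case:
  # 9/800 = 1.125% rounds up to 1.13 (round-half-even would give 1.12)
  expect_equal(rate_percent(9, 800), 1.13)
})

test_that("local neighborhoods follow undirected BFS distance", {
  g <- mixed_graph(c("a", "b", "t", "c"), kind = "dag")
  g <- add_directed_edge(g, "a", "b")
  g <- add_directed_edge(g, "b", "t")
  g <- add_directed_edge(g, "t", "c")
  n1 <- local_neighborhood(g, "t", steps = 1)
  expect_setequal(n1$nodes, c("b", "t", "c"))
  n2 <- local_neighborhood(g, "t", steps = 2)
  expect_setequal(n2$nodes, c("a", "b", "t", "c"))
  expect_true(all(n1$nodes %in% n2$nodes))               # monotone in steps

  iso <- mixed_graph(c("t", "z"), kind = "dag")
  expect_equal(local_neighborhood(iso, "t")$nodes, "t")

  # BFS oracle on a random 10-node DAG
  spec <- random_sem_spec(10, seed = 81, p = 0.25)
  A <- dag_view(spec$graph)
  U <- ((A + t(A)) > 0) * 1L
  target <- "V5"
  dist2 <- (U %*% U > 0) | (U > 0); diag(dist2) <- TRUE
  oracle_nodes <- spec$graph$nodes[dist2[match(target, spec$graph$nodes), ]]
  got <- local_neighborhood(spec$graph, target, 2)$nodes
  expect_setequal(got, oracle_nodes)
})

test_that("pathway enumeration matches exhaustive DFS and sorts stably", {
  dia <- mixed_graph(c("a", "b", "c", "t"), kind = "dag")
  dia <- add_directed_edge(dia, "a", "b")
  dia <- add_directed_edge(dia, "b", "t")
  dia <- add_directed_edge(dia, "a", "c")
  dia <- add_directed_edge(dia, "c", "t")
  pw <- enumerate_pathways(dia, "t")
  keys <- vapply(pw, function(p) paste(p$nodes, collapse = ">"), character(1))
  expect_identical(keys, c("b>t", "c>t", "a>b>t", "a>c>t"))  # fixed sort
  # exactly reproducible across calls
  keys2 <- vapply(enumerate_pathways(dia, "t"),
                  function(p) paste(p$nodes, collapse = ">"), character(1))
  expect_identical(keys, keys2)

  one <- add_directed_edge(mixed_graph(c("x", "t")), "x", "t")
  p1 <- enumerate_pathways(one, "t")
  expect_length(p1, 1L)
  expect_equal(p1[[1]]$nodes, c("x", "t"))

  # DFS oracle on random 8-node DAGs: count all directed paths into the
  # target with <= 6 edges
  for (s in 1:5) {
    spec <- random_sem_spec(8, seed = 820 + s, p = 0.35)
    A <- dag_view(spec$graph)
    target <- "V8"
    count_paths <- function(v, depth) {
      if (depth > 6) return(0L)
      pa <- which(A[, v] == 1L)
      n <- length(pa)
      for (p in pa) n <- n + count_paths(p, depth + 1)
      n
    }
    expect_length(enumerate_pathways(spec$graph, target),
                  count_paths(match(target, spec$graph$nodes), 1))
  }

  cyc <- mixed_graph(c("x", "y", "z"), kind = "skeleton")
  cyc <- add_directed_edge(cyc, "x", "y")
  cyc <- add_directed_edge(cyc, "y", "z")
  cyc <- add_directed_edge(cyc, "z", "x")
  expect_error(enumerate_pathways(cyc, "y"), "acyclic")
})

test_that("pathways carry polarity annotations from the weighted graph", {
  g <- mixed_graph(c("PYD", "Depression", "NSSI"), kind = "dag")
  g <- add_directed_edge(g, "PYD", "Depression")
  g <- add_directed_edge(g, "Depression", "NSSI")
  A <- matrix(0, 3, 3); A[1, 2] <- -0.5; A[2, 3] <- 0.7
  w <- threshold_weights(weighted_digraph(A, g$nodes), 0.3)
  pw <- enumerate_pathways(g, "NSSI", weights = w)
  long <- pw[[which(vapply(pw, function(p) length(p$nodes), integer(1)) == 3)]]
  expect_identical(long$polarity, c("protective", "risk"))
})

test_that("upstream and downstream sets equal the matrix closure", {
  ch <- mixed_graph(c("a", "b", "c"), kind = "dag")
  ch <- add_directed_edge(ch, "a", "b")
  ch <- add_directed_edge(ch, "b", "c")
  ud <- upstream_downstream(ch, "c")
  expect_setequal(ud$upstream, c("a", "b"))
  expect_length(upstream_downstream(ch, "a")$upstream, 0L)

  for (s in 1:5) {
    spec <- random_sem_spec(8, seed = 840 + s, p = 0.3)
    A <- dag_view(spec$graph)
    R <- closure_oracle(A)
    v <- "V4"; vi <- match(v, spec$graph$nodes)
    ud <- upstream_downstream(spec$graph, v)
    expect_setequal(ud$upstream, spec$graph$nodes[R[, vi] > 0 &
                                                  seq_len(8) != vi])
    expect_setequal(ud$downstream, spec$graph$nodes[R[vi, ] > 0 &
                                                    seq_len(8) != vi])
  }
})
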