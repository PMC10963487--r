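test_that("the shipped survey spec has the documented structure", {
  spec <- make_cpcd_like_spec()
  expect_length(spec$graph$nodes, 22L)
  A <- dag_view(spec$graph)
  expect_gte(sum(A[, "NSSI"]), 9L)                  # nine direct influences
  exo <- names(spec$tiers)[spec$tiers != "endogenous"]
  expect_setequal(exo, c("Gender", "Grade", "SleepChange", "PhysActChange",
                         "ScreenChange", "SSBChange"))
  expect_equal(sum(A[, exo]), 0L)                   # nothing points into them
  expect_true(is_acyclic(spec$graph))
  # signed pathways: protective factors carry negative weights into NSSI
  expect_lt(spec$weights[["PYD->NSSI"]], 0)
  expect_lt(spec$weights[["LifeSatisfaction->NSSI"]], 0)
  expect_gt(spec$weights[["Depression->NSSI"]], 0)
  expect_true(all(abs(spec$weights) >= 0.2 & abs(spec$weights) <= 0.8))
})

test_that("spec construction validates weights, thresholds and tiers", {
  g <- add_directed_edge(mixed_graph(c("A", "B"), kind = "dag"), "A", "B")
  expect_error(scm_spec(g, c("B->A" = 1), c(A = 1, B = 1)), "keyed exactly")
  expect_error(scm_spec(g, c("A->B" = 1), c(A = 1, B = 1),
                        thresholds = list(B = c(1, 0.5))),
               "strictly increasing")
  expect_error(scm_spec(g, c("A->B" = 1), c(A = 1, B = 1),
                        tiers = c(A = "endogenous", B = "exogenous_fixed")),
               "exogenous")
})

test_that("sampling is deterministic and independent under zero weights", {
  spec <- zero_weight_spec(5)
  d1 <- sample_scm(spec, 5000, seed = 77)
  d2 <- sample_scm(spec, 5000, seed = 77)
  expect_identical(d1$values, d2$values)            # bit-identical
  C <- stats::cor(d1$values)
  expect_lt(max(abs(C[upper.tri(C)])), 3 / sqrt(5000))
})

test_that("a single linear edge reproduces its analytic correlation", {
  # X -> Y with weight 0.8, unit noise: rho = 0.8 / sqrt(0.64 + 1)
  d <- sample_scm(two_node_spec(0.8), 20000, seed = 5)
  expect_equal(stats::cor(d$values[, "X"], d$values[, "Y"]),
               0.62469504755442426, tolerance = 0.02)
})

test_that("per-node substreams keep exogenous draws invariant to edge weights", {
  spec <- make_cpcd_like_spec()
  spec0 <- spec
  spec0$weights[] <- 0                              # cut every causal path
  d <- sample_scm(spec, 500, seed = 3)
  d0 <- sample_scm(spec0, 500, seed = 3)
  exo <- names(spec$tiers)[spec$tiers != "endogenous"]
  expect_identical(d$values[, exo], d0$values[, exo])
})

test_that("discretization is monotone in the latent value", {
  # stronger latent drive must never lower the expected ordinal code
  g <- add_directed_edge(mixed_graph(c("X", "K"), kind = "dag"), "X", "K")
  spec <- scm_spec(g, c("X->K" = 0.9), noise_sd = c(X = 1, K = 0.4),
                   thresholds = list(K = c(-0.8, 0.3, 1.1)),
                   tiers = c(X = "endogenous", K = "endogenous"))
  d <- sample_scm(spec, 8000, seed = 9)
  x <- d$values[, "X"]; k <- d$values[, "K"]
  bins <- cut(x, stats::quantile(x, seq(0, 1, 0.2)), include.lowest = TRUE)
  means <- tapply(k, bins, mean)
  expect_true(all(diff(means) >= 0))
  expect_setequal(sort(unique(k)), 0:3)
})

test_that("marginal_report counts levels and summarizes continuous columns", {
  meta <- list(variable_meta("flag", "binary", level_order = c("no", "yes")),
               variable_meta("konst", "binary", level_order = c("a", "b")),
               variable_meta("size", "continuous"))
  vals <- cbind(flag = c(rep(1, 26), rep(0, 74)),
                konst = rep(0, 100),
                size = seq_len(100))
  mr <- marginal_report(rd_dataset(vals, meta))
  expect_equal(mr$percent[mr$variable == "flag" & mr$level == "yes"], 26)
  expect_equal(mr$percent[mr$variable == "konst" & mr$level == "a"], 100)
  expect_equal(mr$mean[mr$variable == "size"], 50.5)

  # independent hand tabulation on a 10-row fixture
  vals10 <- cbind(flag = c(1, 0, 0, 1, 1, 0, 0, 0, 1, 0),
                  konst = rep(0, 10), size = rep(2, 10))
  mr10 <- marginal_report(rd_dataset(vals10, meta))
  expect_equal(mr10$count[mr10$variable == "flag" & mr10$level == "yes"], 4)
  expect_equal(mr10$percent[mr10$variable == "flag" & mr10$level == "yes"], 40)
})

test_that("default marginals sit near the reference survey table", {
  d <- sample_scm(make_cpcd_like_spec(), 5307, seed = 42)
  mr <- marginal_report(d)
  pct <- function(v, l) mr$percent[mr$variable == v & mr$level == l]
  expect_equal(pct("NSSI", "yes"), 26.27, tolerance = 0.08)        # ratio
  expect_equal(pct("Depression", "yes"), 35.01, tolerance = 0.08)
  expect_equal(pct("PTSD", "yes"), 34.65, tolerance = 0.08)
  expect_equal(pct("Gender", "male"), 50.63, tolerance = 0.05)
})

test_that("missing-value injection is separate from sampling and block-aware", {
  spec <- zero_weight_spec(4)
  d <- sample_scm(spec, 100, seed = 1)
  expect_false(anyNA(d$values))
  dc <- inject_missing(d, rate = 0.2, seed = 2)
  expect_gt(sum(is.na(dc$values)), 0)
  db <- inject_missing(d, blank_blocks = list(list(vars = c("V1", "V2"),
                                                   rows = 1:5)))
  expect_true(all(is.na(db$values[1:5, c("V1", "V2")])))
  expect_false(anyNA(db$values[6:100, ]))
})

test_that("specs serialize to YAML and back", {
  spec <- make_cpcd_like_spec()
  p <- file.path(withr::local_tempdir(), "spec.yaml")
  write_scm_spec(spec, p)
  spec2 <- read_scm_spec(p)
  expect_setequal(names(spec2$weights), names(spec$weights))
  expect_equal(spec2$weights[names(spec$weights)], spec$weights)
  expect_equal(spec2$tiers, spec$tiers)
  expect_equal(spec2$thresholds[["NSSI"]], spec$thresholds[["NSSI"]])
  d1 <- sample_scm(spec, 50, seed = 8)
  d2 <- sample_scm(spec2, 50, seed = 8)
  expect_equal(d2$values[, colnames(d1$values)], d1$values)
})

test_that("generator faithfulness: Fisher-z separates d-connected from d-separated pairs", {
  spec <- make_cpcd_like_spec()
  std <- std_data(spec, 20000, seed = 60)
  eng <- ci_engine_fisherz(std, alpha = 0.01)
  A <- dag_view(spec$graph)
  nodes <- spec$graph$nodes
  topo <- nodes[as.integer(igraph::topo_sort(
    igraph::graph_from_adjacency_matrix(A, mode = "directed")))]
  rank <- match(nodes, topo)
  err <- 0L; total <- 0L
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    total <- total + 1L
    late <- if (rank[i] > rank[j]) i else j
    other <- if (late == i) j else i
    pa <- nodes[A[, late] == 1L]
    adjacent <- A[i, j] == 1L || A[j, i] == 1L
    s <- setdiff(pa, nodes[other])
    res <- riskdag:::ci_test_engine(eng, nodes[i], nodes[j], s)
    if (adjacent) {
      if (res$independent) err <- err + 1L      # missed a true edge
    } else {
      # conditioning on the later node's parents d-separates the pair
      if (!res$independent) err <- err + 1L     # false rejection
    }
  }
  expect_lt(err / total, 0.05)
})
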