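mk_data <- function(vals, types = NULL) {
  nm <- colnames(vals)
  if (is.null(types)) types <- rep("continuous", ncol(vals))
  meta <- lapply(seq_along(nm), function(j) {
    if (types[j] == "continuous") variable_meta(nm[j], "continuous")
    else variable_meta(nm[j], types[j],
                       level_order = as.character(0:max(as.numeric(vals[, j]),
                                                        1, na.rm = TRUE)))
  })
  rd_dataset(vals, meta)
}

test_that("sparse variables are dropped on a strict 90% threshold", {
  vals <- cbind(mostly_na = c(rep(NA, 95), rnorm(5)),
                boundary = c(rep(NA, 90), rnorm(10)),
                full = rnorm(100))
  d <- mk_data(vals)
  out <- drop_sparse_variables(d, 0.9)
  expect_setequal(var_names(out$dataset), c("boundary", "full"))  # 0.90 kept
  expect_equal(out$report$dropped_variables$name, "mostly_na")
  expect_equal(out$report$dropped_variables$missing_rate, 0.95)

  full <- mk_data(cbind(a = rnorm(10)))
  id <- drop_sparse_variables(full, 0.9)
  expect_identical(id$dataset$values, full$values)   # fully observed: identity
  expect_equal(nrow(id$report$dropped_variables), 0L)

  all_na <- mk_data(cbind(a = rep(NA_real_, 10)))
  expect_error(drop_sparse_variables(all_na, 0.5), "all variables")
})

test_that("samples lacking an entire required block are removed, gaps imputed", {
  vals <- cbind(cg1 = c(NA, NA, 1, 2, 3),
                cg2 = c(NA, 5, NA, 6, 7),
                other = c(1, 2, 3, 4, 100))
  d <- mk_data(vals)
  out <- drop_incomplete_samples(d, list(c("cg1", "cg2")))
  # row 1 misses the whole caregiver block -> removed; rows 2,3 keep
  # one cell and are imputed
  expect_equal(out$dataset$n, 4L)
  expect_equal(out$report$n_removed_missing_block, 1L)
  expect_false(anyNA(out$dataset$values))
  # imputed by column median of the retained rows
  expect_equal(unname(out$dataset$values[1, "cg1"]),
               stats::median(c(1, 2, 3)))

  id <- drop_incomplete_samples(d, list())
  expect_equal(id$dataset$n, 5L)
  expect_error(drop_incomplete_samples(d, list("nope")), "unknown variable")
})

test_that("outlier removal is robust, continuous-only, and matches a row scan", {
  vals <- cbind(u = c(stats::runif(99), 100), o = rep(1, 100))
  d <- mk_data(vals, c("continuous", "binary"))
  out <- remove_outliers(d, k = 4)
  expect_equal(out$report$n_removed_outlier, 1L)
  expect_false(100 %in% out$dataset$values[, "u"])

  ordn <- mk_data(cbind(a = sample(0:3, 50, TRUE)), "ordinal")
  expect_equal(remove_outliers(ordn, 4)$report$n_removed_outlier, 0L)

  # independent per-row scan oracle on random data
  set.seed(10)
  X <- cbind(a = stats::rt(300, df = 2), b = stats::rt(300, df = 2))
  d2 <- mk_data(X)
  out2 <- remove_outliers(d2, k = 4)
  flag <- rep(FALSE, 300)
  for (j in 1:2) {
    med <- stats::median(X[, j]); iqr <- diff(stats::quantile(X[, j], c(.25, .75)))
    flag <- flag | X[, j] < med - 4 * iqr | X[, j] > med + 4 * iqr
  }
  expect_equal(out2$report$n_removed_outlier, sum(flag))
})

test_that("ordinal encoding follows the declared level order, not lexical order", {
  meta <- list(variable_meta("freq", "ordinal",
                             level_order = c("never", "once", "twice+")),
               variable_meta("rev", "ordinal",
                             level_order = c("zebra", "apple")),
               variable_meta("covid", "binary", level_order = c("-", "+")))
  vals <- data.frame(freq = c("never", "twice+", "once"),
                     rev = c("apple", "zebra", "zebra"),
                     covid = c("+", "-", "+"))
  enc <- encode_ordinal(rd_dataset(vals, meta))
  expect_equal(enc$values[, "freq"], c(0, 2, 1))
  expect_equal(enc$values[, "rev"], c(1, 0, 0))     # declared order wins
  expect_equal(enc$values[, "covid"], c(1, 0, 1))   # "-" = 0, "+" = 1

  bad <- rd_dataset(data.frame(freq = "sometimes", rev = "apple", covid = "-"),
                    meta)
  expect_error(encode_ordinal(bad), "'sometimes'")
})

test_that("standardization hits exact moments, inverts, and preserves correlations", {
  set.seed(4)
  X <- cbind(a = c(1, 2, 3), b = rnorm(3, 50, 10))
  d <- mk_data(X)
  out <- standardize(d)
  expect_lt(max(abs(colMeans(out$dataset$values))), 1e-10)
  expect_equal(unname(apply(out$dataset$values, 2, stats::sd)), c(1, 1))

  # parameters invert the transform
  back <- sweep(sweep(out$dataset$values, 2, out$scales, "*"), 2,
                out$centers, "+")
  expect_lt(max(abs(back - X)), 1e-10)

  # idempotence up to numerical noise
  again <- standardize(out$dataset)$dataset$values
  expect_lt(max(abs(again - out$dataset$values)), 1e-10)

  # affine invariance of correlations
  set.seed(5)
  Y <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  Y <- sweep(sweep(Y, 2, c(1, 2, 3, 4), "*"), 2, c(10, -5, 0, 100), "+")
  dy <- mk_data(Y)
  expect_equal(stats::cor(standardize(dy)$dataset$values), stats::cor(Y),
               tolerance = 1e-12)

  cst <- mk_data(cbind(a = rep(2, 10), b = rnorm(10)))
  expect_error(standardize(cst), "constant")
})

test_that("the pipeline runs in its fixed order and the report telescopes", {
  spec <- make_cpcd_like_spec()
  d <- sample_scm(spec, 400, seed = 12)
  d <- inject_missing(d, rate = 0.005, seed = 1,
                      blank_blocks = list(list(vars = c("CaregiverMentalHealth"),
                                               rows = 1:6)))
  out <- preprocess_pipeline(d, required_blocks = list("CaregiverMentalHealth"))
  rep <- out$report
  expect_equal(rep$n_input, 400L)
  expect_equal(rep$n_output,
               rep$n_input - rep$n_removed_missing_block - rep$n_removed_outlier)
  expect_equal(out$dataset$n, rep$n_output)
  expect_false(anyNA(out$dataset$values))
  expect_lt(max(abs(colMeans(out$dataset$values))), 1e-10)
})
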