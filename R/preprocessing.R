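# Sample refinement and encoding: sparse-variable drop, required-block
# sample drop with deterministic imputation of isolated gaps, robust
# outlier removal, ordinal label encoding, standardization. Pipeline
# order is fixed (see preprocess_pipeline); standardization preserves
# all sample correlations, so conditional-independence decisions do not
# depend on pre-standardization location or scale.

filter_report <- function(n_input, n_removed_outlier = 0L,
                          n_removed_missing_block = 0L,
                          dropped_variables = data.frame(
                            name = character(), missing_rate = numeric())) {
  n_output <- n_input - n_removed_outlier - n_removed_missing_block
  stopifnot(n_output >= 0L)
  structure(list(n_input = n_input,
                 n_removed_outlier = n_removed_outlier,
                 n_removed_missing_block = n_removed_missing_block,
                 n_output = n_output,
                 dropped_variables = dropped_variables),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> in=", x$n_input,
      " -outliers=", x$n_removed_outlier,
      " -missing_block=", x$n_removed_missing_block,
      " out=", x$n_output,
      "; dropped vars: ", nrow(x$dropped_variables), "\n", sep = "")
  invisible(x)
}

#' Drop variables whose missing rate exceeds a threshold
#'
#' @param d An [rd_dataset].
#' @param max_missing_rate Variables with missing fraction strictly
#'   greater than this are removed (default 0.9, i.e. "missing rate
#'   exceeding 90%").
#' @return `list(dataset=, report=)`.
#' @export
drop_sparse_variables <- function(d, max_missing_rate = 0.9) {
  stopifnot(max_missing_rate > 0, max_missing_rate <= 1)
  rates <- colMeans(is.na(d$values))
  drop <- which(rates > max_missing_rate)
  if (length(drop) == ncol(d$values))
    stop("all variables exceed the missing-rate threshold")
  rep <- filter_report(d$n, dropped_variables = data.frame(
    name = var_names(d)[drop], missing_rate = unname(rates[drop]),
    stringsAsFactors = FALSE))
  if (length(drop) > 0L)
    d <- rd_dataset(d$values[, -drop, drop = FALSE], d$meta[-drop])
  list(dataset = d, report = rep)
}

#' Drop samples missing an entire required block; impute isolated gaps
#'
#' A row is removed iff, for some block, every variable in that block is
#' missing (e.g. a wholly absent caregiver questionnaire). Remaining
#' isolated missing cells are imputed deterministically: variable mode
#' for ordinal/binary, median for continuous.
#'
#' @param d An [rd_dataset].
#' @param required_blocks List of character vectors of variable names.
#' @return `list(dataset=, report=)`.
#' @export
drop_incomplete_samples <- function(d, required_blocks = list()) {
  nms <- var_names(d)
  for (bl in required_blocks) {
    bad <- setdiff(bl, nms)
    if (length(bad) > 0L) stop("required block names unknown variable(s): ",
                               paste(bad, collapse = ", "))
  }
  remove <- rep(FALSE, d$n)
  for (bl in required_blocks) {
    miss <- is.na(d$values[, bl, drop = FALSE])
    remove <- remove | rowSums(miss) == length(bl)
  }
  if (all(remove)) stop("every sample lacks a required block; empty output")
  vals <- d$values[!remove, , drop = FALSE]
  # deterministic single-pass imputation of residual gaps
  vt <- var_types(d)
  for (j in seq_along(nms)) {
    x <- vals[, j]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop("variable '", nms[j], "' entirely missing after filtering")
    fill <- if (vt[j] == "continuous")
      stats::median(as.numeric(x), na.rm = TRUE)
    else names(which.max(table(x)))   # mode; works for labels and codes alike
    vals[is.na(x), j] <- fill
  }
  rep <- filter_report(d$n, n_removed_missing_block = sum(remove))
  list(dataset = rd_dataset(vals, d$meta), report = rep)
}

#' Remove rows with extreme continuous values
#'
#' A row is removed when any of its continuous values lies outside
#' `median +/- k * IQR` of that column. The robust rule avoids masking;
#' ordinal/binary columns never trigger removal.
#'
#' @param d An [rd_dataset].
#' @param k Multiplier (default 4).
#' @return `list(dataset=, report=)`.
#' @export
remove_outliers <- function(d, k = 4) {
  stopifnot(k > 0)
  vt <- var_types(d)
  remove <- rep(FALSE, d$n)
  for (j in which(vt == "continuous")) {
    x <- as.numeric(d$values[, j])
    med <- stats::median(x, na.rm = TRUE)
    iqr <- stats::quantile(x, 0.75, na.rm = TRUE) - stats::quantile(x, 0.25, na.rm = TRUE)
    out <- !is.na(x) & (x < med - k * iqr | x > med + k * iqr)
    remove <- remove | out
  }
  rep <- filter_report(d$n, n_removed_outlier = sum(remove))
  d2 <- if (any(remove)) rd_dataset(d$values[!remove, , drop = FALSE], d$meta) else d
  list(dataset = d2, report = rep)
}

#' Encode ordinal/binary variables as consecutive integers
#'
#' Level `i` of the declared `level_order` maps to code `i - 1`; the
#' declared order is authoritative (never lexical), so encoding is
#' monotone in the survey's intended ordering. Columns already holding
#' numeric codes `0..k-1` pass through unchanged; any other value is a
#' hard error naming the offending datum.
#'
#' @param d An [rd_dataset].
#' @return The encoded dataset with a numeric value matrix.
#' @export
encode_ordinal <- function(d) {
  vals <- matrix(NA_real_, d$n, length(d$meta),
                 dimnames = list(NULL, var_names(d)))
  chr <- is.character(d$values)
  for (j in seq_along(d$meta)) {
    m <- d$meta[[j]]
    x <- d$values[, j]
    if (m$var_type == "continuous") {
      vals[, j] <- as.numeric(x)
      next
    }
    k <- length(m$level_order)
    if (chr) {
      # a column may hold labels, numeric codes, or a mix (after
      # imputation of a numeric sheet everything is character anyway)
      idx <- match(x, m$level_order) - 1L
      num <- suppressWarnings(as.numeric(x))
      code <- ifelse(!is.na(idx), idx, num)
    } else {
      code <- as.numeric(x)
    }
    ok <- is.na(x) | (!is.na(code) & code == floor(code) & code >= 0 & code <= k - 1)
    if (!all(ok)) {
      bad <- x[which(!ok)[1]]
      stop("value '", bad, "' of variable '", m$name,
           "' is neither a declared level nor a code in 0..", k - 1,
           " (declared levels: ", paste(m$level_order, collapse = ", "), ")")
    }
    vals[, j] <- ifelse(is.na(x), NA_real_, code)
  }
  rd_dataset(vals, d$meta)
}

#' Center and scale every column to mean zero, unit variance
#'
#' Uses the n-1 standard-deviation denominator. Constant columns are a
#' hard error: they carry no conditional-independence information.
#'
#' @param d An [rd_dataset] with no missing values.
#' @return `list(dataset=, centers=, scales=)`; the returned parameters
#'   invert the transform.
#' @export
standardize <- function(d) {
  if (!is.numeric(d$values))
    stop("standardize requires an encoded (numeric) dataset; run encode_ordinal first")
  if (anyNA(d$values)) stop("standardize requires complete data")
  mu <- colMeans(d$values)
  sg <- apply(d$values, 2, stats::sd)
  if (any(sg == 0))
    stop("constant column(s): ",
         paste(var_names(d)[sg == 0], collapse = ", "))
  vals <- sweep(sweep(d$values, 2, mu, "-"), 2, sg, "/")
  list(dataset = rd_dataset(vals, d$meta), centers = mu, scales = sg)
}

#' Run the full preprocessing pipeline in its fixed order
#'
#' sparse-variable drop, then incomplete-sample drop (with imputation),
#' then outlier removal, then ordinal encoding, then standardization.
#' The combined report's counts telescope.
#'
#' @param d An [rd_dataset].
#' @param max_missing_rate,required_blocks,outlier_k Stage parameters.
#' @return `list(dataset=, report=, centers=, scales=)`.
#' @export
preprocess_pipeline <- function(d, max_missing_rate = 0.9,
                                required_blocks = list(), outlier_k = 4) {
  s1 <- drop_sparse_variables(d, max_missing_rate)
  s2 <- drop_incomplete_samples(s1$dataset, required_blocks)
  s3 <- remove_outliers(s2$dataset, outlier_k)
  enc <- encode_ordinal(s3$dataset)
  s4 <- standardize(enc)
  rep <- filter_report(
    d$n,
    n_removed_outlier = s3$report$n_removed_outlier,
    n_removed_missing_block = s2$report$n_removed_missing_block,
    dropped_variables = s1$report$dropped_variables)
  list(dataset = s4$dataset, report = rep,
       centers = s4$centers, scales = s4$scales)
}
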