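#' Change-in-expression (CE) values against reference medians
#'
#' For single-channel data, the CE-value of case sample i is its expression
#' minus the per-feature median over the reference samples (medians rather
#' than means, for robustness to outliers): `y_i - mu` for mRNAs, `x_i - nu`
#' for miRNAs. For two-channel data every array is already a case-vs-reference
#' contrast, so the input values ARE the CE-values and are passed through;
#' supplying a design with a named reference group in two-channel mode is
#' contradictory and raises an error.
#'
#' @param expr Numeric matrix (features x samples), log-scale.
#' @param design A [group_design()] (single-channel mode) or NULL (two-channel).
#' @param condition Case condition label (single-channel mode); its samples
#'   become the CE columns.
#' @param channel_mode `"single"` or `"two"`.
#' @return An object of class `ce_profile`: list with `values` (features x
#'   N_biol CE matrix), `ref_medians`, `n_ref`, `n_biol`, `condition`.
#' @export
compute_ce <- function(expr, design = NULL, condition = NULL,
                       channel_mode = c("single", "two")) {
  channel_mode <- match.arg(channel_mode)
  stopifnot(is.matrix(expr))
  if (channel_mode == "two") {
    if (!is.null(design)) {
      stop("two-channel mode: arrays are already case-vs-reference contrasts; ",
           "a design with a reference group is contradictory")
    }
    if (ncol(expr) < 2L) stop("need at least 2 case samples")
    return(structure(list(values = expr,
                          ref_medians = stats::setNames(rep(0, nrow(expr)),
                                                        rownames(expr)),
                          n_ref = 0L, n_biol = ncol(expr),
                          condition = condition %||% "case"),
                     class = "ce_profile"))
  }
  stopifnot(inherits(design, "group_design"), !is.null(condition))
  cond_of <- design$sample_to_condition[colnames(expr)]
  ref_cols <- which(cond_of == design$reference)
  case_cols <- which(cond_of == condition)
  if (length(ref_cols) < 1L) stop("no reference samples in expression matrix")
  if (length(case_cols) < 2L) {
    stop("condition '", condition, "' has fewer than 2 samples")
  }
  med <- apply(expr[, ref_cols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
  ce <- expr[, case_cols, drop = FALSE] - med
  structure(list(values = ce, ref_medians = med,
                 n_ref = length(ref_cols), n_biol = length(case_cols),
                 condition = condition),
            class = "ce_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Through-origin regression slope of mRNA change on miRNA change
#'
#' The matched-data model posits that for a genuine pair the change in mRNA
#' expression is proportional to the change in miRNA expression, both measured
#' relative to the reference medians: `y_i - mu = lambda * (x_i - nu) + error`.
#' lambda is estimated by least squares through the origin,
#' `sum(x y) / sum(x^2)`; a negative lambda is consistent with miRNA-mediated
#' repression.
#'
#' @param mirna_ce,mrna_ce Equal-length CE vectors (length N_biol >= 2).
#' @return The slope estimate (log-units mRNA change per unit miRNA change).
#' @export
estimate_lambda <- function(mirna_ce, mrna_ce) {
  stopifnot(length(mirna_ce) == length(mrna_ce), length(mirna_ce) >= 2L)
  sxx <- sum(mirna_ce^2)
  if (sxx == 0) stop("miRNA CE-values are all zero; slope undefined")
  sum(mirna_ce * mrna_ce) / sxx
}

# jumble-then-resample pseudo-mRNA CE matrix: pool all Z x N values (Q1),
# redraw each entry of a Z x N matrix uniformly from the pool (Q2), then
# sample n_rep rows with replacement (Q3)
pseudo_mrna_rows <- function(values, n_rep) {
  z <- nrow(values)
  n <- ncol(values)
  pool <- as.vector(values)
  q2 <- matrix(pool[sample.int(length(pool), z * n, replace = TRUE)], z, n)
  q2[sample.int(z, n_rep, replace = TRUE), , drop = FALSE]
}

#' Null distribution of lambda from pseudo-mRNA profiles
#'
#' Builds the permutation null for a given miRNA: the Z x N_biol mRNA CE
#' matrix is pooled, jumbled into a same-shape matrix of i.i.d. draws from the
#' pool, `n_rep` pseudo-mRNA rows are sampled with replacement, and the
#' through-origin slope against the miRNA CE vector is computed for each.
#'
#' @param mirna_ce Length-N_biol CE vector for the miRNA.
#' @param mrna_ce_matrix Z x N_biol CE matrix (the pool).
#' @param cfg A [perm_config()].
#' @return Numeric vector of `n_rep` null slopes.
#' @export
md_null_lambdas <- function(mirna_ce, mrna_ce_matrix, cfg = perm_config()) {
  stopifnot(is.matrix(mrna_ce_matrix),
            ncol(mrna_ce_matrix) == length(mirna_ce))
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  sxx <- sum(mirna_ce^2)
  if (sxx == 0) stop("miRNA CE-values are all zero; slope undefined")
  q3 <- pseudo_mrna_rows(mrna_ce_matrix, cfg$n_rep)
  as.vector(q3 %*% mirna_ce) / sxx
}

#' Left-tail permutation p-value for an observed slope
#'
#' A genuine target shows a more negative slope than pseudo-mRNAs, so the
#' p-value is Pr(lambda <= lambda_obs) under the null, estimated with the
#' add-one correction `(1 + #\{null <= obs\}) / (1 + n_rep)` so that p is
#' never exactly zero.
#'
#' @param lambda_obs Observed slope.
#' @param null_lambdas Vector of null slopes.
#' @return A p-value in `(0, 1]`.
#' @export
md_pvalue <- function(lambda_obs, null_lambdas) {
  stopifnot(length(null_lambdas) >= 1L)
  (1 + sum(null_lambdas <= lambda_obs)) / (1 + length(null_lambdas))
}

#' Matched-data association test for one miRNA-mRNA pair
#'
#' Composes [estimate_lambda()], [md_null_lambdas()] and [md_pvalue()]. The
#' pair is significant only if the observed slope is negative AND the
#' BH-adjusted p-value (assigned by the pipeline) is below alpha; this
#' function fills the raw statistic and p-value.
#'
#' @param pair List/row with `mirna_id`, `mrna_id`.
#' @param mirna_ce,mrna_ce [compute_ce()] profiles with identical sample
#'   columns.
#' @param cfg A [perm_config()].
#' @param null_lambdas Optional precomputed null slopes for this miRNA.
#' @return One-row data.frame (`measure = "MD"`, `statistic` = lambda_obs).
#' @export
md_test_pair <- function(pair, mirna_ce, mrna_ce, cfg = perm_config(),
                         null_lambdas = NULL) {
  a <- as.character(pair$mirna_id)
  b <- as.character(pair$mrna_id)
  if (!a %in% rownames(mirna_ce$values)) stop("unknown miRNA id: ", a)
  if (!b %in% rownames(mrna_ce$values)) stop("unknown mRNA id: ", b)
  x <- mirna_ce$values[a, ]
  y <- mrna_ce$values[b, ]
  lam <- estimate_lambda(x, y)
  if (is.null(null_lambdas)) {
    null_lambdas <- md_null_lambdas(x, mrna_ce$values, cfg)
  }
  p <- md_pvalue(lam, null_lambdas)
  data.frame(mirna_id = a, mrna_id = b, measure = "MD",
             statistic = lam, p = p, adj_p = NA_real_, significant = NA,
             direction_conditions = "", testable = TRUE,
             stringsAsFactors = FALSE)
}

#' Pearson-correlation permutation comparator for one pair
#'
#' The conventional alternative to the matched-data slope test: Pearson
#' correlation of the two CE vectors, with significance from the same
#' pseudo-mRNA null construction (left tail: a more negative correlation is a
#' stronger association). Unlike the slope test it ignores the average
#' CE-values, so it can call a pair significant even when miRNA and mRNA move
#' in the same direction on average.
#'
#' @param pair List/row with `mirna_id`, `mrna_id`.
#' @param mirna_ce,mrna_ce [compute_ce()] profiles.
#' @param cfg A [perm_config()].
#' @param null_rows Optional precomputed pseudo-mRNA CE matrix for this miRNA.
#' @return One-row data.frame (`measure = "CORR"`, `statistic` = r); a
#'   zero-variance vector yields `testable = FALSE` with p = NA.
#' @export
correlation_comparator <- function(pair, mirna_ce, mrna_ce,
                                   cfg = perm_config(), null_rows = NULL) {
  a <- as.character(pair$mirna_id)
  b <- as.character(pair$mrna_id)
  if (!a %in% rownames(mirna_ce$values)) stop("unknown miRNA id: ", a)
  if (!b %in% rownames(mrna_ce$values)) stop("unknown mRNA id: ", b)
  x <- mirna_ce$values[a, ]
  y <- mrna_ce$values[b, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(mirna_id = a, mrna_id = b, measure = "CORR",
                      statistic = NA_real_, p = NA_real_, adj_p = NA_real_,
                      significant = NA, direction_conditions = "",
                      testable = FALSE, stringsAsFactors = FALSE))
  }
  r <- stats::cor(x, y)
  if (is.null(null_rows)) {
    if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
    null_rows <- pseudo_mrna_rows(mrna_ce$values, cfg$n_rep)
  }
  null_r <- suppressWarnings(as.vector(stats::cor(x, t(null_rows))))
  ok <- is.finite(null_r)
  p <- (1 + sum(null_r[ok] <= r)) / (1 + sum(ok))
  data.frame(mirna_id = a, mrna_id = b, measure = "CORR",
             statistic = r, p = p, adj_p = NA_real_, significant = NA,
             direction_conditions = "", testable = TRUE,
             stringsAsFactors = FALSE)
}

#' Matched-data association pipeline over a pair list
#'
#' Applies the average-CE direction filter (only pairs whose mean miRNA and
#' mean mRNA CE-values have opposite signs are tested; the rest get status
#' "filtered"), computes one pseudo-mRNA null per miRNA, tests every retained
#' pair, adjusts p-values by BH across the tested family, and calls a pair
#' significant when its slope is negative and `adj_p < alpha`.
#'
#' The per-miRNA nulls are drawn from substreams derived from `cfg$seed`, so
#' [corr_test_all()] run with the same config sees identical pseudo-mRNA
#' pools.
#'
#' @inheritParams md_test_pair
#' @param pairs data.frame with columns `mirna_id`, `mrna_id`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return data.frame of pair results with a `status` column.
#' @export
md_test_all <- function(pairs, mirna_ce, mrna_ce, cfg = perm_config(),
                        alpha = 0.05) {
  keep <- md_direction_filter(pairs, mirna_ce, mrna_ce)
  key <- function(df) paste(df$mirna_id, df$mrna_id, sep = "\r")
  tested <- pairs[key(pairs) %in% key(keep), , drop = FALSE]
  filtered <- pairs[!key(pairs) %in% key(keep), , drop = FALSE]
  out_tested <- NULL
  if (nrow(tested) > 0L) {
    mirnas <- rownames(mirna_ce$values)
    seeds <- derive_seeds(cfg$seed, length(mirnas))
    null_cache <- list()
    res <- vector("list", nrow(tested))
    for (i in seq_len(nrow(tested))) {
      a <- tested$mirna_id[i]
      if (is.null(null_cache[[a]])) {
        sub_cfg <- perm_config(cfg$n_rep, seeds[[match(a, mirnas)]])
        null_cache[[a]] <- md_null_lambdas(mirna_ce$values[a, ],
                                           mrna_ce$values, sub_cfg)
      }
      res[[i]] <- md_test_pair(tested[i, ], mirna_ce, mrna_ce, cfg,
                               null_lambdas = null_cache[[a]])
    }
    out_tested <- do.call(rbind, res)
    out_tested$adj_p <- bh_adjust(out_tested$p)
    out_tested$significant <- out_tested$statistic < 0 &
      out_tested$adj_p < alpha
    out_tested$status <- "tested"
  }
  out_filt <- NULL
  if (nrow(filtered) > 0L) {
    out_filt <- data.frame(mirna_id = filtered$mirna_id,
                           mrna_id = filtered$mrna_id, measure = "MD",
                           statistic = NA_real_, p = NA_real_,
                           adj_p = NA_real_, significant = FALSE,
                           direction_conditions = "", testable = FALSE,
                           status = "filtered", stringsAsFactors = FALSE)
  }
  out <- rbind(out_tested, out_filt)
  rownames(out) <- NULL
  out
}

#' Correlation-comparator pipeline over a pair list
#'
#' Runs [correlation_comparator()] for every pair (no direction filter: the
#' correlation measure, as conventionally applied, does not condition on the
#' direction of average change), BH-adjusts across testable pairs, and calls
#' significance at `adj_p < alpha`. With the same `cfg` as [md_test_all()],
#' each miRNA's pseudo-mRNA pool is identical across the two measures.
#'
#' @inheritParams md_test_all
#' @export
corr_test_all <- function(pairs, mirna_ce, mrna_ce, cfg = perm_config(),
                          alpha = 0.05) {
  mirnas <- rownames(mirna_ce$values)
  seeds <- derive_seeds(cfg$seed, length(mirnas))
  rows_cache <- list()
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$mirna_id[i]
    if (is.null(rows_cache[[a]])) {
      s <- seeds[[match(a, mirnas)]]
      if (!is.null(s)) withr::local_seed(s)
      rows_cache[[a]] <- pseudo_mrna_rows(mrna_ce$values, cfg$n_rep)
    }
    res[[i]] <- correlation_comparator(pairs[i, ], mirna_ce, mrna_ce, cfg,
                                       null_rows = rows_cache[[a]])
  }
  out <- do.call(rbind, res)
  testable <- out$testable
  out$adj_p[testable] <- bh_adjust(out$p[testable])
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  out$status <- ifelse(testable, "tested", "not_testable")
  rownames(out) <- NULL
  out
}
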