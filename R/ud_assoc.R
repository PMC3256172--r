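#' Resampling configuration
#'
#' Governs all permutation/resampling nulls in the package.
#'
#' @param n_rep Number of pseudo-mRNA replicates (default 10000, the value
#'   used throughout the original analyses).
#' @param seed Optional integer seed. When non-NULL, a function consuming this
#'   config seeds its own RNG scope (the caller's RNG state is untouched);
#'   when NULL, the current RNG stream is used.
#' @export
perm_config <- function(n_rep = 10000, seed = NULL) {
  stopifnot(is.numeric(n_rep), length(n_rep) == 1L, n_rep >= 1)
  structure(list(n_rep = as.integer(n_rep), seed = seed), class = "perm_config")
}

cell_levels <- c("-1", "0", "1")

#' Build the 3x3 contingency table for one miRNA-mRNA pair
#'
#' Rows index the miRNA discretized FC-value (-1, 0, +1), columns the mRNA
#' value. Cell (r, c) counts the biological conditions where the miRNA takes
#' value r and the mRNA value c; e.g. the (-1, -1) cell is the number of
#' conditions where both are underexpressed relative to the reference. The
#' nine counts sum to C, the number of non-reference conditions.
#'
#' @param mirna_vec,mrna_vec Equal-length vectors over \{-1, 0, +1\}.
#' @return A 3x3 integer matrix with dimnames `c("-1","0","1")`.
#' @export
build_contingency <- function(mirna_vec, mrna_vec) {
  if (length(mirna_vec) != length(mrna_vec)) {
    stop("miRNA and mRNA discretized vectors differ in length (",
         length(mirna_vec), " vs ", length(mrna_vec), ")")
  }
  if (!all(mirna_vec %in% c(-1, 0, 1)) || !all(mrna_vec %in% c(-1, 0, 1))) {
    stop("discretized values must be in {-1, 0, +1}")
  }
  tab <- table(factor(mirna_vec, levels = c(-1, 0, 1)),
               factor(mrna_vec, levels = c(-1, 0, 1)))
  m <- matrix(as.integer(tab), 3L, 3L, dimnames = list(cell_levels, cell_levels))
  m
}

#' Null cell probabilities from pooled resampling of pseudo-mRNAs
#'
#' Under the null of no association, the nine contingency-table cells for a
#' given miRNA follow a multinomial whose cell probabilities are estimated by
#' resampling: all Z x C discretized mRNA values are pooled (W1); a jumbled
#' matrix W2 of the same shape is formed by drawing each entry uniformly at
#' random (with replacement) from the pool; `n_rep` rows are then drawn with
#' replacement from W2 (W3, the pseudo-mRNAs). Each pseudo-mRNA is tabulated
#' against the miRNA's discretized vector and the pooled counts, divided by
#' `n_rep * C`, give the cell probabilities (they sum to 1).
#'
#' @param mirna_vec Length-C discretized vector for the miRNA.
#' @param mrna_profile Z x C discretized mRNA matrix (the pool).
#' @param cfg A [perm_config()].
#' @return A 3x3 probability matrix summing to 1.
#' @export
null_cell_probs <- function(mirna_vec, mrna_profile, cfg = perm_config()) {
  stopifnot(is.matrix(mrna_profile), ncol(mrna_profile) == length(mirna_vec))
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  z <- nrow(mrna_profile)
  cc <- ncol(mrna_profile)
  pool <- as.vector(mrna_profile)
  w2 <- matrix(pool[sample.int(length(pool), z * cc, replace = TRUE)], z, cc)
  w3 <- w2[sample.int(z, cfg$n_rep, replace = TRUE), , drop = FALSE]
  # column k of w3 is always paired with mirna_vec[k]: tally all n_rep tables
  # at once
  tab <- table(factor(rep(mirna_vec, each = cfg$n_rep), levels = c(-1, 0, 1)),
               factor(as.vector(w3), levels = c(-1, 0, 1)))
  probs <- matrix(as.numeric(tab), 3L, 3L,
                  dimnames = list(cell_levels, cell_levels))
  probs / (cfg$n_rep * cc)
}

# cache of 9-part composition enumerations, keyed by total count C
.comp_cache <- new.env(parent = emptyenv())

compositions9 <- function(total) {
  key <- as.character(total)
  if (!is.null(.comp_cache[[key]])) return(.comp_cache[[key]])
  gen <- function(t, parts) {
    if (parts == 1L) return(matrix(t, ncol = 1L))
    do.call(rbind, lapply(0:t, function(k) cbind(k, gen(t - k, parts - 1L))))
  }
  x <- gen(as.integer(total), 9L)
  dimnames(x) <- NULL
  .comp_cache[[key]] <- x
  x
}

#' Exact multinomial goodness-of-fit p-value for a contingency table
#'
#' Computes the exact multinomial p-value: the probability, under the null
#' cell probabilities, of observing any 9-cell outcome with total C whose
#' multinomial probability is less than or equal to that of the observed
#' table (the standard exact goodness-of-fit extremeness convention; ties are
#' included). Outcomes placing counts in a zero-probability cell contribute
#' nothing; an observed count in such a cell yields p = 0 with a warning.
#'
#' Full enumeration over all `choose(C + 8, 8)` compositions is used when that
#' number does not exceed `enumeration_limit`; beyond it, a Monte-Carlo
#' estimate with `n_mc` multinomial draws (add-one corrected) is returned,
#' with its standard error attached as attribute `"mc_se"`.
#'
#' @param table A 3x3 count matrix from [build_contingency()].
#' @param probs A 3x3 probability matrix from [null_cell_probs()].
#' @param enumeration_limit Maximum composition count for exact enumeration.
#' @param n_mc Monte-Carlo draws past the limit.
#' @return A p-value in `[0, 1]`.
#' @export
exact_multinomial_pvalue <- function(table, probs, enumeration_limit = 5e6,
                                     n_mc = 10000) {
  obs <- as.vector(table)
  p <- as.vector(probs)
  stopifnot(length(obs) == 9L, length(p) == 9L, all(obs >= 0), all(p >= -1e-12))
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > 1e-8) stop("null cell probabilities must sum to 1")
  cc <- sum(obs)
  if (cc == 0L) return(1)
  zero <- p == 0
  if (any(obs[zero] > 0)) {
    warning("observed count in a zero-probability cell; p = 0")
    return(0)
  }
  lp_pos <- log(p[!zero])
  log_obs <- lgamma(cc + 1) - sum(lgamma(obs[!zero] + 1)) +
    sum(obs[!zero] * lp_pos)
  tol <- 1e-9
  if (choose(cc + 8, 8) <= enumeration_limit) {
    comp <- compositions9(cc)
    if (any(zero)) {
      comp <- comp[rowSums(comp[, zero, drop = FALSE]) == 0L, , drop = FALSE]
    }
    xk <- comp[, !zero, drop = FALSE]
    logp <- lgamma(cc + 1) - rowSums(lgamma(xk + 1)) +
      as.vector(xk %*% lp_pos)
    min(1, sum(exp(logp[logp <= log_obs + tol])))
  } else {
    draws <- stats::rmultinom(n_mc, cc, p)
    logd <- lgamma(cc + 1) - colSums(lgamma(draws + 1)) +
      as.vector(t(draws[!zero, , drop = FALSE]) %*% lp_pos)
    hits <- sum(logd <= log_obs + tol)
    pv <- (1 + hits) / (n_mc + 1)
    attr(pv, "mc_se") <- sqrt(pv * (1 - pv) / n_mc)
    pv
  }
}

#' Pearson chi-squared goodness-of-fit p-value for a contingency table
#'
#' Large-C alternative to the exact test: the Pearson statistic
#' `sum((obs - C p)^2 / (C p))` over cells with positive null probability,
#' referred to a chi-squared distribution with (number of positive cells - 1)
#' degrees of freedom. Appropriate when the number of conditions C is large
#' (> 15).
#'
#' @inheritParams exact_multinomial_pvalue
#' @return A p-value; the statistic is attached as attribute `"statistic"`.
#' @export
chisq_pvalue <- function(table, probs) {
  obs <- as.vector(table)
  p <- pmax(as.vector(probs), 0)
  cc <- sum(obs)
  stopifnot(cc > 0)
  pos <- p > 0
  if (any(obs[!pos] > 0)) {
    warning("observed count in a zero-probability cell; p = 0")
    return(structure(0, statistic = Inf))
  }
  expected <- cc * p[pos]
  stat <- sum((obs[pos] - expected)^2 / expected)
  df <- sum(pos) - 1L
  pv <- if (df < 1L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(pv, statistic = stat)
}

#' Unmatched-data association test for one miRNA-mRNA pair
#'
#' Composes [build_contingency()], [null_cell_probs()] and
#' [exact_multinomial_pvalue()] (or [chisq_pvalue()] when C > 15) for a single
#' pair, and records the conditions where the pair's discretized values are
#' nonzero and opposite-signed. A pair whose two vectors are all zero carries
#' no information and is flagged not testable with p = 1.
#'
#' @param pair A list/row with `mirna_id` and `mrna_id`.
#' @param mirna_profile,mrna_profile Discretized matrices (features x
#'   conditions) with matching condition columns.
#' @param cfg A [perm_config()].
#' @param null_probs Optional precomputed 3x3 null-probability matrix for this
#'   miRNA (the null depends only on the miRNA and the mRNA pool, so pipelines
#'   compute it once per miRNA).
#' @return One-row data.frame: `mirna_id`, `mrna_id`, `measure`, `statistic`
#'   (Pearson goodness-of-fit statistic), `p`, `adj_p`, `significant`,
#'   `direction_conditions`, `testable`.
#' @export
ud_test_pair <- function(pair, mirna_profile, mrna_profile,
                         cfg = perm_config(), null_probs = NULL) {
  a <- as.character(pair$mirna_id)
  b <- as.character(pair$mrna_id)
  if (!a %in% rownames(mirna_profile)) stop("unknown miRNA id: ", a)
  if (!b %in% rownames(mrna_profile)) stop("unknown mRNA id: ", b)
  x <- mirna_profile[a, ]
  y <- mrna_profile[b, ]
  conds <- colnames(mirna_profile)
  opp <- which(x * y == -1L)
  dir_str <- paste(conds[opp], collapse = ",")
  if (all(x == 0L) && all(y == 0L)) {
    return(data.frame(mirna_id = a, mrna_id = b, measure = "UD",
                      statistic = NA_real_, p = 1, adj_p = NA_real_,
                      significant = NA, direction_conditions = dir_str,
                      testable = FALSE, stringsAsFactors = FALSE))
  }
  tab <- build_contingency(x, y)
  if (is.null(null_probs)) {
    null_probs <- null_cell_probs(x, mrna_profile, cfg)
  }
  cc <- length(x)
  if (cc > 15L) {
    pv <- chisq_pvalue(tab, null_probs)
    stat <- attr(pv, "statistic")
  } else {
    pv <- exact_multinomial_pvalue(tab, null_probs)
    stat <- attr(chisq_pvalue(tab, null_probs), "statistic")
  }
  data.frame(mirna_id = a, mrna_id = b, measure = "UD",
             statistic = as.numeric(stat), p = as.numeric(pv),
             adj_p = NA_real_, significant = NA,
             direction_conditions = dir_str, testable = TRUE,
             stringsAsFactors = FALSE)
}

#' Unmatched-data association pipeline over a pair list
#'
#' Applies the opposite-direction filter (only pairs whose miRNA and mRNA
#' discretized values are nonzero and opposite-signed in at least one
#' condition are tested; the rest are reported with status "filtered"),
#' computes one pooled-resampling null per miRNA, tests every retained pair,
#' adjusts p-values by Benjamini-Hochberg across the tested family, and calls
#' significance at `adj_p < alpha`.
#'
#' @param pairs data.frame with columns `mirna_id`, `mrna_id`.
#' @param mirna_profile,mrna_profile Discretized matrices sharing condition
#'   columns.
#' @param cfg A [perm_config()]; its seed governs all resampling in the run.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return data.frame of pair results with a `status` column
#'   ("tested"/"filtered").
#' @export
ud_test_all <- function(pairs, mirna_profile, mrna_profile,
                        cfg = perm_config(), alpha = 0.05) {
  stopifnot(identical(colnames(mirna_profile), colnames(mrna_profile)))
  keep <- ud_direction_filter(pairs, mirna_profile, mrna_profile)
  key <- function(df) paste(df$mirna_id, df$mrna_id, sep = "\r")
  tested <- pairs[key(pairs) %in% key(keep), , drop = FALSE]
  filtered <- pairs[!key(pairs) %in% key(keep), , drop = FALSE]
  res <- list()
  if (nrow(tested) > 0L) {
    mirnas <- unique(tested$mirna_id)
    seeds <- derive_seeds(cfg$seed, length(mirnas))
    res <- vector("list", nrow(tested))
    probs_cache <- list()
    for (i in seq_len(nrow(tested))) {
      a <- tested$mirna_id[i]
      if (is.null(probs_cache[[a]])) {
        sub_cfg <- perm_config(cfg$n_rep, seeds[[match(a, mirnas)]])
        probs_cache[[a]] <- null_cell_probs(mirna_profile[a, ], mrna_profile,
                                            sub_cfg)
      }
      res[[i]] <- ud_test_pair(tested[i, ], mirna_profile, mrna_profile,
                               cfg, null_probs = probs_cache[[a]])
    }
  }
  out_tested <- if (length(res)) do.call(rbind, res) else NULL
  if (!is.null(out_tested)) {
    out_tested$adj_p <- bh_adjust(out_tested$p)
    out_tested$significant <- out_tested$adj_p < alpha
    out_tested$status <- "tested"
  }
  out_filt <- NULL
  if (nrow(filtered) > 0L) {
    out_filt <- data.frame(mirna_id = filtered$mirna_id,
                           mrna_id = filtered$mrna_id, measure = "UD",
                           statistic = NA_real_, p = NA_real_,
                           adj_p = NA_real_, significant = FALSE,
                           direction_conditions = "", testable = FALSE,
                           status = "filtered", stringsAsFactors = FALSE)
  }
  out <- rbind(out_tested, out_filt)
  rownames(out) <- NULL
  out
}

# deterministic per-unit substreams from one run seed, so each miRNA's null
# does not depend on how many other miRNAs were processed before it
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list(withr::with_seed(seed, sample.int(.Machine$integer.max, n)))
}
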