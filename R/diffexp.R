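#' Per-condition differential expression versus the reference group
#'
#' For every feature and every non-reference condition, tests the null
#' hypothesis that the average (log-scale) expression in the condition equals
#' that in the reference, using a Welch two-sample t-test. The FC-value is the
#' difference in group means, `mean(condition) - mean(reference)`, in log
#' units, so a negative FC-value means higher expression in the reference.
#' P-values are Benjamini-Hochberg adjusted across features within each
#' condition, and a feature is called differentially expressed (DE) when
#' `|FC| > fc_threshold` and the adjusted p-value is below `alpha`.
#'
#' Missing values are dropped per feature and group; a feature with fewer than
#' two observed values in either group gets `p_raw = 1` and is never DE.
#'
#' @param expr Numeric matrix (features x samples), log-scale.
#' @param design A [group_design()] covering all columns of `expr`.
#' @param fc_threshold Minimum absolute difference in group means (log units)
#'   for a DE call; default 1.5.
#' @param alpha Adjusted-p cutoff for a DE call; default 0.05.
#' @return A data.frame with one row per (feature, condition):
#'   `feature_id`, `condition`, `fc_value`, `p_raw`, `p_adj`, `is_de`.
#' @export
de_test <- function(expr, design, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(inherits(design, "group_design"), is.matrix(expr))
  samp <- colnames(expr)
  unmapped <- setdiff(samp, names(design$sample_to_condition))
  if (length(unmapped) > 0L) {
    stop("sample(s) missing from design: ", paste(unmapped, collapse = ", "))
  }
  cond_of <- design$sample_to_condition[samp]
  ref_cols <- which(cond_of == design$reference)
  if (length(ref_cols) < 2L) {
    stop("reference condition '", design$reference, "' has fewer than 2 samples")
  }
  res <- vector("list", length(design$conditions))
  for (j in seq_along(design$conditions)) {
    cond <- design$conditions[j]
    case_cols <- which(cond_of == cond)
    if (length(case_cols) < 2L) {
      stop("condition '", cond, "' has fewer than 2 samples")
    }
    fc <- rep(NA_real_, nrow(expr))
    p <- rep(1, nrow(expr))
    for (i in seq_len(nrow(expr))) {
      x <- expr[i, case_cols]
      y <- expr[i, ref_cols]
      x <- x[is.finite(x)]
      y <- y[is.finite(y)]
      if (length(x) >= 1L && length(y) >= 1L) fc[i] <- mean(x) - mean(y)
      if (length(x) >= 2L && length(y) >= 2L &&
          (stats::var(x) > 0 || stats::var(y) > 0)) {
        p[i] <- stats::t.test(x, y)$p.value
      }
    }
    padj <- bh_adjust(p)
    res[[j]] <- data.frame(
      feature_id = rownames(expr), condition = cond, fc_value = fc,
      p_raw = p, p_adj = padj,
      is_de = !is.na(fc) & abs(fc) > fc_threshold & padj < alpha,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Discretize differential-expression calls to \{-1, 0, +1\}
#'
#' A feature gets +1 in a condition when it is DE and overexpressed there
#' relative to the reference (FC-value > 0), -1 when DE and underexpressed
#' (FC-value < 0; equivalently overexpressed in the reference), and 0 when not
#' DE. The resulting per-feature vector over the C conditions is the
#' discretized FC-value profile consumed by the unmatched-data measure.
#'
#' @param de A data.frame from [de_test()].
#' @return Integer matrix (features x conditions) over \{-1, 0, +1\}, ordered
#'   as in `de`.
#' @export
discretize <- function(de) {
  stopifnot(all(c("feature_id", "condition", "fc_value", "is_de") %in%
                colnames(de)))
  bad <- de$is_de & (!is.finite(de$fc_value) | de$fc_value == 0)
  if (any(bad)) {
    stop("contradictory DE call: is_de with zero/undefined fc_value for ",
         de$feature_id[bad][1L], " in ", de$condition[bad][1L])
  }
  feats <- unique(de$feature_id)
  conds <- unique(de$condition)
  m <- matrix(0L, nrow = length(feats), ncol = length(conds),
              dimnames = list(feats, conds))
  val <- ifelse(de$is_de, ifelse(de$fc_value > 0, 1L, -1L), 0L)
  m[cbind(match(de$feature_id, feats), match(de$condition, conds))] <- val
  m
}
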