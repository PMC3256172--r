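#' Restrict predicted pairs to differentially expressed members
#'
#' Keeps the putative target pairs whose miRNA and mRNA are both in the
#' supplied DE sets (features DE in at least one condition), preserving input
#' order and dropping duplicates.
#'
#' @param predictions data.frame with `mirna_id`, `mrna_id`.
#' @param de_mirnas,de_mrnas Character vectors of DE feature ids.
#' @export
candidate_pairs <- function(predictions, de_mirnas, de_mrnas) {
  keep <- predictions$mirna_id %in% de_mirnas &
    predictions$mrna_id %in% de_mrnas
  out <- predictions[keep, , drop = FALSE]
  out <- out[!duplicated(paste(out$mirna_id, out$mrna_id, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Opposite-direction filter on discretized profiles (unmatched data)
#'
#' miRNAs repress their targets, so a genuine pair must change in opposite
#' directions: keep pairs with at least one condition where the product of
#' the discretized miRNA and mRNA values is -1.
#'
#' @param pairs data.frame with `mirna_id`, `mrna_id`.
#' @param mirna_profile,mrna_profile Discretized matrices.
#' @export
ud_direction_filter <- function(pairs, mirna_profile, mrna_profile) {
  missing_a <- setdiff(pairs$mirna_id, rownames(mirna_profile))
  missing_b <- setdiff(pairs$mrna_id, rownames(mrna_profile))
  if (length(missing_a) > 0L) stop("miRNA id(s) not in profile: ",
                                   paste(missing_a, collapse = ", "))
  if (length(missing_b) > 0L) stop("mRNA id(s) not in profile: ",
                                   paste(missing_b, collapse = ", "))
  if (nrow(pairs) == 0L) return(pairs)
  prod <- mirna_profile[pairs$mirna_id, , drop = FALSE] *
    mrna_profile[pairs$mrna_id, , drop = FALSE]
  out <- pairs[rowSums(prod == -1L) > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Opposite-direction filter on average CE-values (matched data)
#'
#' Keeps pairs whose mean miRNA CE-value and mean mRNA CE-value have strictly
#' opposite signs; pairs involving a zero-mean feature are dropped with a
#' warning (no direction can be assigned).
#'
#' @param pairs data.frame with `mirna_id`, `mrna_id`.
#' @param mirna_ce,mrna_ce [compute_ce()] profiles.
#' @export
md_direction_filter <- function(pairs, mirna_ce, mrna_ce) {
  missing_a <- setdiff(pairs$mirna_id, rownames(mirna_ce$values))
  missing_b <- setdiff(pairs$mrna_id, rownames(mrna_ce$values))
  if (length(missing_a) > 0L) stop("miRNA id(s) not in CE profile: ",
                                   paste(missing_a, collapse = ", "))
  if (length(missing_b) > 0L) stop("mRNA id(s) not in CE profile: ",
                                   paste(missing_b, collapse = ", "))
  if (nrow(pairs) == 0L) return(pairs)
  ma <- rowMeans(mirna_ce$values)[pairs$mirna_id]
  mb <- rowMeans(mrna_ce$values)[pairs$mrna_id]
  zero <- sign(ma) == 0 | sign(mb) == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) dropped: zero average CE-value, ",
            "direction undefined")
  }
  out <- pairs[!zero & sign(ma) * sign(mb) == -1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, applied across all pairs tested within
#' one measure and one run.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Apply the per-measure significance rule to pair results
#'
#' UD and CORR: significant when `adj_p < alpha`. MD additionally requires a
#' negative observed slope (repression direction). Logs summary counts of
#' significant pairs and their unique miRNAs/mRNAs.
#'
#' @param results data.frame of pair results (columns `measure`, `statistic`,
#'   `adj_p`).
#' @param alpha Threshold; the comparison is strict (`adj_p < alpha`).
#' @export
call_significant <- function(results, alpha = 0.05) {
  sig <- !is.na(results$adj_p) & results$adj_p < alpha
  md <- results$measure == "MD"
  sig[md] <- sig[md] & !is.na(results$statistic[md]) & results$statistic[md] < 0
  results$significant <- sig
  s <- results[sig, , drop = FALSE]
  message(sum(sig), " significant pair(s): ",
          length(unique(s$mirna_id)), " unique miRNA(s), ",
          length(unique(s$mrna_id)), " unique mRNA(s)")
  results
}

#' Overlap between two sets of significant pairs
#'
#' Compares the significant calls of two result tables (e.g. the unmatched
#' and matched measures run on the same candidate family) on the
#' (mirna_id, mrna_id) key.
#'
#' @param results_a,results_b data.frames of pair results with `significant`.
#' @return List with `n_shared`, `n_a_only`, `n_b_only`, `n_a`, `n_b`, and
#'   the shared pairs as a data.frame.
#' @export
concordance <- function(results_a, results_b) {
  key <- function(df) {
    s <- df[!is.na(df$significant) & df$significant, , drop = FALSE]
    paste(s$mirna_id, s$mrna_id, sep = "\r")
  }
  ka <- unique(key(results_a))
  kb <- unique(key(results_b))
  shared <- intersect(ka, kb)
  parts <- strsplit(shared, "\r", fixed = TRUE)
  list(n_a = length(ka), n_b = length(kb), n_shared = length(shared),
       n_a_only = length(setdiff(ka, kb)), n_b_only = length(setdiff(kb, ka)),
       shared = data.frame(
         mirna_id = vapply(parts, `[[`, character(1), 1L),
         mrna_id = vapply(parts, `[[`, character(1), 2L),
         stringsAsFactors = FALSE))
}
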