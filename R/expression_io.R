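#' Read an expression matrix from tab-separated text
#'
#' Parses a feature-by-sample table of (already normalized, log-scale)
#' expression values. The first column holds feature identifiers, the header
#' row holds sample identifiers, and missing values are encoded as `NA`.
#' The package never normalizes raw arrays: platform-specific preprocessing
#' (background correction, quantile normalization, probe summarization) is
#' assumed to have happened upstream.
#'
#' @param path Path to a TSV file; first column feature id, header sample ids.
#' @param feature_kind Either `"miRNA"` or `"mRNA"`; stored as an attribute.
#' @return A numeric matrix (features x samples) with `rownames` = feature ids,
#'   `colnames` = sample ids and attribute `feature_kind`.
#' @export
read_expression_table <- function(path, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  n_samp <- length(sample_ids)
  if (n_samp < 1L) stop("expression file has no sample columns: ", path)
  body <- fields[-1L]
  body <- body[vapply(body, function(f) length(f) > 0L && any(nzchar(f)), logical(1))]
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup) > 0L) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  values <- matrix(NA_real_, nrow = length(body), ncol = n_samp,
                   dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_samp + 1L) {
      stop("row ", i + 1L, " (feature '", feature_ids[i], "') has ",
           length(row) - 1L, " values but header names ", n_samp, " samples")
    }
    cells <- row[-1L]
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !(cells %in% c("NA", "", "NaN")))
    if (length(bad) > 0L) {
      stop("non-numeric value '", cells[bad[1L]], "' at row ", i + 1L,
           ", column ", bad[1L] + 1L, " of ", path)
    }
    values[i, ] <- num
  }
  structure(values, feature_kind = feature_kind)
}

#' Write an expression (or discretized) matrix as tab-separated text
#'
#' @param values Numeric matrix with feature `rownames` and sample/condition
#'   `colnames`.
#' @param path Output path.
#' @param id_column Header label for the feature-id column.
#' @export
write_expression_table <- function(values, path, id_column = "feature_id") {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample-to-condition design
#'
#' @param sample_to_condition Named character vector mapping sample id to
#'   condition label.
#' @param reference Label of the reference condition (e.g. healthy donors).
#' @return An object of class `group_design`.
#' @export
group_design <- function(sample_to_condition, reference) {
  stopifnot(length(sample_to_condition) > 0L,
            !is.null(names(sample_to_condition)),
            all(nzchar(names(sample_to_condition))))
  sample_to_condition <- vapply(sample_to_condition, as.character, character(1))
  conditions <- unique(unname(sample_to_condition))
  if (!reference %in% conditions) {
    stop("reference condition '", reference, "' not present in the design")
  }
  if (length(setdiff(conditions, reference)) < 1L) {
    stop("design needs at least one non-reference condition")
  }
  structure(list(sample_to_condition = sample_to_condition,
                 reference = reference,
                 conditions = setdiff(conditions, reference)),
            class = "group_design")
}

#' Read a design table (columns sample_id, condition) from TSV
#'
#' @param path TSV with header `sample_id<TAB>condition`.
#' @param reference Reference condition label.
#' @export
read_design_table <- function(path, reference) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% colnames(df))) {
    stop("design table must have columns 'sample_id' and 'condition': ", path)
  }
  map <- stats::setNames(as.character(df$condition), as.character(df$sample_id))
  group_design(map, reference)
}

#' Read a putative miRNA-mRNA target-pair list
#'
#' Two-column tab- or whitespace-separated text (miRNA id, gene id), in the
#' style of a TargetScanS-type prediction export; an optional header row is
#' skipped if its first field looks like a label ("mirna", "miRNA", ...).
#' Duplicate rows are removed, keeping first-occurrence order.
#'
#' @param path Input path.
#' @return A data.frame with columns `mirna_id`, `mrna_id`.
#' @export
read_target_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty target-pair file: ", path)
    return(data.frame(mirna_id = character(0), mrna_id = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop("target-pair row ", which(nf != 2L)[1L], " has ", nf[nf != 2L][1L],
         " columns; expected 2")
  }
  m <- do.call(rbind, fields)
  header_words <- c("mirna", "mirna_id", "mirnaid", "microrna", "mir_id")
  if (tolower(m[1L, 1L]) %in% header_words) {
    m <- m[-1L, , drop = FALSE]
  }
  pairs <- data.frame(mirna_id = m[, 1L], mrna_id = m[, 2L],
                      stringsAsFactors = FALSE)
  pairs[!duplicated(paste(pairs$mirna_id, pairs$mrna_id, sep = "\r")), ,
        drop = FALSE]
}

#' Merge two discretized profiles into a multi-study "master" profile
#'
#' Features are matched by exact id; the merged profile keeps the intersection
#' of the two feature sets, restricted to features whose discretized vector is
#' nonzero (differentially expressed) in at least one condition of the union.
#' Condition columns are concatenated, so the two studies must use disjoint
#' condition labels.
#'
#' @param disc_a,disc_b Integer matrices over \{-1, 0, +1\} with feature
#'   `rownames` and condition `colnames` (as returned by [discretize()]).
#' @return A discretized matrix with `ncol(disc_a) + ncol(disc_b)` conditions.
#' @export
build_master <- function(disc_a, disc_b) {
  validate_discretized(disc_a)
  validate_discretized(disc_b)
  shared_cond <- intersect(colnames(disc_a), colnames(disc_b))
  if (length(shared_cond) > 0L) {
    stop("condition labels overlap between studies (ambiguous merge): ",
         paste(shared_cond, collapse = ", "))
  }
  feats <- intersect(rownames(disc_a), rownames(disc_b))
  merged <- cbind(disc_a[feats, , drop = FALSE], disc_b[feats, , drop = FALSE])
  keep <- rowSums(merged != 0L) > 0L
  merged[keep, , drop = FALSE]
}

validate_discretized <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (!all(x %in% c(-1L, 0L, 1L))) {
    stop("discretized profile contains values outside {-1, 0, +1}")
  }
  invisible(x)
}

#' Read a discretized profile from TSV
#'
#' Same layout as an expression table; values must be in \{-1, 0, +1\}.
#' @param path Input path.
#' @export
read_discretized_profile <- function(path) {
  m <- read_expression_table(path)
  storage.mode(m) <- "integer"
  attr(m, "feature_kind") <- NULL
  validate_discretized(m)
  m
}

#' Write pair-level results as a TSV table
#'
#' Columns: mirna_id, mrna_id, measure, statistic, p, adj_p, significant,
#' direction_conditions (comma-separated). Rows are sorted by adjusted p-value
#' with ties broken lexicographically by (mirna_id, mrna_id).
#'
#' @param results A data.frame of pair results (see [ud_test_all()] /
#'   [md_test_all()]).
#' @param path Output path.
#' @export
write_pair_results <- function(results, path) {
  cols <- c("mirna_id", "mrna_id", "measure", "statistic", "p", "adj_p",
            "significant", "direction_conditions")
  if (nrow(results) == 0L) {
    out <- data.frame(matrix(ncol = length(cols), nrow = 0L))
    colnames(out) <- cols
  } else {
    missing_cols <- setdiff(cols, colnames(results))
    if (length(missing_cols) > 0L) {
      stop("results lack column(s): ", paste(missing_cols, collapse = ", "))
    }
    ord <- order(results$adj_p, results$mirna_id, results$mrna_id,
                 method = "radix")
    out <- results[ord, cols]
  }
  utils::write.table(format(out, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair-results TSV written by [write_pair_results()]
#' @param path Input path.
#' @export
read_pair_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(direction_conditions = "character"))
  df$significant <- as.logical(df$significant)
  df
}
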