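#' Simulation scenario with known ground truth
#'
#' Defines the shape and signal of a synthetic data set. The defaults mirror
#' the cohort shapes of the multiple-myeloma studies the measures were
#' designed around — 3 reference (healthy-donor) samples versus 14 case
#' samples for the matched design, and C = 9 disease subgroups for the
#' unmatched design — with feature counts scaled down about tenfold
#' (12 miRNAs, 326 mRNAs) so simulated pipelines stay quick.
#'
#' @param n_mirna,n_mrna Feature counts.
#' @param n_ref,n_biol Reference and case sample counts (matched design).
#' @param n_conditions Number of non-reference biological groups C
#'   (unmatched design).
#' @param n_planted Number of planted regulatory pairs (used when
#'   `planted_pairs` is NULL).
#' @param planted_pairs Optional data.frame `mirna_id`, `mrna_id`, and for the
#'   matched generator `lambda_true`.
#' @param lambda_true Default true slope for planted pairs (log-units mRNA
#'   change per unit miRNA change; negative = repression).
#' @param noise_sd Gaussian noise SD on log-scale expression.
#' @param de_shift Case-vs-reference shift (log units) given to each miRNA,
#'   with random sign; drives the miRNA CE-values.
#' @param background_nonzero_rate P(discretized background entry is nonzero),
#'   split evenly between -1 and +1 (unmatched design).
#' @param planted_n_conditions Number of conditions in which a planted pair is
#'   forced opposite-signed (unmatched design).
#' @param seed Integer seed; every generator output is a deterministic
#'   function of (scenario, seed).
#' @export
simulation_scenario <- function(n_mirna = 12, n_mrna = 326, n_ref = 3,
                                n_biol = 14, n_conditions = 9,
                                n_planted = 4, planted_pairs = NULL,
                                lambda_true = -1, noise_sd = 0.2,
                                de_shift = 2, background_nonzero_rate = 0.1,
                                planted_n_conditions = 5, seed = 1L) {
  stopifnot(noise_sd > 0, background_nonzero_rate >= 0,
            background_nonzero_rate <= 1, n_biol >= 2, n_ref >= 1,
            n_conditions >= 1)
  sc <- list(n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
             n_ref = as.integer(n_ref), n_biol = as.integer(n_biol),
             n_conditions = as.integer(n_conditions),
             n_planted = as.integer(n_planted), planted_pairs = planted_pairs,
             lambda_true = lambda_true, noise_sd = noise_sd,
             de_shift = de_shift,
             background_nonzero_rate = background_nonzero_rate,
             planted_n_conditions = as.integer(planted_n_conditions),
             seed = as.integer(seed))
  structure(sc, class = "simulation_scenario")
}

scenario_feature_ids <- function(sc) {
  list(mirna = sprintf("mir%03d", seq_len(sc$n_mirna)),
       mrna = sprintf("gene%04d", seq_len(sc$n_mrna)))
}

default_planted <- function(sc, ids) {
  n <- min(sc$n_planted, sc$n_mrna)
  if (n == 0L) {
    return(data.frame(mirna_id = character(0), mrna_id = character(0),
                      lambda_true = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(mirna_id = ids$mirna[(seq_len(n) - 1L) %% sc$n_mirna + 1L],
             mrna_id = ids$mrna[seq_len(n)],
             lambda_true = sc$lambda_true, stringsAsFactors = FALSE)
}

#' Simulate a matched reference/case cohort with planted regulatory pairs
#'
#' Log-scale expression is generated as a per-feature baseline (uniform on
#' [6, 12]) plus Gaussian noise. Each miRNA's case samples are additionally
#' shifted by `de_shift` with a random sign, creating nonzero average
#' CE-values. For each planted pair the mRNA's case values follow the
#' through-origin change model: mRNA CE = lambda_true * miRNA CE + noise,
#' anchored at the miRNA's emitted reference median, so the generating model
#' is exactly the one the matched-data slope test fits. Non-planted mRNAs are
#' independent noise around their baseline (null pairs).
#'
#' @param scenario A [simulation_scenario()].
#' @return List: `mirna`, `mrna` (expression matrices with shared sample
#'   columns `ref_*`/`case_*`), `design` (a [group_design()]; reference
#'   "reference", case condition "case"), `truth` (planted pairs with
#'   `lambda_true`, and per-miRNA case shifts).
#' @export
simulate_matched <- function(scenario) {
  sc <- scenario
  withr::local_seed(sc$seed)
  ids <- scenario_feature_ids(sc)
  planted <- sc$planted_pairs %||% default_planted(sc, ids)
  bad <- !(planted$mirna_id %in% ids$mirna) | !(planted$mrna_id %in% ids$mrna)
  if (any(bad)) {
    stop("planted pair references missing feature: ",
         planted$mirna_id[bad][1L], ":", planted$mrna_id[bad][1L])
  }
  samples <- c(sprintf("ref_%02d", seq_len(sc$n_ref)),
               sprintf("case_%02d", seq_len(sc$n_biol)))
  is_case <- c(rep(FALSE, sc$n_ref), rep(TRUE, sc$n_biol))
  n_samp <- length(samples)

  base_mi <- stats::runif(sc$n_mirna, 6, 12)
  shift <- sample(c(-1, 1), sc$n_mirna, replace = TRUE) * sc$de_shift
  mirna <- matrix(stats::rnorm(sc$n_mirna * n_samp, sd = sc$noise_sd),
                  sc$n_mirna, n_samp, dimnames = list(ids$mirna, samples))
  mirna <- mirna + base_mi
  mirna[, is_case] <- mirna[, is_case] + shift

  base_m <- stats::runif(sc$n_mrna, 6, 12)
  mrna <- matrix(stats::rnorm(sc$n_mrna * n_samp, sd = sc$noise_sd),
                 sc$n_mrna, n_samp, dimnames = list(ids$mrna, samples))
  mrna <- mrna + base_m
  # planted targets: case mRNA values follow the change model against the
  # miRNA's realized CE-values (anchored at its emitted reference median)
  mi_ref_med <- apply(mirna[, !is_case, drop = FALSE], 1L, stats::median)
  for (k in seq_len(nrow(planted))) {
    a <- planted$mirna_id[k]
    b <- planted$mrna_id[k]
    mi_ce <- mirna[a, is_case] - mi_ref_med[a]
    mrna[b, is_case] <- base_m[match(b, ids$mrna)] +
      planted$lambda_true[k] * mi_ce +
      stats::rnorm(sc$n_biol, sd = sc$noise_sd)
  }
  design <- group_design(
    stats::setNames(ifelse(is_case, "case", "reference"), samples), "reference")
  list(mirna = structure(mirna, feature_kind = "miRNA"),
       mrna = structure(mrna, feature_kind = "mRNA"),
       design = design,
       truth = list(planted = planted,
                    mirna_shift = stats::setNames(shift, ids$mirna)))
}

#' Simulate unmatched multi-condition discretized profiles
#'
#' Background entries of both discretized matrices are drawn i.i.d. over
#' \{-1, 0, +1\} with P(nonzero) = `background_nonzero_rate`, split evenly
#' between the two signs (features DE in a random scatter of conditions).
#' Each planted pair is forced to opposite-signed nonzero values in
#' `planted_n_conditions` randomly chosen conditions, emulating a genuine
#' repressive pair co-dysregulated across disease subgroups.
#'
#' @param scenario A [simulation_scenario()].
#' @return List: `mirna`, `mrna` (discretized matrices, conditions
#'   `cond_1..C`), `truth` (planted pairs with the conditions where they are
#'   opposite-signed).
#' @export
simulate_unmatched <- function(scenario) {
  sc <- scenario
  withr::local_seed(sc$seed)
  ids <- scenario_feature_ids(sc)
  planted <- sc$planted_pairs %||% default_planted(sc, ids)
  bad <- !(planted$mirna_id %in% ids$mirna) | !(planted$mrna_id %in% ids$mrna)
  if (any(bad)) {
    stop("planted pair references missing feature: ",
         planted$mirna_id[bad][1L], ":", planted$mrna_id[bad][1L])
  }
  conds <- sprintf("cond_%d", seq_len(sc$n_conditions))
  rate <- sc$background_nonzero_rate
  draw_bg <- function(n) {
    matrix(sample(c(-1L, 0L, 1L), n * sc$n_conditions, replace = TRUE,
                  prob = c(rate / 2, 1 - rate, rate / 2)),
           n, sc$n_conditions)
  }
  mirna <- draw_bg(sc$n_mirna)
  dimnames(mirna) <- list(ids$mirna, conds)
  mrna <- draw_bg(sc$n_mrna)
  dimnames(mrna) <- list(ids$mrna, conds)
  k_cond <- min(sc$planted_n_conditions, sc$n_conditions)
  opp <- character(nrow(planted))
  for (k in seq_len(nrow(planted))) {
    a <- planted$mirna_id[k]
    b <- planted$mrna_id[k]
    chosen <- sort(sample.int(sc$n_conditions, k_cond))
    for (j in chosen) {
      if (mirna[a, j] == 0L) mirna[a, j] <- sample(c(-1L, 1L), 1L)
      mrna[b, j] <- -mirna[a, j]
    }
    opp[k] <- paste(conds[chosen], collapse = ",")
  }
  planted$opposite_conditions <- opp
  list(mirna = mirna, mrna = mrna, truth = list(planted = planted))
}
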