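# Independent oracles used to cross-check the package's own implementations.
# Each deliberately uses a different algorithm from the code it checks.

# exact multinomial goodness-of-fit p-value by brute-force enumeration:
# all 9-cell outcomes with the given total, via expand.grid over the first
# eight cells, probabilities via stats::dmultinom row by row
enum_multinom_pvalue <- function(obs, probs, comp_cache = NULL) {
  total <- sum(obs)
  comp <- comp_cache %||% enum_compositions(total)
  pv <- apply(comp, 1L, function(x) stats::dmultinom(x, prob = probs))
  pobs <- stats::dmultinom(obs, prob = probs)
  sum(pv[pv <= pobs * (1 + 1e-9)])
}

enum_compositions <- function(total) {
  g <- as.matrix(expand.grid(rep(list(0:total), 8L)))
  g <- g[rowSums(g) <= total, , drop = FALSE]
  unname(cbind(g, total - rowSums(g)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nested-loop contingency counter
loop_contingency <- function(mirna_vec, mrna_vec) {
  levels <- c(-1L, 0L, 1L)
  out <- matrix(0L, 3L, 3L, dimnames = list(c("-1", "0", "1"), c("-1", "0", "1")))
  for (r in 1:3) for (c in 1:3) {
    n <- 0L
    for (k in seq_along(mirna_vec)) {
      if (mirna_vec[k] == levels[r] && mrna_vec[k] == levels[c]) n <- n + 1L
    }
    out[r, c] <- n
  }
  out
}

# textbook Benjamini-Hochberg step-up, written from the definition
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- ranked * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# random discretized vector
rand_disc <- function(n, p_nonzero = 0.4) {
  sample(c(-1L, 0L, 1L), n, replace = TRUE,
         prob = c(p_nonzero / 2, 1 - p_nonzero, p_nonzero / 2))
}

# small matched CE fixture: features x (ref + case) expression matrix plus
# design, for hand-checked CE computation
make_expr_fixture <- function(n_feat, n_ref, n_case, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(round(stats::runif(n_feat * (n_ref + n_case), 4, 12), 4),
                n_feat, n_ref + n_case)
  })
  rownames(m) <- sprintf("f%02d", seq_len(n_feat))
  colnames(m) <- c(sprintf("r%02d", seq_len(n_ref)),
                   sprintf("s%02d", seq_len(n_case)))
  design <- group_design(
    stats::setNames(rep(c("reference", "case"), c(n_ref, n_case)),
                    colnames(m)), "reference")
  list(expr = m, design = design)
}
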