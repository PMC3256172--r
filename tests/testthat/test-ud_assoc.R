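test_that("contingency tables count condition co-occurrences", {
  t0 <- build_contingency(c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_identical(t0["0", "0"], 4L)
  expect_identical(sum(t0), 4L)

  t1 <- build_contingency(c(-1, 0, 1), c(1, 0, -1))
  expect_identical(t1["-1", "1"], 1L)
  expect_identical(t1["0", "0"], 1L)
  expect_identical(t1["1", "-1"], 1L)
  expect_identical(sum(t1), 3L)

  expect_error(build_contingency(c(0, 1), c(0, 1, -1)), "length")
  expect_error(build_contingency(c(0, 2), c(0, 1)), "\\{-1, 0, \\+1\\}")
})

test_that("contingency tables match a nested-loop counter on random input", {
  withr::with_seed(5, {
    for (i in 1:100) {
      x <- rand_disc(9)
      y <- rand_disc(9)
      expect_identical(build_contingency(x, y), loop_contingency(x, y))
    }
  })
})

test_that("null cell probabilities are a distribution and handle degenerate pools", {
  zero_pool <- matrix(0L, 5, 4, dimnames = list(sprintf("g%d", 1:5),
                                                sprintf("c%d", 1:4)))
  # all-zero mRNA pool: all mass in the mRNA = 0 column, split across miRNA
  # rows by the empirical frequency of the miRNA values
  probs <- null_cell_probs(c(1L, 1L, 0L, 0L), zero_pool, perm_config(2000, 1))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_equal(probs[, "0"], c(`-1` = 0, `0` = 0.5, `1` = 0.5))
  expect_equal(sum(probs[, c("-1", "1")]), 0)

  # all-zero miRNA: rows -1 and +1 are impossible
  mixed <- matrix(rand_disc(20), 5, 4, dimnames = dimnames(zero_pool))
  probs2 <- null_cell_probs(rep(0L, 4), mixed, perm_config(2000, 1))
  expect_equal(sum(probs2[c("-1", "1"), ]), 0)
  expect_equal(sum(probs2), 1, tolerance = 1e-12)
})

test_that("null cell probabilities approach the product form for a large pool", {
  # pool with exactly 50% zeros and 25% each sign; miRNA (1,1,0,0)
  z <- 2000
  pool_vals <- rep(c(-1L, 0L, 1L), times = c(z, 2 * z, z))
  mrna <- matrix(withr::with_seed(2, sample(pool_vals)), nrow = z, ncol = 4,
                 dimnames = list(sprintf("g%d", 1:z), sprintf("c%d", 1:4)))
  mirna <- c(1L, 1L, 0L, 0L)
  n_rep <- 1e5
  probs <- null_cell_probs(mirna, mrna, perm_config(n_rep, 42))
  expected <- outer(c(`-1` = 0, `0` = 0.5, `1` = 0.5),
                    c(`-1` = 0.25, `0` = 0.5, `1` = 0.25))
  # three Monte-Carlo SEs, including the finite-pool jumbling layer
  tol <- 3 * sqrt(expected * (1 - expected)) * sqrt(1 / n_rep + 1 / (4 * z))
  expect_true(all(abs(probs - expected) <= tol + 1e-12))
  # reproducible under the same config
  expect_identical(probs, null_cell_probs(mirna, mrna, perm_config(n_rep, 42)))
})

test_that("exact multinomial p-values handle closed-form corner cases", {
  probs <- matrix(0, 3, 3)
  probs[1, 1] <- 1
  tab <- matrix(0L, 3, 3)
  tab[1, 1] <- 5L
  expect_equal(exact_multinomial_pvalue(tab, probs), 1)

  # C = 1: p is the mass of all cells no more probable than the observed one
  p9 <- matrix(c(0.4, 0.3, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01), 3, 3)
  tab1 <- matrix(0L, 3, 3)
  tab1[2, 1] <- 1L  # cell prob 0.3
  expect_equal(exact_multinomial_pvalue(tab1, p9),
               sum(p9[p9 <= 0.3 + 1e-12]))

  # observed count in a zero-probability cell is impossible under the null
  probs0 <- matrix(1 / 8, 3, 3)
  probs0[2, 2] <- 0
  tab0 <- matrix(0L, 3, 3)
  tab0[2, 2] <- 2L
  expect_warning(p0 <- exact_multinomial_pvalue(tab0, probs0), "zero")
  expect_identical(p0, 0)
})

test_that("exact multinomial p-values agree with brute-force enumeration", {
  comp3 <- enum_compositions(3)
  expect_equal(nrow(comp3), choose(11, 8))
  withr::with_seed(8, {
    for (i in 1:10) {
      pr <- stats::runif(9)
      pr <- pr / sum(pr)
      x <- rand_disc(3)
      y <- rand_disc(3)
      tab <- build_contingency(x, y)
      expect_equal(exact_multinomial_pvalue(tab, matrix(pr, 3, 3)),
                   enum_multinom_pvalue(as.vector(tab), pr, comp3),
                   tolerance = 1e-12)
    }
  })
})

test_that("chi-squared p-values match the reference upper tail", {
  # observed exactly C * p in every cell
  pr <- matrix(1 / 9, 3, 3)
  tab <- matrix(10L, 3, 3)  # C = 90
  pv <- chisq_pvalue(tab, pr)
  expect_equal(attr(pv, "statistic"), 0)
  expect_equal(as.numeric(pv), 1)

  # hand-built table at C = 100, uniform probabilities
  obs <- matrix(c(20L, 10L, 5L, 15L, 10L, 10L, 10L, 10L, 10L), 3, 3)
  pv2 <- chisq_pvalue(obs, pr)
  stat <- sum((obs - 100 / 9)^2 / (100 / 9))
  expect_equal(attr(pv2, "statistic"), stat)
  expect_equal(as.numeric(pv2), stats::pchisq(stat, 8, lower.tail = FALSE))

  # zero-probability cell with zero count is excluded, not divided by
  pr0 <- matrix(c(0.5, 0.5, rep(0, 7)), 3, 3)
  obs0 <- matrix(c(6L, 4L, rep(0L, 7)), 3, 3)
  pv3 <- chisq_pvalue(obs0, pr0)
  expect_true(is.finite(attr(pv3, "statistic")))
  expect_equal(as.numeric(pv3), stats::pchisq(attr(pv3, "statistic"), 1,
                                              lower.tail = FALSE))
})

test_that("the pair test is invariant to jointly permuting condition order", {
  withr::with_seed(13, {
    mirna <- matrix(rand_disc(9), 1, 9,
                    dimnames = list("mirA", sprintf("c%d", 1:9)))
    mrna <- matrix(rand_disc(9 * 40), 40, 9,
                   dimnames = list(sprintf("g%d", 1:40), sprintf("c%d", 1:9)))
    perm <- sample(9)
  })
  pair <- data.frame(mirna_id = "mirA", mrna_id = "g1")
  # the contingency table ignores condition order entirely, so with the same
  # null probabilities the p-value is unchanged
  tab1 <- build_contingency(mirna["mirA", ], mrna["g1", ])
  tab2 <- build_contingency(mirna["mirA", perm], mrna["g1", perm])
  expect_identical(tab1, tab2)
  probs <- null_cell_probs(mirna["mirA", ], mrna, perm_config(500, 99))
  r1 <- ud_test_pair(pair, mirna, mrna, null_probs = probs)
  r2 <- ud_test_pair(pair, mirna[, perm, drop = FALSE],
                     mrna[, perm, drop = FALSE], null_probs = probs)
  expect_equal(r2$p, r1$p)
  expect_equal(r2$statistic, r1$statistic)
})

test_that("ud_test_pair flags degenerate pairs and detects planted signal", {
  conds <- sprintf("c%d", 1:8)
  mirna <- matrix(0L, 2, 8, dimnames = list(c("mir0", "mirP"), conds))
  mrna <- matrix(withr::with_seed(4, rand_disc(8 * 200, p_nonzero = 0.1)),
                 200, 8, dimnames = list(sprintf("g%d", 1:200), conds))
  mrna["g1", ] <- 0L
  # planted: opposite nonzero values in 6 of 8 conditions
  mirna["mirP", 1:6] <- 1L
  mrna["g2", 1:6] <- -1L

  degenerate <- ud_test_pair(data.frame(mirna_id = "mir0", mrna_id = "g1"),
                             mirna, mrna, perm_config(200, 1))
  expect_false(degenerate$testable)
  expect_identical(degenerate$p, 1)

  planted <- ud_test_pair(data.frame(mirna_id = "mirP", mrna_id = "g2"),
                          mirna, mrna, perm_config(10000, 1))
  expect_lt(planted$p, 0.05)
  expect_identical(planted$direction_conditions,
                   paste(conds[1:6], collapse = ","))

  expect_error(ud_test_pair(data.frame(mirna_id = "nope", mrna_id = "g1"),
                            mirna, mrna), "nope")
})

test_that("many conditions switch the pair test to the chi-squared branch", {
  conds <- sprintf("c%d", 1:20)
  withr::with_seed(6, {
    mirna <- matrix(rand_disc(20), 1, 20, dimnames = list("mirA", conds))
    mrna <- matrix(rand_disc(20 * 50, p_nonzero = 0.3), 50, 20,
                   dimnames = list(sprintf("g%d", 1:50), conds))
  })
  cfg <- perm_config(2000, 3)
  res <- ud_test_pair(data.frame(mirna_id = "mirA", mrna_id = "g7"),
                      mirna, mrna, cfg)
  probs <- null_cell_probs(mirna["mirA", ], mrna,
                           perm_config(2000, 3))
  tab <- build_contingency(mirna["mirA", ], mrna["g7", ])
  expect_equal(res$p, as.numeric(chisq_pvalue(tab, probs)))
})

test_that("null pairs yield conservative p-values", {
  conds <- sprintf("c%d", 1:9)
  withr::with_seed(31, {
    mrna <- matrix(rand_disc(9 * 300, p_nonzero = 0.2), 300, 9,
                   dimnames = list(sprintf("g%d", 1:300), conds))
    mirna <- matrix(rand_disc(9 * 50, p_nonzero = 0.2), 50, 9,
                    dimnames = list(sprintf("m%d", 1:50), conds))
  })
  pairs <- data.frame(mirna_id = rep(rownames(mirna), each = 4),
                      mrna_id = sprintf("g%d", 1:200))
  res <- ud_test_all(pairs, mirna, mrna, perm_config(1000, 77), alpha = 0.05)
  tested <- res[res$status == "tested", ]
  expect_gt(nrow(tested), 20)
  frac <- mean(tested$p < 0.05)
  # conservative: at or below nominal plus 3 binomial SEs
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(tested)))
  expect_false(any(res$significant %in% TRUE))
})
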