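# Conditional FDR, conjunction FDR and stratified conditional Q-Q.

toy_table <- function() {
  # 10 rows designed so the query (0.01, 0.05) sees 4 rows with p2 <= 0.05,
  # of which 2 also have p1 <= 0.01
  tibble::tibble(
    p1 = c(0.001, 0.010, 0.200, 0.500, 0.030, 0.700, 0.900, 0.050, 0.400, 0.800),
    p2 = c(0.020, 0.050, 0.010, 0.040, 0.300, 0.600, 0.100, 0.700, 0.900, 0.250)
  )
}

test_that("joint exceedance counts: toy table, full table, self-inclusion", {
  tab <- toy_table()
  got <- joint_exceedance_counts(tab, 0.01, 0.05)
  expect_equal(got$n_cond, 4L)
  expect_equal(got$n_joint, 2L)

  full <- joint_exceedance_counts(tab, 1, 1)
  expect_equal(full$n_cond, 10L)
  expect_equal(full$n_joint, 10L)

  # query at an actual SNP's values always counts itself
  i <- which.min(tab$p1 + tab$p2)
  self <- joint_exceedance_counts(tab, tab$p1[i], tab$p2[i])
  expect_gte(self$n_cond, 1L)
  expect_gte(self$n_joint, 1L)

  expect_error(joint_exceedance_counts(tab[0, ], 0.5, 0.5), "Empty")
  expect_error(joint_exceedance_counts(tab, 0, 0.5), "\\(0, 1\\]")
})

test_that("cFDR equals p1 * n_cond / n_joint, clamped, on the toy table", {
  tab <- toy_table()
  vals <- conditional_fdr(tab, principal = 1)
  # row 2 has (p1, p2) = (0.01, 0.05): counts (4, 2) -> 0.01 * 4 / 2 = 0.02
  expect_equal(vals[2], 0.02)
  # every row against the brute-force oracle
  expect_equal(vals, brute_cfdr(tab$p1, tab$p2))
  # the other ordering conditions the other way
  expect_equal(conditional_fdr(tab, principal = 2), brute_cfdr(tab$p2, tab$p1))
})

test_that("sweep-based counting equals the brute-force double loop, ties included", {
  set.seed(101)
  for (rep in 1:20) {
    tab <- random_p_table(300)
    expect_equal(conditional_fdr(tab, 1), brute_cfdr(tab$p1, tab$p2))
  }
})

test_that("degenerate conditioning reduces to the empirical BH quantity", {
  set.seed(55)
  p1 <- sample(runif(200))  # distinct with probability 1
  tab <- tibble::tibble(p1 = p1, p2 = 1)
  vals <- conditional_fdr(tab, 1)
  rank_count <- vapply(p1, function(x) sum(p1 <= x), 0)
  expect_equal(vals, pmin(1, p1 * 200 / rank_count))
})

test_that("cFDR is bounded below by the principal p-value", {
  set.seed(77)
  for (rep in 1:5) {
    tab <- random_p_table(500)
    expect_true(all(conditional_fdr(tab, 1) >= tab$p1))
    expect_true(all(conditional_fdr(tab, 2) >= tab$p2))
    expect_true(all(conditional_fdr(tab, 1) <= 1))
  }
})

test_that("ccFDR is the maximum of the two orderings", {
  # the five pleiotropic SNP pairs with printed per-ordering cFDR values
  printed <- tibble::tibble(
    snp_id = c("rs12197879", "rs1293935", "rs34955778", "rs198542", "rs2423512"),
    cfdr_1_given_2 = c(1.01e-06, 3.95e-06, 3.59e-02, 1.49e-02, 8.36e-03),
    cfdr_2_given_1 = c(2.55e-02, 2.80e-09, 1.60e-02, 1.74e-02, 9.41e-06)
  )
  out <- ccfdr(printed)
  expect_equal(out$ccfdr,
               c(2.55e-02, 3.95e-06, 3.59e-02, 1.74e-02, 8.36e-03))

  eq <- ccfdr(tibble::tibble(cfdr_1_given_2 = 0.3, cfdr_2_given_1 = 0.3))
  expect_equal(eq$ccfdr, 0.3)
  expect_true(all(out$ccfdr >= out$cfdr_1_given_2 &
                    out$ccfdr >= out$cfdr_2_given_1))
  expect_error(ccfdr(tibble::tibble(cfdr_1_given_2 = 1)), "cfdr_2_given_1")
  expect_error(ccfdr(tibble::tibble(cfdr_1_given_2 = 1,
                                    cfdr_2_given_1 = NA_real_)), "align")
})

test_that("significance calls are strict and counted; empty input gives zeros", {
  rec <- tibble::tibble(cfdr_1_given_2 = c(0.049, 0.05, 0.2),
                        cfdr_2_given_1 = c(0.01, 0.02, 0.03))
  out <- call_significant(rec, threshold = 0.05)
  expect_equal(out$sig_1_given_2, c(TRUE, FALSE, FALSE))
  expect_equal(out$sig_conjunction, c(TRUE, FALSE, FALSE))
  # conjunction-significant iff both orderings significant
  expect_equal(out$sig_conjunction, out$sig_1_given_2 & out$sig_2_given_1)

  empty <- call_significant(rec[0, ])
  s <- attr(empty, "summary", exact = TRUE)
  expect_equal(s$n_sig_1_given_2, 0L)
  expect_equal(s$n_sig_conjunction, 0L)
})

test_that("cfdr_table assembles both orderings with flags and glance counts", {
  sim <- simulate_two_trait_sumstats(sim_config(m = 1000, seed = 12))
  merged <- suppressMessages(harmonize_and_merge(sim$trait1, sim$trait2))
  res <- cfdr_table(merged, threshold = 0.05)
  expect_equal(res$cfdr_1_given_2, conditional_fdr(merged, 1))
  expect_equal(res$cfdr_2_given_1, conditional_fdr(merged, 2))
  expect_equal(res$ccfdr, pmax(res$cfdr_1_given_2, res$cfdr_2_given_1))
  g <- glance(res)
  expect_equal(g$n_sig_conjunction, sum(res$sig_conjunction))
})

test_that("a single threshold of 1 gives the marginal Q-Q curve", {
  set.seed(9)
  tab <- tibble::tibble(p1 = runif(500), p2 = runif(500))
  qq <- stratified_qq(tab, principal = 1, thresholds = 1, grid_n = 64)
  expect_equal(nrow(qq$summary), 1)
  expect_equal(qq$summary$enrichment, 0)
  grid <- seq(0, log10(500), length.out = 64)
  marginal <- -log10(quantile(tab$p1, probs = 10^(-grid), type = 1, names = FALSE))
  expect_equal(qq$curves$neglog_p, marginal)
})

test_that("strata use a strict conditional cutoff and flag small strata", {
  set.seed(3)
  tab <- tibble::tibble(p1 = runif(100),
                        p2 = c(rep(0.01, 50), rep(0.5, 50)))
  # rows at exactly p2 = 0.01 are excluded from the p < 0.01 stratum,
  # which is therefore empty and an error naming the threshold
  expect_error(stratified_qq(tab, thresholds = c(1, 0.01)), "0.01")
  # a non-empty stratum under 10 SNPs is flagged with a message
  tab$p2[1:5] <- 0.001
  expect_message(qq <- stratified_qq(tab, thresholds = c(1, 0.01)), "< 10 SNPs")
  expect_equal(qq$summary$n_snps, c(100L, 5L))
  expect_true(qq$summary$flagged_small[2])
})

test_that("under independence the curves hug the identity line", {
  set.seed(202)
  m <- 20000
  tab <- tibble::tibble(p1 = runif(m), p2 = runif(m))
  qq <- stratified_qq(tab, thresholds = c(1, 0.1, 0.01))
  # the q = 0.01 order statistic in the smallest stratum (~200 SNPs) has a
  # log10 sd near 0.35; 1.0 is a ~3-sd band
  expect_true(all(abs(qq$summary$enrichment) < 1))
  # on the curve itself, compare only where strata have resolution
  c1 <- dplyr::filter(qq$curves, .data$threshold == 0.1,
                      .data$neglog_q < log10(.data$n_snps) - 1)
  expect_lt(max(abs(c1$neglog_p - c1$neglog_q)), 0.5)
})

test_that("pleiotropic signal produces nested enrichment", {
  sim <- simulate_two_trait_sumstats(sim_config(
    m = 20000, pi00 = 0.94, pi10 = 0.02, pi01 = 0.02, pi11 = 0.02,
    sigma1 = 3, sigma2 = 3, seed = 404))
  merged <- suppressMessages(harmonize_and_merge(sim$trait1, sim$trait2))
  qq <- stratified_qq(merged, thresholds = c(1, 0.1, 0.01, 0.001))
  expect_true(all(diff(qq$summary$enrichment) > 0))
})
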