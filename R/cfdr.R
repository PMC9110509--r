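# Conditional FDR (cFDR), conjunction cFDR (ccFDR) and stratified conditional
# Q-Q enrichment — the central statistics of the package.
#
# The estimator is the empirical one: for SNP i with observed (p1_i, p2_i),
#
#   cFDR_i = min(1, p1_i * n_cond(p2_i) / n_joint(p1_i, p2_i))
#
# where n_cond = #{j : p2_j <= p2_i} and n_joint = #{j : p1_j <= p1_i and
# p2_j <= p2_i}. Comparisons are inclusive, so the index SNP counts itself
# and n_joint >= 1 always. p1 / (n_joint/n_cond) is the observed p-value
# divided by the empirical conditional cdf of p1 given p2 <= p2_i.

check_merged <- function(data) {
  need <- c("p1", "p2")
  if (!all(need %in% names(data))) abort("Data must contain columns p1 and p2.")
  if (nrow(data) == 0) abort("Empty data.")
  if (any(data$p1 <= 0 | data$p1 > 1 | data$p2 <= 0 | data$p2 > 1, na.rm = TRUE) ||
      anyNA(data$p1) || anyNA(data$p2)) {
    abort("p1 and p2 must lie in (0, 1] with no missing values.")
  }
  invisible(data)
}

#' Joint exceedance counts at query points
#'
#' For each query pair `(p1_obs, p2_obs)` counts `n_cond`, the SNPs with
#' `p2 <= p2_obs`, and `n_joint`, the SNPs with both `p1 <= p1_obs` and
#' `p2 <= p2_obs` (inclusive comparisons). When the query is an actual SNP's
#' value pair, both counts are at least 1 (the SNP counts itself).
#'
#' @param data A `merged_pair` (or any data frame with `p1`, `p2`).
#' @param p1_obs,p2_obs Numeric query vectors of equal length (recycled).
#' @return A tibble with columns `p1_obs`, `p2_obs`, `n_cond`, `n_joint`.
#' @export
joint_exceedance_counts <- function(data, p1_obs, p2_obs) {
  check_merged(data)
  q <- vctrs_recycle2(p1_obs, p2_obs)
  if (any(q$a <= 0 | q$a > 1 | q$b <= 0 | q$b > 1)) {
    abort("Query thresholds must lie in (0, 1].")
  }
  n_cond <- vapply(q$b, function(t2) sum(data$p2 <= t2), 0L)
  n_joint <- mapply(function(t1, t2) sum(data$p1 <= t1 & data$p2 <= t2),
                    q$a, q$b)
  tibble(p1_obs = q$a, p2_obs = q$b,
         n_cond = as.integer(n_cond), n_joint = as.integer(n_joint))
}

vctrs_recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  list(a = rep_len(a, n), b = rep_len(b, n))
}

#' Per-SNP conditional FDR for one trait ordering
#'
#' Computes the empirical cFDR of the principal trait conditioned on the
#' other, for every SNP, by an exact O(M log M) sort-and-sweep (a Fenwick
#' tree over p-value ranks). Ties are counted inclusively; values are clamped
#' at 1, and `cFDR >= p` always holds for the principal trait's p.
#'
#' @param data A `merged_pair` with columns `p1`, `p2` (merged and, for the
#'   intended inference, LD-pruned).
#' @param principal Which trait slot is the principal one: `1` (conditioning
#'   on trait 2) or `2`.
#' @return Numeric vector of cFDR values aligned to the rows of `data`.
#' @export
conditional_fdr <- function(data, principal = 1) {
  check_merged(data)
  principal <- as.integer(principal)
  if (!principal %in% c(1L, 2L)) abort("'principal' must be 1 or 2.")
  p <- if (principal == 1L) data$p1 else data$p2
  q <- if (principal == 1L) data$p2 else data$p1
  cnt <- exceedance_counts_sweep(p, q)
  if (any(cnt$n_joint < 1)) abort("Internal error: n_joint < 1 despite self-inclusion.")
  # pmax guards the cFDR >= p invariant against floating-point round-down
  # when n_cond/n_joint is an inexact ratio near 1
  pmin(1, pmax(p, p * cnt$n_cond / cnt$n_joint))
}

#' Conjunction cFDR from the two trait orderings
#'
#' The conjunction cFDR of a SNP is the maximum of its two cFDR values
#' (principal trait 1 conditioned on 2, and vice versa); a small ccFDR
#' indicates association with both traits, i.e. pleiotropy.
#'
#' @param records Data frame with columns `cfdr_1_given_2` and
#'   `cfdr_2_given_1`, both computed on the same rows.
#' @return `records` with a `ccfdr` column appended (max rule).
#' @export
ccfdr <- function(records) {
  need <- c("cfdr_1_given_2", "cfdr_2_given_1")
  if (!all(need %in% names(records))) {
    abort("Records must contain cfdr_1_given_2 and cfdr_2_given_1.")
  }
  if (anyNA(records$cfdr_1_given_2) || anyNA(records$cfdr_2_given_1)) {
    abort("cFDR values for the two orderings do not align (missing values).")
  }
  dplyr::mutate(records,
                ccfdr = pmax(.data$cfdr_1_given_2, .data$cfdr_2_given_1))
}

#' Flag significant SNPs at a cFDR threshold
#'
#' Significance is strict: a SNP is called for the principal trait when
#' `cFDR < threshold`, and called pleiotropic when `ccFDR < threshold`.
#'
#' @param records Data frame with `cfdr_1_given_2`, `cfdr_2_given_1` and
#'   (optionally, else computed here) `ccfdr`.
#' @param threshold Significance cutoff (default 0.05).
#' @return `records` with logical columns `sig_1_given_2`, `sig_2_given_1`,
#'   `sig_conjunction`; summary counts are stored in the `"summary"`
#'   attribute and available via [glance()].
#' @export
call_significant <- function(records, threshold = 0.05) {
  if (!"ccfdr" %in% names(records)) records <- ccfdr(records)
  out <- dplyr::mutate(records,
                       sig_1_given_2 = .data$cfdr_1_given_2 < threshold,
                       sig_2_given_1 = .data$cfdr_2_given_1 < threshold,
                       sig_conjunction = .data$ccfdr < threshold)
  attr(out, "summary") <- tibble(
    threshold = threshold,
    n_snps = nrow(out),
    n_sig_1_given_2 = sum(out$sig_1_given_2),
    n_sig_2_given_1 = sum(out$sig_2_given_1),
    n_sig_conjunction = sum(out$sig_conjunction)
  )
  attr(out, "threshold") <- threshold
  log_provenance("call_significant", threshold = threshold,
                 n_sig_1 = sum(out$sig_1_given_2),
                 n_sig_2 = sum(out$sig_2_given_1),
                 n_conj = sum(out$sig_conjunction))
  out
}

#' Full per-SNP cFDR/ccFDR table for a merged pair
#'
#' Convenience pipeline step: computes the cFDR in both trait orderings, the
#' conjunction ccFDR, and strict significance flags at `threshold`.
#'
#' @param data A `merged_pair` (merged, harmonized and LD-pruned).
#' @param threshold Significance cutoff (default 0.05).
#' @return A `cfdr_tbl` tibble: the input identifier columns plus `p1`, `p2`,
#'   `cfdr_1_given_2`, `cfdr_2_given_1`, `ccfdr` and the three `sig_*` flags.
#' @examples
#' sim <- simulate_two_trait_sumstats(sim_config(m = 500, seed = 7))
#' merged <- harmonize_and_merge(sim$trait1, sim$trait2)
#' res <- cfdr_table(merged)
#' dplyr::filter(res, sig_conjunction)
#' @export
cfdr_table <- function(data, threshold = 0.05) {
  check_merged(data)
  keep <- intersect(c("snp_id", "chrom", "pos", "p1", "p2"), names(data))
  out <- as_tibble(data)[keep]
  out$cfdr_1_given_2 <- conditional_fdr(data, 1)
  out$cfdr_2_given_1 <- conditional_fdr(data, 2)
  out <- call_significant(ccfdr(out), threshold)
  for (a in c("trait1", "trait2")) attr(out, a) <- attr(data, a, exact = TRUE)
  class(out) <- c("cfdr_tbl", class(tibble()))
  out
}

#' @export
glance.cfdr_tbl <- function(x, ...) {
  attr(x, "summary", exact = TRUE) %||%
    tibble(threshold = NA_real_, n_snps = nrow(x))
}

#' Stratified conditional Q-Q curves
#'
#' For each conditional threshold `t`, restricts to SNPs with conditional-
#' trait p-value strictly below `t` (nested strata) and computes the
#' principal trait's empirical p-value quantiles on a shared grid of
#' empirical quantile levels `q`. Under no cross-trait enrichment every
#' stratum's curve follows the identity line; leftward deflection (larger
#' nominal -log10 p at a given empirical -log10 q) with more stringent
#' conditioning indicates pleiotropic enrichment.
#'
#' The per-stratum scalar enrichment summary is the nominal `-log10 p` at
#' empirical quantile `q = 0.01`, minus the same quantity in the all-SNP
#' stratum.
#'
#' @param data A `merged_pair`.
#' @param principal Principal trait slot (1 or 2).
#' @param thresholds Descending conditional p cutoffs; default
#'   `c(1, 0.1, 0.01, 0.001, 0.0001)`.
#' @param grid_n Number of grid points in `-log10(q)`, equally spaced from 0
#'   to `log10(nrow(data))`.
#' @return A `qq_strata` object: list with `curves` (tibble: `threshold`,
#'   `n_snps`, `neglog_q`, `neglog_p`), `summary` (tibble: `threshold`,
#'   `n_snps`, `enrichment`, `mean_neglog_p` — the stratum mean of
#'   `-log10 p`, the stable statistic for monotone-enrichment checks — and
#'   `flagged_small` for strata under 10 SNPs) and `principal`.
#' @export
stratified_qq <- function(data, principal = 1,
                          thresholds = c(1, 0.1, 0.01, 0.001, 0.0001),
                          grid_n = 512) {
  check_merged(data)
  if (any(thresholds <= 0 | thresholds > 1)) abort("Thresholds must lie in (0, 1].")
  thresholds <- sort(thresholds, decreasing = TRUE)
  p <- if (principal == 1) data$p1 else data$p2
  cond <- if (principal == 1) data$p2 else data$p1
  m <- length(p)
  grid <- seq(0, log10(m), length.out = grid_n)
  qs <- 10^(-grid)

  one_stratum <- function(t) {
    sel <- if (t >= 1) rep(TRUE, m) else cond < t   # strict <, "p < t"
    ps <- p[sel]
    if (length(ps) == 0) abort(sprintf("Empty stratum at conditional threshold %g.", t))
    yq <- -log10(quantile(ps, probs = qs, type = 1, names = FALSE))
    list(curve = tibble(threshold = t, n_snps = length(ps),
                        neglog_q = grid, neglog_p = yq),
         at01 = -log10(quantile(ps, probs = 0.01, type = 1, names = FALSE)),
         mean_nlp = mean(-log10(ps)),
         n = length(ps))
  }
  strata <- lapply(thresholds, one_stratum)
  ref <- strata[[1]]$at01
  # two per-stratum scalars: `enrichment`, the nominal -log10 p at empirical
  # q = 0.01 relative to the all-SNP stratum (a tail summary, noisy in small
  # strata), and `mean_neglog_p`, the stratum mean of -log10 p (the stable
  # statistic for monotone-enrichment checks)
  summary <- tibble(
    threshold = thresholds,
    n_snps = vapply(strata, function(s) s$n, 0L),
    enrichment = vapply(strata, function(s) s$at01, 0) - ref,
    mean_neglog_p = vapply(strata, function(s) s$mean_nlp, 0),
    flagged_small = vapply(strata, function(s) s$n < 10, TRUE)
  )
  if (any(summary$flagged_small)) {
    inform(sprintf("Stratum/strata with < 10 SNPs at threshold(s): %s",
                   paste(summary$threshold[summary$flagged_small], collapse = ", ")))
  }
  structure(list(curves = dplyr::bind_rows(lapply(strata, `[[`, "curve")),
                 summary = summary, principal = principal),
            class = "qq_strata")
}

#' @export
print.qq_strata <- function(x, ...) {
  cat(sprintf("<qq_strata> principal trait %d, %d strata\n",
              x$principal, nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.qq_strata <- function(x, ...) x$curves

#' @export
glance.qq_strata <- function(x, ...) x$summary
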