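# Two-sample Mendelian randomization: instrument selection by p-value and
# genome-wide greedy clumping, per-instrument Wald ratios, and fixed-effect
# inverse-variance-weighted (IVW) and maximum-likelihood (ML) causal-effect
# estimates.
#
# The ML model: per instrument i, beta_x_i ~ N(xi_i, se_x_i^2) and
# beta_y_i ~ N(theta * xi_i, se_y_i^2), maximized over (theta, xi_1..k).
# The xi are profiled out in closed form; the profile score in theta is
# polished by Newton steps, and se(theta) comes from the observed
# information with the xi block eliminated.

#' Select independent genome-wide-significant instruments
#'
#' Keeps exposure SNPs with `p < p_max`, then clumps greedily in ascending-p
#' order: a SNP is retained unless its panel r^2 with any already-retained
#' SNP exceeds `r2_max` (genome-wide, no window limit).
#'
#' @param exposure A `sumstats_tbl` for the exposure trait.
#' @param panel An [ld_panel()] covering the candidate SNPs.
#' @param p_max Inclusion threshold on the exposure p-value (default 5e-8).
#' @param r2_max Independence threshold (default 0.01); r^2 strictly greater
#'   disqualifies.
#' @return Character vector of retained instrument `snp_id`s, in
#'   ascending-p order.
#' @export
select_instruments <- function(exposure, panel, p_max = 5e-8, r2_max = 0.01) {
  stopifnot(inherits(panel, "ld_panel"))
  cand <- exposure[!is.na(exposure$p) & exposure$p < p_max, ]
  if (nrow(cand) == 0) abort("No instruments: no SNP passes the p-value threshold.")
  missing <- setdiff(cand$snp_id, panel$meta$snp_id)
  if (length(missing)) {
    abort(sprintf("Candidate instrument(s) absent from the LD panel: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  cand <- cand[order(cand$p, cand$snp_id), ]
  rows <- match(cand$snp_id, panel$meta$snp_id)
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      if (compute_r2(panel$dosage[rows[i], ], panel$dosage[j, ]) > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, rows[i])
  }
  ids <- panel$meta$snp_id[kept]
  log_provenance("select_instruments", p_max = p_max, r2_max = r2_max,
                 n_candidates = nrow(cand), n_instruments = length(ids))
  ids
}

#' Fill in per-instrument Wald ratios
#'
#' `wald_ratio = beta_y / beta_x`; `wald_se = se_y / |beta_x|` (first-order
#' delta method, appropriate for strong instruments).
#'
#' @param instruments Data frame with columns `beta_x`, `se_x`, `beta_y`,
#'   `se_y` (and usually `snp_id`).
#' @return The input with `wald_ratio` and `wald_se` columns.
#' @export
wald_ratios <- function(instruments) {
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(instruments))) {
    abort("Instruments must have beta_x, se_x, beta_y, se_y.")
  }
  if (any(instruments$se_x <= 0 | instruments$se_y <= 0)) {
    abort("Standard errors must be > 0.")
  }
  zero <- instruments$beta_x == 0
  if (any(zero)) {
    ids <- if ("snp_id" %in% names(instruments)) {
      instruments$snp_id[zero]
    } else {
      which(zero)
    }
    abort(sprintf("beta_x = 0 for instrument(s): %s",
                  paste(utils::head(ids, 5), collapse = ", ")))
  }
  dplyr::mutate(instruments,
                wald_ratio = .data$beta_y / .data$beta_x,
                wald_se = .data$se_y / abs(.data$beta_x))
}

new_mr_fit <- function(method, estimate, se, n_instruments, instruments,
                       converged = TRUE) {
  structure(list(method = method, estimate = estimate, se = se,
                 p = 2 * pnorm(-abs(estimate / se)),
                 n_instruments = n_instruments,
                 instruments = instruments, converged = converged),
            class = "mr_fit")
}

#' Fixed-effect inverse-variance-weighted causal estimate
#'
#' The IVW estimate is the weighted mean of the Wald ratios with weights
#' `1 / wald_se^2` (equivalently `beta_x^2 / se_y^2`);
#' `se = 1 / sqrt(sum(weights))`; p two-sided normal.
#'
#' @param instruments Data frame with Wald ratios (computed via
#'   [wald_ratios()] if absent).
#' @return An `mr_fit` object; see [tidy.mr_fit()].
#' @export
ivw <- function(instruments) {
  if (nrow(instruments) < 1) abort("At least one instrument required.")
  if (!"wald_ratio" %in% names(instruments)) instruments <- wald_ratios(instruments)
  w <- 1 / instruments$wald_se^2
  est <- sum(w * instruments$wald_ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  log_provenance("ivw", n_instruments = nrow(instruments), estimate = est)
  new_mr_fit("IVW", est, se, nrow(instruments), instruments)
}

# profile score in theta: d l / d theta at xi = xi_hat(theta)
mr_profile_pieces <- function(theta, bx, by, sx2, sy2) {
  xi <- (bx / sx2 + theta * by / sy2) / (1 / sx2 + theta^2 / sy2)
  score <- sum(xi * (by - theta * xi) / sy2)
  list(xi = xi, score = score)
}

#' Maximum-likelihood causal estimate
#'
#' Maximizes the joint normal likelihood in which each instrument's exposure
#' association `beta_x ~ N(xi, se_x^2)` and outcome association
#' `beta_y ~ N(theta * xi, se_y^2)`, over `(theta, xi_1..k)`. The nuisance
#' `xi` are profiled out in closed form; `theta` starts at the IVW estimate
#' and is polished by Newton iterations on the profile score until the full
#' gradient norm is below `tol`. The standard error comes from the observed
#' information with the `xi` block eliminated. In the `se_x -> 0` limit the
#' estimate equals IVW.
#'
#' @param instruments Data frame with `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @param tol Convergence tolerance on the gradient norm (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return An `mr_fit` object.
#' @export
ml_estimate <- function(instruments, tol = 1e-8, max_iter = 100) {
  if (nrow(instruments) < 1) abort("At least one instrument required.")
  inst <- wald_ratios(instruments)
  bx <- inst$beta_x; by <- inst$beta_y
  sx2 <- inst$se_x^2; sy2 <- inst$se_y^2

  theta <- ivw(inst)$estimate
  h <- 1e-6 * max(1, abs(theta))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- mr_profile_pieces(theta, bx, by, sx2, sy2)$score
    if (abs(g) < tol) { converged <- TRUE; break }
    gp <- (mr_profile_pieces(theta + h, bx, by, sx2, sy2)$score -
             mr_profile_pieces(theta - h, bx, by, sx2, sy2)$score) / (2 * h)
    if (!is.finite(gp) || gp >= 0) gp <- -sum(bx^2 / sy2)  # safeguarded slope
    step <- g / gp
    theta <- theta - step
    if (abs(step) < tol * max(1, abs(theta))) { converged <- TRUE; break }
  }
  g_final <- mr_profile_pieces(theta, bx, by, sx2, sy2)
  if (!converged && abs(g_final$score) >= tol) {
    abort(sprintf(
      "ML estimation did not converge after %d iterations (|score| = %.3g).",
      max_iter, abs(g_final$score)))
  }
  xi <- g_final$xi
  # observed information, xi block eliminated:
  # J_tt = sum xi^2/sy2 ; J_txi = (2 theta xi - by)/sy2 ; J_xixi = 1/sx2 + theta^2/sy2
  J_tt <- sum(xi^2 / sy2)
  J_txi <- (2 * theta * xi - by) / sy2
  J_xixi <- 1 / sx2 + theta^2 / sy2
  info <- J_tt - sum(J_txi^2 / J_xixi)
  if (info <= 0) abort("Observed information for theta is not positive.")
  se <- 1 / sqrt(info)
  log_provenance("ml_estimate", n_instruments = nrow(inst), estimate = theta)
  new_mr_fit("ML", theta, se, nrow(inst), inst, converged = TRUE)
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit %s> estimate = %.4g (se %.3g, p = %.3g), %d instruments\n",
              x$method, x$estimate, x$se, x$p, x$n_instruments))
  invisible(x)
}

#' Tidy an MR fit
#' @param x An `mr_fit`.
#' @param conf.level Confidence level for the normal interval.
#' @param ... Unused.
#' @return One-row tibble with `method`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.mr_fit <- function(x, conf.level = 0.95, ...) {
  zcrit <- qnorm(1 - (1 - conf.level) / 2)
  tibble(method = x$method, estimate = x$estimate, std.error = x$se,
         statistic = x$estimate / x$se, p.value = x$p,
         conf.low = x$estimate - zcrit * x$se,
         conf.high = x$estimate + zcrit * x$se)
}

#' @export
glance.mr_fit <- function(x, ...) {
  tibble(method = x$method, n_instruments = x$n_instruments,
         converged = x$converged)
}

#' Run a two-sample MR analysis end to end
#'
#' Selects instruments from the exposure table, pulls the matched outcome
#' associations (dropping instruments whose alleles cannot be harmonized and
#' flipping `beta_y` where the outcome's effect allele is the exposure's
#' other allele), computes Wald ratios, and fits the requested estimators.
#'
#' @param exposure,outcome `sumstats_tbl`s with `beta` and `se`.
#' @param panel An [ld_panel()] for clumping.
#' @param p_max,r2_max Instrument-selection thresholds (defaults 5e-8, 0.01).
#' @param methods Estimators to run, subset of `c("ivw", "ml")`.
#' @return A list with `instruments` (tibble) and `results` (tidy tibble,
#'   one row per method).
#' @export
mr_analysis <- function(exposure, outcome, panel, p_max = 5e-8, r2_max = 0.01,
                        methods = c("ivw", "ml")) {
  methods <- match.arg(methods, c("ivw", "ml"), several.ok = TRUE)
  ids <- select_instruments(exposure, panel, p_max = p_max, r2_max = r2_max)
  ex <- exposure[match(ids, exposure$snp_id), ]
  merged <- harmonize_and_merge(ex, outcome)
  keep <- match(merged$snp_id, ex$snp_id)
  out_rows <- match(merged$snp_id, outcome$snp_id)
  sign_flip <- sign(merged$z2) != sign(outcome$z[out_rows]) &
    outcome$z[out_rows] != 0
  inst <- tibble(
    snp_id = merged$snp_id,
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    beta_y = ifelse(sign_flip, -outcome$beta[out_rows], outcome$beta[out_rows]),
    se_y = outcome$se[out_rows]
  )
  inst <- wald_ratios(inst)
  fits <- list(ivw = ivw, ml = ml_estimate)[methods]
  results <- dplyr::bind_rows(lapply(fits, function(f) tidy(f(inst))))
  list(instruments = inst, results = results)
}

#' Simulate a two-sample MR instrument set with known causal effect
#'
#' Exposure effects `xi_i ~ N(xi_mean, xi_sd^2)`; observed
#' `beta_x ~ N(xi, se_x^2)` and `beta_y ~ N(theta * xi, se_y^2)`, i.e.
#' exactly the ML model. Defaults emulate strong instruments of the kind a
#' `p < 5e-8` selection yields.
#'
#' @param k Number of instruments.
#' @param theta True causal effect.
#' @param xi_mean,xi_sd Distribution of the latent exposure effects.
#' @param se_x,se_y Per-instrument standard errors (recycled to length `k`).
#' @param seed Optional integer seed.
#' @return A tibble of instruments with columns `snp_id`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y` and attribute `truth = list(theta, xi)`.
#' @export
simulate_mr_dataset <- function(k = 46, theta = 0.25, xi_mean = 0.1,
                                xi_sd = 0.02, se_x = 0.005, se_y = 0.02,
                                seed = NULL) {
  if (k < 1) abort("'k' must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  se_x <- rep_len(se_x, k)
  se_y <- rep_len(se_y, k)
  xi <- rnorm(k, xi_mean, xi_sd)
  out <- tibble(
    snp_id = sprintf("iv%03d", seq_len(k)),
    beta_x = rnorm(k, xi, se_x), se_x = se_x,
    beta_y = rnorm(k, theta * xi, se_y), se_y = se_y
  )
  attr(out, "truth") <- list(theta = theta, xi = xi)
  out
}
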