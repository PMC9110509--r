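# Simplified multi-trait fine-mapping of one locus under a shared
# single-causal-variant model.
#
# Per trait, the evidence at a SNP is the Wakefield-style approximate Bayes
# factor for its z-score under a N(0, W) prior on the latent non-centrality:
#
#   ABF(z, W) = sqrt(1 / (1 + W)) * exp(z^2 * W / (2 * (1 + W)))
#
# i.e. the density ratio N(z; 0, 1 + W) / N(z; 0, 1). Under exactly one
# causal variant shared by both traits, per-SNP evidence multiplies across
# traits and posteriors follow by normalizing prior * BF over the locus.
# All arithmetic is in log space (z-scores up to +/-40 must not overflow).

log_abf <- function(z, W) {
  if (any(!is.finite(z))) abort("Non-finite z-score(s) in locus.")
  if (W <= 0) abort("'W' (prior variance) must be > 0.")
  -0.5 * log1p(W) + z^2 * W / (2 * (1 + W))
}

#' Approximate Bayes factor for a z-score
#'
#' @param z Signed z-score(s).
#' @param W Prior variance of the non-centrality on the z^2 scale
#'   (default 10, weakly informative for GWAS-scale z-scores).
#' @return Bayes factor(s), alternative vs null; values below 1 favour the
#'   null. Vectorized over `z`.
#' @examples
#' abf(0, 10)           # sqrt(1/11), evidence for the null
#' abf(5, 10)
#' @export
abf <- function(z, W = 10) exp(log_abf(z, W))

#' Shared single-causal-variant posterior over a locus
#'
#' Combines each SNP's per-trait approximate Bayes factors multiplicatively
#' and normalizes `prior * BF` over the locus (log-sum-exp). The MAP SNP is
#' the posterior maximizer; exact ties go to the smaller position.
#'
#' @param locus Data frame with columns `snp_id`, `pos`, `z1`, `z2`.
#' @param prior_variance Prior variance `W` shared by both traits.
#' @param prior Optional per-SNP prior probabilities of being the causal
#'   variant (recycled/normalized); uniform by default.
#' @param ld Optional square LD correlation matrix (r values), carried along
#'   for reporting/plotting only; must be symmetric with unit diagonal. Under
#'   the single-causal-variant approximation it does not enter the ranking.
#' @return A `finemap_result` tibble: per-SNP `log_bf1`, `log_bf2`, `log_bf`,
#'   `posterior`; attributes `map_snp` and `prior_variance`.
#' @examples
#' loc <- data.frame(snp_id = c("a", "b", "c"), pos = c(100, 200, 300),
#'                   z1 = c(5, 2, 0), z2 = c(4, 1, 0))
#' shared_causal_posterior(loc)
#' @export
shared_causal_posterior <- function(locus, prior_variance = 10, prior = NULL,
                                    ld = NULL) {
  need <- c("snp_id", "pos", "z1", "z2")
  if (!all(need %in% names(locus))) {
    abort("Locus must have columns snp_id, pos, z1, z2.")
  }
  if (nrow(locus) < 1) abort("Locus must contain at least one SNP.")
  if (!is.null(ld)) {
    ld <- as.matrix(ld)
    if (nrow(ld) != nrow(locus) || !isSymmetric(unname(ld)) ||
        any(abs(diag(ld) - 1) > 1e-8)) {
      abort("'ld' must be a symmetric matrix with unit diagonal, one row per SNP.")
    }
  }
  k <- nrow(locus)
  prior <- if (is.null(prior)) rep(1 / k, k) else rep_len(prior, k) / sum(rep_len(prior, k))
  if (any(prior < 0)) abort("Priors must be non-negative.")

  lb1 <- log_abf(locus$z1, prior_variance)
  lb2 <- log_abf(locus$z2, prior_variance)
  lb <- lb1 + lb2 + log(prior)
  lmax <- max(lb)
  post <- exp(lb - lmax) / sum(exp(lb - lmax))

  out <- tibble(snp_id = locus$snp_id, pos = locus$pos,
                z1 = locus$z1, z2 = locus$z2,
                log_bf1 = lb1, log_bf2 = lb2, log_bf = lb1 + lb2,
                posterior = post)
  top <- which(post == max(post))
  map_i <- top[which.min(locus$pos[top])]
  attr(out, "map_snp") <- locus$snp_id[map_i]
  attr(out, "prior_variance") <- prior_variance
  attr(out, "ld") <- ld
  class(out) <- c("finemap_result", class(tibble()))
  log_provenance("shared_causal_posterior", n_snps = k, W = prior_variance,
                 map_snp = locus$snp_id[map_i])
  out
}

#' @export
tidy.finemap_result <- function(x, ...) as_tibble(x)

#' @export
glance.finemap_result <- function(x, ...) {
  tibble(n_snps = nrow(x),
         map_snp = attr(x, "map_snp", exact = TRUE),
         map_posterior = max(x$posterior),
         prior_variance = attr(x, "prior_variance", exact = TRUE))
}
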