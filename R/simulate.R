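# Synthetic two-trait GWAS generator with known pleiotropic structure, plus a
# toy block-LD genotype panel. This is the ground-truth engine behind all
# calibration, power and FDR-control experiments in the package.

#' Simulation configuration
#'
#' Defines the study conditions of the synthetic two-trait experiment: a
#' four-group mixture over SNPs (null `00`, trait-1-only `10`, trait-2-only
#' `01`, pleiotropic `11`) with z-score inflation `sigma` per non-null trait,
#' and a block-structured LD reference panel.
#'
#' Defaults describe a desk-scale two-trait GWAS: 20,000 SNPs, 2% of SNPs
#' non-null per trait alone, 2% pleiotropic, non-null z-scores inflated with
#' `sigma = 3` (marginal sd `sqrt(1 + 9) ~ 3.2`, typical of well-powered GWAS
#' hits after pruning), LD blocks of 10 SNPs with adjacent latent correlation
#' 0.8 in a 500-sample panel.
#'
#' @param m Number of SNPs.
#' @param pi00,pi10,pi01,pi11 Mixture proportions (must sum to 1).
#' @param sigma1,sigma2 Non-null z-score inflation sd per trait: a non-null z
#'   is drawn `N(0, 1 + sigma^2)`.
#' @param rho_block Adjacent-SNP latent (haplotype-level) correlation within
#'   an LD block, in `[0, 1)`.
#' @param block_size SNPs per LD block.
#' @param n_samples Diploid sample count of the genotype panel.
#' @param maf_range Allele-frequency range `(low, high)` within `(0, 0.5]`.
#' @param seed Integer seed; every simulation from this config is reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m = 20000,
                       pi00 = 0.94, pi10 = 0.02, pi01 = 0.02, pi11 = 0.02,
                       sigma1 = 3, sigma2 = 3,
                       rho_block = 0.8, block_size = 10,
                       n_samples = 500, maf_range = c(0.05, 0.5),
                       seed = 1L) {
  pis <- c(pi00, pi10, pi01, pi11)
  if (m < 1) abort("'m' must be >= 1.")
  if (any(pis < 0) || abs(sum(pis) - 1) > 1e-12) {
    abort("Mixture proportions must be >= 0 and sum to 1 (within 1e-12).")
  }
  if (sigma1 < 0 || sigma2 < 0) abort("'sigma1'/'sigma2' must be >= 0.")
  if (rho_block < 0 || rho_block >= 1) abort("'rho_block' must be in [0, 1).")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("'maf_range' must be (low, high) within (0, 0.5].")
  }
  structure(
    list(m = as.integer(m), pi00 = pi00, pi10 = pi10, pi01 = pi01, pi11 = pi11,
         sigma1 = sigma1, sigma2 = sigma2, rho_block = rho_block,
         block_size = as.integer(block_size),
         n_samples = as.integer(n_samples), maf_range = maf_range,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Lay m SNPs out over 22 autosomes in contiguous runs, 10 kb apart.
snp_layout <- function(m) {
  chrom <- as.character(ceiling(seq_len(m) / ceiling(m / 22)))
  idx_within <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  tibble(snp_id = sprintf("snp%07d", seq_len(m)),
         chrom = chrom, pos = idx_within * 10000L)
}

#' Simulate paired GWAS summary statistics with known pleiotropy
#'
#' Each SNP is assigned one of four components with probabilities
#' `(pi00, pi10, pi01, pi11)`. Per trait, the z-score is `N(0, 1)` when the
#' SNP is null for that trait and `N(0, 1 + sigma^2)` when non-null;
#' p-values are two-sided normal. Both traits share the SNP panel (ids,
#' positions, MAFs). Z-scores are simulated exchangeably across SNPs (no
#' LD-induced correlation): the operative post-pruning assumption.
#'
#' @param config A [sim_config()].
#' @return A list with elements `trait1`, `trait2` (each a `sumstats_tbl`)
#'   and `truth`, a tibble with the per-SNP `component` label (`"00"`,
#'   `"10"`, `"01"`, `"11"`) and the per-trait sd used.
#' @examples
#' sim <- simulate_two_trait_sumstats(sim_config(m = 100, seed = 42))
#' table(sim$truth$component)
#' @export
simulate_two_trait_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m
  comp <- sample(c("00", "10", "01", "11"), m, replace = TRUE,
                 prob = c(config$pi00, config$pi10, config$pi01, config$pi11))
  nn1 <- comp %in% c("10", "11")
  nn2 <- comp %in% c("01", "11")
  sd1 <- ifelse(nn1, sqrt(1 + config$sigma1^2), 1)
  sd2 <- ifelse(nn2, sqrt(1 + config$sigma2^2), 1)
  z1 <- rnorm(m, 0, sd1)
  z2 <- rnorm(m, 0, sd2)
  maf <- runif(m, config$maf_range[1], config$maf_range[2])

  layout <- snp_layout(m)
  base <- dplyr::mutate(layout,
                        effect_allele = "A", other_allele = "G",
                        maf = maf)
  t1 <- as_sumstats(dplyr::mutate(base, z = z1, p = p_from_z(z1)),
                    trait_label = "trait1")
  t2 <- as_sumstats(dplyr::mutate(base, z = z2, p = p_from_z(z2)),
                    trait_label = "trait2")
  truth <- tibble(snp_id = layout$snp_id, component = comp,
                  sd1 = sd1, sd2 = sd2)
  log_provenance("simulate_two_trait_sumstats", m = m, seed = config$seed,
                 n_pleiotropic = sum(comp == "11"))
  list(trait1 = t1, trait2 = t2, truth = truth)
}

#' Simulate a block-LD genotype reference panel
#'
#' Genotype dosages in `{0, 1, 2}` are built from two independent latent
#' haplotypes per sample. Within a block of `block_size` SNPs the latent
#' Gaussians follow an AR(1) with parameter `rho_block`; each is thresholded
#' at `qnorm(f)` so the allele frequency at SNP j is `f_j ~ U(maf_range)`.
#' Blocks are mutually independent; the per-SNP metadata MAF is recomputed
#' from the realized dosages.
#'
#' @param config A [sim_config()]; uses `m`, `block_size`, `rho_block`,
#'   `n_samples`, `maf_range` and `seed`.
#' @return An `ld_panel` object (see [ld_panel()]).
#' @export
simulate_genotype_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 2) abort("'n_samples' must be >= 2.")
  set.seed(config$seed + 1L)  # distinct stream from the sumstats draw
  m <- config$m
  n <- config$n_samples
  rho <- config$rho_block
  bs <- config$block_size
  freq <- runif(m, config$maf_range[1], config$maf_range[2])
  thr <- qnorm(freq)

  latent_haplo <- function() {
    h <- matrix(NA_real_, nrow = m, ncol = n)
    block_id <- ceiling(seq_len(m) / bs)
    for (b in unique(block_id)) {
      rows <- which(block_id == b)
      e <- matrix(rnorm(length(rows) * n), nrow = length(rows))
      x <- e
      if (length(rows) > 1 && rho > 0) {
        for (j in 2:length(rows)) {
          x[j, ] <- rho * x[j - 1, ] + sqrt(1 - rho^2) * e[j, ]
        }
      }
      h[rows, ] <- x
    }
    h
  }
  dosage <- (latent_haplo() < thr) + (latent_haplo() < thr)
  storage.mode(dosage) <- "integer"

  layout <- snp_layout(m)
  af <- rowMeans(dosage) / 2
  meta <- dplyr::mutate(layout, maf = pmin(af, 1 - af))
  rownames(dosage) <- meta$snp_id
  log_provenance("simulate_genotype_panel", m = m, n_samples = n,
                 rho_block = rho, seed = config$seed)
  ld_panel(dosage, meta)
}

#' Write a genotype panel as a minimal VCF
#'
#' Renders dosages as unphased GT genotypes (`0/0`, `0/1`, `1/1`) in a
#' VCFv4.2 text file. REF/ALT are written as G/A for every site (the panel is
#' synthetic; allele identity does not enter any LD computation).
#'
#' @param panel An `ld_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "ld_panel"))
  gt <- matrix(c("0/0", "0/1", "1/1")[panel$dosage + 1L],
               nrow = nrow(panel$dosage))
  samples <- sprintf("S%04d", seq_len(ncol(gt)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pleiocfdr-synthetic-panel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(panel$meta$chrom, panel$meta$pos, panel$meta$snp_id,
                "G", "A", ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
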