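# GWAS summary-statistics I/O: reading, validation, genomic control, and
# allele-harmonized merging of two traits.
#
# A summary-statistics table ("sumstats_tbl") is a tibble with canonical
# columns snp_id, chrom, pos, effect_allele, other_allele, beta, se, z, p,
# maf, n (not all required), sorted by (chrom, pos), carrying attributes
# trait_label and gc_lambda.

CANONICAL_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "beta", "se", "z", "p", "maf", "n")
NUMERIC_COLS <- c("pos", "beta", "se", "z", "p", "maf", "n")

P_FLOOR <- 1e-300

new_sumstats <- function(df, trait_label = NULL, gc_lambda = NA_real_) {
  out <- as_tibble(df)
  attr(out, "trait_label") <- trait_label
  attr(out, "gc_lambda") <- gc_lambda
  class(out) <- c("sumstats_tbl", class(tibble()))
  out
}

#' Coerce a data frame to a validated summary-statistics table
#'
#' Validates per-SNP GWAS association results, fills in derivable columns and
#' sorts by genomic position. A missing `z` is derived as `beta / se`; a
#' missing `p` is derived from `z` under the two-sided standard-normal
#' relationship. p-values of exactly 0 are floored to `1e-300` with a warning
#' (the cFDR estimator requires strictly positive p).
#'
#' @param df Data frame with (a subset of) columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `z`, `p`, `maf`, `n`.
#'   `snp_id` is required, plus at least one of `p`, `z`, or the pair
#'   (`beta`, `se`).
#' @param trait_label Optional character label for the trait.
#' @param gc_lambda Genomic-control inflation factor already applied upstream
#'   (`NA` if unknown/none).
#' @return A `sumstats_tbl` tibble sorted by `(chrom, pos)`.
#' @examples
#' as_sumstats(data.frame(snp_id = "rs1", chrom = "1", pos = 100,
#'                        beta = 0.1, se = 0.05), trait_label = "height")
#' @export
as_sumstats <- function(df, trait_label = NULL, gc_lambda = NA_real_) {
  df <- as_tibble(df)
  if (!"snp_id" %in% names(df)) abort("Column 'snp_id' is required.")
  has <- function(col) {
    col %in% names(df) && (nrow(df) == 0 || !all(is.na(df[[col]])))
  }
  if (!has("p") && !has("z") && !(has("beta") && has("se"))) {
    abort("Need at least one of: 'p', 'z', or both 'beta' and 'se'.")
  }
  for (col in intersect(NUMERIC_COLS, names(df))) {
    if (is.character(df[[col]])) {
      parsed <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(parsed) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad)) {
        abort(sprintf("Unparseable numeric value(s) in column '%s', row(s): %s",
                      col, paste(utils::head(bad, 5), collapse = ", ")))
      }
      df[[col]] <- parsed
    }
  }
  if (nrow(df) == 0) {
    return(new_sumstats(df, trait_label, gc_lambda))
  }

  dup <- unique(df$snp_id[duplicated(df$snp_id)])
  if (length(dup)) {
    abort(sprintf("Duplicate snp_id(s): %s",
                  paste(utils::head(dup, 10), collapse = ", ")))
  }

  # derive z from beta/se, check consistency where both given
  if (all(c("beta", "se") %in% names(df))) {
    if (any(df$se <= 0, na.rm = TRUE)) abort("'se' must be > 0.")
    z_impl <- df$beta / df$se
    if ("z" %in% names(df)) {
      both <- !is.na(df$z) & !is.na(z_impl)
      rel <- abs(df$z[both] - z_impl[both]) /
        pmax(abs(z_impl[both]), .Machine$double.eps)
      if (any(rel > 1e-6)) {
        abort("'z' inconsistent with beta/se (relative error > 1e-6).")
      }
      df$z[is.na(df$z)] <- z_impl[is.na(df$z)]
    } else {
      df$z <- z_impl
    }
  }
  if ("p" %in% names(df)) {
    n0 <- sum(df$p == 0, na.rm = TRUE)
    if (n0 > 0) {
      warn(sprintf("%d p-value(s) of exactly 0 floored to %g", n0, P_FLOOR))
      log_provenance("p_floor", trait = trait_label %||% "", n_floored = n0)
      df$p[!is.na(df$p) & df$p == 0] <- P_FLOOR
    }
    bad_p <- !is.na(df$p) & (df$p <= 0 | df$p > 1)
    if (any(bad_p)) {
      abort(sprintf("p-value(s) outside (0, 1] at row(s): %s",
                    paste(utils::head(which(bad_p), 5), collapse = ", ")))
    }
    if ("z" %in% names(df)) {
      df$p[is.na(df$p)] <- p_from_z(df$z[is.na(df$p)])
    }
  } else if ("z" %in% names(df)) {
    df$p <- p_from_z(df$z)
  }
  if ("maf" %in% names(df)) {
    bad <- !is.na(df$maf) & (df$maf <= 0 | df$maf > 0.5)
    if (any(bad)) abort("'maf' must lie in (0, 0.5].")
  }
  if (all(c("effect_allele", "other_allele") %in% names(df))) {
    ok <- is.na(df$effect_allele) | is.na(df$other_allele) |
      (df$effect_allele %in% c("A", "C", "G", "T") &
         df$other_allele %in% c("A", "C", "G", "T") &
         df$effect_allele != df$other_allele)
    if (!all(ok)) {
      abort(sprintf("Invalid allele pair(s) at row(s): %s",
                    paste(utils::head(which(!ok), 5), collapse = ", ")))
    }
  }
  if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
  if (all(c("chrom", "pos") %in% names(df))) {
    df$chrom <- as.character(df$chrom)
    df <- order_genome(df)
  }
  new_sumstats(df, trait_label, gc_lambda)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-delimited (optionally gzip-compressed) file with a header row,
#' renames columns to the canonical scheme via `column_map`, then validates
#' through [as_sumstats()].
#'
#' @param path File path; `.gz` files are decompressed transparently.
#' @param column_map Named character vector mapping canonical names to file
#'   column names, e.g. `c(snp_id = "SNP", p = "P", z = "Z")`. Canonical names
#'   already present in the file need not be mapped. May also be the path of a
#'   flat key-value config file (see [read_config()]).
#' @param trait_label Optional trait label.
#' @return A validated `sumstats_tbl`.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.character(column_map) && length(column_map) == 1 &&
      is.null(names(column_map)) && file.exists(column_map)) {
    column_map <- read_config(column_map)
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("Unparseable row(s) at line(s): %s",
                  paste(utils::head(unique(prob$row) + 1L, 5), collapse = ", ")))
  }
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src)) {
      abort(sprintf("Mapped column(s) absent from file: %s",
                    paste(missing_src, collapse = ", ")))
    }
    idx <- match(unname(column_map), names(df))
    names(df)[idx] <- names(column_map)
  }
  df <- df[, intersect(names(df), CANONICAL_COLS), drop = FALSE]
  out <- as_sumstats(df, trait_label = trait_label)
  log_provenance("read_sumstats", path = path, n_snps = nrow(out),
                 trait = trait_label %||% "")
  out
}

#' Write a summary-statistics table to a tab-delimited file
#'
#' Numeric fields are written with round-trip (shortest lossless) formatting,
#' so write-then-read reproduces every finite value bit-identically.
#'
#' @param x A `sumstats_tbl` (or plain data frame with canonical columns).
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return `x`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(x)
}

#' Genomic-control correction of a summary-statistics table
#'
#' Estimates the inflation factor `lambda = median(z^2) / qchisq(0.5, 1)`
#' (the median of a 1-df chi-square is 0.4549364). If `lambda > 1`, each
#' squared z-score is divided by `lambda` (signs preserved), p-values are
#' recomputed, and any standard errors are rescaled to keep `z = beta/se`
#' consistent. If `lambda <= 1` the statistics are returned unchanged (no
#' deflation, standard genomic-control practice); in both cases the estimated
#' `lambda` is recorded in the `gc_lambda` attribute.
#'
#' @param x A `sumstats_tbl` with `z` available for all records and at least
#'   2 records.
#' @return The corrected `sumstats_tbl`.
#' @export
genomic_control <- function(x) {
  if (nrow(x) < 2) abort("Genomic control needs >= 2 records (median undefined for inference).")
  if (!"z" %in% names(x) || anyNA(x$z)) abort("'z' must be available for all records.")
  lambda <- median(x$z^2) / qchisq(0.5, df = 1)
  if (lambda > 1) {
    x$z <- x$z / sqrt(lambda)
    x$p <- p_from_z(x$z)
    if ("se" %in% names(x)) x$se <- x$se * sqrt(lambda)
  }
  attr(x, "gc_lambda") <- lambda
  log_provenance("genomic_control", lambda = lambda, corrected = lambda > 1)
  x
}

strand_complement <- function(a) chartr("ACGT", "TGCA", a)

is_strand_ambiguous <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize alleles and merge two traits' summary statistics
#'
#' Intersects two validated tables by `snp_id` and aligns the second trait's
#' z-scores to the first trait's effect allele:
#' * same alleles, same orientation: kept as is;
#' * effect/other alleles swapped: `z2` sign is flipped;
#' * opposite-strand representation (complemented alleles): aligned after
#'   complementing, with a sign flip if also swapped;
#' * strand-ambiguous SNPs (A/T or C/G) are dropped and counted;
#' * irreconcilable allele pairs are dropped and counted.
#'
#' When either table lacks allele columns the tables are assumed to share an
#' effect-allele convention (a note is emitted); this is the case for
#' simulated data.
#'
#' @param t1 `sumstats_tbl` for the principal-candidate trait (slot 1).
#' @param t2 `sumstats_tbl` for the conditional-candidate trait (slot 2).
#' @return A `merged_pair` tibble with columns `snp_id`, `chrom`, `pos`,
#'   `p1`, `z1`, `p2`, `z2`, `maf`, sorted by position; attributes `trait1`,
#'   `trait2`, `n_ambiguous_dropped`, `n_irreconcilable_dropped`.
#' @export
harmonize_and_merge <- function(t1, t2) {
  shared <- intersect(t1$snp_id, t2$snp_id)
  if (length(shared) == 0) abort("Empty SNP intersection between the two tables.")
  i1 <- match(shared, t1$snp_id)
  i2 <- match(shared, t2$snp_id)

  z2 <- t2$z[i2]
  p2 <- t2$p[i2]
  have_alleles <- all(c("effect_allele", "other_allele") %in% names(t1)) &&
    all(c("effect_allele", "other_allele") %in% names(t2)) &&
    !anyNA(t1$effect_allele[i1]) && !anyNA(t2$effect_allele[i2])
  n_amb <- 0L
  n_irr <- 0L
  if (have_alleles) {
    ea1 <- t1$effect_allele[i1]; oa1 <- t1$other_allele[i1]
    ea2 <- t2$effect_allele[i2]; oa2 <- t2$other_allele[i2]
    amb <- is_strand_ambiguous(ea1, oa1) | is_strand_ambiguous(ea2, oa2)
    same <- ea2 == ea1 & oa2 == oa1
    swap <- ea2 == oa1 & oa2 == ea1
    cea2 <- strand_complement(ea2); coa2 <- strand_complement(oa2)
    same_c <- cea2 == ea1 & coa2 == oa1
    swap_c <- cea2 == oa1 & coa2 == ea1
    flip <- !amb & (swap | (!same & swap_c))
    keep <- !amb & (same | swap | same_c | swap_c)
    n_amb <- sum(amb)
    n_irr <- sum(!keep & !amb)
    z2[flip] <- -z2[flip]
    if (n_amb > 0) inform(sprintf("Dropped %d strand-ambiguous (A/T or C/G) SNP(s).", n_amb))
    if (n_irr > 0) inform(sprintf("Dropped %d SNP(s) with irreconcilable alleles.", n_irr))
  } else {
    inform("Allele columns unavailable in both tables; assuming a shared effect-allele convention.")
    keep <- rep(TRUE, length(shared))
  }

  maf1 <- if ("maf" %in% names(t1)) t1$maf[i1] else rep(NA_real_, length(i1))
  if ("maf" %in% names(t2)) {
    maf1[is.na(maf1)] <- t2$maf[i2][is.na(maf1)]
  }
  out <- tibble(
    snp_id = shared, chrom = as.character(t1$chrom[i1]), pos = t1$pos[i1],
    p1 = t1$p[i1], z1 = t1$z[i1], p2 = p2, z2 = z2, maf = maf1
  )[keep, ]
  if (nrow(out) == 0) abort("No SNPs left after allele harmonization.")
  out <- order_genome(out)
  attr(out, "trait1") <- attr(t1, "trait_label", exact = TRUE)
  attr(out, "trait2") <- attr(t2, "trait_label", exact = TRUE)
  attr(out, "n_ambiguous_dropped") <- n_amb
  attr(out, "n_irreconcilable_dropped") <- n_irr
  class(out) <- c("merged_pair", class(tibble()))
  log_provenance("harmonize_and_merge", n_shared = length(shared),
                 n_kept = nrow(out), n_ambiguous = n_amb, n_irreconcilable = n_irr)
  out
}
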