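# LD reference panel container and windowed r^2-based SNP pruning.
#
# The pruning procedure mirrors the classic sliding-window thinning: within a
# window of `window` consecutive currently-retained SNPs, any pair with
# r^2 > r2_max loses its smaller-MAF member immediately; the window advances
# `step` SNPs and passes repeat until a full scan removes nothing. A final
# every-offset sweep guarantees the post-condition that no pair within any
# window of `window` consecutive retained SNPs exceeds r2_max.

#' Construct an LD reference panel
#'
#' @param dosage Numeric matrix, SNPs x samples, values 0/1/2 (NA allowed).
#' @param meta Data frame with `snp_id`, `chrom`, `pos` (1-based), one row
#'   per dosage row, in the same order; a `maf` column, if present, must
#'   match the MAF recomputed from dosages within 1e-9, otherwise it is
#'   filled in.
#' @return An `ld_panel` list with elements `dosage` and `meta`, rows sorted
#'   by `(chrom, pos)`.
#' @export
ld_panel <- function(dosage, meta) {
  dosage <- as.matrix(dosage)
  meta <- as_tibble(meta)
  stopifnot(nrow(dosage) == nrow(meta),
            all(c("snp_id", "chrom", "pos") %in% names(meta)))
  if (any(!dosage %in% c(0L, 1L, 2L, NA))) {
    abort("Dosages must be 0, 1, 2 or NA.")
  }
  ord <- order(chrom_rank(meta$chrom), meta$pos)
  meta <- meta[ord, ]
  dosage <- dosage[ord, , drop = FALSE]
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  if ("maf" %in% names(meta)) {
    if (any(abs(meta$maf - maf) > 1e-9, na.rm = TRUE)) {
      abort("Metadata 'maf' disagrees with MAF recomputed from dosages (> 1e-9).")
    }
  } else {
    meta$maf <- maf
  }
  rownames(dosage) <- meta$snp_id
  structure(list(dosage = dosage, meta = meta), class = "ld_panel")
}

#' Read an LD panel from a tab-delimited dosage matrix
#'
#' Expected layout: header row; columns `snp_id`, `chrom`, `pos`, then one
#' numeric dosage column per sample.
#'
#' @param path File path (gzip accepted).
#' @return An `ld_panel`.
#' @export
read_ld_panel <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(df))) {
    abort("Dosage file must have columns snp_id, chrom, pos before the samples.")
  }
  samp <- setdiff(names(df), need)
  if (length(samp) == 0) abort("No sample columns found.")
  ld_panel(as.matrix(df[samp]),
           dplyr::mutate(df[need], chrom = as.character(.data$chrom)))
}

#' Write an LD panel as a tab-delimited dosage matrix
#' @param panel An `ld_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ld_panel"))
  df <- dplyr::bind_cols(panel$meta[c("snp_id", "chrom", "pos")],
                         as_tibble(as.data.frame(panel$dosage),
                                   .name_repair = "minimal"))
  names(df) <- c("snp_id", "chrom", "pos",
                 sprintf("S%04d", seq_len(ncol(panel$dosage))))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an LD panel from a VCF
#'
#' GT genotypes (phased or unphased) are converted to ALT-allele dosages.
#'
#' @param path VCF path (plain or gzipped).
#' @return An `ld_panel`.
#' @export
read_ld_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  meta <- tibble(snp_id = fix$ID, chrom = as.character(fix$CHROM),
                 pos = as.integer(fix$POS))
  ld_panel(dose, meta)
}

#' Squared Pearson correlation between two dosage vectors
#'
#' Computed over pairwise-complete samples. This is the r^2 used for both
#' pruning and instrument clumping.
#'
#' @param x,y Dosage vectors of equal length.
#' @return r^2 in `[0, 1]`.
#' @export
compute_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("Vectors must have equal length.")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) abort("Fewer than 2 pairwise-complete samples.")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("Zero variance after pairwise deletion (monomorphic SNP).")
  }
  cor(x, y)^2
}

# One scan over a chromosome's retained sequence with window starts at
# offsets 1, 1+step, ...; removal is immediate. r2m is the precomputed
# pairwise r^2 matrix for the chromosome (NA marks a monomorphic member).
prune_pass <- function(keep, r2m, maf, pos, ids, window, step, r2_max, removed) {
  ptr <- 1L
  repeat {
    cur <- which(keep)
    if (ptr > length(cur)) break
    win <- cur[ptr:min(ptr + window - 1L, length(cur))]
    if (length(win) >= 2) {
      for (a in seq_len(length(win) - 1L)) {
        ia <- win[a]
        if (!keep[ia]) next
        for (b in (a + 1L):length(win)) {
          ib <- win[b]
          if (!keep[ia]) break
          if (!keep[ib]) next
          r2 <- r2m[ia, ib]
          if (is.na(r2)) {
            abort(sprintf("Monomorphic SNP in pair (%s, %s); r^2 undefined.",
                          ids[ia], ids[ib]))
          }
          if (r2 > r2_max) {
            # smaller MAF goes; on ties the later-position SNP goes
            drop <- if (maf[ia] < maf[ib]) ia
                    else if (maf[ib] < maf[ia]) ib
                    else if (pos[ia] > pos[ib]) ia else ib
            partner <- if (drop == ia) ib else ia
            keep[drop] <- FALSE
            removed[[length(removed) + 1L]] <-
              list(snp_id = ids[drop], partner = ids[partner], r2 = r2)
          }
        }
      }
    }
    ptr <- ptr + step
  }
  list(keep = keep, removed = removed)
}

#' Sliding-window LD pruning
#'
#' Thins the panel so that no pair of retained SNPs within any window of
#' `window` consecutive retained SNPs has `r^2 > r2_max`. Within a window,
#' pairs are examined in position order and the smaller-MAF member of a
#' violating pair is removed immediately (MAF ties drop the later-position
#' SNP). The scan advances `step` SNPs at a time; passes repeat until a full
#' scan (including a final every-offset audit sweep) removes nothing. Pairs
#' at exactly `r2_max` are kept.
#'
#' @param panel An [ld_panel()].
#' @param window Window size in SNPs (>= 2).
#' @param step Step size in SNPs (1 <= step <= window).
#' @param r2_max r^2 threshold; strictly greater triggers removal.
#' @return A `prune_result` list: `retained` (snp_id character vector),
#'   `removed` (tibble with `snp_id`, `partner`, `r2`), `params`.
#' @export
window_prune <- function(panel, window = 50, step = 5, r2_max = 0.2) {
  stopifnot(inherits(panel, "ld_panel"))
  if (window < 2) abort("'window' must be >= 2.")
  if (step < 1 || step > window) abort("'step' must satisfy 1 <= step <= window.")
  meta <- panel$meta
  removed <- list()
  retained <- character(0)
  for (ch in unique(meta$chrom)) {
    idx <- which(meta$chrom == ch)
    ids <- meta$snp_id[idx]
    maf <- meta$maf[idx]
    pos <- meta$pos[idx]
    d <- panel$dosage[idx, , drop = FALSE]
    r2m <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))^2
    keep <- rep(TRUE, length(idx))
    repeat {
      n_before <- sum(keep)
      st <- prune_pass(keep, r2m, maf, pos, ids, window, step, r2_max, removed)
      keep <- st$keep; removed <- st$removed
      if (sum(keep) == n_before) {
        # audit sweep at every offset to guarantee the post-condition
        st <- prune_pass(keep, r2m, maf, pos, ids, window, 1L, r2_max, removed)
        if (sum(st$keep) == n_before) break
        keep <- st$keep; removed <- st$removed
      }
    }
    retained <- c(retained, ids[keep])
  }
  removed_tbl <- if (length(removed)) {
    dplyr::bind_rows(lapply(removed, as_tibble))
  } else {
    tibble(snp_id = character(0), partner = character(0), r2 = numeric(0))
  }
  log_provenance("window_prune", window = window, step = step, r2_max = r2_max,
                 n_input = nrow(meta), n_retained = length(retained))
  structure(list(retained = retained, removed = removed_tbl,
                 params = list(window = window, step = step, r2_max = r2_max)),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("<prune_result> retained %d SNPs, removed %d (window=%d, step=%d, r2_max=%g)\n",
              length(x$retained), nrow(x$removed), x$params$window,
              x$params$step, x$params$r2_max))
  invisible(x)
}

#' Restrict a merged two-trait table to LD-pruned SNPs
#'
#' @param merged A `merged_pair` from [harmonize_and_merge()].
#' @param pruned A `prune_result` from [window_prune()].
#' @return The `merged_pair` restricted to retained SNPs, order preserved.
#' @export
intersect_after_prune <- function(merged, pruned) {
  stopifnot(inherits(pruned, "prune_result"))
  keep <- merged$snp_id %in% pruned$retained
  out <- merged[keep, ]
  if (nrow(out) == 0) abort("No SNPs left after intersecting with the pruned set.")
  for (a in c("trait1", "trait2")) {
    attr(out, a) <- attr(merged, a, exact = TRUE)
  }
  class(out) <- class(merged)
  log_provenance("intersect_after_prune", n_in = nrow(merged), n_out = nrow(out))
  out
}
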