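# Independent reference implementations used as test oracles. These are kept
# deliberately naive and separate from the package's computation paths.

# O(M^2) brute-force exceedance counts: for every row, count comparisons
# directly over the whole table.
brute_exceedance <- function(p1, p2) {
  m <- length(p1)
  n_cond <- integer(m)
  n_joint <- integer(m)
  for (i in seq_len(m)) {
    n_cond[i] <- sum(p2 <= p2[i])
    n_joint[i] <- sum(p1 <= p1[i] & p2 <= p2[i])
  }
  list(n_cond = n_cond, n_joint = n_joint)
}

brute_cfdr <- function(p1, p2) {
  cnt <- brute_exceedance(p1, p2)
  pmin(1, pmax(p1, p1 * cnt$n_cond / cnt$n_joint))
}

# Random (p1, p2) table; with prob 1/2 p-values are rounded to 2 digits so
# ties are exercised.
random_p_table <- function(m, tie_prone = NULL) {
  p1 <- runif(m)
  p2 <- runif(m)
  tie_prone <- tie_prone %||% (runif(1) < 0.5)
  if (tie_prone) {
    p1 <- pmax(round(p1, 2), 0.005)
    p2 <- pmax(round(p2, 2), 0.005)
  }
  tibble::tibble(p1 = p1, p2 = p2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive sliding-window pruning with the same normative policy as
# window_prune (immediate smaller-MAF removal, MAF ties drop the later
# position, stepped passes to fixpoint then an every-offset audit), but
# recomputing r^2 from dosages for every examined pair and rebuilding the
# retained list from scratch at each window.
prune_oracle <- function(panel, window, step, r2_max) {
  meta <- panel$meta
  retained_all <- character(0)
  for (ch in unique(meta$chrom)) {
    idx <- which(meta$chrom == ch)
    ids <- meta$snp_id[idx]
    maf <- meta$maf[idx]
    pos <- meta$pos[idx]
    dos <- panel$dosage[idx, , drop = FALSE]
    alive <- rep(TRUE, length(idx))

    scan <- function(alive, this_step) {
      ptr <- 1L
      repeat {
        cur <- which(alive)
        if (ptr > length(cur)) break
        win <- cur[ptr:min(ptr + window - 1L, length(cur))]
        a <- 1L
        while (a < length(win)) {
          b <- a + 1L
          while (b <= length(win)) {
            ia <- win[a]; ib <- win[b]
            if (alive[ia] && alive[ib]) {
              r2 <- suppressWarnings(stats::cor(dos[ia, ], dos[ib, ],
                                                use = "pairwise.complete.obs"))^2
              if (!is.na(r2) && r2 > r2_max) {
                drop <- if (maf[ia] < maf[ib]) ia
                        else if (maf[ib] < maf[ia]) ib
                        else if (pos[ia] > pos[ib]) ia else ib
                alive[drop] <- FALSE
              }
            }
            b <- b + 1L
          }
          a <- a + 1L
        }
        ptr <- ptr + this_step
      }
      alive
    }

    repeat {
      n0 <- sum(alive)
      alive <- scan(alive, step)
      if (sum(alive) == n0) {
        alive <- scan(alive, 1L)
        if (sum(alive) == n0) break
      }
    }
    retained_all <- c(retained_all, ids[alive])
  }
  retained_all
}

# Exhaustive post-condition audit: TRUE iff no pair within any window of
# `window` consecutive retained SNPs (per chromosome) has r^2 > r2_max.
audit_prune <- function(panel, retained, window, r2_max) {
  meta <- panel$meta
  for (ch in unique(meta$chrom)) {
    idx <- which(meta$chrom == ch & meta$snp_id %in% retained)
    if (length(idx) < 2) next
    for (s in seq_len(length(idx))) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      if (length(win) < 2) next
      cmb <- utils::combn(win, 2)
      for (k in seq_len(ncol(cmb))) {
        r2 <- suppressWarnings(stats::cor(panel$dosage[cmb[1, k], ],
                                          panel$dosage[cmb[2, k], ],
                                          use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 > r2_max) return(FALSE)
      }
    }
  }
  TRUE
}

# Density-ratio oracle for the approximate Bayes factor.
abf_density_ratio <- function(z, W) {
  stats::dnorm(z, 0, sqrt(1 + W)) / stats::dnorm(z, 0, 1)
}

# Brute-force nearest/overlap gene assignment by all-pairs distance scan.
map_genes_oracle <- function(snps, genes, max_dist) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$chrom == snps$chrom[i], ]
    if (nrow(g) == 0) {
      out[[i]] <- tibble::tibble(snp_id = snps$snp_id[i],
                                 gene_symbol = NA_character_,
                                 distance = NA_real_)
      next
    }
    d <- ifelse(snps$pos[i] >= g$start & snps$pos[i] <= g$end, 0,
                pmin(abs(snps$pos[i] - g$start), abs(snps$pos[i] - g$end)))
    if (any(d == 0)) {
      sel <- which(d == 0)
    } else if (min(d) <= max_dist) {
      sel <- which(d == min(d))
    } else {
      sel <- integer(0)
    }
    out[[i]] <- if (length(sel)) {
      o <- order(d[sel], g$gene_symbol[sel])
      tibble::tibble(snp_id = snps$snp_id[i],
                     gene_symbol = g$gene_symbol[sel][o],
                     distance = d[sel][o])
    } else {
      tibble::tibble(snp_id = snps$snp_id[i], gene_symbol = NA_character_,
                     distance = NA_real_)
    }
  }
  dplyr::bind_rows(out)
}

# Greedy clumping oracle: ascending-p enumeration with explicit r^2 checks.
clump_oracle <- function(ids, p, r2_lookup, r2_max) {
  ord <- order(p, ids)
  kept <- character(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (r2_lookup(ids[i], k) > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, ids[i])
  }
  kept
}
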