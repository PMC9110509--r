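# Offline annotation: SNP-to-gene mapping against BED gene intervals,
# novelty flagging against a user-supplied association catalog, and
# Manhattan-plot coordinate preparation.
#
# Conventions: BED intervals are 0-based half-open (handled by rtracklayer on
# import); SNP positions are 1-based. Internally both live as 1-based closed
# GRanges.

#' Read gene intervals from a BED file
#'
#' @param path BED file path (>= 4 columns; the name field is the gene
#'   symbol). Coordinates are 0-based half-open per the BED standard and are
#'   converted on import.
#' @return Tibble with `gene_symbol`, `chrom`, `start`, `end` (1-based
#'   closed coordinates).
#' @export
read_gene_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) {
                   abort(sprintf("Malformed BED file '%s': %s", path,
                                 conditionMessage(e)))
                 })
  if (is.null(gr$name)) abort("BED file must carry gene symbols in the name field.")
  tibble(gene_symbol = gr$name,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr))
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    gene_symbol = genes$gene_symbol
  )
}

#' Map SNPs to overlapping or nearby genes
#'
#' A SNP inside a gene interval is assigned all overlapping genes (distance
#' 0); otherwise the nearest gene within `max_dist` base pairs by edge
#' distance; otherwise the SNP is unassigned (`NA` gene). Ties are broken
#' deterministically by (distance, gene symbol).
#'
#' @param snps Data frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes Data frame with `gene_symbol`, `chrom`, `start`, `end`
#'   (1-based closed, as from [read_gene_bed()]); need not be sorted.
#' @param max_dist Maximum edge distance in bp for nearest-gene assignment
#'   (default 100000).
#' @return Tibble with one row per assignment: `snp_id`, `gene_symbol`,
#'   `distance` (0 for containment, `NA` gene for unassigned SNPs), ordered
#'   by SNP then (distance, gene symbol).
#' @export
map_snps_to_genes <- function(snps, genes, max_dist = 100000) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_symbol", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) abort("Gene intervals must have start <= end.")
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = snps$pos, width = 1)
  )
  gene_gr <- genes_to_granges(genes)

  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr,
                                      maxgap = as.integer(max_dist))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # edge distance: 0 inside the interval, else bp to the nearer edge
  # (GRanges only finds the candidates; the gap-based distance() is off by
  # one from the edge convention, so compute directly)
  pos <- snps$pos[qh]
  gs <- genes$start[sh]
  ge <- genes$end[sh]
  cand <- tibble(
    snp_id = snps$snp_id[qh],
    gene_symbol = genes$gene_symbol[sh],
    distance = ifelse(pos >= gs & pos <= ge, 0,
                      pmin(abs(pos - gs), abs(pos - ge)))
  )
  cand <- dplyr::filter(cand, .data$distance <= max_dist)
  # containment keeps every overlapping gene; otherwise only nearest-distance
  assigned <- cand |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::filter(if (any(.data$distance == 0)) .data$distance == 0
                  else .data$distance == min(.data$distance)) |>
    dplyr::ungroup()
  un <- setdiff(snps$snp_id, assigned$snp_id)
  out <- dplyr::bind_rows(
    assigned,
    tibble(snp_id = un, gene_symbol = NA_character_, distance = NA_real_)
  )
  out[order(match(out$snp_id, snps$snp_id), out$distance, out$gene_symbol), ]
}

#' Flag significant SNPs as known or novel against a catalog
#'
#' A hit is `KNOWN` when it, or any LD proxy with `r^2 > r2_proxy` (strict),
#' appears in the catalog with a reported p-value below `p_gwas`; otherwise
#' `NOVEL`. Enlarging the catalog can only turn NOVEL into KNOWN.
#'
#' @param hits Character vector of significant SNP ids (or data frame with
#'   `snp_id`).
#' @param catalog Data frame with `snp_id` and `p` (reported association
#'   p-value); optionally a `trait` column, filtered by the caller.
#' @param proxies Optional data frame with `snp_id`, `proxy_id`, `r2` giving
#'   LD proxies of the hits.
#' @param p_gwas Genome-wide significance threshold for catalog entries
#'   (default 5e-8); entries at or above it do not establish KNOWN status.
#' @param r2_proxy Proxy LD threshold (default 0.8, strict inequality).
#' @return Tibble with `snp_id`, `status` (`"KNOWN"`/`"NOVEL"`), `via`
#'   (the catalog SNP establishing KNOWN status, `NA` for novel hits).
#' @export
flag_novel <- function(hits, catalog, proxies = NULL, p_gwas = 5e-8,
                       r2_proxy = 0.8) {
  ids <- if (is.data.frame(hits)) hits$snp_id else as.character(hits)
  known_snps <- catalog$snp_id[!is.na(catalog$p) & catalog$p < p_gwas]
  via <- rep(NA_character_, length(ids))
  direct <- ids %in% known_snps
  via[direct] <- ids[direct]
  if (!is.null(proxies) && nrow(proxies) > 0) {
    px <- dplyr::filter(proxies, .data$r2 > r2_proxy,
                        .data$proxy_id %in% known_snps)
    for (i in which(!direct)) {
      hit_px <- px$proxy_id[px$snp_id == ids[i]]
      if (length(hit_px)) via[i] <- hit_px[1]
    }
  }
  tibble(snp_id = ids,
         status = ifelse(is.na(via), "NOVEL", "KNOWN"),
         via = via)
}

#' Manhattan-plot coordinates from a cFDR table
#'
#' Lays chromosomes end to end (cumulative x-coordinate) and converts the
#' selected FDR quantity to `-log10`. The conventional significance
#' reference line sits at `-log10(0.05) = 1.3`.
#'
#' @param records A `cfdr_tbl` (needs `snp_id`, `chrom`, `pos` and the cFDR
#'   columns).
#' @param mode Which value to plot: `"cfdr_1_given_2"`, `"cfdr_2_given_1"`
#'   or `"conjunction"` (the ccFDR).
#' @return Tibble with `snp_id`, `chrom`, `pos`, `x` (cumulative), `y`
#'   (`-log10` FDR), `chrom_index` (1-based color index); attributes
#'   `ref_line` (1.3...) and `chrom_centers` for axis labelling.
#' @export
manhattan_data <- function(records,
                           mode = c("cfdr_1_given_2", "cfdr_2_given_1",
                                    "conjunction")) {
  mode <- match.arg(mode)
  col <- if (mode == "conjunction") "ccfdr" else mode
  stopifnot(all(c("chrom", "pos", col) %in% names(records)))
  df <- as_tibble(records)[c(intersect("snp_id", names(records)),
                             "chrom", "pos", col)]
  df <- order_genome(df)
  chroms <- unique(df$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(ch) {
    max(df$pos[df$chrom == ch])
  }, 0)))[seq_along(chroms)]
  names(offsets) <- chroms
  df$chrom_index <- match(df$chrom, chroms)
  df$x <- df$pos + unname(offsets[df$chrom])
  df$y <- -log10(df[[col]])
  centers <- vapply(chroms, function(ch) mean(range(df$x[df$chrom == ch])), 0)
  out <- df[c(intersect("snp_id", names(df)), "chrom", "pos",
              "x", "y", "chrom_index")]
  attr(out, "ref_line") <- -log10(0.05)
  attr(out, "chrom_centers") <- tibble(chrom = chroms, center = centers)
  attr(out, "mode") <- mode
  out
}
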