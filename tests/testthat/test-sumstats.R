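# Reading, validation, genomic control and allele-harmonized merging.

write_fixture <- function(df, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

test_that("read_sumstats derives z from beta/se and handles the empty file", {
  path <- write_fixture(tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"), chrom = "1", pos = c(100, 200, 300),
    beta = 0.1, se = 0.05
  ))
  tab <- read_sumstats(path, trait_label = "bmd")
  expect_equal(tab$z, rep(2, 3))
  expect_equal(tab$p, rep(2 * pnorm(-2), 3))
  expect_identical(attr(tab, "trait_label"), "bmd")

  empty <- write_fixture(tibble::tibble(snp_id = character(0), p = numeric(0)))
  expect_equal(nrow(read_sumstats(empty)), 0)
})

test_that("rows come back sorted by (chrom, pos) and match an independent sort", {
  set.seed(11)
  df <- tibble::tibble(
    snp_id = sprintf("rs%d", 1:10),
    chrom = sample(c("2", "10", "X", "1"), 10, replace = TRUE),
    pos = sample.int(1e6, 10), p = runif(10)
  )
  tab <- read_sumstats(write_fixture(df))
  # brute-force oracle: numeric chromosomes ascending, then X, pos within
  key <- function(ch) ifelse(ch == "X", 23, suppressWarnings(as.numeric(ch)))
  oracle <- df[order(key(df$chrom), df$pos), ]
  expect_equal(tab$snp_id, oracle$snp_id)
  expect_true(all(diff(order(key(tab$chrom), tab$pos)) > 0))
})

test_that("column_map renames, including via a key-value config file", {
  df <- tibble::tibble(SNP = "rs1", CHR = "1", BP = 5, P = 0.5, Z = 0.1)
  path <- write_fixture(df)
  map <- c(snp_id = "SNP", chrom = "CHR", pos = "BP", p = "P", z = "Z")
  tab <- read_sumstats(path, column_map = map)
  expect_named(tab, c("snp_id", "chrom", "pos", "z", "p"), ignore.order = TRUE)

  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# column mapping", paste(names(map), "=", map)), cfg)
  expect_identical(read_config(cfg), map)
  tab2 <- read_sumstats(path, column_map = read_config(cfg))
  expect_identical(tab, tab2)
})

test_that("validation: floors p = 0, rejects bad p, duplicates, bad alleles", {
  expect_warning(
    tab <- as_sumstats(data.frame(snp_id = c("a", "b"), p = c(0, 0.5))),
    "floored"
  )
  expect_equal(tab$p[tab$snp_id == "a"], 1e-300)
  expect_error(as_sumstats(data.frame(snp_id = "a", p = 1.2)), "outside")
  expect_error(as_sumstats(data.frame(snp_id = c("a", "a"), p = c(0.1, 0.2))),
               "Duplicate")
  expect_error(as_sumstats(data.frame(snp_id = "a", p = 0.1,
                                      effect_allele = "A", other_allele = "A")),
               "allele")
  expect_error(as_sumstats(data.frame(snp_id = "a", p = 0.1, z = 1,
                                      beta = 5, se = 1)), "inconsistent")
  expect_error(as_sumstats(data.frame(snp_id = "a", chrom = "1", pos = 1)),
               "at least one")
})

test_that("write-then-read round-trips every field bit-identically", {
  set.seed(21)
  tab <- as_sumstats(tibble::tibble(
    snp_id = sprintf("rs%d", 1:50),
    chrom = as.character(sample(1:3, 50, TRUE)), pos = sample.int(1e7, 50),
    effect_allele = sample(c("A", "C"), 50, TRUE), other_allele = "G",
    beta = rnorm(50), se = exp(rnorm(50)), maf = runif(50, 0.01, 0.5),
    n = 1000
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path)
  for (col in names(tab)) expect_identical(back[[col]], tab[[col]], info = col)
})

test_that("genomic control: lambda from the chi-square median, floor at 1, idempotence", {
  # odd-length set whose median z^2 is exactly the 1-df chi-square median
  z0 <- c(-0.1, 0.2, sqrt(qchisq(0.5, 1)), -3, 5)
  tab0 <- as_sumstats(data.frame(snp_id = letters[1:5], z = z0))
  out0 <- genomic_control(tab0)
  expect_equal(attr(out0, "gc_lambda"), 1)
  expect_equal(out0$p, tab0$p)

  tab2 <- as_sumstats(data.frame(snp_id = letters[1:5], z = sqrt(2) * z0))
  out2 <- genomic_control(tab2)
  # recompute lambda by explicit median
  expect_equal(attr(out2, "gc_lambda"), median((sqrt(2) * z0)^2) / qchisq(0.5, 1))
  expect_equal(attr(out2, "gc_lambda"), 2)
  expect_equal(out2$z^2, z0^2)

  # idempotent: second pass is a no-op (lambda = 1 within 1e-12)
  again <- genomic_control(out2)
  expect_equal(attr(again, "gc_lambda"), 1, tolerance = 1e-12)
  expect_equal(again$z, out2$z)

  expect_error(genomic_control(as_sumstats(data.frame(snp_id = "a", z = 1))),
               ">= 2 records")
})

make_pair <- function(ea2, oa2, z2 = 1.5) {
  t1 <- as_sumstats(data.frame(snp_id = "rs1", chrom = "1", pos = 100,
                               effect_allele = "A", other_allele = "G",
                               z = 1, maf = 0.2))
  t2 <- as_sumstats(data.frame(snp_id = "rs1", chrom = "1", pos = 100,
                               effect_allele = ea2, other_allele = oa2,
                               z = z2, maf = 0.2))
  suppressMessages(harmonize_and_merge(t1, t2))
}

test_that("harmonization: orientation, swap, strand complement, ambiguity", {
  expect_equal(make_pair("A", "G")$z2, 1.5)    # identical orientation
  expect_equal(make_pair("G", "A")$z2, -1.5)   # swapped effect/other
  expect_equal(make_pair("T", "C")$z2, 1.5)    # opposite strand, same orient.
  expect_equal(make_pair("C", "T")$z2, -1.5)   # opposite strand + swap
  expect_error(make_pair("A", "C"), "No SNPs left")  # irreconcilable
})

test_that("strand-ambiguous SNPs are dropped and counted", {
  t1 <- as_sumstats(data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = "1", pos = c(1, 2, 3) * 100,
    effect_allele = c("A", "A", "C"), other_allele = c("G", "T", "G"),
    z = c(1, 2, 3)
  ))
  expect_message(merged <- harmonize_and_merge(t1, t1), "2 strand-ambiguous")
  expect_equal(merged$snp_id, "rs1")
  expect_equal(attr(merged, "n_ambiguous_dropped"), 2L)
})

test_that("merge properties: intersection bound and allele-swap sign flip", {
  set.seed(31)
  n <- 40
  t1 <- as_sumstats(tibble::tibble(
    snp_id = sprintf("rs%d", 1:n), chrom = "2", pos = seq_len(n) * 50,
    effect_allele = sample(c("A", "C"), n, TRUE), other_allele = "G",
    z = rnorm(n), maf = runif(n, 0.05, 0.5)
  ))
  t2 <- t1[sample(n, 25), ]
  merged <- suppressMessages(harmonize_and_merge(t1, t2))
  expect_lte(nrow(merged), 25)
  expect_true(all(merged$snp_id %in% t1$snp_id & merged$snp_id %in% t2$snp_id))
  expect_equal(merged$z1, merged$z2)

  swapped <- t1
  swapped$effect_allele <- t1$other_allele
  swapped$other_allele <- t1$effect_allele
  flipped <- suppressMessages(harmonize_and_merge(t1, swapped))
  expect_equal(flipped$z2, -flipped$z1)

  t_disjoint <- as_sumstats(data.frame(snp_id = "zz", p = 0.1))
  expect_error(harmonize_and_merge(t1, t_disjoint), "Empty")
})

test_that("pipeline stages append provenance blocks to the run log", {
  logf <- withr::local_tempfile(fileext = ".log")
  withr::local_options(pleiocfdr.log_file = logf)
  sim <- simulate_two_trait_sumstats(sim_config(m = 50, seed = 2))
  suppressMessages(harmonize_and_merge(sim$trait1, sim$trait2))
  lines <- readLines(logf)
  expect_true(any(grepl("stage=simulate_two_trait_sumstats", lines)))
  expect_true(any(grepl("stage=harmonize_and_merge", lines)))
  expect_true(any(grepl("n_kept = 50", lines)))
})
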