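# Shared internal helpers: chromosome ordering, provenance logging,
# flat key-value config files.

# Chromosomes sort numerically with X/Y/MT after 22; anything else after that,
# alphabetically. Returned rank is numeric and stable.
chrom_rank <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  r <- suppressWarnings(as.numeric(chrom))
  special <- c(X = 23, Y = 24, MT = 25, M = 25)
  r[is.na(r)] <- special[chrom[is.na(r)]]
  other <- is.na(r)
  if (any(other)) {
    r[other] <- 25 + match(chrom[other], sort(unique(chrom[other])))
  }
  r
}

# Order rows of a data frame by (chrom, pos).
order_genome <- function(df) {
  df[order(chrom_rank(df$chrom), df$pos), , drop = FALSE]
}

#' Append a provenance block to the run log
#'
#' Every pipeline stage records its inputs, parameters and counts. Logging is
#' off unless `options(pleiocfdr.log_file = <path>)` is set; each call appends
#' one timestamped block to that file.
#'
#' @param stage Character label of the pipeline stage.
#' @param ... Named values (parameters, counts, seeds) to record.
#' @return Invisibly, the lines written (character vector), or `NULL` when
#'   logging is disabled.
#' @export
log_provenance <- function(stage, ...) {
  path <- getOption("pleiocfdr.log_file", NULL)
  vals <- list(...)
  lines <- c(
    sprintf("[%s] stage=%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage),
    if (length(vals)) {
      paste0("  ", names(vals), " = ",
             vapply(vals, function(v) paste(format(v), collapse = ","), ""))
    }
  )
  if (!is.null(path)) cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(if (is.null(path)) NULL else lines)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored. Values are returned as a named character
#' vector, suitable e.g. as the `column_map` of [read_sumstats()].
#'
#' @param path Path to the config file.
#' @return Named character vector.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    abort(sprintf("Unparseable config line(s): %s",
                  paste(lines[bad], collapse = "; ")))
  }
  vals <- vapply(m, function(x) trimws(x[3]), "")
  names(vals) <- vapply(m, function(x) trimws(x[2]), "")
  vals
}

# two-sided normal p from z, and |z| from p
p_from_z <- function(z) 2 * pnorm(-abs(z))
z_mag_from_p <- function(p) qnorm(p / 2, lower.tail = FALSE)
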