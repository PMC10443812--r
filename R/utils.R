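# Internal helpers shared across modules.

#' @importFrom data.table as.data.table setorder fread fwrite data.table
NULL

PAT_ALPHABET <- c("C", "T", ".")

# Deterministic fan-out of one user seed into independent child seeds.
# Child seeds stay below 2^31 so they remain valid R integer seeds.
childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Validate a fragment table (chrom, cpg_start, pattern, count).
# Returns invisibly; stops with the first offending row on violation.
validatePat <- function(pat, what = "fragment table") {
  need <- c("chrom", "cpg_start", "pattern", "count")
  miss <- setdiff(need, names(pat))
  if (length(miss))
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(pat) == 0L) return(invisible(pat))
  bad <- grep("[^CT.]", pat$pattern)
  if (length(bad))
    stop(sprintf("%s row %d: pattern '%s' contains characters outside {C,T,.}",
                 what, bad[1], pat$pattern[bad[1]]))
  bad <- which(nchar(pat$pattern) < 1L)
  if (length(bad)) stop(sprintf("%s row %d: empty pattern", what, bad[1]))
  bad <- grep("^\\.|\\.$", pat$pattern)
  if (length(bad))
    stop(sprintf("%s row %d: pattern '%s' must begin and end with a called site",
                 what, bad[1], pat$pattern[bad[1]]))
  bad <- which(is.na(pat$count) | pat$count < 1)
  if (length(bad)) stop(sprintf("%s row %d: count must be >= 1", what, bad[1]))
  bad <- which(is.na(pat$cpg_start) | pat$cpg_start < 0)
  if (length(bad))
    stop(sprintf("%s row %d: cpg_start must be a non-negative CpG index",
                 what, bad[1]))
  invisible(pat)
}

# Clip fragments to the CpG interval [cpgStart, cpgEnd); drop fragments with
# fewer than minCalled called sites inside. Leading/trailing '.' produced by
# clipping are trimmed. Returns a data.frame(pattern, count).
clipPatToBlock <- function(pat, cpgStart, cpgEnd, minCalled = 1L) {
  if (nrow(pat) == 0L)
    return(data.frame(pattern = character(0), count = numeric(0)))
  s <- pat$cpg_start
  len <- nchar(pat$pattern)
  keep <- s < cpgEnd & (s + len) > cpgStart
  if (!any(keep))
    return(data.frame(pattern = character(0), count = numeric(0)))
  s <- s[keep]; len <- len[keep]
  p <- pat$pattern[keep]; cnt <- pat$count[keep]
  from <- pmax(cpgStart - s, 0L) + 1L
  to <- pmin(cpgEnd - s, len)
  p <- substr(p, from, to)
  p <- sub("^\\.+", "", p)
  p <- sub("\\.+$", "", p)
  called <- nchar(gsub("[.]", "", p))
  ok <- called >= minCalled & nchar(p) > 0L
  data.frame(pattern = p[ok], count = cnt[ok])
}

# Aggregate duplicate (chrom, cpg_start, pattern) rows, summing counts, and
# sort by (chrom, cpg_start, pattern).
aggregatePat <- function(pat) {
  dt <- data.table::as.data.table(pat)
  out <- dt[, list(count = sum(count)), by = c("chrom", "cpg_start", "pattern")]
  data.table::setorder(out, chrom, cpg_start, pattern)
  as.data.frame(out)
}

# Quantile with the linear-interpolation convention (type 7); isolated here
# because the soft-margin threshold is sensitive to the convention.
lerpQuantile <- function(x, p) {
  unname(stats::quantile(x, p, type = 7, names = FALSE, na.rm = FALSE))
}

md5OfString <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}
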