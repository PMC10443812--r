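#' Read a PAT-style fragment file
#'
#' PAT files hold fragment-level bisulfite methylation calls: one line per
#' distinct molecule pattern with columns chromosome, starting CpG index
#' (1-based on disk), the methylation pattern over \code{C} (methylated),
#' \code{T} (unmethylated) and \code{.} (missing), and the number of
#' fragments sharing that exact pattern. Gzip-compressed input is detected
#' from the file content, not the extension. Lines starting with \code{#}
#' are treated as header comments.
#'
#' @param path Path to a (optionally gzipped) tab-separated PAT file.
#' @param cpgMap Optional [CpGIndexMap-class]; when given, fragment spans are
#'   checked against the map extent.
#' @return \code{data.frame} with columns \code{chrom}, \code{cpg_start}
#'   (0-based global CpG index), \code{pattern}, \code{count}.
#' @seealso [writePat()], [patToBeta()]
#' @export
readPat <- function(path, cpgMap = NULL) {
  # gzfile() transparently reads both gzip-compressed and plain text, so
  # autodetection works off the magic bytes rather than the filename
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), cpg_start = integer(0),
                      pattern = character(0), count = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L))
    stop(sprintf("PAT parse error at line %d: expected 4 tab-separated fields, got %d",
                 lineNo[which(nf < 4L)[1]], nf[which(nf < 4L)[1]]))
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  idx <- suppressWarnings(as.integer(m[, 2]))
  cnt <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(idx))
    stop(sprintf("PAT parse error at line %d: non-integer CpG index '%s'",
                 lineNo[which(is.na(idx))[1]], m[which(is.na(idx))[1], 2]))
  if (anyNA(cnt))
    stop(sprintf("PAT parse error at line %d: non-numeric count '%s'",
                 lineNo[which(is.na(cnt))[1]], m[which(is.na(cnt))[1], 4]))
  bad <- grep("[^CT.]", m[, 3])
  if (length(bad))
    stop(sprintf("PAT format error at line %d: pattern '%s' contains characters outside {C,T,.}",
                 lineNo[bad[1]], m[bad[1], 3]))
  pat <- data.frame(chrom = m[, 1], cpg_start = idx - 1L,
                    pattern = m[, 3], count = cnt)
  validatePat(pat, what = sprintf("PAT file '%s'", path))
  if (!is.null(cpgMap)) {
    n <- nCpGs(cpgMap)
    over <- which(pat$cpg_start + nchar(pat$pattern) > n)
    if (length(over))
      stop(sprintf("PAT file '%s' line %d: fragment extends past the CpG map (%d sites)",
                   path, lineNo[over[1]], n))
  }
  pat
}

#' Write a PAT-style fragment file
#'
#' Inverse of [readPat()]; the round trip reproduces the input exactly.
#' CpG indices are written 1-based, matching the prevailing PAT dialect.
#' Output is gzip-compressed when \code{path} ends in \code{.gz}.
#'
#' @param pat Fragment \code{data.frame} (see [readPat()]), sorted by
#'   \code{(chrom, cpg_start)}.
#' @param path Output path.
#' @param header Optional character vector of header lines (written with a
#'   leading \code{#}).
#' @return \code{path}, invisibly.
#' @export
writePat <- function(pat, path, header = NULL) {
  validatePat(pat)
  o <- order(pat$chrom, pat$cpg_start)  # stable, so sorted input is identity
  if (any(o != seq_len(nrow(pat))))
    stop("fragments must be sorted by (chrom, cpg_start) before writing")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  if (nrow(pat))
    writeLines(paste(pat$chrom, pat$cpg_start + 1L, pat$pattern,
                     format(pat$count, scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  invisible(path)
}

#' Read / write BETA-style per-CpG summary files
#'
#' BETA files summarise methylation per CpG site: chromosome, CpG index
#' (1-based on disk), methylated call count, and total call count. Reading
#' requires the [CpGIndexMap-class] so that sites absent from the file are
#' representable as uncovered (total 0).
#'
#' @param path Path to a tab-separated BETA file (optionally gzipped).
#' @param cpgMap A [CpGIndexMap-class] defining the site universe.
#' @param track A [MethylomeTrack-class] to write.
#' @param sampleId Sample identifier attached to the returned track.
#' @param header Optional header lines for [writeBeta()].
#' @return [readBeta()]: a [MethylomeTrack-class]; [writeBeta()]: the path,
#'   invisibly.
#' @export
readBeta <- function(path, cpgMap, sampleId = NA_character_) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  n <- nCpGs(cpgMap)
  meth <- numeric(n); total <- numeric(n)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 4L))
      stop(sprintf("BETA parse error at line %d: expected 4 fields",
                   lineNo[which(nf < 4L)[1]]))
    m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4L, byrow = TRUE)
    idx <- as.integer(m[, 2])
    me <- as.numeric(m[, 3]); to <- as.numeric(m[, 4])
    bad <- which(me > to)
    if (length(bad))
      stop(sprintf("BETA validation error at line %d: meth (%g) > total (%g)",
                   lineNo[bad[1]], me[bad[1]], to[bad[1]]))
    if (any(idx < 1L | idx > n))
      stop(sprintf("BETA file '%s': CpG index outside the map (1..%d)", path, n))
    meth[idx] <- me; total[idx] <- to
  }
  MethylomeTrack(meth, total, sampleId)
}

#' @rdname readBeta
#' @export
writeBeta <- function(track, cpgMap, path, header = NULL) {
  stopifnot(is(track, "MethylomeTrack"), is(cpgMap, "CpGIndexMap"))
  if (nCpGs(track) != nCpGs(cpgMap))
    stop("track length does not match the CpG map")
  validObject(track)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  writeLines(paste(cpgChrom(cpgMap), seq_len(nCpGs(cpgMap)),
                   format(track@meth, scientific = FALSE, trim = TRUE),
                   format(track@total, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' Collapse fragments to per-site counts
#'
#' Bridges the fragment-level and per-site views: at each CpG site, the
#' methylated count is the total multiplicity of fragments calling \code{C}
#' there, and the total count additionally includes \code{T} calls;
#' \code{.} positions contribute nothing.
#'
#' @param pat Fragment \code{data.frame} (see [readPat()]).
#' @param nSites Number of CpG sites in the index space.
#' @param sampleId Sample identifier for the returned track.
#' @return A [MethylomeTrack-class] of length \code{nSites}.
#' @export
patToBeta <- function(pat, nSites, sampleId = NA_character_) {
  validatePat(pat)
  meth <- numeric(nSites); total <- numeric(nSites)
  if (nrow(pat)) {
    len <- nchar(pat$pattern)
    if (any(pat$cpg_start + len > nSites))
      stop("fragment extends past the site universe (nSites = ", nSites, ")")
    chars <- strsplit(pat$pattern, "", fixed = TRUE)
    idx <- unlist(lapply(seq_len(nrow(pat)),
                         function(i) pat$cpg_start[i] + seq_len(len[i]))) # 1-based
    ch <- unlist(chars)
    w <- rep(pat$count, len)
    called <- ch != "."
    total <- as.numeric(tapply(w[called], factor(idx[called], levels = seq_len(nSites)),
                               sum, default = 0))
    isC <- ch == "C"
    meth <- as.numeric(tapply(w[isC], factor(idx[isC], levels = seq_len(nSites)),
                              sum, default = 0))
  }
  MethylomeTrack(meth, total, sampleId)
}

#' Bisulfite conversion efficiency from an unmethylated spike-in
#'
#' Unmethylated lambda phage DNA is spiked into every library as an internal
#' conversion control: every cytosine in its reads should convert, so any
#' \code{C} call is a conversion failure. Efficiency is the fraction of
#' called sites read as \code{T}.
#'
#' @param pat Fragments from the unmethylated spike-in region.
#' @return Conversion efficiency in \[0, 1\]; 1 means perfect conversion.
#' @export
conversionEfficiency <- function(pat) {
  validatePat(pat)
  if (nrow(pat) == 0L) stop("no spike-in observations: conversion efficiency undefined")
  chars <- strsplit(pat$pattern, "", fixed = TRUE)
  w <- rep(pat$count, nchar(pat$pattern))
  ch <- unlist(chars)
  called <- ch != "."
  nCalls <- sum(w[called])
  if (nCalls == 0) stop("no called sites in spike-in fragments: conversion efficiency undefined")
  sum(w[ch == "T"]) / nCalls
}

#' Read / write methylation blocks as BED6+
#'
#' Blocks are stored as BED6 plus two extra columns carrying the CpG-index
#' interval: chrom, start, end (0-based half-open bp), name, score
#' (\code{n_cpgs}), strand (\code{.}), \code{cpg_start}, \code{cpg_end}
#' (0-based half-open global CpG indices).
#'
#' @param blocks A [GenomicRanges::GRanges] with metadata columns
#'   \code{n_cpgs}, \code{cpg_start}, \code{cpg_end} (as produced by
#'   [segmentMethylome()]).
#' @param path File path.
#' @param header Optional header lines.
#' @return [readBlocksBed()]: a \code{GRanges}; [writeBlocksBed()]: the
#'   path, invisibly.
#' @export
writeBlocksBed <- function(blocks, path, header = NULL) {
  mc <- mcols(blocks)
  nm <- if (!is.null(mc$name)) mc$name else
    sprintf("block_%05d", seq_along(blocks))
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  if (length(blocks))
    writeLines(paste(as.character(seqnames(blocks)), start(blocks) - 1L,
                     end(blocks), nm, mc$n_cpgs, ".",
                     mc$cpg_start, mc$cpg_end, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeBlocksBed
#' @export
readBlocksBed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "n_cpgs", "strand", "cpg_start",
                                        "cpg_end"))
  gr <- GRanges(dt$chrom, IRanges(start = dt$start + 1L, end = dt$end))
  mcols(gr)$name <- dt$name
  mcols(gr)$n_cpgs <- as.integer(dt$n_cpgs)
  mcols(gr)$cpg_start <- as.integer(dt$cpg_start)
  mcols(gr)$cpg_end <- as.integer(dt$cpg_end)
  gr
}

#' Read / write a CpG index map as TSV
#'
#' Two columns: chromosome and 0-based genomic position of each CpG, in
#' global index order.
#' @param cpgMap A [CpGIndexMap-class].
#' @param path File path.
#' @return [readCpgMap()]: a [CpGIndexMap-class]; [writeCpgMap()]: the path,
#'   invisibly.
#' @export
writeCpgMap <- function(cpgMap, path) {
  data.table::fwrite(data.table::data.table(chrom = cpgChrom(cpgMap),
                                            pos = cpgBp(cpgMap)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname writeCpgMap
#' @export
readCpgMap <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos"))
  CpGIndexMap(dt$chrom, dt$pos)
}

#' Read / write a sample manifest
#'
#' Tab-separated manifest with one row per sample: \code{sample_id},
#' \code{group}, \code{species}, optional file path columns and optional
#' \code{cfdna_conc_ng_per_ml} and covariates.
#'
#' @param manifest \code{data.frame} to write.
#' @param path File path.
#' @param groups Optional controlled vocabulary; group labels outside it are
#'   an error.
#' @return [readManifest()]: a \code{data.frame}.
#' @export
readManifest <- function(path, groups = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("sample_id", "group", "species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(df$species %in% c("human", "mouse")))
    stop("manifest species must be 'human' or 'mouse'")
  if (!is.null(groups)) {
    bad <- setdiff(unique(df$group), groups)
    if (length(bad))
      stop("manifest group label(s) outside the declared vocabulary: ",
           paste(bad, collapse = ", "))
  }
  df
}

#' @rdname readManifest
#' @export
writeManifest <- function(manifest, path) {
  data.table::fwrite(data.table::as.data.table(manifest), path, sep = "\t")
  invisible(path)
}

#' Read / write a methylation atlas
#'
#' The on-disk atlas is a directory with \code{markers.tsv} (BED6+ columns
#' plus target group, direction, delta-beta, soft margin, methylation score)
#' and \code{atlas.yaml} (species, groups with roles and member samples,
#' per-role priors, hierarchy, and the deconvolution subset size).
#'
#' @param atlas A [MethylAtlas-class].
#' @param dir Directory path.
#' @return [readAtlas()]: a [MethylAtlas-class]; [writeAtlas()]: \code{dir},
#'   invisibly.
#' @export
writeAtlas <- function(atlas, dir) {
  stopifnot(is(atlas, "MethylAtlas"))
  validObject(atlas)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(atlas@markers),
                     file.path(dir, "markers.tsv"), sep = "\t")
  grp <- split(atlas@groups$sample_id, atlas@groups$group)
  roles <- vapply(split(atlas@groups$role, atlas@groups$group), `[`, "", 1)
  cfg <- list(species = atlas@species,
              priors = as.list(atlas@priors),
              subset_size = atlas@subsetSize,
              hierarchy = list(
                pan_group = atlas@hierarchy$pan_group,
                subtypes = as.list(atlas@hierarchy$subtypes)),
              groups = lapply(names(grp), function(g)
                list(name = g, role = unname(roles[g]),
                     samples = as.list(grp[[g]]))))
  yaml::write_yaml(cfg, file.path(dir, "atlas.yaml"))
  invisible(dir)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "atlas.yaml"))
  markers <- as.data.frame(data.table::fread(file.path(dir, "markers.tsv"),
                                             header = TRUE, sep = "\t"))
  groups <- do.call(rbind, lapply(cfg$groups, function(g)
    data.frame(sample_id = unlist(g$samples), group = g$name, role = g$role)))
  new("MethylAtlas", species = cfg$species, groups = groups,
      markers = markers, priors = unlist(cfg$priors),
      hierarchy = list(pan_group = cfg$hierarchy$pan_group,
                       subtypes = unlist(cfg$hierarchy$subtypes)),
      subsetSize = as.integer(cfg$subset_size))
}
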