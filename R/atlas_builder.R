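#' Average methylation (beta) of a block
#'
#' The block beta is the ratio of methylated CpG observations to all
#' observations across the block's sites: \eqn{\sum meth / \sum total}.
#'
#' @param track A [MethylomeTrack-class].
#' @param cpgStart,cpgEnd 0-based half-open global CpG index interval.
#' @return Beta in \[0, 1\], or \code{NA} when the block has no coverage.
#' @export
blockBeta <- function(track, cpgStart, cpgEnd) {
  stopifnot(cpgEnd > cpgStart, cpgStart >= 0, cpgEnd <= nCpGs(track))
  sites <- (cpgStart + 1L):cpgEnd
  tot <- sum(totalCounts(track)[sites])
  if (tot == 0) return(NA_real_)
  sum(methCounts(track)[sites]) / tot
}

#' Block-by-sample beta matrix
#'
#' @param tracks Named list of [MethylomeTrack-class] (names become column
#'   names).
#' @param blocks Blocks \code{GRanges} (see [segmentMethylome()]).
#' @return Numeric matrix, blocks x samples, \code{NA} where uncovered.
#' @export
blockBetaMatrix <- function(tracks, blocks) {
  mc <- mcols(blocks)
  cs <- mc$cpg_start; ce <- mc$cpg_end
  out <- vapply(tracks, function(tr) {
    m <- methCounts(tr); t <- totalCounts(tr)
    cm <- c(0, cumsum(m)); ct <- c(0, cumsum(t))
    tot <- ct[ce + 1L] - ct[cs + 1L]
    ifelse(tot > 0, (cm[ce + 1L] - cm[cs + 1L]) / tot, NA_real_)
  }, numeric(length(blocks)))
  if (length(blocks) == 1L) out <- matrix(out, nrow = 1L)
  rownames(out) <- mc$name
  out
}

#' Fragment observation counts per block
#'
#' Number of fragments (weighted by multiplicity) with at least one called
#' site inside each block, per sample; the "observations" used by the
#' candidate filter.
#'
#' @param pats Named list of fragment \code{data.frame}s, one per sample.
#' @param blocks Blocks \code{GRanges}.
#' @return Numeric matrix, blocks x samples.
#' @export
blockFragmentCounts <- function(pats, blocks) {
  mc <- mcols(blocks)
  blkR <- IRanges::IRanges(start = mc$cpg_start + 1L, end = mc$cpg_end)
  out <- vapply(pats, function(pat) {
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pat$cpg_start + 1L,
                       width = nchar(pat$pattern)), blkR)
    bySubject <- split(S4Vectors::queryHits(hits),
                       factor(S4Vectors::subjectHits(hits),
                              levels = seq_along(blocks)))
    vapply(seq_along(blocks), function(i) {
      cl <- clipPatToBlock(pat[bySubject[[i]], , drop = FALSE],
                           mc$cpg_start[i], mc$cpg_end[i], minCalled = 1L)
      sum(cl$count)
    }, 1.0)
  }, numeric(length(blocks)))
  if (length(blocks) == 1L) out <- matrix(out, nrow = 1L)
  rownames(out) <- mc$name
  out
}

#' Candidate block filter for marker discovery
#'
#' Retains blocks covering at least \code{minCpgs} CpG sites, shorter than
#' \code{maxSpanBp} in genomic span, and with at least \code{minObs}
#' fragment observations in every target-group sample (the strict
#' per-sample reading; prevents markers driven by a single deep sample).
#'
#' @param blocks Blocks \code{GRanges}.
#' @param obsCounts Numeric matrix blocks x target-group samples of
#'   fragment observation counts (see [blockFragmentCounts()]), or
#'   \code{NULL} to skip the observation rule.
#' @param minCpgs Minimum CpG sites (default 3).
#' @param maxSpanBp Blocks must be strictly shorter than this (default 2000).
#' @param minObs Minimum per-sample observations (default 10).
#' @return The retained subset of \code{blocks}.
#' @export
candidateFilter <- function(blocks, obsCounts = NULL, minCpgs = 3L,
                            maxSpanBp = 2000, minObs = 10) {
  mc <- mcols(blocks)
  keep <- mc$n_cpgs >= minCpgs & width(blocks) < maxSpanBp
  if (!is.null(obsCounts)) {
    stopifnot(nrow(obsCounts) == length(blocks))
    keep <- keep & apply(obsCounts >= minObs, 1L, all)
  }
  blocks[keep]
}

#' Hard margin (delta-beta) between target and background
#'
#' The minimal per-sample separation: for hypomethylated markers,
#' \code{min(background) - max(target)}; for hypermethylated markers,
#' \code{min(target) - max(background)}.
#'
#' @param target,background Numeric vectors of per-sample block betas
#'   (\code{NA}s removed).
#' @param direction \code{"hypo"} or \code{"hyper"}.
#' @return Delta-beta in \[-1, 1\].
#' @export
deltaBeta <- function(target, background, direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  target <- target[!is.na(target)]; background <- background[!is.na(background)]
  stopifnot(length(target) >= 1, length(background) >= 1)
  if (direction == "hypo") min(background) - max(target)
  else min(target) - max(background)
}

#' Soft margin between target and background
#'
#' Quantile-trimmed separation allowing for outliers: for hypomethylated
#' markers, the 10th percentile of the background minus the 80th percentile
#' of the target; the hypermethylated form mirrors it (20th percentile of
#' the target minus the 90th percentile of the background). Quantiles use
#' linear interpolation between order statistics.
#'
#' @inheritParams deltaBeta
#' @param targetQuant Trim fraction on the target side (default 0.2, i.e.
#'   the 80th percentile for hypomethylated markers).
#' @param bgQuant Trim fraction on the background side (default 0.1).
#' @return Soft margin in \[-1, 1\]; always \eqn{\ge} the hard margin.
#' @export
softMargin <- function(target, background, direction = c("hypo", "hyper"),
                       targetQuant = 0.2, bgQuant = 0.1) {
  direction <- match.arg(direction)
  target <- target[!is.na(target)]; background <- background[!is.na(background)]
  stopifnot(length(target) >= 1, length(background) >= 1)
  if (direction == "hypo")
    lerpQuantile(background, bgQuant) - lerpQuantile(target, 1 - targetQuant)
  else
    lerpQuantile(target, targetQuant) - lerpQuantile(background, 1 - bgQuant)
}

#' One-vs-all selection of cell-type-specific marker blocks
#'
#' For every group, compares its samples against all remaining samples at
#' each candidate block, in both directions. Blocks whose soft margin meets
#' the species threshold (0.4 human, 0.35 mouse; boundary retained) become
#' markers with the better-scoring direction, sorted by delta-beta
#' descending (ties by genomic position). A block enters a comparison only
#' if its beta is missing in at most \code{maxMissingFrac} of samples;
#' samples missing at the block are excluded from its quantiles.
#'
#' @param blocks Candidate blocks \code{GRanges} (after [candidateFilter()]).
#' @param betas Numeric matrix blocks x samples of block betas.
#' @param groups \code{data.frame} with columns \code{sample_id},
#'   \code{group} (and optionally \code{role}); sample_ids must match
#'   \code{colnames(betas)}.
#' @param species \code{"human"} or \code{"mouse"}; sets the default margin.
#' @param margin Soft-margin threshold; overrides the species default.
#' @param targetQuant,bgQuant Quantile trims (see [softMargin()]).
#' @param maxMissingFrac Maximum fraction of samples allowed to miss a
#'   block (default 0.1).
#' @param groupSampleSets Optional named list mapping group name to the
#'   character vector of member sample ids, for merged groups (e.g. a
#'   pan-endothelial group spanning several endothelial subtypes). Defaults
#'   to the leaf groups in \code{groups}.
#' @param obsCounts Optional blocks x samples fragment observation matrix
#'   (see [blockFragmentCounts()]); a block is eligible for a group only if
#'   every target-group sample has at least \code{minObs} observations.
#' @param minObs Per-sample observation minimum (default 10).
#' @return \code{data.frame} of markers: block coordinates plus
#'   \code{group}, \code{direction}, \code{delta_beta}, \code{soft_margin}.
#' @export
selectMarkers <- function(blocks, betas, groups,
                          species = c("human", "mouse"), margin = NULL,
                          targetQuant = 0.2, bgQuant = 0.1,
                          maxMissingFrac = 0.1, groupSampleSets = NULL,
                          obsCounts = NULL, minObs = 10) {
  species <- match.arg(species)
  if (is.null(margin)) margin <- if (species == "human") 0.4 else 0.35
  stopifnot(length(blocks) == nrow(betas))
  if (is.null(colnames(betas)))
    colnames(betas) <- groups$sample_id
  if (is.null(groupSampleSets))
    groupSampleSets <- split(groups$sample_id, groups$group)
  mc <- mcols(blocks)
  usable <- rowMeans(is.na(betas)) <= maxMissingFrac

  out <- list()
  for (g in names(groupSampleSets)) {
    tgt <- groupSampleSets[[g]]
    if (length(tgt) < 1L) stop("group '", g, "' has no samples")
    bg <- setdiff(colnames(betas), tgt)
    tb <- betas[, tgt, drop = FALSE]
    bb <- betas[, bg, drop = FALSE]
    eligible <- usable
    if (!is.null(obsCounts))
      eligible <- eligible &
        apply(obsCounts[, tgt, drop = FALSE] >= minObs, 1L, all)
    for (i in which(eligible)) {
      tv <- tb[i, ][!is.na(tb[i, ])]
      bv <- bb[i, ][!is.na(bb[i, ])]
      if (!length(tv) || !length(bv)) next
      smHypo <- softMargin(tv, bv, "hypo", targetQuant, bgQuant)
      smHyper <- softMargin(tv, bv, "hyper", targetQuant, bgQuant)
      dir <- if (smHypo >= smHyper) "hypo" else "hyper"
      sm <- max(smHypo, smHyper)
      # boundary semantics: a margin exactly at threshold is retained, so
      # the comparison carries a tolerance against floating-point error
      if (sm < margin - 1e-9) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(seqnames(blocks))[i],
        start = start(blocks)[i] - 1L, end = end(blocks)[i],
        name = mc$name[i], n_cpgs = mc$n_cpgs[i],
        cpg_start = mc$cpg_start[i], cpg_end = mc$cpg_end[i],
        group = g, direction = dir,
        delta_beta = deltaBeta(tv, bv, dir), soft_margin = sm)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      n_cpgs = integer(0), cpg_start = integer(0),
                      cpg_end = integer(0), group = character(0),
                      direction = character(0), delta_beta = numeric(0),
                      soft_margin = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$group, -df$delta_beta, df$chrom, df$start), , drop = FALSE]
}

#' Methylation score of a marker
#'
#' Fraction of fragments at the marker whose called in-block sites are
#' fully concordant with the marker's direction: all unmethylated
#' (\code{T}) for hypomethylated markers, all methylated (\code{C}) for
#' hypermethylated markers, out of all fragments with at least one called
#' site in the block.
#'
#' @param pat Fragment \code{data.frame}.
#' @param cpgStart,cpgEnd Marker CpG interval (0-based half-open).
#' @param direction \code{"hypo"} or \code{"hyper"}.
#' @return Score in \[0, 1\], or \code{NA} if no fragment overlaps the
#'   marker with a called site.
#' @export
methylationScore <- function(pat, cpgStart, cpgEnd,
                             direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  cl <- clipPatToBlock(pat, cpgStart, cpgEnd, minCalled = 1L)
  if (nrow(cl) == 0L) return(NA_real_)
  called <- gsub("[.]", "", cl$pattern)
  want <- if (direction == "hypo") "T" else "C"
  concordant <- !grepl(if (want == "T") "C" else "T", called, fixed = TRUE)
  sum(cl$count[concordant]) / sum(cl$count)
}

#' Top-k markers
#'
#' Returns the best \code{k} markers either by methylation score (for
#' display heatmaps) or in the existing delta-beta sort order (the subset
#' used for deconvolution). Ties break deterministically by genomic
#' position.
#'
#' @param markers Marker \code{data.frame} (see [selectMarkers()]).
#' @param k Number to keep; when larger than the marker count, all are
#'   returned.
#' @param by \code{"score"} (requires a \code{score} column) or
#'   \code{"sort"}.
#' @return The top-k subset.
#' @export
topMarkers <- function(markers, k, by = c("sort", "score")) {
  by <- match.arg(by)
  if (nrow(markers) <= k) return(markers)
  if (by == "score") {
    stopifnot(!is.null(markers$score))
    o <- order(-markers$score, markers$chrom, markers$start)
    markers <- markers[o, , drop = FALSE]
  }
  markers[seq_len(k), , drop = FALSE]
}

#' Assemble a hierarchical methylation atlas
#'
#' Combines per-group marker sets into the tiers used for deconvolution in
#' the circulation: the bulk-immune group that splits hematopoietic from
#' solid-organ cfDNA, individual solid-organ cell types, pan-endothelial
#' markers common to all endothelial populations, and tissue-specific
#' endothelial subtypes whose marker sets must not overlap. Groups with
#' more than \code{subsetSize} markers are cut to the top
#' \code{subsetSize} by delta-beta order.
#'
#' @param markers Marker \code{data.frame} from [selectMarkers()] (rows for
#'   all tiers, including the pan-endothelial group if present).
#' @param groups Sample-to-group \code{data.frame} with columns
#'   \code{sample_id}, \code{group}, \code{role}.
#' @param species \code{"human"} or \code{"mouse"}.
#' @param priors Named per-role priors; defaults to the serum expectation
#'   (immune 0.85, endothelial 0.10, other solid organs 0.05).
#' @param panGroup Name of the pan-endothelial marker group (or \code{NA}).
#' @param subsetSize Markers retained per group for deconvolution
#'   (default 200).
#' @return A validated [MethylAtlas-class].
#' @export
buildHierarchicalAtlas <- function(markers, groups,
                                   species = c("human", "mouse"),
                                   priors = c(bulk_immune = 0.85,
                                              solid_organ = 0.05,
                                              pan_endothelial = 0.10,
                                              endothelial_subtype = 0.05,
                                              plain = 0.05),
                                   panGroup = NA_character_,
                                   subsetSize = 200L) {
  species <- match.arg(species)
  stopifnot(all(c("sample_id", "group", "role") %in% names(groups)))
  markers <- do.call(rbind, lapply(split(markers, markers$group),
                                   topMarkers, k = subsetSize, by = "sort"))
  rownames(markers) <- NULL
  subtypes <- unique(groups$group[groups$role == "endothelial_subtype"])
  atlas <- new("MethylAtlas", species = species, groups = groups,
               markers = markers, priors = priors,
               hierarchy = list(pan_group = panGroup, subtypes = subtypes),
               subsetSize = as.integer(subsetSize))
  validObject(atlas)
  atlas
}

#' Top variable blocks across samples
#'
#' Ranks blocks by the variance of their betas across samples, after
#' requiring at least \code{minCpgs} CpG sites and coverage (non-missing
#' beta) in at least \code{minCoverageFrac} of samples. Used to pick the
#' blocks driving atlas QC clustering.
#'
#' @param betas Blocks x samples beta matrix.
#' @param blocks Matching blocks \code{GRanges}.
#' @param n Number of blocks to return (default 30000).
#' @param minCpgs Minimum CpG sites per block (default 3).
#' @param minCoverageFrac Minimum fraction of samples covering the block
#'   (default 0.9).
#' @return List with \code{blocks} (the selected \code{GRanges}, variance
#'   order) and \code{betas} (their rows).
#' @export
selectTopVariableBlocks <- function(betas, blocks, n = 30000L, minCpgs = 3L,
                                    minCoverageFrac = 0.9) {
  stopifnot(nrow(betas) == length(blocks))
  mc <- mcols(blocks)
  ok <- mc$n_cpgs >= minCpgs &
    rowMeans(!is.na(betas)) >= minCoverageFrac
  v <- apply(betas, 1L, stats::var, na.rm = TRUE)
  v[!ok] <- -Inf
  o <- order(-v, seq_along(v))
  o <- o[seq_len(min(n, sum(ok)))]
  list(blocks = blocks[o], betas = betas[o, , drop = FALSE])
}

#' UPGMA clustering of sample methylomes
#'
#' Agglomerative clustering with average linkage (UPGMA) on pairwise L1
#' (manhattan) distances between sample beta profiles, computed over blocks
#' covered in every sample.
#'
#' @param betas Blocks x samples beta matrix.
#' @return List with \code{hclust} (merge heights equal UPGMA cluster
#'   distances), \code{phylo} (an [ape::as.phylo()] tree), and \code{dist}.
#' @export
upgmaTree <- function(betas) {
  shared <- stats::complete.cases(betas)
  d <- stats::dist(t(betas[shared, , drop = FALSE]), method = "manhattan")
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, phylo = ape::as.phylo(hc), dist = d)
}

#' Within- vs between-group distance ratio
#'
#' Mean L1 distance between samples of different groups divided by the mean
#' distance between samples of the same group; large values indicate that
#' cell identity dominates the methylome distances.
#'
#' @param betas Blocks x samples beta matrix.
#' @param labels Group label per sample (column).
#' @return The ratio (inter / intra).
#' @export
withinBetweenRatio <- function(betas, labels) {
  stopifnot(ncol(betas) == length(labels))
  shared <- stats::complete.cases(betas)
  d <- as.matrix(stats::dist(t(betas[shared, , drop = FALSE]),
                             method = "manhattan"))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  intra <- d[ut & same]
  inter <- d[ut & !same]
  if (!length(intra) || !length(inter))
    stop("need at least one within-group and one between-group pair")
  mean(inter) / mean(intra)
}
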