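# Synthetic data generator: reference methylomes with planted cell-type
# markers, serum-like cfDNA mixtures, lambda spike-ins, and dose-response
# study designs, all with recorded ground truth.

#' Specification of a synthetic reference atlas
#'
#' Describes the synthetic genome and reference cohort the generator
#' emulates: one CpG-indexed chromosome carrying marker blocks planted for
#' each cell type (hypo- or hypermethylated in the target type against a
#' common background level), a pan-endothelial tier shared by the
#' endothelial subtypes, and null blocks with no cell-type signal. Default
#' cell types mirror a serum cfDNA study: a leukocyte (bulk immune) group,
#' three solid-organ types, and two tissue-specific endothelial subtypes.
#'
#' @param groups \code{data.frame} with columns \code{group} and
#'   \code{role} (one row per leaf cell type).
#' @param panGroup Name of the pan-endothelial marker tier.
#' @param nMarkersPerType Marker blocks planted per leaf type (default 20).
#' @param nPanMarkers Pan-endothelial blocks (default 20).
#' @param nNullBlocks Blocks with no cell-type signal (default 50).
#' @param nReplicates Reference samples per leaf type (default 3).
#' @param cpgsPerBlock Range of CpG counts per block (default 3..15).
#' @param siteGapBp Spacing between CpGs within a block (default 30 bp).
#' @param blockGapBp Spacing between blocks (default 6000 bp, larger than
#'   the 5 kb segmentation span cap so blocks segment independently).
#' @param levelTarget,levelBackground Planted methylation levels on the
#'   marker side and the background side (defaults 0.05 / 0.85; hypo
#'   markers put the target type at \code{levelTarget}, hyper markers
#'   mirror them).
#' @param fracHypo Fraction of per-type markers planted hypomethylated
#'   (default 0.86, matching the hypo/hyper balance typical of cell-type
#'   marker catalogues).
#' @param sigma Within-type standard deviation of per-sample block levels
#'   (default 0.02).
#' @param coverage Mean per-site read depth (default 50).
#' @param fragsPerBlock Reference fragments per block per sample (default
#'   300; hybridization capture yields hundreds-fold depth at targeted
#'   blocks).
#' @param fragLen Range of CpGs covered per fragment (default 5..7: a
#'   ~167 bp molecule spans ~5.6 CpGs at the 30 bp within-block spacing).
#' @param errCT Inappropriate-conversion rate: probability a methylated C
#'   is read as T (default 0.005).
#' @param errTC Conversion-failure rate: probability an unmethylated C is
#'   read as C (default 0.005).
#' @param rho Within-fragment co-methylation persistence of the order-4
#'   emission chain, in \[0, 1) (default 0.1).
#' @param missingRate Per-interior-site probability of a missing call
#'   (default 0.02).
#' @param chrom Chromosome name (default \code{"chr1"}).
#' @param seed Integer seed; all generator randomness fans out from it.
#' @return A list of class \code{SyntheticAtlasSpec}.
#' @export
syntheticAtlasSpec <- function(
    groups = data.frame(
      group = c("leukocyte", "hepatocyte", "cardiomyocyte",
                "lung_epithelial", "cpec", "lsec"),
      role = c("bulk_immune", "solid_organ", "solid_organ", "solid_organ",
               "endothelial_subtype", "endothelial_subtype")),
    panGroup = "endothelial",
    nMarkersPerType = 20L, nPanMarkers = 20L, nNullBlocks = 50L,
    nReplicates = 3L, cpgsPerBlock = 3:15, siteGapBp = 30L,
    blockGapBp = 6000L, levelTarget = 0.05, levelBackground = 0.85,
    fracHypo = 0.86, sigma = 0.02, coverage = 50, fragsPerBlock = 300L,
    fragLen = 5:7, errCT = 0.005, errTC = 0.005, rho = 0.1,
    missingRate = 0.02, chrom = "chr1", seed = 1L) {
  stopifnot(levelTarget >= 0, levelTarget <= 1,
            levelBackground >= 0, levelBackground <= 1,
            fracHypo >= 0, fracHypo <= 1, sigma >= 0, rho >= 0, rho < 1,
            errCT >= 0, errCT < 1, errTC >= 0, errTC < 1)
  structure(as.list(environment()), class = "SyntheticAtlasSpec")
}

#' Specification of a synthetic cfDNA mixture
#'
#' True cell-type composition and sequencing characteristics of one
#' serum-like cfDNA sample: leukocyte-dominated with a ~10% endothelial
#' contribution and small solid-organ fractions, matching the prior
#' structure expected in healthy circulation.
#'
#' @param fractions Named true cell-type fractions (must cover the leaf
#'   groups of the atlas spec and sum to 1).
#' @param fragsPerMarker cfDNA fragments generated per marker block
#'   (default 200).
#' @param fragLen,errCT,errTC,rho,missingRate As in [syntheticAtlasSpec()].
#' @param concNgPerMl Total cfDNA concentration in ng/mL (default 10).
#' @param seed Integer seed.
#' @return A list of class \code{SyntheticMixtureSpec}.
#' @export
syntheticMixtureSpec <- function(
    fractions = c(leukocyte = 0.85, cpec = 0.06, lsec = 0.04,
                  hepatocyte = 0.02, cardiomyocyte = 0.02,
                  lung_epithelial = 0.01),
    fragsPerMarker = 200L, fragLen = 5:7, errCT = 0.005, errTC = 0.005,
    rho = 0.1, missingRate = 0.02, concNgPerMl = 10, seed = 1L) {
  stopifnot(all(fractions >= 0), abs(sum(fractions) - 1) < 1e-8)
  structure(as.list(environment()), class = "SyntheticMixtureSpec")
}

# Emit n fragment patterns from the 2-state order-4 co-methylation chain:
# P(methylated | context) = p + rho * (mean(context) - p), where the
# context is the up-to-4 previous true states. Conversion errors flip
# observed calls (C->T with errCT, T->C with errTC); interior sites go
# missing with missingRate. Returns patterns truncated to lens.
.emitPatterns <- function(lens, p, rho, errCT, errTC, missingRate) {
  n <- length(lens)
  if (n == 0L) return(character(0))
  maxlen <- max(lens)
  S <- matrix(FALSE, n, maxlen)
  for (j in seq_len(maxlen)) {
    pj <- if (j == 1L) p else {
      ctx <- rowMeans(S[, max(1L, j - 4L):(j - 1L), drop = FALSE])
      p + rho * (ctx - p)
    }
    pj <- pmin(pmax(pj, 0), 1)
    S[, j] <- stats::runif(n) < pj
  }
  obs <- ifelse(S, stats::runif(n * maxlen) >= errCT,
                stats::runif(n * maxlen) < errTC)
  ch <- matrix(ifelse(obs, "C", "T"), n, maxlen)
  if (missingRate > 0 && maxlen > 2L) {
    miss <- matrix(stats::runif(n * maxlen) < missingRate, n, maxlen)
    miss[, 1L] <- FALSE
    miss[cbind(seq_len(n), lens)] <- FALSE  # pattern ends stay called
    ch[miss] <- "."
  }
  full <- do.call(paste0, lapply(seq_len(maxlen), function(j) ch[, j]))
  substr(full, 1L, lens)
}

# sample() treats a scalar first argument as 1:x; these draws must not
.sampleFrom <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
}

# Draw fragment CpG spans within blocks: lengths from lenRange capped by
# block size, start offsets uniform. Returns data.frame(start, len).
.drawSpans <- function(blockIdx, blockCpgStart, blockNCpgs, lenRange) {
  ln <- pmin(.sampleFrom(lenRange, length(blockIdx)),
             blockNCpgs[blockIdx])
  off <- floor(stats::runif(length(blockIdx)) *
                 (blockNCpgs[blockIdx] - ln + 1L))
  data.frame(start = blockCpgStart[blockIdx] + as.integer(off), len = ln)
}

#' Generate a synthetic reference atlas
#'
#' Builds the CpG index map, the planted block truth table, the per-type
#' level matrix, and per-reference-sample BETA tracks and PAT fragments.
#' Deterministic under the spec's seed: the same spec yields byte-identical
#' outputs. In the noiseless case (\code{sigma == 0} and both error rates
#' 0) BETA counts are deterministic (depth exactly \code{coverage}, meth
#' counts rounded), so block betas equal the planted levels exactly.
#'
#' @param spec A [syntheticAtlasSpec()].
#' @param what \code{"both"} (default), \code{"beta"} or \code{"pat"}:
#'   which per-sample artifacts to generate.
#' @return List with \code{map} ([CpGIndexMap-class]), \code{blocks}
#'   (truth \code{GRanges} with kind/group/direction), \code{truth}
#'   (\code{data.frame} of planted markers), \code{levels} (types x blocks
#'   planted level matrix), \code{manifest}, \code{tracks} (named list of
#'   [MethylomeTrack-class]) and \code{pats} (named list of fragment
#'   \code{data.frame}s).
#' @export
generateReference <- function(spec, what = c("both", "beta", "pat")) {
  what <- match.arg(what)
  stopifnot(inherits(spec, "SyntheticAtlasSpec"))
  seeds <- childSeeds(spec$seed, 3L + 2L * nrow(spec$groups) * spec$nReplicates)

  # ---- genome layout and planted levels ----
  set.seed(seeds[1])
  types <- spec$groups$group
  nPerType <- rep(spec$nMarkersPerType, length(types))
  kinds <- c(rep("marker", sum(nPerType)), rep("pan", spec$nPanMarkers),
             rep("null", spec$nNullBlocks))
  blkGroup <- c(rep(types, nPerType), rep(spec$panGroup, spec$nPanMarkers),
                rep(NA_character_, spec$nNullBlocks))
  nHypo <- round(spec$fracHypo * spec$nMarkersPerType)
  blkDir <- c(unlist(lapply(types, function(g)
    rep(c("hypo", "hyper"), c(nHypo, spec$nMarkersPerType - nHypo)))),
    rep("hypo", spec$nPanMarkers), rep(NA_character_, spec$nNullBlocks))
  nBlocks <- length(kinds)
  nCpgsBlk <- .sampleFrom(spec$cpgsPerBlock, nBlocks)

  pos <- integer(0); cpgStart <- integer(nBlocks)
  at <- 1000L
  for (b in seq_len(nBlocks)) {
    cpgStart[b] <- length(pos)
    pos <- c(pos, at + spec$siteGapBp * (seq_len(nCpgsBlk[b]) - 1L))
    at <- at + spec$siteGapBp * (nCpgsBlk[b] - 1L) + spec$blockGapBp
  }
  cpgEnd <- cpgStart + nCpgsBlk
  map <- CpGIndexMap(rep(spec$chrom, length(pos)), pos)

  lv <- matrix(NA_real_, nrow = length(types), ncol = nBlocks,
               dimnames = list(types, NULL))
  endo <- spec$groups$group[spec$groups$role == "endothelial_subtype"]
  nullLevel <- stats::runif(nBlocks, 0.2, 0.8)
  for (b in seq_len(nBlocks)) {
    if (kinds[b] == "null") { lv[, b] <- nullLevel[b]; next }
    tgt <- if (kinds[b] == "pan") endo else blkGroup[b]
    lo <- spec$levelTarget; hi <- spec$levelBackground
    if (identical(blkDir[b], "hyper")) { lo <- hi; hi <- spec$levelTarget }
    lv[, b] <- hi
    lv[tgt, b] <- lo
  }

  truth <- data.frame(
    name = sprintf("planted_%03d", seq_len(nBlocks)), chrom = spec$chrom,
    start = pos[cpgStart + 1L], end = pos[cpgEnd] + 2L,
    cpg_start = cpgStart, cpg_end = cpgEnd, n_cpgs = nCpgsBlk,
    kind = kinds, group = blkGroup, direction = blkDir)
  blocks <- GRanges(truth$chrom, IRanges(start = truth$start + 1L,
                                         end = truth$end))
  mcols(blocks) <- truth[, c("name", "n_cpgs", "cpg_start", "cpg_end",
                             "kind", "group", "direction")]

  # ---- per-sample tracks and fragments ----
  manifest <- do.call(rbind, lapply(seq_along(types), function(i)
    data.frame(sample_id = sprintf("%s_rep%d", types[i],
                                   seq_len(spec$nReplicates)),
               group = types[i], role = spec$groups$role[i],
               species = "human")))
  deterministic <- spec$sigma == 0 && spec$errCT == 0 && spec$errTC == 0
  nSites <- nCpGs(map)
  siteBlock <- rep(seq_len(nBlocks), nCpgsBlk)
  tracks <- list(); pats <- list()
  for (si in seq_len(nrow(manifest))) {
    g <- manifest$group[si]
    set.seed(seeds[3L + si])
    sampleLv <- pmin(pmax(lv[g, ] + stats::rnorm(nBlocks, 0, spec$sigma),
                          0), 1)
    if (what %in% c("both", "beta")) {
      lvlSite <- sampleLv[siteBlock]
      lvlObs <- lvlSite * (1 - spec$errCT) + (1 - lvlSite) * spec$errTC
      if (deterministic) {
        total <- rep(spec$coverage, nSites)
        meth <- round(total * lvlObs)
      } else {
        total <- stats::rpois(nSites, spec$coverage)
        meth <- stats::rbinom(nSites, total, lvlObs)
      }
      tracks[[manifest$sample_id[si]]] <-
        MethylomeTrack(meth, total, manifest$sample_id[si])
    }
    if (what %in% c("both", "pat")) {
      set.seed(seeds[3L + nrow(manifest) + si])
      blockIdx <- rep(seq_len(nBlocks), each = spec$fragsPerBlock)
      sp <- .drawSpans(blockIdx, cpgStart, nCpgsBlk, spec$fragLen)
      pattern <- .emitPatterns(sp$len, sampleLv[blockIdx], spec$rho,
                               spec$errCT, spec$errTC, spec$missingRate)
      pats[[manifest$sample_id[si]]] <- aggregatePat(data.frame(
        chrom = spec$chrom, cpg_start = sp$start, pattern = pattern,
        count = 1))
    }
  }
  list(map = map, blocks = blocks, truth = truth, levels = lv,
       manifest = manifest, tracks = tracks, pats = pats, spec = spec)
}

#' Generate a synthetic cfDNA sample
#'
#' Draws cfDNA fragments over the reference atlas' marker blocks (the
#' capture panel): each fragment's cell type of origin follows the true
#' fraction vector, and its pattern is emitted from that type's planted
#' level at the block through the order-4 co-methylation chain with
#' conversion noise.
#'
#' @param mixSpec A [syntheticMixtureSpec()].
#' @param ref Output of [generateReference()].
#' @param panel Optional character vector of truth block names restricting
#'   the captured panel (e.g. one cell type's marker blocks for a mix-in
#'   pool); default: all planted marker blocks.
#' @return List with \code{pat} (fragments), \code{concNgPerMl},
#'   \code{truthFractions}, and \code{truthCounts} (realized per-type
#'   fragment counts).
#' @export
generateCfdna <- function(mixSpec, ref, panel = NULL) {
  stopifnot(inherits(mixSpec, "SyntheticMixtureSpec"))
  fr <- mixSpec$fractions
  miss <- setdiff(names(fr), rownames(ref$levels))
  if (length(miss))
    stop("mixture names cell types absent from the reference: ",
         paste(miss, collapse = ", "))
  set.seed(mixSpec$seed)
  inPanel <- if (is.null(panel)) ref$truth$kind != "null" else
    ref$truth$name %in% panel
  if (!any(inPanel)) stop("panel matches no planted blocks")
  tr <- ref$truth[inPanel, , drop = FALSE]
  nBlk <- nrow(tr)
  blockIdx <- rep(seq_len(nBlk), each = mixSpec$fragsPerMarker)
  n <- length(blockIdx)
  type <- sample(names(fr), n, replace = TRUE, prob = fr)
  sp <- .drawSpans(blockIdx, tr$cpg_start, tr$n_cpgs, mixSpec$fragLen)
  # levels matrix columns follow truth row order
  p <- ref$levels[cbind(match(type, rownames(ref$levels)),
                        which(inPanel)[blockIdx])]
  pattern <- .emitPatterns(sp$len, p, mixSpec$rho, mixSpec$errCT,
                           mixSpec$errTC, mixSpec$missingRate)
  pat <- aggregatePat(data.frame(chrom = tr$chrom[blockIdx],
                                 cpg_start = sp$start, pattern = pattern,
                                 count = 1))
  list(pat = pat, concNgPerMl = mixSpec$concNgPerMl, truthFractions = fr,
       truthCounts = table(type))
}

#' Generate an unmethylated lambda spike-in
#'
#' Emulates the unmethylated lambda phage DNA spiked into every library as
#' an internal bisulfite-conversion control: every site is truly
#' unmethylated, and a call reads \code{C} only on conversion failure.
#'
#' @param failureRate Per-site conversion failure probability.
#' @param nCalls Approximate total number of called sites to generate.
#' @param seed Integer seed.
#' @return Fragment \code{data.frame} on chromosome \code{"lambda"}.
#' @export
generateLambdaSpikein <- function(failureRate = 0.005, nCalls = 10000L,
                                  seed = 1L) {
  stopifnot(failureRate >= 0, failureRate <= 1)
  set.seed(seed)
  len <- 5L
  nFrag <- ceiling(nCalls / len)
  calls <- matrix(stats::runif(nFrag * len) < failureRate, nFrag, len)
  ch <- matrix(ifelse(calls, "C", "T"), nFrag, len)
  pattern <- do.call(paste0, lapply(seq_len(len), function(j) ch[, j]))
  start <- sample.int(2000L, nFrag, replace = TRUE) - 1L
  aggregatePat(data.frame(chrom = "lambda", cpg_start = start,
                          pattern = pattern, count = 1))
}

#' Generate a synthetic study with a planted dose response
#'
#' Emulates a radiation-injury style design (e.g. sham / 3 Gy / 8 Gy, or
#' serial baseline / end-of-treatment / recovery sampling): designated
#' target cell types release more cfDNA with dose, so their true fractions
#' scale monotonically with the dose metric while the remaining types are
#' renormalized.
#'
#' @param ref Output of [generateReference()].
#' @param mixSpec Baseline [syntheticMixtureSpec()].
#' @param doses Named numeric vector of condition dose levels (names are
#'   condition labels, values the dose metric).
#' @param nPerGroup Samples per condition (paired designs: subjects, each
#'   observed under every condition).
#' @param affected Cell types whose fractions increase with dose.
#' @param slope Per-unit-dose relative increase of affected fractions.
#' @param paired If \code{TRUE}, samples are organized as subjects crossed
#'   with conditions (complete pairs); otherwise independent groups.
#' @param seed Integer seed.
#' @return List with \code{samples} (named list of [generateCfdna()]
#'   outputs), \code{design} (\code{data.frame} with \code{sample_id},
#'   \code{condition}, \code{dose}, \code{subject}), and \code{truth}
#'   (per-sample true fraction matrix).
#' @export
generateStudy <- function(ref, mixSpec = syntheticMixtureSpec(),
                          doses = c(sham = 0, gy3 = 3, gy8 = 8),
                          nPerGroup = 3L,
                          affected = c("lung_epithelial", "cardiomyocyte"),
                          slope = 1, paired = FALSE, seed = 1L) {
  stopifnot(all(affected %in% names(mixSpec$fractions)))
  seeds <- childSeeds(seed, length(doses) * nPerGroup + 1L)
  set.seed(seeds[1])
  subjEffect <- stats::runif(nPerGroup, 0.8, 1.2)  # subject-level scaling
  samples <- list(); design <- list(); truthRows <- list()
  k <- 0L
  for (ci in seq_along(doses)) {
    for (r in seq_len(nPerGroup)) {
      k <- k + 1L
      fr <- mixSpec$fractions
      bump <- 1 + slope * doses[ci] * (if (paired) subjEffect[r] else 1)
      fr[affected] <- fr[affected] * bump
      fr <- fr / sum(fr)
      sid <- sprintf("%s_s%02d", names(doses)[ci], r)
      ms <- mixSpec
      ms$fractions <- fr
      ms$seed <- seeds[1L + k]
      samples[[sid]] <- generateCfdna(ms, ref)
      design[[k]] <- data.frame(
        sample_id = sid, condition = names(doses)[ci], dose = doses[[ci]],
        subject = if (paired) sprintf("subj%02d", r) else NA_character_)
      truthRows[[k]] <- fr
    }
  }
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- vapply(design, function(d) d$sample_id, "")
  list(samples = samples, design = do.call(rbind, design), truth = truth)
}
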