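#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
NULL

#' CpG index map
#'
#' Coordinate system linking global CpG indices to genomic positions. CpG
#' sites are numbered consecutively (0-based internally) along the ordered
#' genome; fragment-level records and methylation blocks are addressed in
#' this index space rather than in base pairs.
#'
#' @slot sites A [GenomicRanges::GRanges] with one width-1 range per CpG
#'   site, in genome order. The global CpG index of site \code{i} is
#'   \code{i - 1}.
#' @export
setClass("CpGIndexMap", representation(sites = "GRanges"))

setValidity("CpGIndexMap", function(object) {
  gr <- object@sites
  if (length(gr) == 0L) return("map contains no CpG sites")
  ch <- as.character(seqnames(gr))
  if (length(rle(ch)$values) != length(unique(ch)))
    return("CpG sites must be grouped by chromosome")
  pos <- start(gr)
  bad <- which(ch[-1] == ch[-length(ch)] & diff(pos) <= 0)
  if (length(bad))
    return(sprintf("positions not strictly increasing at site %d", bad[1] + 1L))
  TRUE
})

#' Construct a CpG index map
#'
#' @param chrom Character vector of chromosome names, one per CpG site
#'   (grouped by chromosome, genome order).
#' @param pos Integer vector of 0-based genomic positions of the C of each
#'   CpG, strictly increasing within a chromosome.
#' @return A [CpGIndexMap-class] object.
#' @examples
#' map <- CpGIndexMap(rep("chr1", 5), c(10L, 40L, 90L, 120L, 500L))
#' nCpGs(map)
#' @export
CpGIndexMap <- function(chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  gr <- GRanges(chrom, IRanges(start = as.integer(pos) + 1L, width = 1L))
  new("CpGIndexMap", sites = gr)
}

#' Per-sample methylome track
#'
#' Per-CpG observation counts for one sample: the number of methylated
#' calls and the total number of calls at every site of a
#' [CpGIndexMap-class]. Sites with \code{total == 0} are uncovered.
#'
#' @slot meth Integer vector, methylated call count per CpG site.
#' @slot total Integer vector, total call count per CpG site.
#' @slot sampleId Character scalar sample identifier.
#' @export
setClass("MethylomeTrack", representation(
  meth = "numeric", total = "numeric", sampleId = "character"))

setValidity("MethylomeTrack", function(object) {
  if (length(object@meth) != length(object@total))
    return("meth and total must have equal length")
  if (any(object@meth < 0) || any(object@total < 0))
    return("counts must be non-negative")
  bad <- which(object@meth > object@total)
  if (length(bad))
    return(sprintf("meth > total at site index %d (0-based %d)",
                   bad[1], bad[1] - 1L))
  TRUE
})

#' Construct a methylome track
#'
#' @param meth,total Non-negative count vectors of equal length with
#'   \code{meth <= total} sitewise.
#' @param sampleId Sample identifier.
#' @return A [MethylomeTrack-class].
#' @export
MethylomeTrack <- function(meth, total, sampleId = NA_character_) {
  new("MethylomeTrack", meth = as.numeric(meth), total = as.numeric(total),
      sampleId = as.character(sampleId))
}

#' Cell-type methylation atlas
#'
#' Bundles the reference group definitions, the selected cell-type-specific
#' differentially methylated blocks (markers), the per-tier prior
#' probabilities used by the fragment classifier, and the marker-group
#' hierarchy (bulk immune vs solid organ; pan-endothelial vs
#' tissue-specific endothelial subtypes).
#'
#' @slot species \code{"human"} or \code{"mouse"}.
#' @slot groups \code{data.frame} with columns \code{sample_id},
#'   \code{group}, \code{role}; every reference sample belongs to exactly
#'   one leaf group. Roles are one of \code{bulk_immune},
#'   \code{solid_organ}, \code{pan_endothelial}, \code{endothelial_subtype},
#'   \code{plain}.
#' @slot markers \code{data.frame} of marker blocks (one row per block and
#'   target group) with genomic and CpG-index coordinates, direction,
#'   delta-beta, soft margin and methylation score.
#' @slot priors Named numeric vector of per-role classifier priors in (0,1).
#' @slot hierarchy List with elements \code{pan_group} (name of the
#'   pan-endothelial group, or \code{NA}) and \code{subtypes} (character
#'   vector of endothelial subtype groups).
#' @slot subsetSize Maximum markers retained per group for deconvolution.
#' @export
setClass("MethylAtlas", representation(
  species = "character", groups = "data.frame", markers = "data.frame",
  priors = "numeric", hierarchy = "list", subsetSize = "integer"))

setValidity("MethylAtlas", function(object) {
  if (!object@species %in% c("human", "mouse"))
    return("species must be 'human' or 'mouse'")
  if (any(object@priors <= 0 | object@priors >= 1))
    return("priors must lie strictly in (0,1)")
  if (anyDuplicated(object@groups$sample_id))
    return("each sample must belong to exactly one leaf group")
  st <- object@hierarchy$subtypes
  m <- object@markers
  if (length(st) > 1L && nrow(m)) {
    sub <- m[m$group %in% st, , drop = FALSE]
    if (nrow(sub) > 1L) {
      # overlap = same block claimed by two different subtype groups
      key <- paste(sub$chrom, sub$cpg_start, sub$cpg_end)
      bygrp <- lapply(split(key, sub$group), unique)
      shared <- unique(unlist(bygrp))[tabulate(match(unlist(bygrp),
                  unique(unlist(bygrp)))) > 1L]
      if (length(shared))
        return(paste0("endothelial-subtype marker sets overlap at block(s): ",
                      paste(shared, collapse = "; ")))
    }
  }
  TRUE
})

#' Fourth-order Markov model for one marker block
#'
#' Conditional probability tables P(site methylated | up to 4 previous
#' called sites within the fragment) for the target cell type and the
#' pooled background, estimated from reference fragments clipped to the
#' marker, with additive smoothing and back-off to lower-order contexts.
#'
#' @slot markerId Character identifier of the marker block.
#' @slot order Markov order (4).
#' @slot pseudocount Additive smoothing pseudocount per outcome.
#' @slot target,background Named lists mapping \code{"k"} plus the context
#'   string (previous called states, most recent last; the bare \code{"k"}
#'   is the order-0 context of a fragment's first site) to a numeric
#'   \code{c(C = , T = )} count pair.
#' @slot nTarget,nBackground Training fragment totals (weighted).
#' @export
setClass("MarkovMarkerModel", representation(
  markerId = "character", order = "integer", pseudocount = "numeric",
  target = "list", background = "list",
  nTarget = "numeric", nBackground = "numeric"))

#' Deconvolution result
#'
#' Per-cell-type output of fragment-level deconvolution: raw
#' assigned-fragment proportions (averaged over markers), normalized
#' fractions summing to 1 over the composition tier, endothelial subtype
#' fractions rescaled within the pan-endothelial fraction, and genome
#' equivalents per mL serum.
#'
#' @slot table \code{data.frame} with columns \code{group}, \code{role},
#'   \code{n_markers}, \code{n_fragments}, \code{raw_proportion},
#'   \code{fraction}, \code{geq_per_ml}, \code{in_composition}.
#' @slot species \code{"human"} or \code{"mouse"}.
#' @slot concNgPerMl cfDNA concentration used for the Geq/mL conversion.
#' @slot priors Named per-role priors used.
#' @export
setClass("DeconvResult", representation(
  table = "data.frame", species = "character", concNgPerMl = "numeric",
  priors = "numeric"))

setValidity("DeconvResult", function(object) {
  tab <- object@table
  fr <- tab$fraction[tab$in_composition]
  if (length(fr) && all(!is.na(fr)) && abs(sum(fr) - 1) > 1e-8)
    return("normalized fractions must sum to 1")
  TRUE
})

setMethod("show", "CpGIndexMap", function(object) {
  ch <- unique(as.character(seqnames(object@sites)))
  cat("CpGIndexMap:", length(object@sites), "CpG sites on",
      length(ch), "chromosome(s)\n")
})

setMethod("show", "MethylomeTrack", function(object) {
  cov <- object@total > 0
  cat(sprintf("MethylomeTrack '%s': %d sites, %.1f%% covered, mean depth %.1f\n",
              object@sampleId, length(object@total), 100 * mean(cov),
              if (any(cov)) mean(object@total[cov]) else 0))
})

setMethod("show", "MethylAtlas", function(object) {
  cat(sprintf("MethylAtlas (%s): %d samples in %d leaf groups, %d markers\n",
              object@species, nrow(object@groups),
              length(unique(object@groups$group)), nrow(object@markers)))
  if (nrow(object@markers)) {
    tb <- table(object@markers$group)
    cat("  markers per group:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})

setMethod("show", "MarkovMarkerModel", function(object) {
  cat(sprintf(paste0("MarkovMarkerModel '%s' (order %d, pseudocount %g): ",
                     "%d/%d target/background contexts\n"),
              object@markerId, object@order, object@pseudocount,
              length(object@target), length(object@background)))
})

setMethod("show", "DeconvResult", function(object) {
  cat(sprintf("DeconvResult (%s, %.3g ng/mL):\n", object@species,
              object@concNgPerMl))
  print(object@table, row.names = FALSE, digits = 4)
})
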