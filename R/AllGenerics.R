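#' Number of CpG sites in a map or track
#' @param x A [CpGIndexMap-class] or [MethylomeTrack-class].
#' @return Integer.
#' @export
setGeneric("nCpGs", function(x) standardGeneric("nCpGs"))

#' @rdname nCpGs
#' @export
setMethod("nCpGs", "CpGIndexMap", function(x) length(x@sites))

#' @rdname nCpGs
#' @export
setMethod("nCpGs", "MethylomeTrack", function(x) length(x@total))

#' Genomic positions of CpG sites
#' @param x A [CpGIndexMap-class].
#' @return Integer vector of 0-based genomic positions, one per global CpG
#'   index.
#' @export
setGeneric("cpgBp", function(x) standardGeneric("cpgBp"))

#' @rdname cpgBp
#' @export
setMethod("cpgBp", "CpGIndexMap",
          function(x) GenomicRanges::start(x@sites) - 1L)

#' Chromosome of each CpG site
#' @param x A [CpGIndexMap-class].
#' @return Character vector, one per global CpG index.
#' @export
setGeneric("cpgChrom", function(x) standardGeneric("cpgChrom"))

#' @rdname cpgChrom
#' @export
setMethod("cpgChrom", "CpGIndexMap",
          function(x) as.character(GenomicRanges::seqnames(x@sites)))

#' Methylated / total call counts of a track
#' @param x A [MethylomeTrack-class].
#' @return Numeric vector, one entry per CpG site.
#' @export
setGeneric("methCounts", function(x) standardGeneric("methCounts"))

#' @rdname methCounts
#' @export
setMethod("methCounts", "MethylomeTrack", function(x) x@meth)

#' @rdname methCounts
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname methCounts
#' @export
setMethod("totalCounts", "MethylomeTrack", function(x) x@total)

#' @rdname methCounts
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname methCounts
#' @export
setMethod("sampleId", "MethylomeTrack", function(x) x@sampleId)

#' Atlas accessors
#' @param x A [MethylAtlas-class].
#' @return \code{atlasMarkers}: marker \code{data.frame}; \code{atlasGroups}:
#'   sample-to-group \code{data.frame}; \code{atlasPriors}: named priors;
#'   \code{atlasSpecies}: species string; \code{atlasHierarchy}: hierarchy
#'   list.
#' @export
setGeneric("atlasMarkers", function(x) standardGeneric("atlasMarkers"))
#' @rdname atlasMarkers
#' @export
setMethod("atlasMarkers", "MethylAtlas", function(x) x@markers)
#' @rdname atlasMarkers
#' @export
setGeneric("atlasGroups", function(x) standardGeneric("atlasGroups"))
#' @rdname atlasMarkers
#' @export
setMethod("atlasGroups", "MethylAtlas", function(x) x@groups)
#' @rdname atlasMarkers
#' @export
setGeneric("atlasPriors", function(x) standardGeneric("atlasPriors"))
#' @rdname atlasMarkers
#' @export
setMethod("atlasPriors", "MethylAtlas", function(x) x@priors)
#' @rdname atlasMarkers
#' @export
setGeneric("atlasSpecies", function(x) standardGeneric("atlasSpecies"))
#' @rdname atlasMarkers
#' @export
setMethod("atlasSpecies", "MethylAtlas", function(x) x@species)
#' @rdname atlasMarkers
#' @export
setGeneric("atlasHierarchy", function(x) standardGeneric("atlasHierarchy"))
#' @rdname atlasMarkers
#' @export
setMethod("atlasHierarchy", "MethylAtlas", function(x) x@hierarchy)

#' Deconvolution result accessors
#' @param x A [DeconvResult-class].
#' @return \code{resultTable}: the full per-group \code{data.frame};
#'   \code{cellTypeFractions}: named numeric vector of normalized fractions
#'   (composition groups plus rescaled endothelial subtypes).
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
#' @rdname resultTable
#' @export
setMethod("resultTable", "DeconvResult", function(x) x@table)
#' @rdname resultTable
#' @export
setGeneric("cellTypeFractions", function(x) standardGeneric("cellTypeFractions"))
#' @rdname resultTable
#' @export
setMethod("cellTypeFractions", "DeconvResult", function(x) {
  stats::setNames(x@table$fraction, x@table$group)
})
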