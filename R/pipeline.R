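# End-to-end orchestration: segment -> build atlas -> train -> deconvolve
# -> report, plus study-level group statistics on deconvolved outputs.

#' Pipeline configuration
#'
#' Bundles all stage parameters with their standard defaults: 5 kb
#' segmentation span cap, soft-margin threshold 0.4 (human) / 0.35 (mouse),
#' classifier priors 0.85 immune / 0.10 endothelial / 0.05 other solid
#' organs, a 200-marker deconvolution subset, and the default synthetic
#' study conditions.
#'
#' @param species \code{"human"} or \code{"mouse"}.
#' @param seed Master seed; every stage derives child seeds from it.
#' @param outDir Output directory (created if needed).
#' @param atlasSpec A [syntheticAtlasSpec()] describing the reference
#'   cohort.
#' @param mixtureSpec A [syntheticMixtureSpec()] describing the serum
#'   samples.
#' @param nSamples Number of cfDNA samples to simulate and deconvolve.
#' @param segConfig A [segmentationConfig()].
#' @param margin Soft-margin threshold (\code{NULL}: species default).
#' @param subsetSize Markers per group used for deconvolution.
#' @param minCalled Minimum called in-block sites per classified fragment.
#' @param lambdaCalls Called sites to generate for the conversion-control
#'   spike-in (0 disables it).
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(species = "human", seed = 1L, outDir = NULL,
                           atlasSpec = syntheticAtlasSpec(),
                           mixtureSpec = syntheticMixtureSpec(),
                           nSamples = 3L,
                           segConfig = segmentationConfig(),
                           margin = NULL, subsetSize = 200L,
                           minCalled = 5L, lambdaCalls = 10000L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

.provenance <- function(config) {
  cfg <- config
  cfg$outDir <- NULL  # location must not affect the content hash
  sprintf("cfOrigins %s | seed=%d | config_md5=%s",
          as.character(utils::packageVersion("cfOrigins")),
          as.integer(config$seed),
          md5OfString(paste(utils::capture.output(utils::str(cfg)),
                            collapse = "\n")))
}

#' Run the full synthetic pipeline
#'
#' Executes every stage on generated data: reference methylomes,
#' multichannel segmentation, candidate filtering and one-vs-all marker
#' selection, hierarchical atlas assembly with methylation scores, Markov
#' model training, cfDNA simulation, fragment-level deconvolution, and QC
#' (conversion efficiency from the lambda spike-in; UPGMA clustering of the
#' reference). All outputs land in \code{config$outDir} as headered text
#' files; a fixed seed yields byte-identical outputs across runs.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a result bundle: \code{ref}, \code{blocks},
#'   \code{atlas}, \code{models}, \code{results} (list of
#'   [DeconvResult-class]), \code{samples}, \code{conversionEfficiency},
#'   \code{clusterRatio}, \code{outDir}, \code{config}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  outDir <- if (is.null(config$outDir)) tempfile("cfOrigins_run_") else
    config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(config)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[cfOrigins] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- childSeeds(config$seed, 4L + config$nSamples)

  say("stage reference: generating synthetic reference atlas")
  spec <- config$atlasSpec
  spec$seed <- seeds[1]
  ref <- stage("reference", generateReference(spec))
  say("reference: %d samples, %d blocks, %d CpGs", length(ref$tracks),
      nrow(ref$truth), nCpGs(ref$map))

  say("stage segment: multichannel dynamic-programming segmentation")
  blocks <- stage("segment",
                  segmentMethylome(ref$tracks, ref$map, config$segConfig))
  say("segment: %d blocks (span cap %d bp)", length(blocks),
      config$segConfig$maxBp)

  say("stage build-atlas: betas, candidate filter, one-vs-all markers")
  atlas <- stage("build-atlas", {
    betas <- blockBetaMatrix(ref$tracks, blocks)
    obs <- blockFragmentCounts(ref$pats, blocks)
    cand <- candidateFilter(blocks)
    keep <- mcols(blocks)$name %in% mcols(cand)$name
    groupSets <- split(ref$manifest$sample_id, ref$manifest$group)
    endo <- ref$manifest$sample_id[ref$manifest$role == "endothelial_subtype"]
    if (length(endo)) groupSets[[spec$panGroup]] <- endo
    markers <- selectMarkers(blocks[keep], betas[keep, , drop = FALSE],
                             ref$manifest, species = config$species,
                             margin = config$margin,
                             groupSampleSets = groupSets,
                             obsCounts = obs[keep, , drop = FALSE])
    pooled <- lapply(split(ref$manifest$sample_id, ref$manifest$group),
                     function(ids) do.call(rbind, ref$pats[ids]))
    if (length(endo)) pooled[[spec$panGroup]] <- do.call(rbind, ref$pats[endo])
    markers$score <- vapply(seq_len(nrow(markers)), function(i)
      methylationScore(pooled[[markers$group[i]]], markers$cpg_start[i],
                       markers$cpg_end[i], markers$direction[i]), 1.0)
    buildHierarchicalAtlas(markers, ref$manifest[, c("sample_id", "group",
                                                     "role")],
                           species = config$species,
                           panGroup = spec$panGroup,
                           subsetSize = config$subsetSize)
  })
  say("build-atlas: %d markers across %d groups", nrow(atlasMarkers(atlas)),
      length(unique(atlasMarkers(atlas)$group)))

  say("stage train: fourth-order Markov marker models")
  models <- stage("train", trainAtlasModels(atlas, ref$pats))

  say("stage deconvolve: %d synthetic serum samples", config$nSamples)
  samples <- list(); results <- list()
  for (i in seq_len(config$nSamples)) {
    ms <- config$mixtureSpec
    ms$seed <- seeds[4L + i]
    sid <- sprintf("serum_%02d", i)
    samples[[sid]] <- stage("simulate-cfdna", generateCfdna(ms, ref))
    results[[sid]] <- stage("deconvolve",
                            deconvolve(samples[[sid]]$pat, atlas, models,
                                       samples[[sid]]$concNgPerMl,
                                       minCalled = config$minCalled,
                                       cpgMap = ref$map))
  }

  conv <- NA_real_
  if (config$lambdaCalls > 0) {
    spike <- generateLambdaSpikein(config$atlasSpec$errTC,
                                   config$lambdaCalls, seed = seeds[2])
    conv <- conversionEfficiency(spike)
    say("qc: conversion efficiency %.4f", conv)
  }
  qc <- stage("qc", {
    betas <- blockBetaMatrix(ref$tracks, blocks)
    top <- selectTopVariableBlocks(betas, blocks,
                                   n = min(30000L, length(blocks)))
    withinBetweenRatio(top$betas, ref$manifest$group)
  })
  say("qc: within/between cluster distance ratio %.2f", qc)

  say("stage report: writing outputs")
  writeBlocksBed(blocks, file.path(outDir, "blocks.bed"), header = prov)
  writeAtlas(atlas, file.path(outDir, "atlas"))
  writeManifest(ref$manifest, file.path(outDir, "manifest.tsv"))
  for (sid in names(results)) {
    tab <- resultTable(results[[sid]])
    f <- file.path(outDir, paste0(sid, "_deconv.tsv"))
    con <- file(f, "wt")
    writeLines(paste0("#", prov), con)
    close(con)
    suppressWarnings(utils::write.table(
      tab, f, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  }
  qcdf <- data.frame(metric = c("conversion_efficiency",
                                "within_between_ratio", "n_blocks",
                                "n_markers"),
                     value = c(conv, qc, length(blocks),
                               nrow(atlasMarkers(atlas))))
  utils::write.table(qcdf, file.path(outDir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("#", prov), log), file.path(outDir, "run.log"))

  invisible(list(ref = ref, blocks = blocks, atlas = atlas, models = models,
                 samples = samples, results = results,
                 conversionEfficiency = conv, clusterRatio = qc,
                 outDir = outDir, config = config))
}

#' Group statistics on deconvolved outputs
#'
#' Applies the design-appropriate standard test per cell type to
#' deconvolved values (typically Geq/mL): Kruskal-Wallis for unpaired
#' multi-group comparisons, Friedman for paired repeated measures, Wilcoxon
#' signed-rank for paired two-condition comparisons, and Spearman's rank
#' correlation for dose associations. P values are adjusted across cell
#' types with Benjamini-Hochberg.
#'
#' @param results Long \code{data.frame} with columns \code{sample_id},
#'   \code{cell_type}, \code{value}.
#' @param design \code{data.frame} with columns \code{sample_id},
#'   \code{condition}, and optionally \code{subject} (pairing) and
#'   \code{dose}.
#' @param test \code{"auto"} picks by design shape; or force one of
#'   \code{"kruskal"}, \code{"friedman"}, \code{"wilcoxon"},
#'   \code{"spearman"}.
#' @return \code{data.frame}: cell_type, test, statistic, p_value, p_adj.
#' @export
runGroupTests <- function(results, design,
                          test = c("auto", "kruskal", "friedman",
                                   "wilcoxon", "spearman")) {
  test <- match.arg(test)
  stopifnot(all(c("sample_id", "cell_type", "value") %in% names(results)),
            all(c("sample_id", "condition") %in% names(design)))
  d <- merge(results, design, by = "sample_id")
  paired <- !is.null(design$subject) && !all(is.na(design$subject))
  nCond <- length(unique(design$condition))
  if (test == "auto")
    test <- if (!paired) "kruskal"
    else if (nCond == 2L) "wilcoxon" else "friedman"
  if (test %in% c("friedman", "wilcoxon")) {
    if (!paired) stop("paired test requested but design has no subjects")
    tab <- table(design$subject, design$condition)
    bad <- rownames(tab)[apply(tab != 1L, 1L, any)]
    if (length(bad))
      stop("paired tests require complete pairs; incomplete subject(s): ",
           paste(bad, collapse = ", "))
  }
  if (test == "spearman" && is.null(d$dose))
    stop("Spearman dose association requires a 'dose' column in the design")
  out <- do.call(rbind, lapply(split(d, d$cell_type), function(x) {
    res <- if (length(unique(x$value)) == 1L) c(NA_real_, 1) else switch(test,
      kruskal = {
        h <- stats::kruskal.test(x$value, factor(x$condition))
        c(h$statistic, h$p.value)
      },
      friedman = {
        h <- stats::friedman.test(x$value, factor(x$condition),
                                  factor(x$subject))
        c(h$statistic, h$p.value)
      },
      wilcoxon = {
        x <- x[order(x$subject, x$condition), ]
        conds <- sort(unique(x$condition))
        a <- x$value[x$condition == conds[1]]
        b <- x$value[x$condition == conds[2]]
        h <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
        c(h$statistic, h$p.value)
      },
      spearman = {
        h <- suppressWarnings(stats::cor.test(x$value, x$dose,
                                              method = "spearman"))
        c(h$estimate, h$p.value)
      })
    data.frame(cell_type = x$cell_type[1], test = test,
               statistic = unname(res[1]), p_value = unname(res[2]))
  }))
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Human-readable pipeline summary
#'
#' Summarises a pipeline run: QC (conversion efficiency, fragment counts),
#' per-sample cell-type fractions and Geq/mL, per-cell-type fold changes
#' relative to a baseline condition when a study design is supplied (fold
#' changes are computed per subject and then averaged; zero baselines are
#' floored at the smallest positive value observed, noted in the report),
#' and mix-in recovery when a report is supplied.
#'
#' @param bundle Result bundle from [runPipeline()].
#' @param design Optional study design (see [runGroupTests()]) with a
#'   \code{condition} column whose first level is the baseline.
#' @param mixinReport Optional \code{MixinReport}.
#' @param file Optional path; when given the report is also written there.
#' @return Character vector of report lines, invisibly when \code{file} is
#'   given.
#' @export
makeReport <- function(bundle, design = NULL, mixinReport = NULL,
                       file = NULL) {
  lines <- c("cfOrigins pipeline report",
             strrep("=", 25), "")
  lines <- c(lines, sprintf("Conversion efficiency (lambda spike-in): %s",
                            ifelse(is.na(bundle$conversionEfficiency), "n/a",
                                   sprintf("%.4f",
                                           bundle$conversionEfficiency))))
  lines <- c(lines, sprintf("Reference clustering within/between ratio: %.2f",
                            bundle$clusterRatio),
             sprintf("Blocks: %d; markers: %d", length(bundle$blocks),
                     nrow(atlasMarkers(bundle$atlas))), "")
  for (sid in names(bundle$results)) {
    tab <- resultTable(bundle$results[[sid]])
    lines <- c(lines, sprintf("Sample %s (%d fragments):", sid,
                              sum(bundle$samples[[sid]]$pat$count)))
    lines <- c(lines, sprintf("  %-16s fraction %6.4f   %10.1f Geq/mL",
                              tab$group, tab$fraction, tab$geq_per_ml), "")
  }
  if (!is.null(design)) {
    long <- do.call(rbind, lapply(names(bundle$results), function(sid) {
      tab <- resultTable(bundle$results[[sid]])
      data.frame(sample_id = sid, cell_type = tab$group,
                 value = tab$geq_per_ml)
    }))
    long <- merge(long, design, by = "sample_id")
    base <- design$condition[1]
    if (!is.null(design$subject) && !all(is.na(design$subject))) {
      lines <- c(lines, sprintf("Fold change relative to '%s':", base))
      floorv <- min(long$value[long$value > 0])
      for (ct in unique(long$cell_type)) {
        x <- long[long$cell_type == ct, ]
        fc <- unlist(lapply(split(x, x$subject), function(s) {
          b <- max(s$value[s$condition == base], floorv)
          s$value[s$condition != base] / b
        }))
        lines <- c(lines, sprintf("  %-16s mean fold change %.2f (SEM %.2f)",
                                  ct, mean(fc),
                                  stats::sd(fc) / sqrt(length(fc))))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(mixinReport)) {
    lines <- c(lines, sprintf("Mix-in recovery (%s):",
                              mixinReport$target_group))
    s <- mixinReport$summary
    lines <- c(lines, sprintf("  ratio %7.4f  predicted %7.4f +/- %s",
                              s$ratio, s$mean_pred,
                              ifelse(is.na(s$sd_pred), "NA",
                                     sprintf("%.4f", s$sd_pred))))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
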