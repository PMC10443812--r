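# In-silico mix-in validation: spike known proportions of target-cell
# fragments into a leukocyte background, deconvolve, and report recovery.

#' Mix-in experiment design
#'
#' @param ratios Admixture ratios as fragment-count fractions (default the
#'   standard grid 0.05%, 0.1%, 0.5%, 1%, 2%, 5%, 10%, 15%).
#' @param replicates Replicates per ratio (default 3).
#' @param totalN Total fragments per mixture; the default \code{NULL}
#'   resolves to 200 fragments per marker of the atlas panel.
#' @param includeZero Include a zero-admixture (pure background) control
#'   row (default \code{TRUE}).
#' @param seed Integer seed; each replicate gets a fanned-out child seed,
#'   shared across ratios (common random streams), so recovery curves are
#'   comparable within a replicate.
#' @return A list of class \code{MixinDesign}.
#' @export
mixinDesign <- function(ratios = c(0.0005, 0.001, 0.005, 0.01, 0.02,
                                   0.05, 0.10, 0.15),
                        replicates = 3L, totalN = NULL,
                        includeZero = TRUE, seed = 1L) {
  stopifnot(all(ratios > 0), all(ratios < 1), replicates >= 1,
            is.null(totalN) || totalN >= 1)
  structure(list(ratios = ratios, replicates = as.integer(replicates),
                 totalN = if (is.null(totalN)) NULL else as.integer(totalN),
                 includeZero = includeZero, seed = as.integer(seed)),
            class = "MixinDesign")
}

#' Mix target fragments into a background pool
#'
#' Samples \code{round(ratio * totalN)} molecules (round half to even) from
#' the target pool and the remainder from the background pool, without
#' replacement when the pools suffice (falling back to sampling with
#' replacement, with a message, when they do not). Ratios are
#' fragment-count fractions, not mass fractions.
#'
#' @param targetPat,backgroundPat Fragment \code{data.frame}s (multiplicity
#'   in \code{count} is expanded to molecules before sampling).
#' @param ratio Target admixture fraction in \[0, 1).
#' @param totalN Total molecules in the mixture.
#' @param seed Integer seed.
#' @return Mixed, aggregated, sorted fragment \code{data.frame} with
#'   attribute \code{realized = c(target, background)}.
#' @export
mixFragments <- function(targetPat, backgroundPat, ratio, totalN, seed = 1L) {
  stopifnot(ratio >= 0, ratio < 1, totalN >= 1)
  set.seed(seed)
  targetN <- as.integer(round(ratio * totalN))
  bgN <- totalN - targetN
  if (ratio > 0 && targetN == 0L)
    warning("ratio ", ratio, " rounds to zero target fragments: mixture is pure background")
  drawFrom <- function(pat, n, what) {
    # the full pool is permuted and a prefix taken, so under one seed the
    # molecules drawn at a smaller n are a subset of those at a larger n
    # (common random streams across admixture ratios)
    idx <- rep(seq_len(nrow(pat)), pat$count)
    if (length(idx) >= n) take <- sample(idx)[seq_len(n)] else {
      message("sampling ", what, " pool (", length(idx),
              " molecules) with replacement to reach ", n)
      take <- sample(idx, n, replace = TRUE)
    }
    if (n == 0L) return(pat[integer(0), , drop = FALSE])
    out <- pat[take, , drop = FALSE]
    out$count <- 1
    out
  }
  mixed <- rbind(drawFrom(targetPat, targetN, "target"),
                 drawFrom(backgroundPat, bgN, "background"))
  mixed <- aggregatePat(mixed)
  attr(mixed, "realized") <- c(target = targetN, background = bgN)
  mixed
}

#' Run an in-silico mix-in experiment
#'
#' For each admixture ratio and replicate, mixes target fragments into the
#' leukocyte background over the atlas' full marker panel, deconvolves the
#' mixture, and reports the average predicted (normalized) proportion of
#' the target cell type with its standard deviation across replicates,
#' together with a zero-admixture control. Reproducible bit-for-bit under a
#' fixed design seed.
#'
#' @param design A [mixinDesign()].
#' @param atlas A [MethylAtlas-class] containing markers for
#'   \code{targetGroup}.
#' @param models Trained models from [trainAtlasModels()].
#' @param targetGroup Cell type being spiked in.
#' @param targetPat Pure target-cell fragment pool over the atlas panel.
#' @param backgroundPat Leukocyte (buffy-coat-like) background pool over
#'   the atlas panel.
#' @param minCalled Minimum called in-block sites per classified fragment.
#' @return List of class \code{MixinReport} with \code{summary}
#'   (\code{data.frame}: ratio, truth, n, mean_pred, sd_pred) and
#'   \code{replicates} (per-replicate predictions).
#' @export
runMixinExperiment <- function(design, atlas, models, targetGroup,
                               targetPat, backgroundPat, minCalled = 5L) {
  stopifnot(inherits(design, "MixinDesign"))
  m <- atlasMarkers(atlas)
  if (!any(m$group == targetGroup))
    stop("cell type '", targetGroup, "' has no markers in the atlas")
  ratios <- c(if (design$includeZero) 0, design$ratios)
  totalN <- if (is.null(design$totalN)) 200L * nrow(m) else design$totalN
  # one child seed per replicate, shared across ratios: within a replicate
  # the mixtures are nested, so the recovery curve is monotone up to
  # classification noise rather than resampling noise
  seeds <- childSeeds(design$seed, design$replicates)
  rows <- list(); k <- 0L
  for (ri in seq_along(ratios)) {
    for (rep_ in seq_len(design$replicates)) {
      k <- k + 1L
      mixed <- mixFragments(targetPat, backgroundPat, ratios[ri],
                            totalN, seed = seeds[rep_])
      res <- deconvolve(mixed, atlas, models, minCalled = minCalled)
      tab <- resultTable(res)
      i <- match(targetGroup, tab$group)
      rows[[k]] <- data.frame(ratio = ratios[ri], replicate = rep_,
                              predicted = tab$fraction[i],
                              n_fragments = tab$n_fragments[i])
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$ratio), function(d)
    data.frame(ratio = d$ratio[1], truth = d$ratio[1],
               n = nrow(d), mean_pred = mean(d$predicted),
               sd_pred = if (nrow(d) > 1L) stats::sd(d$predicted)
                         else NA_real_)))
  summ <- summ[order(summ$ratio), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = reps,
                 target_group = targetGroup, design = design),
            class = "MixinReport")
}

#' Recovery metrics of a mix-in report
#'
#' Per-ratio absolute and relative errors of the mean predicted proportion
#' against the true admixture, whether the truth lies within one standard
#' deviation of the mean, and the overall root-mean-square error.
#'
#' @param report A \code{MixinReport} from [runMixinExperiment()].
#' @return List with \code{perRatio} (\code{data.frame}) and \code{rmse}.
#' @export
recoveryMetrics <- function(report) {
  stopifnot(inherits(report, "MixinReport"))
  s <- report$summary
  per <- data.frame(
    ratio = s$ratio, truth = s$truth, mean_pred = s$mean_pred,
    sd_pred = s$sd_pred,
    abs_error = abs(s$mean_pred - s$truth),
    rel_error = ifelse(s$truth > 0, abs(s$mean_pred - s$truth) / s$truth,
                       NA_real_),
    truth_within_1sd = ifelse(is.na(s$sd_pred), NA,
                              abs(s$mean_pred - s$truth) <= s$sd_pred))
  list(perRatio = per, rmse = sqrt(mean((s$mean_pred - s$truth)^2)))
}

#' Build mix-in fragment pools from a synthetic reference
#'
#' Generates the two pure cfDNA pools a mix-in experiment consumes: target
#' cell fragments and leukocyte (buffy-coat-like) background fragments,
#' both over the reference's full marker panel, with the sequencing
#' characteristics of the reference spec.
#'
#' @param ref Output of [generateReference()].
#' @param targetGroup Cell type to spike in.
#' @param backgroundGroup Background cell type (default
#'   \code{"leukocyte"}).
#' @param fragsPerMarker Pool depth per marker block (default 400, twice
#'   the default mixture share so mixtures sample without replacement).
#' @param seed Integer seed (fanned out per pool).
#' @return List with \code{target} and \code{background} fragment
#'   \code{data.frame}s.
#' @export
mixinPools <- function(ref, targetGroup, backgroundGroup = "leukocyte",
                       fragsPerMarker = 400L, seed = 1L) {
  seeds <- childSeeds(seed, 2L)
  mk <- function(group, sd) {
    fr <- stats::setNames(1, group)
    generateCfdna(syntheticMixtureSpec(
      fractions = fr, fragsPerMarker = fragsPerMarker,
      fragLen = ref$spec$fragLen, errCT = ref$spec$errCT,
      errTC = ref$spec$errTC, rho = ref$spec$rho,
      missingRate = ref$spec$missingRate, seed = sd), ref)$pat
  }
  list(target = mk(targetGroup, seeds[1]),
       background = mk(backgroundGroup, seeds[2]))
}
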