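# Fragment-level Bayesian deconvolution with fourth-order Markov models.
#
# Within a marker block, the methylation state of each CpG in a fragment is
# modelled as depending on up to 4 adjacent previous called sites in the
# same fragment. Per marker, two conditional-probability models are trained
# (target cell type vs pooled background); each cfDNA fragment is assigned
# by posterior probability, assignments are aggregated per marker and
# averaged, and group proportions are normalized and converted to genome
# equivalents.

# Count (context -> outcome) transitions of one pattern. '.' sites are
# skipped and reset the context: a gap breaks the adjacency the order-k
# dependence assumes.
.patternSteps <- function(pattern, order = 4L) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  ctx <- ""
  contexts <- character(length(chars))
  outcomes <- character(length(chars))
  k <- 0L
  for (ch in chars) {
    if (ch == ".") { ctx <- ""; next }
    k <- k + 1L
    contexts[k] <- ctx; outcomes[k] <- ch
    ctx <- paste0(ctx, ch)
    if (nchar(ctx) > order) ctx <- substring(ctx, nchar(ctx) - order + 1L)
  }
  list(context = contexts[seq_len(k)], outcome = outcomes[seq_len(k)])
}

# Accumulate context counts over (pattern, weight) pairs into a named list
# of c(C=, T=) vectors. The empty context "" is always present so the
# order-0 table exists even for empty training sets.
.countContexts <- function(patterns, weights, order = 4L) {
  # table keys are "k" + context ("" is neither a legal variable name nor
  # matchable by [[ ]], so the empty order-0 context needs the prefix)
  env <- new.env(hash = TRUE, parent = emptyenv())
  assign("k", c(C = 0, T = 0), envir = env)
  for (i in seq_along(patterns)) {
    st <- .patternSteps(patterns[i], order)
    w <- weights[i]
    for (j in seq_along(st$context)) {
      key <- paste0("k", st$context[j])
      cur <- if (exists(key, envir = env, inherits = FALSE))
        get(key, envir = env) else c(C = 0, T = 0)
      cur[st$outcome[j]] <- cur[st$outcome[j]] + w
      assign(key, cur, envir = env)
    }
  }
  as.list(env)
}

# Smoothed conditional probability of outcome given context, backing off to
# the longest observed suffix when the full context was never seen.
.condProb <- function(tables, ctx, outcome, pseudocount) {
  repeat {
    tab <- tables[[paste0("k", ctx)]]
    if (!is.null(tab) && sum(tab) > 0) break
    if (ctx == "") { tab <- c(C = 0, T = 0); break }
    ctx <- substring(ctx, 2L)
  }
  (tab[[outcome]] + pseudocount) / (sum(tab) + 2 * pseudocount)
}

#' Train a fourth-order Markov marker model
#'
#' Estimates, for one marker block, the conditional probability tables of
#' methylation state given up to \code{order} previous called sites within
#' the fragment, separately for target-cell-type fragments and pooled
#' background fragments, by (weighted) maximum likelihood with additive
#' smoothing. Fragments are clipped to the marker's CpG interval first;
#' positions 1..\code{order} of a fragment contribute lower-order contexts,
#' and a missing (\code{.}) site resets the context.
#'
#' @param targetPat,backgroundPat Fragment \code{data.frame}s (columns
#'   \code{chrom}, \code{cpg_start}, \code{pattern}, \code{count}) from the
#'   reference samples of the target group and of all other groups.
#' @param cpgStart,cpgEnd Marker CpG interval (0-based half-open).
#' @param markerId Identifier used in error messages and the model.
#' @param order Markov order (default 4).
#' @param pseudocount Additive smoothing per outcome per context (default
#'   0.5); contexts never observed back off to the longest observed suffix.
#' @return A [MarkovMarkerModel-class].
#' @export
trainMarkerModel <- function(targetPat, backgroundPat, cpgStart, cpgEnd,
                             markerId = sprintf("cpg%d-%d", cpgStart, cpgEnd),
                             order = 4L, pseudocount = 0.5) {
  tcl <- clipPatToBlock(targetPat, cpgStart, cpgEnd, minCalled = 1L)
  bcl <- clipPatToBlock(backgroundPat, cpgStart, cpgEnd, minCalled = 1L)
  if (nrow(tcl) == 0L || sum(tcl$count) == 0)
    stop("no target training fragments at marker '", markerId, "'")
  # dedup identical clipped patterns before the counting walk
  tagg <- stats::aggregate(count ~ pattern, tcl, sum)
  bagg <- if (nrow(bcl)) stats::aggregate(count ~ pattern, bcl, sum) else
    data.frame(pattern = character(0), count = numeric(0))
  new("MarkovMarkerModel", markerId = markerId, order = as.integer(order),
      pseudocount = pseudocount,
      target = .countContexts(tagg$pattern, tagg$count, order),
      background = .countContexts(bagg$pattern, bagg$count, order),
      nTarget = sum(tagg$count), nBackground = sum(bagg$count))
}

#' Log-likelihood of a fragment pattern under one class
#'
#' Chain-rule log-likelihood \eqn{\sum_i \log P(s_i | s_{i-4} .. s_{i-1})}
#' over the called positions of the pattern, using the smoothed conditional
#' tables of one class. \code{.} positions are skipped and reset the
#' context.
#'
#' @param pattern Pattern string over \code{{C, T, .}}.
#' @param tables Named list of context count tables (slot \code{target} or
#'   \code{background} of a [MarkovMarkerModel-class]).
#' @param order Markov order.
#' @param pseudocount Additive smoothing per outcome.
#' @return Log-likelihood (0 for a pattern with no called sites).
#' @export
fragmentLoglik <- function(pattern, tables, order = 4L, pseudocount = 0.5) {
  st <- .patternSteps(pattern, order)
  if (!length(st$context)) return(0)
  sum(vapply(seq_along(st$context), function(j)
    log(.condProb(tables, st$context[j], st$outcome[j], pseudocount)), 1.0))
}

#' Posterior probability that a fragment originates from the target
#'
#' Bayes' rule with a per-classifier prior \eqn{\pi}:
#' \eqn{\pi L_t / (\pi L_t + (1-\pi) L_b)}, computed in log space.
#'
#' @param pattern Pattern string.
#' @param model A [MarkovMarkerModel-class].
#' @param prior Prior probability \eqn{\pi \in (0,1)} that a fragment at
#'   this marker originates from the target cell type.
#' @return Posterior in \[0, 1\].
#' @export
fragmentPosterior <- function(pattern, model, prior) {
  stopifnot(prior > 0, prior < 1)
  llt <- fragmentLoglik(pattern, model@target, model@order, model@pseudocount)
  llb <- fragmentLoglik(pattern, model@background, model@order,
                        model@pseudocount)
  1 / (1 + exp(log1p(-prior) - log(prior) + llb - llt))
}

#' Hard assignment of a fragment
#'
#' The fragment is assigned to the class with maximal posterior
#' probability; a posterior of exactly 0.5 goes to the background
#' (conservative toward not inflating rare cell types).
#'
#' @param posterior Posterior probability of the target class.
#' @return \code{"target"} or \code{"background"}.
#' @export
assignFragment <- function(posterior) {
  ifelse(posterior > 0.5, "target", "background")
}

#' Classify the fragments overlapping one marker
#'
#' Clips fragments to the marker interval, drops those with fewer than
#' \code{minCalled} called sites inside, and hard-assigns each remaining
#' fragment by posterior probability. Identical clipped patterns are
#' classified once and weighted by multiplicity.
#'
#' @param pat Fragment \code{data.frame}.
#' @param model A [MarkovMarkerModel-class].
#' @param prior Classifier prior.
#' @param cpgStart,cpgEnd Marker CpG interval.
#' @param minCalled Minimum called in-block sites per classified fragment
#'   (default 5 = order + 1, the shortest pattern that exercises one
#'   full-depth fourth-order context; configurable).
#' @return List with \code{nFragments} and \code{nAssigned} (weighted
#'   counts).
#' @export
classifyFragments <- function(pat, model, prior, cpgStart, cpgEnd,
                              minCalled = 5L) {
  cl <- clipPatToBlock(pat, cpgStart, cpgEnd, minCalled = minCalled)
  if (nrow(cl) == 0L) return(list(nFragments = 0, nAssigned = 0))
  agg <- stats::aggregate(count ~ pattern, cl, sum)
  post <- vapply(agg$pattern, fragmentPosterior, 1.0, model = model,
                 prior = prior, USE.NAMES = FALSE)
  list(nFragments = sum(agg$count),
       nAssigned = sum(agg$count[post > 0.5]))
}

#' Proportion of fragments assigned to a cell type
#'
#' Per-marker assigned fractions are averaged, unweighted, across the
#' group's markers ("the proportion of molecules assigned to the tissue of
#' interest across all cell-type-specific markers was then averaged");
#' markers with no eligible fragments are excluded from the mean.
#'
#' @param pat cfDNA fragment \code{data.frame}.
#' @param markers Marker \code{data.frame} rows for one group.
#' @param models Named list of [MarkovMarkerModel-class], keyed by marker
#'   \code{name}.
#' @param prior Classifier prior for this group.
#' @param minCalled See [classifyFragments()].
#' @param weighted If \code{TRUE}, weight markers by fragment coverage
#'   instead of the default unweighted mean.
#' @return List with \code{proportion} (\code{NA} and \code{flagged = TRUE}
#'   when every marker is empty), \code{nFragments}, \code{nMarkersUsed}.
#' @export
groupProportion <- function(pat, markers, models, prior, minCalled = 5L,
                            weighted = FALSE) {
  # assign fragments to candidate markers in one interval-overlap pass
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = pat$cpg_start + 1L,
                     width = nchar(pat$pattern)),
    IRanges::IRanges(start = markers$cpg_start + 1L,
                     end = markers$cpg_end))
  bySubject <- split(S4Vectors::queryHits(hits),
                     factor(S4Vectors::subjectHits(hits),
                            levels = seq_len(nrow(markers))))
  fracs <- numeric(0); ns <- numeric(0)
  for (i in seq_len(nrow(markers))) {
    mod <- models[[markers$name[i]]]
    if (is.null(mod)) stop("no trained model for marker '", markers$name[i], "'")
    cf <- classifyFragments(pat[bySubject[[i]], , drop = FALSE], mod, prior,
                            markers$cpg_start[i], markers$cpg_end[i],
                            minCalled)
    if (cf$nFragments > 0) {
      fracs <- c(fracs, cf$nAssigned / cf$nFragments)
      ns <- c(ns, cf$nFragments)
    }
  }
  if (!length(fracs))
    return(list(proportion = NA_real_, nFragments = 0, nMarkersUsed = 0L,
                flagged = TRUE))
  prop <- if (weighted) sum(fracs * ns) / sum(ns) else mean(fracs)
  list(proportion = prop, nFragments = sum(ns),
       nMarkersUsed = length(fracs), flagged = FALSE)
}

#' Normalize raw proportions to fractions summing to 1
#'
#' @param raw Named non-negative numeric vector of raw per-group
#'   proportions.
#' @return Fractions summing to 1 (order-invariant).
#' @export
normalizeProportions <- function(raw) {
  stopifnot(all(!is.na(raw)), all(raw >= 0))
  s <- sum(raw)
  if (s == 0) stop("all raw proportions are zero: normalization is degenerate")
  raw / s
}

#' Rescale endothelial subtypes within the pan-endothelial fraction
#'
#' Tissue-specific endothelial estimates are normalized within the total
#' endothelial proportion predicted by the pan-endothelial markers, so the
#' subtype fractions always sum exactly to the pan-endothelial fraction.
#'
#' @param subtypeRaw Named non-negative raw proportions per endothelial
#'   subtype.
#' @param panFraction The pan-endothelial normalized fraction.
#' @return Subtype fractions summing to \code{panFraction}.
#' @export
rescaleEndothelial <- function(subtypeRaw, panFraction) {
  stopifnot(all(subtypeRaw >= 0), panFraction >= 0)
  s <- sum(subtypeRaw)
  if (s == 0) return(stats::setNames(rep(0, length(subtypeRaw)),
                                     names(subtypeRaw)))
  subtypeRaw / s * panFraction
}

#' Genome equivalents per mL
#'
#' Converts a cell-type cfDNA fraction and a total cfDNA concentration to
#' genome equivalents per mL serum by dividing by the haploid genome mass
#' (3.3e-3 ng human, 3.0e-3 ng mouse), so ng/mL becomes genomes/mL.
#'
#' @param fraction Cell-type fraction in \[0, 1\].
#' @param concNgPerMl Total cfDNA concentration in ng/mL.
#' @param species \code{"human"} or \code{"mouse"}.
#' @return Geq/mL.
#' @examples
#' geqPerMl(0.1, 10, "human")  # ~303 Geq/mL
#' @export
geqPerMl <- function(fraction, concNgPerMl, species = c("human", "mouse")) {
  species <- match.arg(species)
  mass_ng <- if (species == "human") 3.3e-3 else 3.0e-3
  fraction * concNgPerMl / mass_ng
}

# Reference samples for a group name; the pan-endothelial group pools the
# samples of all endothelial subtypes.
.groupSamples <- function(atlas, group) {
  g <- atlas@groups
  if (identical(group, atlas@hierarchy$pan_group))
    g$sample_id[g$group %in% atlas@hierarchy$subtypes]
  else g$sample_id[g$group == group]
}

.groupRole <- function(atlas, group) {
  if (identical(group, atlas@hierarchy$pan_group)) return("pan_endothelial")
  r <- unique(atlas@groups$role[atlas@groups$group == group])
  if (!length(r)) stop("group '", group, "' not found in the atlas")
  r[1]
}

#' Train Markov models for every marker of an atlas
#'
#' For each marker, the target training pool is the reference fragments of
#' the marker's group (pan-endothelial markers pool all endothelial
#' subtypes) and the background pool is all remaining reference samples.
#' Samples are weighted equally within each pool: each sample's fragment
#' counts at the marker are rescaled to the pool's mean per-sample depth, so
#' a deep sample cannot dominate the tables.
#'
#' @param atlas A [MethylAtlas-class].
#' @param refPats Named list of fragment \code{data.frame}s, one per
#'   reference sample (names are sample ids).
#' @param order,pseudocount See [trainMarkerModel()].
#' @return Named list of [MarkovMarkerModel-class], keyed by marker
#'   \code{name}.
#' @export
trainAtlasModels <- function(atlas, refPats, order = 4L, pseudocount = 0.5) {
  m <- atlas@markers
  models <- vector("list", nrow(m))
  names(models) <- m$name
  poolAt <- function(ids, cpgStart, cpgEnd) {
    parts <- lapply(ids, function(sid) {
      p <- refPats[[sid]]
      if (is.null(p)) stop("reference fragments missing for sample '", sid, "'")
      cl <- clipPatToBlock(p, cpgStart, cpgEnd, minCalled = 1L)
      cl
    })
    depth <- vapply(parts, function(x) sum(x$count), 1.0)
    mu <- mean(depth[depth > 0])
    for (i in seq_along(parts))
      if (depth[i] > 0) parts[[i]]$count <- parts[[i]]$count * mu / depth[i]
    out <- do.call(rbind, parts)
    out$chrom <- "."; out$cpg_start <- cpgStart  # already clipped
    out[, c("chrom", "cpg_start", "pattern", "count")]
  }
  for (i in seq_len(nrow(m))) {
    tgtIds <- .groupSamples(atlas, m$group[i])
    bgIds <- setdiff(atlas@groups$sample_id, tgtIds)
    models[[i]] <- trainMarkerModel(
      poolAt(tgtIds, m$cpg_start[i], m$cpg_end[i]),
      poolAt(bgIds, m$cpg_start[i], m$cpg_end[i]),
      m$cpg_start[i], m$cpg_end[i], markerId = m$name[i],
      order = order, pseudocount = pseudocount)
  }
  models
}

#' Fragment-level deconvolution of a cfDNA sample
#'
#' Orchestrates the marker-group hierarchy: the bulk-immune classifier
#' (prior 0.85) and the solid-organ cell types (prior 0.05) together with
#' the pan-endothelial tier (prior 0.10) form the composition, whose raw
#' proportions are normalized to sum to 1; tissue-specific endothelial
#' subtypes are then rescaled within the pan-endothelial fraction. When a
#' cfDNA concentration is supplied, fractions are converted to Geq/mL.
#' Deterministic given its inputs.
#'
#' @param pat cfDNA fragment \code{data.frame}.
#' @param atlas A [MethylAtlas-class].
#' @param models Trained models from [trainAtlasModels()].
#' @param concNgPerMl cfDNA concentration in ng/mL (\code{NA}: skip Geq).
#' @param minCalled Minimum called in-block sites per classified fragment.
#' @param cpgMap Optional [CpGIndexMap-class]; when supplied, markers whose
#'   CpG interval exceeds the map are an error.
#' @return A [DeconvResult-class].
#' @export
deconvolve <- function(pat, atlas, models, concNgPerMl = NA_real_,
                       minCalled = 5L, cpgMap = NULL) {
  validatePat(pat, "cfDNA fragment table")
  m <- atlas@markers
  if (!is.null(cpgMap)) {
    n <- nCpGs(cpgMap)
    if (any(m$cpg_end > n))
      stop("atlas markers reference CpG indices absent from the sample's map")
  }
  grps <- unique(m$group)
  roles <- vapply(grps, .groupRole, "", atlas = atlas)
  raw <- numeric(length(grps)); names(raw) <- grps
  nfr <- numeric(length(grps)); nmk <- integer(length(grps))
  for (i in seq_along(grps)) {
    gm <- m[m$group == grps[i], , drop = FALSE]
    gp <- groupProportion(pat, gm, models, atlas@priors[[roles[i]]],
                          minCalled = minCalled)
    if (gp$flagged)
      warning("no eligible fragments at any marker of group '", grps[i], "'")
    raw[i] <- gp$proportion; nfr[i] <- gp$nFragments; nmk[i] <- gp$nMarkersUsed
  }
  subtypes <- intersect(atlas@hierarchy$subtypes, grps)
  comp <- grps[!grps %in% subtypes]
  compRaw <- raw[comp]
  if (anyNA(compRaw)) {
    warning("treating groups with no fragments as zero in normalization")
    compRaw[is.na(compRaw)] <- 0
  }
  fractions <- normalizeProportions(compRaw)
  frac <- stats::setNames(rep(NA_real_, length(grps)), grps)
  frac[comp] <- fractions
  pan <- atlas@hierarchy$pan_group
  if (length(subtypes) && !is.na(pan) && pan %in% comp) {
    subRaw <- raw[subtypes]
    subRaw[is.na(subRaw)] <- 0
    frac[subtypes] <- rescaleEndothelial(subRaw, fractions[[pan]])
  }
  geq <- if (is.na(concNgPerMl)) rep(NA_real_, length(grps)) else
    geqPerMl(frac, concNgPerMl, atlas@species)
  tab <- data.frame(group = grps, role = unname(roles), n_markers = nmk,
                    n_fragments = nfr, raw_proportion = unname(raw),
                    fraction = unname(frac), geq_per_ml = unname(geq),
                    in_composition = grps %in% comp)
  new("DeconvResult", table = tab, species = atlas@species,
      concNgPerMl = concNgPerMl, priors = atlas@priors)
}
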