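# Independent oracles: deliberately simple, loop-based re-derivations kept
# separate from the package's implementation paths.

# Seed fan-out for parameterised test loops.
childSeedsForTest <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Per-site tally of fragment calls by explicit loops.
oracleTally <- function(pat, nSites) {
  meth <- numeric(nSites); total <- numeric(nSites)
  for (i in seq_len(nrow(pat))) {
    chars <- strsplit(pat$pattern[i], "")[[1]]
    for (j in seq_along(chars)) {
      s <- pat$cpg_start[i] + j  # 1-based site index
      if (chars[j] == "C") {
        meth[s] <- meth[s] + pat$count[i]
        total[s] <- total[s] + pat$count[i]
      } else if (chars[j] == "T") {
        total[s] <- total[s] + pat$count[i]
      }
    }
  }
  list(meth = meth, total = total)
}

# Exhaustive segmentation: enumerate every tiling of n sites (n <= 12),
# score each with the beta-binomial block marginal minus the penalty, and
# return the maximal score plus all optimal boundary vectors (ties within
# tol, restricted to the minimal block count).
oracleSegment <- function(M, TT, pos, maxBp, lambda, alpha = 1, beta = 1,
                          tol = 1e-9) {
  n <- nrow(M)
  scoreBlock <- function(i, j) {
    if (pos[j] + 2 - pos[i] > maxBp) return(-Inf)
    m <- colSums(M[i:j, , drop = FALSE])
    t <- colSums(TT[i:j, , drop = FALSE])
    sum(lbeta(alpha + m, beta + t - m) - lbeta(alpha, beta)) - lambda
  }
  tilings <- list(); scores <- numeric(0)
  for (mask in 0:(2^(max(n - 1, 0)) - 1)) {
    bnd <- c(0, if (n > 1) which(bitwAnd(mask, 2^(0:(n - 2))) > 0), n)
    sc <- 0
    for (b in seq_len(length(bnd) - 1)) {
      sc <- sc + scoreBlock(bnd[b] + 1, bnd[b + 1])
      if (!is.finite(sc)) break
    }
    if (!is.finite(sc)) next
    tilings[[length(tilings) + 1]] <- bnd
    scores <- c(scores, sc)
  }
  top <- max(scores)
  opt <- tilings[scores >= top - tol]
  nb <- vapply(opt, length, 1L)
  opt <- opt[nb == min(nb)]
  list(score = top, optima = opt)
}

# Chain-rule likelihood and Bayes posterior computed in raw probability
# space with an independent walking loop (the implementation works in log
# space with vectorized steps).
oracleCondProb <- function(tables, ctx, outcome, pc) {
  repeat {
    tab <- tables[[paste0("k", ctx)]]
    if (!is.null(tab) && sum(tab) > 0) break
    if (ctx == "") { if (is.null(tab)) tab <- c(C = 0, T = 0); break }
    ctx <- substring(ctx, 2)
  }
  (tab[[outcome]] + pc) / (sum(tab) + 2 * pc)
}

oracleLik <- function(pattern, tables, pc, order = 4) {
  chars <- strsplit(pattern, "")[[1]]
  lik <- 1; ctx <- ""
  for (ch in chars) {
    if (ch == ".") { ctx <- ""; next }
    lik <- lik * oracleCondProb(tables, ctx, ch, pc)
    ctx <- paste0(ctx, ch)
    if (nchar(ctx) > order) ctx <- substring(ctx, nchar(ctx) - order + 1)
  }
  lik
}

oraclePosterior <- function(pattern, model, prior) {
  lt <- oracleLik(pattern, model@target, model@pseudocount, model@order)
  lb <- oracleLik(pattern, model@background, model@pseudocount, model@order)
  prior * lt / (prior * lt + (1 - prior) * lb)
}

# All patterns over {C, T, .} up to maxLen that begin and end called.
allPatterns <- function(maxLen) {
  out <- character(0)
  for (L in seq_len(maxLen)) {
    grid <- do.call(expand.grid,
                    c(rep(list(c("C", "T", ".")), L),
                      list(stringsAsFactors = FALSE)))
    p <- apply(grid, 1, paste0, collapse = "")
    out <- c(out, p[!startsWith(p, ".") & !endsWith(p, ".")])
  }
  out
}

# Synthetic replicate beta matrix for clustering checks: per group a block
# profile on a grid with 0.4 separation, replicates jittered with sd sigma.
clusterFixture <- function(nGroups = 5, nReps = 3, nBlocks = 100,
                           sigma = 0.02, seed = 1) {
  set.seed(seed)
  profiles <- matrix(sample(c(0.1, 0.5, 0.9), nGroups * nBlocks,
                            replace = TRUE), nBlocks, nGroups)
  betas <- matrix(NA_real_, nBlocks, nGroups * nReps)
  labels <- character(nGroups * nReps)
  k <- 0
  for (g in seq_len(nGroups)) for (r in seq_len(nReps)) {
    k <- k + 1
    betas[, k] <- pmin(pmax(profiles[, g] + rnorm(nBlocks, 0, sigma), 0), 1)
    labels[k] <- paste0("grp", g)
  }
  colnames(betas) <- paste0(labels, "_r", rep(seq_len(nReps), nGroups))
  list(betas = betas, labels = labels)
}
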