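test_that("training counts contexts with smoothing and hand-checked values", {
  # all-C training: every observed context predicts C with certainty at
  # pseudocount 0
  tgt <- data.frame(chrom = "chr1", cpg_start = rep(0L, 3),
                    pattern = rep("CCCCC", 3), count = 1)
  bg <- data.frame(chrom = "chr1", cpg_start = rep(0L, 3),
                   pattern = rep("TTTTT", 3), count = 1)
  mod <- trainMarkerModel(tgt, bg, 0, 5, pseudocount = 0)
  expect_equal(exp(fragmentLoglik("CCCCC", mod@target, 4, 0)), 1)

  # context "CC" followed by C twice and T once, pseudocount 1:
  # P(C | CC) = (2 + 1) / (3 + 2) = 3/5
  tgt2 <- data.frame(chrom = "chr1", cpg_start = rep(0L, 3),
                     pattern = c("CCC", "CCC", "CCT"), count = 1)
  mod2 <- trainMarkerModel(tgt2, bg, 0, 3, pseudocount = 1)
  tab <- mod2@target[["kCC"]]
  expect_equal(unname((tab["C"] + 1) / (sum(tab) + 2)), 3 / 5)

  # zero target fragments names the marker
  expect_error(trainMarkerModel(tgt[0, ], bg, 0, 5, markerId = "mk_x"),
               "mk_x")
})

test_that("trained conditional tables approach the generating chain", {
  # fragments from a known order-4 chain (persistence form): with many
  # fragments the estimated conditionals approach the generating values
  spec <- syntheticAtlasSpec(
    groups = data.frame(group = c("leukocyte", "hepatocyte"),
                        role = c("bulk_immune", "solid_organ")),
    seed = 31, nMarkersPerType = 1L, nPanMarkers = 0L, nNullBlocks = 0L,
    nReplicates = 1L, cpgsPerBlock = 8, fragsPerBlock = 200000L,
    fragLen = 6:8, sigma = 0, errCT = 0, errTC = 0,
    missingRate = 0, rho = 0.3)
  ref <- generateReference(spec, what = "pat")
  tr <- ref$truth[ref$truth$group %in% "hepatocyte" &
                    ref$truth$kind == "marker", ][1, ]
  pat <- ref$pats[["leukocyte_rep1"]]  # level 0.85 at a hepatocyte marker
  mod <- trainMarkerModel(pat, pat, tr$cpg_start, tr$cpg_end,
                          pseudocount = 0.5)
  p <- 0.85; rho <- 0.3
  probe <- function(ctx) {
    tab <- mod@target[[paste0("k", ctx)]]
    (tab[["C"]] + 0.5) / (sum(tab) + 1)
  }
  # first site and a few four-deep contexts
  expect_lt(abs(probe("") - p), 0.02)
  for (ctx in c("CCCC", "TTTT", "CTCT")) {
    states <- as.integer(strsplit(ctx, "")[[1]] == "C")
    want <- p + rho * (mean(states) - p)
    expect_lt(abs(probe(ctx) - want), 0.02)
  }
})

test_that("fragment log-likelihood follows the chain rule with gaps", {
  fx <- atlasFixture()
  mk <- atlasMarkers(fx$atlas)
  mod <- fx$models[[mk$name[1]]]

  # single site uses the order-0 table
  t0 <- mod@target[["k"]]
  expect_equal(fragmentLoglik("C", mod@target, mod@order, mod@pseudocount),
               log((t0[["C"]] + 0.5) / (sum(t0) + 1)))

  # a uniform table gives m * log(1/2) for m called sites
  unif <- list(k = c(C = 1, T = 1))
  expect_equal(fragmentLoglik("CT.TC", unif, 4, 0.5), 4 * log(0.5))

  # random patterns match the raw-probability chain-rule oracle
  set.seed(77)
  pats <- replicate(50, {
    p <- sample(c("C", "T", "."), 6, replace = TRUE)
    p[1] <- sample(c("C", "T"), 1); p[6] <- sample(c("C", "T"), 1)
    paste(p, collapse = "")
  })
  for (p in pats) {
    expect_equal(fragmentLoglik(p, mod@target, mod@order, mod@pseudocount),
                 log(oracleLik(p, mod@target, mod@pseudocount)),
                 tolerance = 1e-12)
  }
})

test_that("posterior follows Bayes rule and its limits", {
  fx <- atlasFixture()
  mod <- fx$models[[1]]
  # equal likelihoods cancel: posterior = prior
  um <- mod
  um@target <- um@background <- list(k = c(C = 2, T = 2))
  for (pri in c(0.05, 0.5, 0.85))
    expect_equal(fragmentPosterior("CTC", um, pri), pri)
  # hand arithmetic: pi = 0.05, Lt = 0.9, Lb = 0.1 -> 0.045 / 0.14
  post <- 0.05 * 0.9 / (0.05 * 0.9 + 0.95 * 0.1)
  expect_equal(post, 0.045 / 0.14)
  expect_equal(round(post, 4), 0.3214)
  # prior -> 1 forces the posterior toward 1 for finite likelihood ratios
  expect_gt(fragmentPosterior("CCCC", mod, 1 - 1e-12), 0.999)
})

test_that("hard assignment thresholds at 0.5 with ties to background", {
  expect_equal(assignFragment(0.51), "target")
  expect_equal(assignFragment(0.5), "background")
  expect_equal(assignFragment(0.49), "background")
})

test_that("group proportion averages per-marker assigned fractions", {
  # two markers with fractions 0.2 and 0.4 -> 0.3; construct via disjoint
  # marker intervals and deterministic models
  mkA <- list(cpg_start = 0L, cpg_end = 3L)
  mkB <- list(cpg_start = 10L, cpg_end = 13L)
  tgt <- data.frame(chrom = "chr1", cpg_start = 0L,
                    pattern = "TTT", count = 50)
  bg <- data.frame(chrom = "chr1", cpg_start = 0L,
                   pattern = "CCC", count = 50)
  modA <- trainMarkerModel(tgt, bg, 0, 3, markerId = "A")
  tgtB <- tgt; tgtB$cpg_start <- 10L
  bgB <- bg; bgB$cpg_start <- 10L
  modB <- trainMarkerModel(tgtB, bgB, 10, 13, markerId = "B")
  markers <- data.frame(name = c("A", "B"), cpg_start = c(0L, 10L),
                        cpg_end = c(3L, 13L))
  pat <- data.frame(
    chrom = "chr1",
    cpg_start = c(0L, 0L, 10L, 10L),
    pattern = c("TTT", "CCC", "TTT", "CCC"),
    count = c(2, 8, 4, 6))
  gp <- groupProportion(pat, markers, list(A = modA, B = modB), prior = 0.5,
                        minCalled = 3L)
  expect_equal(gp$proportion, mean(c(0.2, 0.4)))
  expect_equal(gp$nFragments, 20)
  # all fragments assigned everywhere -> 1
  patT <- pat[pat$pattern == "TTT", ]
  expect_equal(groupProportion(patT, markers, list(A = modA, B = modB),
                               0.5, minCalled = 3L)$proportion, 1)
  # empty markers are flagged
  none <- pat[0, ]
  expect_true(groupProportion(none, markers, list(A = modA, B = modB),
                              0.5, minCalled = 3L)$flagged)
})

test_that("hard-assignment proportion is monotone in the prior", {
  fx <- atlasFixture()
  mk <- atlasMarkers(fx$atlas)
  gm <- mk[mk$group == "hepatocyte", ]
  cf <- generateCfdna(syntheticMixtureSpec(seed = 8), fx$ref)
  props <- vapply(c(0.01, 0.05, 0.2, 0.5, 0.85, 0.99), function(pri)
    groupProportion(cf$pat, gm, fx$models, pri)$proportion, 1.0)
  expect_true(all(diff(props) >= 0))
})

test_that("pure background cfDNA yields a near-zero raw proportion", {
  fx <- atlasFixture()
  mk <- atlasMarkers(fx$atlas)
  gm <- mk[mk$group == "hepatocyte", ]
  for (seed in c(3, 4, 5)) {
    pure <- generateCfdna(syntheticMixtureSpec(
      fractions = c(leukocyte = 1), seed = seed), fx$ref)
    gp <- groupProportion(pure$pat, gm, fx$models, 0.05)
    expect_lt(gp$proportion, 0.01)
  }
})

test_that("normalization and endothelial rescaling conserve totals", {
  expect_equal(normalizeProportions(c(a = 0.5, b = 0.5, c = 1.0)),
               c(a = 0.25, b = 0.25, c = 0.5))
  expect_equal(unname(normalizeProportions(c(x = 0.3))), 1.0)
  expect_error(normalizeProportions(c(0, 0)), "degenerate")

  expect_equal(rescaleEndothelial(c(cpec = 0.6, lsec = 0.2, huvec = 0.2),
                                  0.10),
               c(cpec = 0.06, lsec = 0.02, huvec = 0.02))
  expect_equal(unname(rescaleEndothelial(c(only = 0.4), 0.07)), 0.07)
  set.seed(2)
  for (k in 1:50) {
    raws <- runif(sample(2:5, 1))
    pan <- runif(1)
    expect_equal(sum(rescaleEndothelial(raws, pan)), pan)
  }
})

test_that("genome equivalents per mL follow the haploid-mass conversion", {
  expect_equal(geqPerMl(0, 12, "human"), 0)
  expect_equal(geqPerMl(0.1, 10, "human"), 0.1 * 10 / 3.3e-3)
  expect_equal(round(geqPerMl(0.1, 10, "human"), 1), 303.0)
  expect_equal(geqPerMl(0.1, 10, "mouse"), 0.1 * 10 / 3.0e-3)
  # linear in concentration
  expect_equal(geqPerMl(0.2, 20, "human"), 2 * geqPerMl(0.2, 10, "human"))
})

test_that("deconvolution recovers a leukocyte-dominated serum mixture", {
  fx <- atlasFixture()
  cf <- generateCfdna(syntheticMixtureSpec(seed = 12), fx$ref)
  res <- deconvolve(cf$pat, fx$atlas, fx$models, cf$concNgPerMl,
                    cpgMap = fx$ref$map)
  tab <- resultTable(res)
  expect_equal(sum(tab$fraction[tab$in_composition]), 1)
  # endothelial subtypes sum exactly to the pan-endothelial fraction
  expect_equal(sum(tab$fraction[tab$role == "endothelial_subtype"]),
               tab$fraction[tab$group == "endothelial"])
  # recovered fractions sit near the planted mixture
  truth <- cf$truthFractions
  expect_lt(abs(tab$fraction[tab$group == "leukocyte"] - truth["leukocyte"]),
            0.05)
  expect_lt(abs(tab$fraction[tab$group == "endothelial"] -
                  truth["cpec"] - truth["lsec"]), 0.03)
  # Geq/mL equals fraction * conc / haploid mass
  expect_equal(tab$geq_per_ml,
               geqPerMl(tab$fraction, cf$concNgPerMl, "human"))
  # markers referencing CpGs beyond the map are an error
  shortMap <- CpGIndexMap("chr1", 0L)
  expect_error(deconvolve(cf$pat, fx$atlas, fx$models, cpgMap = shortMap),
               "absent from")
})
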