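test_that("block beta is the pooled methylation ratio", {
  tr <- MethylomeTrack(c(2, 1, 0), c(2, 2, 0))
  expect_equal(blockBeta(tr, 0, 3), 3 / 4)
  # all totals zero -> missing
  tr0 <- MethylomeTrack(c(0, 0), c(0, 0))
  expect_true(is.na(blockBeta(tr0, 0, 2)))
})

test_that("block betas agree across per-site and fragment representations", {
  set.seed(21)
  recs <- aggregatePat(data.frame(
    chrom = "chr1", cpg_start = sample(0:30, 60, replace = TRUE),
    pattern = vapply(seq_len(60), function(i)
      paste(sample(c("C", "T"), sample(2:5, 1), replace = TRUE),
            collapse = ""), ""),
    count = sample(1:3, 60, replace = TRUE)))
  tr <- patToBeta(recs, 40)
  for (iv in list(c(0, 10), c(5, 25), c(30, 40))) {
    sites <- (iv[1] + 1):iv[2]
    want <- oracleTally(recs, 40)
    tot <- sum(want$total[sites])
    if (tot > 0)
      expect_equal(blockBeta(tr, iv[1], iv[2]), sum(want$meth[sites]) / tot)
  }
})

test_that("candidate filter enforces size, span and per-sample observations", {
  map <- CpGIndexMap(rep("chr1", 20), c(0, 30, 60, 90, 3000, 3030, 3060,
                                        3090, 3120, 6000, 6030, 6060,
                                        9000, 9500, 10000, 10600, 12000,
                                        12030, 12060, 12090))
  blocks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1, 3001, 6001, 9001, 12001),
                             end = c(92, 3122, 6062, 10602, 12092)))
  S4Vectors::mcols(blocks)$name <- paste0("b", 1:5)
  S4Vectors::mcols(blocks)$n_cpgs <- c(4L, 5L, 3L, 2L, 4L)
  S4Vectors::mcols(blocks)$cpg_start <- c(0L, 4L, 9L, 12L, 16L)
  S4Vectors::mcols(blocks)$cpg_end <- c(4L, 9L, 12L, 14L, 20L)

  # block 4 has 2 CpGs (removed); block 5 is 4 CpGs but short; a 2.5 kb
  # block is removed by span
  wide <- blocks
  GenomicRanges::end(wide)[5] <- 14501  # 2.5 kb
  kept <- candidateFilter(wide)
  expect_equal(S4Vectors::mcols(kept)$name, c("b1", "b2", "b3"))

  # per-sample observation rule: 9 in one target sample removes the block
  obs <- cbind(s1 = c(20, 9, 15, 20, 20), s2 = c(20, 10, 15, 20, 20))
  kept2 <- candidateFilter(blocks, obsCounts = obs)
  expect_false("b2" %in% S4Vectors::mcols(kept2)$name)
  expect_true("b1" %in% S4Vectors::mcols(kept2)$name)
})

test_that("delta beta is the minimal per-sample separation", {
  expect_equal(deltaBeta(c(0.0, 0.1), c(0.8, 0.9), "hypo"), 0.7)
  expect_equal(deltaBeta(0.5, 0.5, "hypo"), 0)
  expect_equal(deltaBeta(0.5, 0.5, "hyper"), 0)
  expect_equal(deltaBeta(c(0.9, 0.95), c(0.1, 0.2), "hyper"), 0.7)
})

test_that("soft margin uses linear-interpolation quantiles", {
  # hand-computed: q0.8(target) = 0.08, q0.1(bg) = 0.73
  expect_equal(softMargin(c(0, 0.05, 0.10), c(0.7, 0.8, 0.9, 1.0), "hypo"),
               0.73 - 0.08)
  # identical constant groups -> 0
  expect_equal(softMargin(rep(0.4, 3), rep(0.4, 5), "hypo"), 0)
  # singleton groups reduce to delta beta
  expect_equal(softMargin(0.1, 0.6, "hypo"), deltaBeta(0.1, 0.6, "hypo"))
  expect_equal(softMargin(0.9, 0.2, "hyper"), deltaBeta(0.9, 0.2, "hyper"))
})

test_that("soft margin never falls below delta beta", {
  set.seed(9)
  for (k in 1:200) {
    tv <- runif(sample(1:6, 1)); bv <- runif(sample(2:10, 1))
    dir <- sample(c("hypo", "hyper"), 1)
    expect_gte(softMargin(tv, bv, dir) - deltaBeta(tv, bv, dir), -1e-12)
  }
})

test_that("marker selection recovers planted blocks with no false positives", {
  fx <- atlasFixture()
  mk <- atlasMarkers(fx$atlas)
  truth <- fx$ref$truth
  # every selected marker corresponds to a planted block of the same group
  # and direction
  key <- paste(mk$cpg_start, mk$cpg_end)
  tkey <- paste(truth$cpg_start, truth$cpg_end)
  hit <- match(key, tkey)
  expect_false(anyNA(hit))
  planted <- truth[hit, ]
  expGroup <- ifelse(planted$kind == "pan", fx$spec$panGroup, planted$group)
  expect_equal(mk$group, expGroup)
  expect_equal(mk$direction, planted$direction)
  # sensitivity 1: all planted markers found
  expect_equal(nrow(mk), sum(truth$kind != "null"))
  # FDR 0 comes with the group/direction equality above (no null blocks)
  expect_false(any(truth$kind[hit] == "null"))
})

test_that("raising the threshold above the planted margin empties the set", {
  fx <- atlasFixture()
  gs <- split(fx$ref$manifest$sample_id, fx$ref$manifest$group)
  mk <- selectMarkers(fx$blocks, fx$betas, fx$ref$manifest, "human",
                      margin = 0.95, groupSampleSets = gs)
  expect_equal(nrow(mk), 0L)
})

test_that("a soft margin exactly at threshold is retained", {
  blocks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  S4Vectors::mcols(blocks)$name <- "b1"
  S4Vectors::mcols(blocks)$n_cpgs <- 4L
  S4Vectors::mcols(blocks)$cpg_start <- 0L
  S4Vectors::mcols(blocks)$cpg_end <- 4L
  betas <- matrix(c(0.2, 0.2, 0.6, 0.6), 1,
                  dimnames = list("b1", c("t1", "t2", "b1s", "b2s")))
  groups <- data.frame(sample_id = c("t1", "t2", "b1s", "b2s"),
                       group = c("tgt", "tgt", "bg", "bg"))
  mk <- selectMarkers(blocks, betas, groups, "human", margin = 0.4)
  # in a two-group universe the block is a hypo marker for the low group
  # AND a hyper marker for the high group, both exactly at threshold
  expect_setequal(mk$group, c("tgt", "bg"))
  expect_equal(mk$direction[mk$group == "tgt"], "hypo")
  expect_equal(mk$direction[mk$group == "bg"], "hyper")
  expect_equal(mk$soft_margin, c(0.4, 0.4))
})

test_that("marker selection is invariant to sample and group order", {
  fx <- atlasFixture()
  gs <- split(fx$ref$manifest$sample_id, fx$ref$manifest$group)
  mk1 <- selectMarkers(fx$blocks, fx$betas, fx$ref$manifest, "human",
                       groupSampleSets = gs)
  perm <- sample(ncol(fx$betas))
  mk2 <- selectMarkers(fx$blocks, fx$betas[, perm],
                       fx$ref$manifest[perm, ], "human",
                       groupSampleSets = rev(gs))
  o1 <- mk1[order(mk1$group, mk1$name), ]
  o2 <- mk2[order(mk2$group, mk2$name), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("methylation score counts direction-concordant fragments", {
  pat <- data.frame(chrom = "chr1", cpg_start = rep(0L, 4),
                    pattern = c("TT", "TT", "TC", "TT"), count = 1)
  expect_equal(methylationScore(pat, 0, 2, "hypo"), 3 / 4)
  # no overlapping fragments -> missing
  expect_true(is.na(methylationScore(pat, 10, 12, "hypo")))
  # all-'.'-in-block fragments leave the denominator: the first fragment
  # below has only '.' inside [2, 4)
  pat2 <- data.frame(chrom = "chr1", cpg_start = c(0L, 2L),
                     pattern = c("TT..C", "TT"), count = 1)
  expect_equal(methylationScore(pat2, 2, 4, "hypo"), 1)
  # hyper direction mirrors (fully methylated fragments)
  patH <- data.frame(chrom = "chr1", cpg_start = rep(0L, 4),
                     pattern = c("CC", "CC", "TC", "CC"), count = 1)
  expect_equal(methylationScore(patH, 0, 2, "hyper"), 3 / 4)
  expect_equal(methylationScore(pat, 0, 2, "hyper"), 0)
})

test_that("methylation score approaches 1 on pure target fragments", {
  fx <- atlasFixture()
  mk <- atlasMarkers(fx$atlas)
  i <- which(mk$group == "hepatocyte" & mk$direction == "hypo")[1]
  pure <- generateCfdna(
    syntheticMixtureSpec(fractions = c(hepatocyte = 1), errCT = 0,
                         errTC = 0, rho = 0, seed = 3), fx$ref)$pat
  sc <- methylationScore(pure, mk$cpg_start[i], mk$cpg_end[i], "hypo")
  # residual discordance is the planted 5% within-block methylation
  expect_gt(sc, 0.6)
  # with conversion error -> 0 and a fully unmethylated planted level the
  # score is exactly 1
  spec0 <- syntheticAtlasSpec(seed = 5, levelTarget = 0, sigma = 0,
                              errCT = 0, errTC = 0)
  ref0 <- generateReference(spec0, what = "pat")
  tr0 <- ref0$truth
  j <- which(tr0$kind == "marker" & tr0$group == "hepatocyte" &
               tr0$direction == "hypo")[1]
  sc0 <- methylationScore(ref0$pats[["hepatocyte_rep1"]],
                          tr0$cpg_start[j], tr0$cpg_end[j], "hypo")
  expect_equal(sc0, 1)
})

test_that("topMarkers keeps k best with deterministic tie-break", {
  mk <- data.frame(chrom = "chr1", start = c(30, 10, 20), end = c(31, 11, 21),
                   name = c("a", "b", "c"), score = c(0.5, 0.9, 0.5))
  expect_equal(nrow(topMarkers(mk, 10)), 3L)
  top2 <- topMarkers(mk, 2, by = "score")
  expect_equal(top2$name, c("b", "c"))  # tie at 0.5 -> earlier position
})

test_that("hierarchical atlas rejects overlapping endothelial subtype markers", {
  fx <- atlasFixture()
  mk <- atlasMarkers(fx$atlas)
  bad <- mk
  i <- which(bad$group == "cpec")[1]
  j <- which(bad$group == "lsec")[1]
  bad[j, c("chrom", "start", "end", "name", "cpg_start", "cpg_end")] <-
    bad[i, c("chrom", "start", "end", "name", "cpg_start", "cpg_end")]
  expect_error(
    buildHierarchicalAtlas(bad, atlasGroups(fx$atlas), "human",
                           panGroup = "endothelial"),
    "overlap")
})

test_that("top variable blocks are ranked by cross-sample variance", {
  fx <- atlasFixture()
  top <- selectTopVariableBlocks(fx$betas, fx$blocks, n = 50)
  v <- apply(fx$betas, 1, var, na.rm = TRUE)
  ok <- S4Vectors::mcols(fx$blocks)$n_cpgs >= 3 &
    rowMeans(!is.na(fx$betas)) >= 0.9
  want <- order(-ifelse(ok, v, -Inf), seq_along(v))[1:50]
  expect_equal(S4Vectors::mcols(top$blocks)$name,
               S4Vectors::mcols(fx$blocks)$name[want])
  # constant blocks rank last: a constant row must not enter the top set
  # ahead of any variable one
  expect_true(min(v[want]) >= max(0, sort(v[ok], decreasing = TRUE)[50] - 1e-12))
  # coverage filter: a block covered in < 90% of samples is excluded
  betas2 <- fx$betas
  betas2[3, 1:3] <- NA  # 3/18 missing -> 83% coverage
  top2 <- selectTopVariableBlocks(betas2, fx$blocks, n = nrow(betas2))
  expect_false(S4Vectors::mcols(fx$blocks)$name[3] %in%
                 S4Vectors::mcols(top2$blocks)$name)
})

test_that("UPGMA heights match hand calculation and replicates cluster", {
  # 3 samples, L1 distances d(A,B)=2, d(A,C)=8, d(B,C)=6:
  # UPGMA joins A,B at height 2, then (AB),C at (8+6)/2 = 7
  betas <- cbind(A = c(0.0, 0.0), B = c(1.0, 1.0), C = c(4.0, 4.0))
  tree <- upgmaTree(betas)
  expect_equal(tree$hclust$height, c(2, 7))

  # two identical samples merge first at distance 0
  betas2 <- cbind(A = c(0.3, 0.3), B = c(0.3, 0.3), C = c(0.9, 0.1))
  tree2 <- upgmaTree(betas2)
  expect_equal(tree2$hclust$height[1], 0)
  expect_equal(sort(tree2$hclust$merge[1, ]), c(-2, -1))

  # synthetic replicates: perfect grouping, ratio > 5
  fix <- clusterFixture(seed = 4)
  tr <- upgmaTree(fix$betas)
  for (g in unique(fix$labels))
    expect_true(ape::is.monophyletic(tr$phylo,
                                     colnames(fix$betas)[fix$labels == g]))
  expect_gt(withinBetweenRatio(fix$betas, fix$labels), 5)
})
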