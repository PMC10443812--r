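test_that("PAT lines map to fragment records and round-trip identically", {
  f <- tempfile(fileext = ".pat")
  writeLines(c("chr1\t47\tCCT\t2"), f)  # 1-based on disk
  pat <- readPat(f)
  expect_equal(pat$chrom, "chr1")
  expect_equal(pat$cpg_start, 46L)  # 0-based internally
  expect_equal(pat$pattern, "CCT")
  expect_equal(pat$count, 2)

  # empty file -> empty table
  writeLines(character(0), f)
  expect_equal(nrow(readPat(f)), 0L)

  # alphabet violation names the line
  writeLines(c("chr1\t10\tCXT\t1"), f)
  expect_error(readPat(f), "line 1.*outside \\{C,T,\\.\\}")

  # round trip of a synthetic record set, multiplicities preserved as one
  # line per distinct pattern
  set.seed(42)
  pats <- vapply(seq_len(100), function(i)
    paste(sample(c("C", "T"), sample(1:6, 1), replace = TRUE),
          collapse = ""), "")
  recs <- aggregatePat(data.frame(
    chrom = "chr1", cpg_start = sort(sample(0:500, 100, replace = TRUE)),
    pattern = pats, count = as.numeric(sample(1:5, 100, replace = TRUE))))
  writePat(recs, f)
  expect_identical(readPat(f), recs)
  lines <- readLines(f)
  expect_equal(length(lines), nrow(recs))  # counts collapse, not duplicate

  # two records differing only in pattern stay two lines
  two <- data.frame(chrom = "chr1", cpg_start = c(5L, 5L),
                    pattern = c("CT", "TT"), count = c(1, 1))
  writePat(two, f)
  expect_equal(length(readLines(f)), 2L)

  # unsorted input refuses to write
  uns <- data.frame(chrom = "chr1", cpg_start = c(9L, 5L),
                    pattern = c("CT", "TT"), count = c(1, 1))
  expect_error(writePat(uns, f), "sorted")
})

test_that("PAT reader autodetects gzip from content and honors the map", {
  pat <- data.frame(chrom = "chr1", cpg_start = 3L, pattern = "CTC",
                    count = 1)
  fgz <- tempfile(fileext = ".pat.gz")
  writePat(pat, fgz)
  expect_identical(readPat(fgz), pat)
  # a gzipped file without the .gz extension still reads (magic bytes)
  f2 <- tempfile(fileext = ".pat")
  file.copy(fgz, f2)
  expect_identical(readPat(f2), pat)

  map <- CpGIndexMap(rep("chr1", 5), c(0L, 10L, 20L, 30L, 40L))
  expect_error(readPat(f2, cpgMap = map), "extends past")
})

test_that("BETA round-trips and validates meth <= total", {
  map <- CpGIndexMap(rep("chr1", 4), c(0L, 50L, 100L, 150L))
  tr <- MethylomeTrack(c(3, 0, 0, 2), c(4, 0, 0, 2), "s1")
  f <- tempfile(fileext = ".beta")
  writeBeta(tr, map, f)
  tr2 <- readBeta(f, map, "s1")
  expect_equal(methCounts(tr2), methCounts(tr))
  expect_equal(totalCounts(tr2), totalCounts(tr))

  # all-zero totals are a valid, fully uncovered track
  tr0 <- MethylomeTrack(rep(0, 4), rep(0, 4))
  writeBeta(tr0, map, f)
  expect_equal(sum(totalCounts(readBeta(f, map))), 0)

  # meth > total rejected at read and at construction
  writeLines("chr1\t2\t5\t4", f)
  expect_error(readBeta(f, map), "meth.*>.*total")
  expect_error(MethylomeTrack(c(5), c(4)), "meth > total")
})

test_that("patToBeta tallies per-site calls and skips '.'", {
  # one record "CT" count 2 anchored at index 0
  p1 <- data.frame(chrom = "chr1", cpg_start = 0L, pattern = "CT", count = 2)
  tr <- patToBeta(p1, 2)
  expect_equal(methCounts(tr), c(2, 0))
  expect_equal(totalCounts(tr), c(2, 2))

  # '.' contributes nothing at its site
  p2 <- data.frame(chrom = "chr1", cpg_start = 0L, pattern = "C.T",
                   count = 1)
  tr2 <- patToBeta(p2, 3)
  expect_equal(totalCounts(tr2)[2], 0)

  # fragment past the site universe is an error
  expect_error(patToBeta(p2, 2), "extends past")

  # 50 random records match the brute-force per-site tally
  set.seed(11)
  recs <- aggregatePat(data.frame(
    chrom = "chr1",
    cpg_start = sample(0:40, 50, replace = TRUE),
    pattern = vapply(seq_len(50), function(i) {
      p <- sample(c("C", "T", "."), sample(1:6, 1), replace = TRUE)
      p[1] <- sample(c("C", "T"), 1); p[length(p)] <- sample(c("C", "T"), 1)
      paste(p, collapse = "")
    }, ""),
    count = sample(1:4, 50, replace = TRUE)))
  got <- patToBeta(recs, 50)
  want <- oracleTally(recs, 50)
  expect_equal(methCounts(got), want$meth)
  expect_equal(totalCounts(got), want$total)
})

test_that("conversion efficiency is the T fraction of called spike-in sites", {
  # forced arithmetic: 995 T and 5 C calls
  pat <- data.frame(chrom = "lambda", cpg_start = c(0L, 0L),
                    pattern = c("T", "C"), count = c(995, 5))
  expect_equal(conversionEfficiency(pat), 0.995)
  # all unconverted
  allC <- data.frame(chrom = "lambda", cpg_start = 0L, pattern = "CC",
                     count = 10)
  expect_equal(conversionEfficiency(allC), 0)
  # no observations is undefined
  expect_error(conversionEfficiency(allC[0, ]), "undefined")
  # generator closure: planted failure rate 0.01 recovered within 0.005
  spike <- generateLambdaSpikein(failureRate = 0.01, nCalls = 2e4, seed = 3)
  expect_lt(abs(conversionEfficiency(spike) - 0.99), 0.005)
})

test_that("blocks, CpG maps, manifests and atlases round-trip on disk", {
  fx <- atlasFixture()
  d <- tempfile(); dir.create(d)

  writeBlocksBed(fx$blocks, file.path(d, "b.bed"))
  b2 <- readBlocksBed(file.path(d, "b.bed"))
  expect_equal(S4Vectors::mcols(b2)$cpg_start,
               S4Vectors::mcols(fx$blocks)$cpg_start)
  expect_equal(GenomicRanges::start(b2), GenomicRanges::start(fx$blocks))

  writeCpgMap(fx$ref$map, file.path(d, "map.tsv"))
  m2 <- readCpgMap(file.path(d, "map.tsv"))
  expect_equal(cpgBp(m2), cpgBp(fx$ref$map))

  writeManifest(fx$ref$manifest, file.path(d, "mani.tsv"))
  m <- readManifest(file.path(d, "mani.tsv"))
  expect_equal(m$sample_id, fx$ref$manifest$sample_id)
  expect_error(readManifest(file.path(d, "mani.tsv"), groups = "only_this"),
               "outside the declared vocabulary")

  writeAtlas(fx$atlas, file.path(d, "atlas"))
  a2 <- readAtlas(file.path(d, "atlas"))
  expect_equal(atlasMarkers(a2)$name, atlasMarkers(fx$atlas)$name)
  expect_equal(atlasPriors(a2), atlasPriors(fx$atlas))
  expect_equal(sort(atlasGroups(a2)$sample_id),
               sort(atlasGroups(fx$atlas)$sample_id))
  expect_equal(atlasHierarchy(a2)$subtypes,
               atlasHierarchy(fx$atlas)$subtypes)
})

test_that("CpG map and track invariants are enforced", {
  expect_error(CpGIndexMap(c("chr1", "chr1"), c(10L, 10L)),
               "strictly increasing")
  expect_error(MethylomeTrack(c(1, 2), c(2, 2, 2)), "length")
  map <- CpGIndexMap(c("chr1", "chr1", "chr2"), c(5L, 9L, 2L))
  expect_equal(nCpGs(map), 3L)
  expect_equal(cpgChrom(map), c("chr1", "chr1", "chr2"))
  expect_equal(cpgBp(map), c(5L, 9L, 2L))
})
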