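# Shared fixtures. The full reference -> atlas -> models chain is expensive,
# so it is built once per test run and memoized.

.fixtureCache <- new.env(parent = emptyenv())

# Build (and cache) a reference atlas with trained models at the given seed.
atlasFixture <- function(seed = 7, ...) {
  key <- paste0("fx_", seed, "_", paste(deparse(substitute(list(...))),
                                        collapse = ""))
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  spec <- syntheticAtlasSpec(seed = seed, ...)
  ref <- generateReference(spec)
  blocks <- segmentMethylome(ref$tracks, ref$map)
  betas <- blockBetaMatrix(ref$tracks, blocks)
  obs <- blockFragmentCounts(ref$pats, blocks)
  gs <- split(ref$manifest$sample_id, ref$manifest$group)
  endo <- ref$manifest$sample_id[ref$manifest$role == "endothelial_subtype"]
  if (length(endo)) gs[[spec$panGroup]] <- endo
  mk <- selectMarkers(candidateFilter(blocks), betas, ref$manifest, "human",
                      groupSampleSets = gs, obsCounts = obs)
  mk$score <- NA_real_
  atlas <- buildHierarchicalAtlas(mk,
                                  ref$manifest[, c("sample_id", "group",
                                                   "role")],
                                  "human", panGroup = spec$panGroup)
  models <- trainAtlasModels(atlas, ref$pats)
  fx <- list(spec = spec, ref = ref, blocks = blocks, betas = betas,
             atlas = atlas, models = models)
  .fixtureCache[[key]] <- fx
  fx
}

# A tiny hand-checkable fragment table.
tinyPat <- function() {
  data.frame(chrom = "chr1",
             cpg_start = c(0L, 0L, 2L, 5L),
             pattern = c("CT", "C.T", "TTC", "CCT"),
             count = c(2, 1, 1, 3))
}
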