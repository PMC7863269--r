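test_that("zero rates give identical leaves and no events", {
  p <- smallSimParams(seed = 201, slipRate = 0, nonSsrIndelRate = 0,
                      tree = "(a:0,(b:0,c:0):0);")
  tr <- simulatePlastomes(p)
  anc <- as.character(genomeSequence(tr@ancestor))
  for (lf in tr@leaves)
    expect_identical(as.character(genomeSequence(lf)), anc)
  expect_identical(nrow(tr@events), 0L)
  expect_identical(unique(Biostrings::width(tr@alignment)),
                   genomeLength(tr@ancestor))
})

test_that("the same seed reproduces the simulation byte for byte", {
  t1 <- simulatePlastomes(smallSimParams(seed = 202))
  t2 <- simulatePlastomes(smallSimParams(seed = 202))
  expect_identical(as.character(t1@alignment), as.character(t2@alignment))
  expect_identical(t1@events, t2@events)
  expect_identical(t1@ssrCatalog, t2@ssrCatalog)
  t3 <- simulatePlastomes(smallSimParams(seed = 203))
  expect_false(identical(as.character(t1@alignment),
                         as.character(t3@alignment)))
})

test_that("contradictory parameters are rejected", {
  expect_error(simParams(lsc = -5), "positive")
  expect_error(simParams(largeDelRange = c(20000L, 30000L)),
               "smaller than SSC")
  expect_error(simParams(tree = "(a:1,b:1);"), ">= 3 leaves")
  expect_error(simParams(hotspot = list(start = 83000L, width = 5000L,
                                        multiplier = 6.5)),
               "inside the LSC")
})

test_that("the scanner reproduces the planted SSR catalogue exactly", {
  for (sd in c(204, 205)) {
    tr <- simulatePlastomes(smallSimParams(seed = sd))
    found <- findSSRs(genomeSequence(tr@ancestor))
    expect_identical(found[, c("motif", "repeat_count", "start", "end")],
                     tr@ssrCatalog[, c("motif", "repeat_count", "start",
                                       "end")])
  }
})

test_that("every simulated leaf keeps an exact inverted-repeat mirror", {
  tr <- simulatePlastomes(smallSimParams(seed = 206))
  truthLen <- leafRegionLengths(tr)
  for (tp in names(tr@leaves)) {
    st <- detectQuadripartite(tr@leaves[[tp]], minIr = 2000L)
    expect_identical(unname(regionWidths(st)), unname(truthLen[tp, ]),
                     label = sprintf("region lengths of %s", tp))
    s <- as.character(genomeSequence(tr@leaves[[tp]]))
    irb <- substr(s, IRanges::start(st@irb), IRanges::end(st@irb))
    ira <- substr(s, IRanges::start(st@ira), IRanges::end(st@ira))
    expect_identical(rcOracle(irb), ira)
  }
})

test_that("caller recall and classification accuracy meet the truth", {
  tr <- simulatePlastomes(smallSimParams(seed = 207))
  tt <- truthEventTable(tr)
  expect_gte(nrow(tt), 10L)
  ev <- classifyIndels(callIndels(tr@alignment, "A_chinensis"))
  key <- function(s, e) paste(s, e)
  m <- match(key(tt$col_start, tt$col_end), key(ev$col_start, ev$col_end))
  expect_gte(mean(!is.na(m)), 0.95)
  ok <- !is.na(m)
  expect_gte(mean(tt$klass[ok] == ev$klass[m[ok]]), 0.9)
})

test_that("fixtures round-trip through the readers", {
  tr <- simulatePlastomes(smallSimParams(seed = 208))
  dir <- withr::local_tempdir()
  paths <- writeFixture(tr, dir)
  rec <- readPlastome(file.path(dir, "A_lancea.gb"), "genbank")
  expect_identical(as.character(genomeSequence(rec)),
                   as.character(genomeSequence(tr@leaves[["A_lancea"]])))
  expect_identical(
    sort(unique(featuresToDataFrame(geneFeatures(rec))$gene)),
    sort(unique(featuresToDataFrame(
      geneFeatures(tr@leaves[["A_lancea"]]))$gene)))
  aln <- readAlignment(file.path(dir, "alignment.fasta"))
  expect_identical(as.character(aln), as.character(tr@alignment))
  expect_identical(sort(names(aln)), sort(names(tr@leaves)))
  tru <- readNewick(file.path(dir, "true_tree.nwk"))
  expect_setequal(tru$tip.label, names(tr@leaves))
})

test_that("simulated pi is close to the tree-implied expectation", {
  # two taxa at total distance 0.01 on uniform-rate regions: the expected
  # pairwise difference equals the substitution probability
  p <- simParams(lsc = 8000L, ir = 2000L, ssc = 3000L, nTracts = 0L,
                 slipRate = 0, nonSsrIndelRate = 0,
                 regionRateFactors = c(LSC = 1, IR = 1, SSC = 1),
                 hotspot = list(start = 1L, width = 1L, multiplier = 1),
                 largeDelRange = c(100L, 200L),
                 tree = "(a:0.005,b:0.005,c:0.005);", seed = 209)
  B <- 60
  pis <- vapply(seq_len(B), function(i) {
    p$seed <- 209L + i
    tr <- simulatePlastomes(p)
    m <- alignmentMatrix(tr@alignment)[c("a", "b"), ]
    mean(m[1, ] != m[2, ])
  }, 0)
  se <- sd(pis) / sqrt(B)
  expect_lt(abs(mean(pis) - 0.01), 3 * se + 2e-4)
})

test_that("windowed pi peaks inside the seeded hotspot", {
  hits <- 0L
  for (sd in 301:310) {
    tr <- simulatePlastomes(smallSimParams(seed = sd))
    w <- slidingWindowPi(tr@alignment, 600, 100)
    peak <- w[which.max(w$pi), ]
    mid <- (peak$window_start + peak$window_end) / 2
    hotCols <- which(tr@regionLabels == "LSC")
    hs <- tr@params$hotspot
    # hotspot interval in alignment columns (ancestor coords are a lower
    # bound; indels shift by at most a few hundred columns)
    if (mid >= hs$start - 500 && mid <= hs$start + hs$width + 500)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
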