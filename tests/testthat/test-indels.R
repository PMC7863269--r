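test_that("basic deletion and shared gap runs are called as single events", {
  aln <- c(ref = "ACGTACGT", alt = "ACG--CGT", out = "ACGTACGT")
  ev <- callIndels(aln, "ref")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$polarity, "deletion")
  expect_identical(ev$length, 2L)
  expect_identical(ev$ref_pos, 3L)       # base immediately left of the gap
  expect_identical(ev$carriers, "alt")

  # two taxa sharing one 3-column run merge into one multi-carrier event
  aln2 <- c(ref = "AAGGGCCTT", a = "AA---CCTT", b = "AA---CCTT",
            c = "AAGGGCCTT")
  ev2 <- callIndels(aln2, "ref")
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$carriers, "a,b")
  expect_identical(ev2$n_carriers, 2L)

  # insertion relative to the reference
  aln3 <- c(ref = "AAGG--CCTT", a = "AAGGTGCCTT", b = "AAGG--CCTT")
  ev3 <- callIndels(aln3, "ref")
  expect_identical(ev3$polarity, "insertion")
  expect_identical(ev3$carriers, "a")
  # left-normalized: inserting GT after position 3 spells the same string
  expect_identical(ev3$seq, "GT")
  expect_identical(ev3$ref_pos, 3L)

  # overlapping-but-unequal spans stay separate events
  aln4 <- c(ref = "AAGGGCCTT", a = "AA---CCTT", b = "AA--GCCTT")
  ev4 <- callIndels(aln4, "ref")
  expect_identical(nrow(ev4), 2L)
})

test_that("left-normalization gives identical positions for shifted gaps", {
  # the same 1-bp deletion placed at either end of a homopolymer
  left <- c(ref = "GC-AAAT", x = "GCAAAAT")   # note: ref insertion variant
  aln1 <- c(ref = "GCAAAAT", x = "GC-AAAT")
  aln2 <- c(ref = "GCAAAAT", x = "GCAAA-T")
  e1 <- callIndels(aln1, "ref")
  e2 <- callIndels(aln2, "ref")
  expect_identical(e1$ref_pos, e2$ref_pos)
  expect_identical(e1$seq, e2$seq)
  expect_identical(e1$ref_pos, 2L)
  # malformed: a run gapped in every taxon
  expect_error(callIndels(c(ref = "AA--TT", x = "AA--TT"), "ref"),
               "malformed")
  expect_error(callIndels(c(a = "AAA", b = "AAA"), "ref"), "not in")
})

test_that("row order never changes the called event set", {
  set.seed(113)
  tr <- simulatePlastomes(smallSimParams(seed = 301))
  m <- alignmentMatrix(tr@alignment)
  ev <- callIndels(m, "A_chinensis")
  evP <- callIndels(m[sample(nrow(m)), ], "A_chinensis")
  o <- function(d) d[order(d$col_start), c("col_start", "col_end",
                                           "length", "polarity", "seq")]
  expect_identical(o(ev), o(evP))
  evP$carriers <- vapply(strsplit(evP$carriers, ","), function(x)
    paste(sort(x), collapse = ","), "")
  ev$carriers <- vapply(strsplit(ev$carriers, ","), function(x)
    paste(sort(x), collapse = ","), "")
  expect_identical(ev$carriers[order(ev$col_start)],
                   evP$carriers[order(evP$col_start)])
})

test_that("slippage classification follows the SSR thresholds", {
  ref <- paste0("GGCC", strrep("A", 9), "TTGGCCAGT")
  # 1-bp A insertion against a 9-A tract: the longer allele reaches 10
  expect_identical(classifyIndel(4L, 1L, "A", "insertion", ref),
                   "SSR_related")
  # deleting one A from a 10-A tract: the longer allele (the reference)
  # meets the threshold
  ref10 <- paste0("GGCC", strrep("A", 10), "TTGGCCAGT")
  expect_identical(classifyIndel(4L, 1L, "A", "deletion", ref10),
                   "SSR_related")
  # but from a 9-A tract the longer allele stays below it
  expect_identical(classifyIndel(4L, 1L, "A", "deletion", ref),
                   "non_SSR")
  # the same insertion against only 8 As stays below the threshold
  ref8 <- paste0("GGCC", strrep("A", 8), "TTGGCCAGT")
  expect_identical(classifyIndel(4L, 1L, "A", "insertion", ref8),
                   "non_SSR")
  # non-repetitive 3-bp indel
  expect_identical(classifyIndel(4L, 3L, "GGC", "insertion", ref),
                   "non_SSR")
  # a 6-bp duplication that tandem-stacks with its flank into a
  # threshold-meeting hexanucleotide run
  ref6 <- paste0("TTGC", strrep("AATATG", 2), "CCGTA")
  expect_identical(classifyIndel(4L, 6L, "AATATG", "insertion", ref6),
                   "SSR_related")
  expect_identical(classifyIndel(4L, 6L, "AATATG", "insertion",
                                 "TTGCAATATGCCGTA"), "non_SSR")
})

test_that("every event gets exactly one class", {
  tr <- simulatePlastomes(smallSimParams(seed = 302))
  ev <- classifyIndels(callIndels(tr@alignment, "A_chinensis"))
  expect_true(all(ev$klass %in% c("SSR_related", "non_SSR")))
})

test_that("spectrum reports sizes, classes and the largest event", {
  tr <- simulatePlastomes(smallSimParams(seed = 303))
  ev <- classifyIndels(callIndels(tr@alignment, "A_chinensis"))
  sp <- indelSpectrum(ev)
  expect_identical(sp$n_events, nrow(ev))
  expect_identical(sp$n_ssr_related + sp$n_non_ssr, sp$n_events)
  expect_identical(sum(sp$by_size$Freq), nrow(ev))
  expect_identical(sp$largest$length, max(ev$length))
  empty <- indelSpectrum(ev[0, ])
  expect_identical(empty$n_events, 0L)
})

test_that("indel coding yields one informative binary column per event", {
  aln <- c(ref = "AAGGGCCTT", a = "AA---CCTT", b = "AAGGGCCTT",
           c = "AAGGGCCTT")
  ev <- callIndels(aln, "ref")
  mat <- buildIndelMatrix(ev)
  expect_identical(dim(mat), c(4L, 1L))
  expect_identical(unname(mat["a", 1]), 0L)   # deletion carrier lacks it
  expect_identical(unname(mat["ref", 1]), 1L)
  expect_error(buildIndelMatrix(ev[0, ]), "no events")
})

test_that("events round-trip: edits reconstruct every carrier sequence", {
  # indel-only regime (zero branch lengths suppress substitutions)
  tree0 <- paste0("(A_carlinoides:0,(A_macrocephala:0,((A_japonica:0,",
                  "A_lancea:0):0,(A_chinensis:0,A_coreana:0):0):0):0);")
  tr <- simulatePlastomes(smallSimParams(seed = 304, tree = tree0))
  ev <- callIndels(tr@alignment, "A_chinensis")
  refU <- attr(ev, "refSeq")
  for (tx in names(tr@leaves)) {
    s <- refU
    for (i in order(-ev$ref_pos)) {
      carved <- strsplit(ev$carriers[i], ",", fixed = TRUE)[[1]]
      if (!(tx %in% carved)) next
      p <- ev$ref_pos[i]; L <- ev$length[i]
      s <- if (ev$polarity[i] == "deletion")
        paste0(substr(s, 1, p), substr(s, p + L + 1, nchar(s)))
      else paste0(substr(s, 1, p), ev$seq[i],
                  substr(s, p + 1, nchar(s)))
    }
    expect_identical(s, as.character(genomeSequence(tr@leaves[[tx]])),
                     label = sprintf("reconstruction of %s", tx))
  }
})

test_that("VCF export writes one well-formed record per event", {
  aln <- c(ref = "ACGTACGT", alt = "ACG--CGT", out = "ACGTACGT")
  ev <- classifyIndels(callIndels(aln, "ref"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeIndelVcf(ev, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), 1L)
  fields <- strsplit(body, "\t")[[1]]
  expect_identical(fields[1], "ref")
  expect_identical(nchar(fields[4]) - nchar(fields[5]), 2L)
})
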