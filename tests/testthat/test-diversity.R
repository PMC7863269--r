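test_that("site classification matches the per-column definitions", {
  aln <- c(a = "AACA", b = "AACC", c = "AAGA", d = "AAGC")
  sc <- classifySites(aln)
  expect_identical(sc$aligned_length, 4L)
  expect_identical(sc$variable_sites, 2L)
  expect_identical(sc$informative_sites, 2L)     # both CC/GG splits
  # A,A,A,C is variable but not informative
  sc2 <- classifySites(c(a = "A", b = "A", c = "A", d = "C"))
  expect_identical(sc2$variable_sites, 1L)
  expect_identical(sc2$informative_sites, 0L)
  # gaps and N invalidate a column entirely
  sc3 <- classifySites(c(a = "AC-", b = "ANN", c = "ACA"))
  expect_identical(sc3$valid_sites, 1L)
  expect_error(classifySites(c(a = "AA")), "at least 2")
})

test_that("site counts equal an exhaustive per-column recount", {
  set.seed(114)
  for (rep in 1:10) {
    seqs <- vapply(1:6, function(i) randSeq(200), "")
    # sprinkle mutations, gaps and Ns
    seqs <- vapply(seqs, function(s) {
      v <- strsplit(s, "")[[1]]
      idx <- sample(200, 25)
      v[idx] <- sample(c("A", "C", "G", "T", "N", "-"), 25, TRUE)
      paste(v, collapse = "")
    }, "")
    names(seqs) <- paste0("t", 1:6)
    got <- classifySites(seqs)
    want <- bruteSiteCounts(seqs)
    expect_identical(got$valid_sites, unname(want["valid"]))
    expect_identical(got$variable_sites, unname(want["variable"]))
    expect_identical(got$informative_sites, unname(want["informative"]))
  }
})

test_that("pi follows the complete-deletion definition", {
  a <- paste0(strrep("A", 99), "G"); b <- paste0(strrep("A", 99), "T")
  expect_equal(nucleotideDiversity(c(a = a, b = b)), 0.01)
  expect_identical(nucleotideDiversity(c(a = a, b = a)), 0)
  expect_error(nucleotideDiversity(c(a = "---", b = "AAA")), "undefined")
  set.seed(115)
  for (rep in 1:10) {
    seqs <- setNames(vapply(1:4, function(i) {
      v <- strsplit(randSeq(150), "")[[1]]
      v[sample(150, 10)] <- sample(c("A", "C", "G", "T", "-"), 10, TRUE)
      paste(v, collapse = "")
    }, ""), paste0("t", 1:4))
    expect_equal(nucleotideDiversity(seqs), brutePi(seqs),
                 tolerance = 1e-12)
  }
})

test_that("row permutation changes no diversity statistic", {
  set.seed(116)
  seqs <- setNames(vapply(1:5, function(i) randSeq(300), ""),
                   paste0("t", 1:5))
  p <- sample(5)
  expect_equal(nucleotideDiversity(seqs), nucleotideDiversity(seqs[p]))
  expect_identical(classifySites(seqs)[, -1], classifySites(seqs[p])[, -1])
})

test_that("adding a mutation never decreases variable sites", {
  set.seed(117)
  seqs <- setNames(vapply(1:4, function(i) randSeq(200), ""),
                   paste0("t", 1:4))
  v0 <- classifySites(seqs)$variable_sites
  for (rep in 1:10) {
    mseqs <- seqs
    pos <- sample(200, 1)
    old <- substr(mseqs[1], pos, pos)
    substr(mseqs[1], pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                 old), 1)
    expect_gte(classifySites(mseqs)$variable_sites, v0)
  }
})

test_that("mean pi over replicate pairs estimates the mutation rate", {
  set.seed(118)
  p <- 0.02; L <- 400; B <- 250
  pis <- replicate(B, {
    s1 <- strsplit(randSeq(L), "")[[1]]
    s2 <- s1
    hit <- runif(L) < p
    s2[hit] <- vapply(s2[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    nucleotideDiversity(c(a = paste(s1, collapse = ""),
                          b = paste(s2, collapse = "")))
  })
  se <- sd(pis) / sqrt(B)
  expect_lt(abs(mean(pis) - p), 3 * se)
})

test_that("window arithmetic and tiling follow the step rule", {
  aln <- c(a = strrep("A", 1000), b = strrep("A", 1000))
  w <- slidingWindowPi(aln, 600, 100)
  expect_identical(nrow(w), 5L)
  expect_identical(w$window_start, c(1L, 101L, 201L, 301L, 401L))
  expect_true(all(w$pi == 0))
  # every column up to the last window end is covered
  covered <- rep(FALSE, max(w$window_end))
  for (i in seq_len(nrow(w)))
    covered[w$window_start[i]:w$window_end[i]] <- TRUE
  expect_true(all(covered))
  # trailing partial window only on request, and flagged
  w2 <- slidingWindowPi(aln, 600, 100, emitPartial = TRUE)
  expect_identical(nrow(w2), 6L)
  expect_true(w2$partial[6])
  expect_identical(w2$window_end[6], 1000L)
  expect_error(slidingWindowPi(aln, 50, 100), "window >= step")
  expect_error(slidingWindowPi(c(a = "AAA", b = "AAA"), 600, 100),
               "shorter than window")
})

test_that("windows without valid sites get NA pi, not zero", {
  a <- paste0(strrep("A", 300), strrep("-", 700))
  b <- paste0(strrep("A", 300), strrep("-", 700))
  w <- slidingWindowPi(c(a = a, b = b), 600, 100)
  expect_true(is.na(w$pi[nrow(w)]))
  expect_false(is.na(w$pi[1]))
})

test_that("concatenated pi is the valid-site-weighted mean of parts", {
  set.seed(119)
  mk <- function(n) {
    m <- do.call(rbind, strsplit(vapply(1:4, function(i) randSeq(n), ""),
                                 ""))
    m[sample(length(m), n %/% 10)] <- "-"
    rownames(m) <- paste0("t", 1:4)
    m
  }
  m1 <- mk(120); m2 <- mk(200)
  st1 <- classifySites(m1); st2 <- classifySites(m2)
  p1 <- nucleotideDiversity(m1); p2 <- nucleotideDiversity(m2)
  pc <- nucleotideDiversity(cbind(m1, m2))
  expect_equal(pc, (p1 * st1$valid_sites + p2 * st2$valid_sites) /
                     (st1$valid_sites + st2$valid_sites),
               tolerance = 1e-12)
})

test_that("marker extraction maps anchors through the reference row", {
  feats <- data.frame(gene = c("geneA", "geneB"),
                      kind = "protein_coding",
                      start = c(1L, 151L), end = c(100L, 250L),
                      strand = c("+", "-"), part = 1L, copy_tag = "",
                      stringsAsFactors = FALSE)
  ref <- randSeq(250)
  aln <- c(ref = ref, alt = ref)
  sub <- extractMarker(aln, "ref", feats, markerDef("A-B",
                                                    c("geneA", "geneB")))
  expect_identical(ncol(sub), 50L)
  expect_identical(unname(attr(sub, "ref_interval")),
                   c(101L, 150L))
  # anchor order is strand-agnostic: swapping gives the same interval
  sub2 <- extractMarker(aln, "ref", feats, markerDef("B-A",
                                                     c("geneB", "geneA")))
  expect_identical(attr(sub2, "ref_interval")[["start"]], 101L)
  # genic marker spans the gene itself
  subg <- extractMarker(aln, "ref", feats, markerDef("geneA", "geneA"))
  expect_identical(ncol(subg), 100L)
  expect_error(extractMarker(aln, "ref", feats,
                             markerDef("x", c("geneA", "nope"))),
               "nope")
  # insertion columns inside the interval are kept
  aln3 <- c(ref = paste0(substr(ref, 1, 120), "--",
                         substr(ref, 121, 250)),
            alt = paste0(substr(ref, 1, 120), "GG",
                         substr(ref, 121, 250)))
  sub3 <- extractMarker(aln3, "ref", feats, markerDef("A-B",
                                                      c("geneA", "geneB")))
  expect_identical(ncol(sub3), 52L)
})

test_that("marker report concatenations add lengths and counts", {
  set.seed(120)
  feats <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                      kind = "protein_coding",
                      start = c(1L, 201L, 401L, 601L),
                      end = c(100L, 300L, 500L, 700L),
                      strand = "+", part = 1L, copy_tag = "",
                      stringsAsFactors = FALSE)
  ref <- randSeq(700)
  alt <- ref
  substr(alt, 150, 150) <- if (substr(ref, 150, 150) == "A") "C" else "A"
  aln <- c(ref = ref, alt = alt, o3 = ref)
  mks <- list("m1" = markerDef("m1", c("g1", "g2")),
              "m2" = markerDef("m2", c("g3", "g4")))
  rep <- markerReport(aln, "ref", feats, mks,
                      groups = list(both = c("m1", "m2")))
  expect_identical(rep$length[3], rep$length[1] + rep$length[2])
  expect_identical(rep$variable_sites[3],
                   rep$variable_sites[1] + rep$variable_sites[2])
  expect_identical(rep$variable_sites, c(1L, 0L, 1L))
  expect_identical(rep$pi[2], 0)
})

test_that("per-region diversity table slices through the reference", {
  tr <- simulatePlastomes(smallSimParams(seed = 305))
  st <- detectQuadripartite(tr@leaves[["A_chinensis"]], minIr = 2000L)
  tab <- regionDiversityTable(tr@alignment, "A_chinensis", st)
  expect_identical(tab$region, c("LSC", "IRb", "SSC", "IRa", "total"))
  tot <- tab[tab$region == "total", ]
  expect_gte(tot$aligned_length, sum(tab$aligned_length[1:4]) - 4L)
  expect_true(all(tab$informative_sites <= tab$variable_sites))
  expect_true(all(tab$variable_sites <= tab$valid_sites))
})
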