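test_that("p-distance uses pairwise deletion and matches oracles", {
  aln <- c(a = "AAAA", b = "AAAT", c = "TTTT")
  d <- pDistance(aln)
  expect_equal(unname(d["a", "b"]), 0.25)
  expect_equal(unname(d["a", "c"]), 1)
  expect_true(all(diag(d) == 0))
  # identical rows give a zero matrix
  z <- pDistance(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_true(all(z == 0))
  set.seed(121)
  for (rep in 1:5) {
    seqs <- setNames(vapply(1:5, function(i) {
      v <- strsplit(randSeq(120), "")[[1]]
      v[sample(120, 8)] <- "-"
      paste(v, collapse = "")
    }, ""), paste0("t", 1:5))
    d <- pDistance(seqs)
    # brute recount
    m <- do.call(rbind, strsplit(seqs, ""))
    for (i in 1:4) for (j in (i + 1):5) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      expect_equal(unname(d[i, j]), sum(m[i, ok] != m[j, ok]) / sum(ok))
    }
    # independent implementation cross-check
    db <- as.matrix(ape::dist.dna(ape::as.DNAbin(
      do.call(rbind, strsplit(tolower(seqs), ""))), model = "raw",
      pairwise.deletion = TRUE))
    expect_equal(unname(d), unname(db[rownames(d), colnames(d)]),
                 tolerance = 1e-12)
  }
  expect_error(pDistance(c(a = "A-", b = "-A", c = "AA")), "comparable")
})

test_that("indel distances are normalized Hamming distances", {
  m <- rbind(a = c(1L, 0L, 1L, 0L), b = c(0L, 1L, 0L, 1L),
             c = c(1L, 0L, 1L, 0L))
  d <- indelDistance(m)
  expect_equal(unname(d["a", "b"]), 1)
  expect_equal(unname(d["a", "c"]), 0)
  expect_error(indelDistance(matrix(1L, 3, 2)), "constant")
  expect_error(indelDistance(matrix(integer(), 3, 0)), "at least one")
})

test_that("NJ recovers additive topologies and clamps negative branches", {
  # 3 taxa: the unique unrooted tree with additive branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighborJoining(d3)
  expect_identical(ape::Ntip(t3), 3L)
  expect_equal(sum(t3$edge.length), 6)   # a=1, b=2, c=3
  # additive matrices from random trees, 4-6 taxa
  set.seed(122)
  for (rep in 1:20) {
    k <- sample(4:6, 1)
    tr <- ape::rtree(k, br = function(n) runif(n, 0.05, 0.5))
    d <- cophenetic(tr)
    got <- neighborJoining(d[sort(rownames(d)), sort(rownames(d))])
    expect_true(sameTopology(got, tr))
  }
  expect_error(neighborJoining(matrix(c(0, NA, NA, 0), 2, 2)),
               "non-finite")
  dneg <- matrix(c(0, 0.302, 0.404, 0.913,
                   0.302, 0, 0.594, 0.242,
                   0.404, 0.594, 0, 0.903,
                   0.913, 0.242, 0.903, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tneg <- neighborJoining(dneg), "clamped")
  expect_true(all(tneg$edge.length >= 0))
})

test_that("topology is invariant under taxon relabeling of the input", {
  set.seed(123)
  seqs <- setNames(vapply(1:5, function(i) randSeq(400), ""),
                   paste0("t", 1:5))
  # add shared signal
  seqs[2] <- seqs[1]; substr(seqs[2], 1, 5) <- "CCCCC"
  t1 <- neighborJoining(pDistance(seqs))
  p <- sample(5)
  t2 <- neighborJoining(pDistance(seqs[p]))
  expect_true(sameTopology(t1, t2))
})

test_that("newick output round-trips topology, lengths and labels", {
  set.seed(124)
  tr <- ape::rtree(6)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  tr2 <- readNewick(f)
  expect_setequal(tr2$tip.label, tr$tip.label)
  expect_true(sameTopology(tr, tr2))
  o <- match(tr$tip.label, tr2$tip.label)
  d1 <- cophenetic(tr); d2 <- cophenetic(tr2)
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-9)
})

test_that("bootstrap supports behave at the degenerate settings", {
  set.seed(125)
  # perfectly congruent signal: blocks of identical columns
  blocks <- c(a = "AAAACCCC", b = "AAAACCCC", c = "TTTTGGGG",
              d = "TTTTGGGG", e = "TTAAGGCC")
  bt <- bootstrapSupport(blocks, replicates = 30, seed = 9)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] == 1))
  # one replicate: supports are 0 or 1
  b1 <- bootstrapSupport(blocks, replicates = 1, seed = 3)
  s1 <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 1)))
  # seeded determinism
  b2 <- bootstrapSupport(blocks, replicates = 10, seed = 77)
  b3 <- bootstrapSupport(blocks, replicates = 10, seed = 77)
  expect_identical(ape::write.tree(b2), ape::write.tree(b3))
  expect_error(bootstrapSupport(blocks, replicates = 0), ">= 1")
})

test_that("alignments export to relaxed PHYLIP and NEXUS", {
  aln <- c(tax_one = "ACGT-CGT", tax_two = "ACGTACGT", tax_three = "ACCTACGT")
  fp <- withr::local_tempfile(fileext = ".phy")
  exportAlignment(aln, fp, "phylip")
  lines <- readLines(fp)
  expect_match(lines[1], "^ 3 8$")
  expect_match(lines[2], "^tax_one  ACGT-CGT$")
  fn <- withr::local_tempfile(fileext = ".nex")
  exportAlignment(aln, fn, "nexus")
  expect_true(any(grepl("NEXUS", readLines(fn), ignore.case = TRUE)))
})
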