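# Quadripartite structure delimitation.
#
# The inverted-repeat pair is found by exact seed-and-extend: k-mer probes
# taken from the reverse complement are matched against the doubled sequence
# (so repeats spanning the record origin are seen), and every seed hit is
# extended to the maximal exact inverted match. Base-to-base, a position a of
# one arm pairs with position b of the other with a + b constant along the
# repeat, so extension walks that diagonal. N never matches anything.

# Maximal exact inverted-repeat candidates of a circular sequence.
# Returns a data.frame: len, startA, startB (0-based circle coords of the
# ascending arm starts).
.invertedRepeatCandidates <- function(s, minIr, seedK) {
  n <- nchar(s)
  x <- .seqToInt(s)          # A,C,G,T -> 1..4, N -> NA
  y <- 5L - x                # complement codes
  rc <- .revcompChr(s)
  s2 <- Biostrings::DNAString(paste0(s, s))
  stride <- max(seedK, minIr %/% 4L)
  probes <- seq(1L, n - seedK + 1L, by = stride)

  okAt <- function(aa, bb) {
    # vectorized inverted-match test at 0-based circle positions
    v <- x[(aa %% n) + 1L] == y[(bb %% n) + 1L]
    v & !is.na(v)
  }
  extend <- function(a0, b0, k) {
    # seed guarantees t = 0..k-1; extend the diagonal both ways, chunked
    chunk <- 2048L
    thi <- k - 1L
    repeat {
      t <- (thi + 1L):(thi + chunk)
      good <- okAt(a0 + t, b0 - t)
      bad <- which(!good)
      if (length(bad)) { thi <- thi + bad[1] - 1L; break }
      thi <- thi + chunk
      if (thi - 0L + 1L > n) { thi <- n - 1L; break }
    }
    tlo <- 0L
    repeat {
      t <- (tlo - 1L):(tlo - chunk)
      good <- okAt(a0 + t, b0 - t)
      bad <- which(!good)
      if (length(bad)) { tlo <- tlo - bad[1] + 1L; break }
      tlo <- tlo - chunk
      if (thi - tlo + 1L > n) break
    }
    len <- thi - tlo + 1L
    aS <- (a0 + tlo) %% n          # ascending arm start
    bS <- (b0 - thi) %% n          # other arm start (also ascending coords)
    # arms must be disjoint on the circle; a palindromic center can make the
    # extension run through the gap — trim until the arms no longer overlap
    while (len > 0L && aS != bS &&
           (((bS - aS) %% n) < len || ((aS - bS) %% n) < len)) {
      len <- len - 1L
      bS <- (bS + 1L) %% n
    }
    c(len = len, startA = aS, startB = bS)
  }

  out <- list()
  seen <- character()
  for (p in probes) {
    probe <- substr(rc, p, p + seedK - 1L)
    if (grepl("N", probe, fixed = TRUE)) next
    hits <- Biostrings::matchPattern(probe, s2)
    if (length(hits) == 0) next
    for (m in BiocGenerics::start(hits)) {
      if (m > n) next                    # each circle position once
      a0 <- m - 1L                       # 0-based
      b0 <- (n - p) %% n                 # 0-based partner of t = 0
      # skip the trivial pairing of a probe with its own source only when the
      # two arms coincide; leave real palindromic IRs to the extension
      run <- extend(a0, b0, seedK)
      if (run["len"] < minIr) next
      arms <- sort(c(run["startA"], run["startB"]))
      key <- paste(run["len"], arms[1], arms[2])
      if (key %in% seen) next
      seen <- c(seen, key)
      if (run["startA"] == run["startB"]) next   # self-palindrome
      out[[length(out) + 1L]] <- run
    }
  }
  if (length(out) == 0)
    return(data.frame(len = integer(), startA = integer(),
                      startB = integer()))
  df <- as.data.frame(do.call(rbind, out))
  # the same physical pair is found from both arms; canonicalize
  a1 <- pmin(df$startA, df$startB); a2 <- pmax(df$startA, df$startB)
  df$startA <- a1; df$startB <- a2
  unique(df)
}

#' Delimit the quadripartite structure of a circular plastome
#'
#' Finds the maximal exact inverted-repeat pair of length at least
#' \code{minIr}, which partitions the circle into four arcs; the longer
#' single-copy arc is the LSC. The returned intervals are on the canonical
#' orientation (genome starts at the LSC start; SSC follows IRb);
#' \code{rotationOffset} records the 0-based rotation that maps the input
#' sequence onto that orientation.
#'
#' @param x a \code{\link{PlastomeRecord}} or a character sequence
#' @param minIr minimum inverted-repeat length in bp (default 10000,
#'   appropriate for plastomes; lower it for toy sequences)
#' @param seedK k-mer seed length for the search (default 25)
#' @return a \code{\link{QuadripartiteStructure}}
#' @examples
#' lsc <- paste(sample(c("A","C","G","T"), 1000, TRUE), collapse = "")
#' # see vignette for a full constructed example
#' @export
detectQuadripartite <- function(x, minIr = 10000L, seedK = 25L) {
  s <- if (is(x, "PlastomeRecord")) as.character(genomeSequence(x))
       else toupper(x)
  .assertDna(s)
  n <- nchar(s)
  if (n <= 2L * minIr)
    .stopf("sequence length %d must exceed 2*minIr = %d", n, 2L * minIr)
  if (seedK > minIr) .stopf("seedK (%d) must not exceed minIr (%d)",
                            seedK, minIr)
  cand <- .invertedRepeatCandidates(s, minIr, seedK)
  cand <- cand[cand$len >= minIr, , drop = FALSE]
  if (nrow(cand) == 0)
    .stopf("structure not found: no inverted repeat of length >= %d", minIr)
  top <- cand[cand$len == max(cand$len), , drop = FALSE]
  if (nrow(top) > 1)
    .stopf(paste0("ambiguous structure: %d distinct inverted-repeat pairs ",
                  "of maximal length %d (starts: %s)"),
           nrow(top), top$len[1],
           paste(sprintf("(%d,%d)", top$startA, top$startB), collapse = " "))
  L <- top$len[1]
  aS <- top$startA[1]; bS <- top$startB[1]    # 0-based arm starts
  gap1 <- ((bS - (aS + L)) %% n)              # arc after arm A (before B)
  gap2 <- ((aS - (bS + L)) %% n)              # arc after arm B (before A)
  if (gap1 == gap2)
    .stopf("ambiguous structure: the two single-copy arcs have equal length")
  if (gap1 > gap2) {
    lscStart <- (aS + L) %% n; lscLen <- gap1
    irbStart <- bS; sscLen <- gap2
  } else {
    lscStart <- (bS + L) %% n; lscLen <- gap2
    irbStart <- aS; sscLen <- gap1
  }
  st <- new("QuadripartiteStructure",
    lsc = IRanges::IRanges(1L, lscLen),
    irb = IRanges::IRanges(lscLen + 1L, lscLen + L),
    ssc = IRanges::IRanges(lscLen + L + 1L, lscLen + L + sscLen),
    ira = IRanges::IRanges(lscLen + L + sscLen + 1L, n),
    genomeLength = n,
    rotationOffset = as.integer(lscStart))
  validObject(st)
  # mirror check on the canonical frame
  rot <- .rotateSeq(s, lscStart)
  irb <- substr(rot, lscLen + 1L, lscLen + L)
  ira <- substr(rot, lscLen + L + sscLen + 1L, n)
  if (!identical(.revcompChr(irb), ira))
    .stopf("internal error: detected IR arms are not exact mirror images")
  st
}

.rotateSeq <- function(s, offset0) {
  n <- nchar(s)
  offset0 <- offset0 %% n
  if (offset0 == 0) return(s)
  paste0(substr(s, offset0 + 1L, n), substr(s, 1L, offset0))
}

#' Rotate a plastome onto its canonical orientation
#'
#' Applies the rotation implied by \code{\link{detectQuadripartite}} so the
#' sequence starts at the LSC start; feature coordinates are shifted
#' accordingly.
#'
#' @param record a \code{\link{PlastomeRecord}}
#' @param structure optional precomputed structure; detected if missing
#' @param ... passed to \code{\link{detectQuadripartite}}
#' @return list with elements \code{record} (rotated) and \code{structure}
#'   (with \code{rotationOffset} reset to 0)
#' @export
canonicalizePlastome <- function(record, structure = NULL, ...) {
  if (is.null(structure)) structure <- detectQuadripartite(record, ...)
  off <- structure@rotationOffset
  n <- genomeLength(record)
  s <- .rotateSeq(as.character(genomeSequence(record)), off)
  df <- featuresToDataFrame(geneFeatures(record))
  if (nrow(df) && off != 0) {
    ns <- ((df$start - 1L - off) %% n) + 1L
    ne <- ((df$end - 1L - off) %% n) + 1L
    if (any(ns > ne))
      .stopf("feature '%s' would span the origin after canonicalization",
             df$gene[which(ns > ne)[1]])
    df$start <- ns; df$end <- ne
  }
  structure@rotationOffset <- 0L
  list(record = plastomeRecord(taxonId(record), s, df,
                               accession = accession(record)),
       structure = structure)
}

#' Region label of positions under a quadripartite structure
#'
#' @param structure a \code{\link{QuadripartiteStructure}}
#' @param position integer vector of 1-based positions
#' @param mergeIr collapse IRa/IRb into \code{"IR"} (default TRUE)
#' @return character vector of labels
#' @export
regionOfPosition <- function(structure, position, mergeIr = TRUE) {
  if (any(position < 1 | position > structure@genomeLength))
    .stopf("position out of range [1, %d]", structure@genomeLength)
  br <- c(IRanges::end(structure@lsc), IRanges::end(structure@irb),
          IRanges::end(structure@ssc), IRanges::end(structure@ira))
  lab <- c("LSC", "IRb", "SSC", "IRa")[findInterval(position - 1L, c(0L, br),
                                                    rightmost.closed = FALSE)]
  if (mergeIr) lab[lab %in% c("IRa", "IRb")] <- "IR"
  lab
}
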