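# Perfect microsatellite (SSR) scanning with per-motif-length minimum
# repeat counts, in the style of GMATA's perfect-repeat search.
#
# For each motif length u the sequence is compared against itself shifted by
# u bases; a maximal run of m consecutive matches means a stretch of length
# m + u with period u. The stretch's unit (its first u bases) is kept only
# if primitive — a stretch whose unit is itself a power of a shorter motif is
# exactly the stretch the shorter scan reports, with more units. Reported
# loci span whole units only, anchored at the leftmost phase.

#' Default SSR thresholds
#'
#' Minimum repeat counts by motif length: 10 (mono), 5 (di), 4 (tri),
#' 3 (tetra/penta/hexa).
#'
#' @param min_repeats named or positional integer vector of length 6
#' @return validated integer vector, names "1".."6"
#' @export
ssrThresholds <- function(min_repeats = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  if (length(min_repeats) != 6)
    .stopf("min_repeats must have exactly 6 values (motif lengths 1-6)")
  min_repeats <- as.integer(min_repeats)
  if (any(min_repeats < 2))
    .stopf("all minimum repeat counts must be >= 2")
  setNames(min_repeats, as.character(1:6))
}

.isPrimitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1) return(TRUE)
  for (d in seq_len(u - 1)) {
    if (u %% d != 0) next
    if (motif == strrep(substr(motif, 1, d), u %/% d)) return(FALSE)
  }
  TRUE
}

#' Find perfect microsatellites
#'
#' Returns maximal perfect tandem repeats with primitive motifs of length
#' 1-6 meeting the per-length minimum repeat counts. N breaks runs. A locus
#' reportable under two motif lengths is reported once under the shortest
#' motif; loci contained inside another reported locus are dropped.
#'
#' @param sequence character scalar or \code{DNAString} over {A,C,G,T,N}
#' @param thresholds from \code{\link{ssrThresholds}}
#' @return data.frame: motif, motif_length, repeat_count, start, end
#'   (1-based closed), seq
#' @examples
#' findSSRs(paste0("GC", strrep("A", 10), "GGCT"))
#' @export
findSSRs <- function(sequence, thresholds = ssrThresholds()) {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  empty <- data.frame(motif = character(), motif_length = integer(),
                      repeat_count = integer(), start = integer(),
                      end = integer(), seq = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  .assertDna(sequence)
  x <- .seqToInt(sequence)         # N -> NA, never matches
  n <- length(x)
  out <- list()
  for (u in 1:6) {
    if (n < 2L * u) next
    minRep <- thresholds[[as.character(u)]]
    eq <- x[seq_len(n - u)] == x[(u + 1L):n]
    eq[is.na(eq)] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= u * (minRep - 1L))
    for (h in hit) {
      i <- starts[h]                       # stretch = i .. ends[h] + u
      m <- r$lengths[h]
      count <- (m + u) %/% u
      if (count < minRep) next
      motif <- substr(sequence, i, i + u - 1L)
      if (!.isPrimitive(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, motif_length = u, repeat_count = count,
        start = i, end = i + count * u - 1L,
        seq = strrep(motif, count), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  df <- do.call(rbind, out)
  # drop loci contained in another reported locus
  if (nrow(df) > 1) {
    keep <- vapply(seq_len(nrow(df)), function(i) {
      contained <- df$start <= df$start[i] & df$end >= df$end[i] &
        !(df$start == df$start[i] & df$end == df$end[i])
      !any(contained)
    }, TRUE)
    df <- df[keep, , drop = FALSE]
  }
  df <- df[order(df$start, df$motif_length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Annotate SSR loci with region and genic context
#'
#' @param loci output of \code{\link{findSSRs}}
#' @param structure \code{\link{QuadripartiteStructure}} of the genome
#' @param features feature \code{GRanges}/data.frame (canonical frame)
#' @param taxon taxon label to attach
#' @return loci with added columns taxon, region, context, locus
#' @export
annotateSSRs <- function(loci, structure, features, taxon = "genome") {
  if (nrow(loci) == 0) {
    loci$taxon <- character(); loci$region <- character()
    loci$context <- character(); loci$locus <- character()
    return(loci)
  }
  if (any(loci$start < 1 | loci$end > structure@genomeLength))
    .stopf("SSR locus outside genome bounds [1, %d]",
           structure@genomeLength)
  mid <- (loci$start + loci$end) %/% 2L
  cl <- classifyPosition(structure, features, mid)
  loci$taxon <- taxon
  loci$region <- cl$region
  loci$context <- cl$context
  loci$locus <- cl$locus
  loci
}

#' Canonicalized motif (strand-independent representative)
#'
#' The lexicographically smallest string among all rotations of the motif
#' and of its reverse complement, so e.g. "T", "A" pool to "A" and
#' "AT"/"TA" pool to "AT".
#'
#' @param motif character vector of motifs
#' @return character vector
#' @export
canonicalMotif <- function(motif) {
  vapply(motif, function(m) {
    rots <- function(s) {
      k <- nchar(s)
      vapply(seq_len(k), function(i)
        paste0(substr(s, i, k), substr(s, 1, i - 1)), "")
    }
    min(c(rots(m), rots(.revcompChr(m))))
  }, "", USE.NAMES = FALSE)
}

#' Tabulate SSRs by taxon, region, context and motif class
#'
#' @param lociList named list (by taxon) of annotated locus tables from
#'   \code{\link{annotateSSRs}}
#' @param dedupIr if TRUE, count inverted-repeat loci once per genome
#'   (drops, per taxon, IR loci whose motif+length duplicate another IR
#'   locus); default FALSE counts both copies
#' @return list of data.frames: \code{by_region}, \code{by_context},
#'   \code{by_class} (motif-length class), \code{totals}, and \code{loci}
#'   (the row-bound annotated loci)
#' @export
tabulateSSRs <- function(lociList, dedupIr = FALSE) {
  if (is.null(names(lociList)))
    names(lociList) <- vapply(lociList, function(d)
      if (nrow(d)) d$taxon[1] else "taxon", "")
  all <- do.call(rbind, lociList)
  rownames(all) <- NULL
  if (dedupIr && nrow(all)) {
    keep <- rep(TRUE, nrow(all))
    ir <- which(all$region == "IR")
    if (length(ir)) {
      # the IRa copy of a tract reads as the reverse complement on the
      # forward strand, so de-duplicate on the canonicalized motif
      key <- paste(all$taxon[ir], canonicalMotif(all$motif[ir]),
                   all$repeat_count[ir])
      keep[ir[duplicated(key)]] <- FALSE
    }
    all <- all[keep, , drop = FALSE]
  }
  classNames <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  lv <- function(x, levels) factor(x, levels = levels)
  taxa <- names(lociList)
  tab <- function(what, levels) {
    t0 <- table(lv(all$taxon, taxa), lv(what, levels))
    df <- as.data.frame.matrix(t0)
    df <- cbind(taxon = rownames(df), df, total = as.integer(rowSums(df)))
    rownames(df) <- NULL
    df
  }
  list(
    by_region = tab(all$region, c("LSC", "SSC", "IR")),
    by_context = tab(all$context,
                     c("exon", "intron", "intergenic_spacer")),
    by_class = tab(classNames[all$motif_length], classNames),
    totals = data.frame(taxon = taxa,
                        n = as.integer(table(lv(all$taxon, taxa))),
                        stringsAsFactors = FALSE),
    loci = all)
}
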