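# Indel calling from a whole-genome multiple alignment against a named
# reference taxon, replication-slippage (SSR-related) classification, size
# spectra and binary indel coding.
#
# Event granularity: a maximal run of gap-bearing columns sharing one
# per-taxon gap pattern is one event; runs with identical span across
# several taxa are therefore a single multi-carrier event, while
# overlapping-but-unequal spans split into separate events. Events are
# left-normalized (shifted to the leftmost equivalent placement within
# repetitive context), as in VCF indel normalization.

#' Call indel events from a multiple alignment
#'
#' @param aln aligned sequences: \code{DNAStringSet}, named character vector
#'   or character matrix (gaps as \code{-})
#' @param refTaxon name of the reference row; indel size/position are
#'   reported on this taxon's ungapped coordinates
#' @return data.frame with one row per event: ref_pos (1-based position of
#'   the reference base immediately left of the event after
#'   left-normalization; 0 when at the reference start), length, seq,
#'   polarity ("insertion"/"deletion" relative to the reference), carriers
#'   (comma-separated taxa whose state differs from the reference),
#'   n_carriers, col_start, col_end (alignment columns of the gap run).
#'   Attributes: \code{taxa}, \code{refTaxon}, \code{refSeq} (ungapped).
#' @export
callIndels <- function(aln, refTaxon) {
  m <- alignmentMatrix(aln)
  taxa <- rownames(m)
  if (!refTaxon %in% taxa)
    .stopf("reference taxon '%s' not in alignment (%s)", refTaxon,
           paste(taxa, collapse = ", "))
  k <- nrow(m)
  if (k > 30) .stopf("more than 30 taxa not supported by the gap-mask coding")
  gap <- m == "-"
  mask <- as.integer(colSums(gap * 2 ^ (seq_len(k) - 1L)))
  refRow <- match(refTaxon, taxa)
  refU <- paste(m[refRow, !gap[refRow, ]], collapse = "")
  refCum <- cumsum(!gap[refRow, ])   # ref coordinate of each column's base

  empty <- data.frame(ref_pos = integer(), length = integer(),
                      seq = character(), polarity = character(),
                      carriers = character(), n_carriers = integer(),
                      col_start = integer(), col_end = integer(),
                      stringsAsFactors = FALSE)
  attr(empty, "taxa") <- taxa
  attr(empty, "refTaxon") <- refTaxon
  attr(empty, "refSeq") <- refU
  if (!any(mask > 0)) return(empty)

  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values > 0L)
  rows <- vector("list", length(runs))
  refChars <- .chars(refU)
  for (j in seq_along(runs)) {
    h <- runs[j]
    c1 <- starts[h]; c2 <- ends[h]
    G <- which(bitwAnd(r$values[h], 2 ^ (seq_len(k) - 1L)) > 0)
    if (length(G) == k)
      .stopf(paste0("malformed alignment: columns %d-%d are gapped in ",
                    "every taxon"), c1, c2)
    len <- c2 - c1 + 1L
    refGapped <- refRow %in% G
    if (refGapped) {
      polarity <- "insertion"
      src <- setdiff(seq_len(k), G)[1]
      sq <- paste(m[src, c1:c2], collapse = "")
      carriers <- taxa[setdiff(seq_len(k), G)]
    } else {
      polarity <- "deletion"
      sq <- paste(m[refRow, c1:c2], collapse = "")
      carriers <- taxa[G]
    }
    refPos <- if (c1 == 1L) 0L else refCum[c1 - 1L]
    # left-normalize within repetitive context on the reference
    sqv <- .chars(sq)
    while (refPos >= 1L && refChars[refPos] == sqv[len]) {
      sqv <- c(refChars[refPos], sqv[-len])
      refPos <- refPos - 1L
    }
    rows[[j]] <- data.frame(
      ref_pos = refPos, length = len, seq = .collapse(sqv),
      polarity = polarity, carriers = paste(carriers, collapse = ","),
      n_carriers = length(carriers), col_start = c1, col_end = c2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "taxa") <- taxa
  attr(out, "refTaxon") <- refTaxon
  attr(out, "refSeq") <- refU
  out
}

#' Classify one indel as SSR-related or not
#'
#' An event is SSR-related when (a) its sequence is whole copies of some
#' unit of length 1-6 and (b) the allele carrying more copies forms,
#' together with the adjacent reference sequence and in phase with the
#' event, a perfect tandem run meeting the SSR threshold for that unit
#' length — i.e. the event is attributable to replication slippage at a
#' microsatellite.
#'
#' @param ref_pos,length,seq,polarity event fields as returned by
#'   \code{\link{callIndels}}
#' @param refSeq the ungapped reference sequence (character scalar)
#' @param thresholds from \code{\link{ssrThresholds}}
#' @return "SSR_related" or "non_SSR"
#' @export
classifyIndel <- function(ref_pos, length, seq, polarity, refSeq,
                          thresholds = ssrThresholds()) {
  units <- unique(c(Filter(function(u) length %% u == 0, 1:6)))
  units <- units[units <= length]
  for (u in units) {
    unit <- substr(seq, 1, u)
    if (grepl("N", unit, fixed = TRUE)) next
    if (strrep(unit, length %/% u) != seq) next
    # build the longer allele around the event
    if (polarity == "deletion") {
      longer <- refSeq
      a <- ref_pos + 1L                       # event start in longer allele
    } else {
      longer <- paste0(substr(refSeq, 1, ref_pos), seq,
                       substr(refSeq, ref_pos + 1L, nchar(refSeq)))
      a <- ref_pos + 1L
    }
    copies <- length %/% u
    # in-phase copies to the left
    p <- a - u
    while (p >= 1 && substr(longer, p, p + u - 1L) == unit) {
      copies <- copies + 1L; p <- p - u
    }
    # and to the right
    p <- a + length
    while (p + u - 1L <= nchar(longer) &&
           substr(longer, p, p + u - 1L) == unit) {
      copies <- copies + 1L; p <- p + u
    }
    if (copies >= thresholds[[as.character(u)]]) return("SSR_related")
  }
  "non_SSR"
}

#' Classify all events in an indel table
#'
#' @param events table from \code{\link{callIndels}}
#' @param refSeq ungapped reference sequence; taken from the table's
#'   \code{refSeq} attribute when NULL
#' @param thresholds from \code{\link{ssrThresholds}}
#' @return events with a \code{klass} column added
#' @export
classifyIndels <- function(events, refSeq = NULL,
                           thresholds = ssrThresholds()) {
  if (is.null(refSeq)) refSeq <- attr(events, "refSeq")
  if (is.null(refSeq)) .stopf("refSeq missing (no attribute on events)")
  events$klass <- if (nrow(events) == 0) character() else
    vapply(seq_len(nrow(events)), function(i)
      classifyIndel(events$ref_pos[i], events$length[i], events$seq[i],
                    events$polarity[i], refSeq, thresholds), "")
  events
}

#' Annotate indel events with region and genic context
#'
#' @param events indel table (reference coordinates)
#' @param structure \code{\link{QuadripartiteStructure}} of the reference
#' @param features reference feature \code{GRanges}/data.frame
#' @return events with region, context, locus columns added
#' @export
annotateIndels <- function(events, structure, features) {
  if (nrow(events) == 0) {
    events$region <- character(); events$context <- character()
    events$locus <- character()
    return(events)
  }
  p <- ifelse(events$polarity == "deletion", events$ref_pos + 1L,
              pmax(events$ref_pos, 1L))
  p <- pmin(pmax(p, 1L), structure@genomeLength)
  cl <- classifyPosition(structure, features, p)
  events$region <- cl$region
  events$context <- cl$context
  events$locus <- cl$locus
  events
}

#' Indel size spectrum and context table
#'
#' @param events classified (and optionally annotated) indel table
#' @return list: \code{by_size} (size x class counts), \code{by_context}
#'   (class x context counts, when annotated), \code{largest} (row of the
#'   largest event), \code{n_events}, \code{n_ssr_related}, \code{n_non_ssr}
#' @export
indelSpectrum <- function(events) {
  if (nrow(events) == 0)
    return(list(by_size = data.frame(), by_context = data.frame(),
                largest = data.frame(), n_events = 0L,
                n_ssr_related = 0L, n_non_ssr = 0L))
  kl <- if ("klass" %in% names(events)) events$klass
        else rep("unclassified", nrow(events))
  bySize <- as.data.frame(table(size = events$length, klass = kl),
                          stringsAsFactors = FALSE)
  bySize <- bySize[bySize$Freq > 0, ]
  bySize$size <- as.integer(bySize$size)
  bySize <- bySize[order(bySize$size), ]
  rownames(bySize) <- NULL
  byCtx <- if ("context" %in% names(events))
    as.data.frame.matrix(table(kl, events$context)) else data.frame()
  list(by_size = bySize,
       by_context = byCtx,
       largest = events[which.max(events$length), , drop = FALSE],
       n_events = nrow(events),
       n_ssr_related = sum(kl == "SSR_related"),
       n_non_ssr = sum(kl == "non_SSR"))
}

#' Binary indel matrix (simple indel coding)
#'
#' One binary character per event; 1 means the taxon has the sequence
#' present at that event (so the reference row is 1 for deletions and 0
#' for insertions). Constant columns are dropped.
#'
#' @param events indel table from \code{\link{callIndels}} (needs the
#'   \code{taxa}/\code{refTaxon} attributes, or pass \code{taxa})
#' @param taxa optional character vector of taxa
#' @return integer matrix, taxa x events
#' @export
buildIndelMatrix <- function(events, taxa = NULL) {
  if (is.null(taxa)) taxa <- attr(events, "taxa")
  if (is.null(taxa)) .stopf("taxa missing (no attribute on events)")
  if (nrow(events) == 0) .stopf("no events to code")
  mat <- matrix(0L, nrow = length(taxa), ncol = nrow(events),
                dimnames = list(taxa,
                                sprintf("e%d_%d", events$ref_pos,
                                        events$length)))
  for (j in seq_len(nrow(events))) {
    carriers <- strsplit(events$carriers[j], ",", fixed = TRUE)[[1]]
    if (events$polarity[j] == "deletion") {
      mat[, j] <- 1L
      mat[carriers, j] <- 0L
    } else {
      mat[carriers, j] <- 1L
    }
  }
  keep <- apply(mat, 2, function(v) length(unique(v)) > 1)
  mat[, keep, drop = FALSE]
}

#' Write indel events as a minimal VCF
#'
#' CHROM is the reference taxon; POS is the 1-based anchor base (VCF
#' convention: base immediately left of the event).
#'
#' @param events classified indel table
#' @param path output file
#' @param refSeq,refTaxon default to the table's attributes
#' @return invisibly, the path
#' @export
writeIndelVcf <- function(events, path, refSeq = NULL, refTaxon = NULL) {
  if (is.null(refSeq)) refSeq <- attr(events, "refSeq")
  if (is.null(refTaxon)) refTaxon <- attr(events, "refTaxon")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", refTaxon,
                       nchar(refSeq)),
               "##INFO=<ID=CARRIERS,Number=1,Type=String,Description=\"Taxa differing from reference\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"SSR_related or non_SSR\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$ref_pos >= 1) {
      anchor <- substr(refSeq, e$ref_pos, e$ref_pos)
      pos <- e$ref_pos
      if (e$polarity == "deletion") {
        ref <- paste0(anchor, e$seq); alt <- anchor
      } else {
        ref <- anchor; alt <- paste0(anchor, e$seq)
      }
    } else {     # event at the very start: anchor on the right
      anchor <- substr(refSeq, e$length + 1L, e$length + 1L)
      pos <- 1L
      if (e$polarity == "deletion") {
        ref <- paste0(e$seq, anchor); alt <- anchor
      } else {
        anchor <- substr(refSeq, 1L, 1L)
        ref <- anchor; alt <- paste0(e$seq, anchor)
      }
    }
    info <- sprintf("CARRIERS=%s%s", e$carriers,
                    if (!is.null(e$klass)) paste0(";CLASS=", e$klass) else "")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       refTaxon, pos, ref, alt, info), con)
  }
  invisible(path)
}
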