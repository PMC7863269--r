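# Site classification, nucleotide diversity (pi) with complete gap
# deletion, sliding-window hotspot scanning and marker variability scoring.
#
# Conventions: a column is *valid* when no row carries a gap or N; pi uses
# complete deletion (invalid columns dropped); the percentage columns of
# the site-count table use the aligned length as denominator.

.colStats <- function(m) {
  # per-column: valid flag, number of differing pairs, distinct-base counts
  k <- nrow(m)
  valid <- colSums(m == "-" | m == "N") == 0
  counts <- vapply(DNA_BASES, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1) counts <- matrix(counts, nrow = 1,
                                     dimnames = list(NULL, DNA_BASES))
  # pairs of equal bases per column
  samePairs <- rowSums(counts * (counts - 1) / 2)
  totPairs <- k * (k - 1) / 2
  list(valid = valid,
       diffPairs = totPairs - samePairs,   # meaningful on valid columns
       nStates = rowSums(counts > 0),
       nStatesGe2 = rowSums(counts >= 2),
       totPairs = totPairs)
}

#' Count valid, variable and parsimony-informative sites
#'
#' A column is valid if it has no gap and no N; variable if at least two
#' distinct bases occur among its rows; parsimony-informative if at least
#' two distinct bases each occur in at least two sequences. Percentages are
#' of the aligned length.
#'
#' @param aln alignment (\code{DNAStringSet}/character/matrix)
#' @return one-row data.frame: aligned_length, valid_sites, variable_sites,
#'   informative_sites, pct_variable, pct_informative
#' @export
classifySites <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2) .stopf("need at least 2 sequences")
  st <- .colStats(m)
  v <- st$valid
  variable <- sum(v & st$nStates >= 2)
  informative <- sum(v & st$nStatesGe2 >= 2)
  data.frame(aligned_length = ncol(m), valid_sites = sum(v),
             variable_sites = variable, informative_sites = informative,
             pct_variable = 100 * variable / ncol(m),
             pct_informative = 100 * informative / ncol(m))
}

#' Nucleotide diversity (pi) with complete deletion
#'
#' pi = mean over sequence pairs of (differences / valid columns), where
#' valid columns have no gap or N in any row. Errors when no valid column
#' exists (pi is undefined, not 0).
#'
#' @param aln alignment (\code{DNAStringSet}/character/matrix)
#' @return numeric pi in [0, 0.75]
#' @export
nucleotideDiversity <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2) .stopf("need at least 2 sequences")
  st <- .colStats(m)
  L <- sum(st$valid)
  if (L == 0) .stopf("pi undefined: no gap- and N-free column")
  sum(st$diffPairs[st$valid]) / (st$totPairs * L)
}

#' Sliding-window nucleotide diversity
#'
#' Windows advance over alignment columns by \code{step}; pi is computed
#' per window with complete deletion inside the window. Windows without a
#' single valid column get \code{NA} pi. A trailing partial window
#' (remaining columns >= window/2) is emitted only when
#' \code{emitPartial = TRUE} and flagged.
#'
#' @param aln alignment
#' @param window window length in columns (default 600)
#' @param step step size in columns (default 100)
#' @param emitPartial emit the trailing partial window (default FALSE)
#' @return data.frame: window_start, window_end (1-based closed columns),
#'   midpoint, pi, valid_sites, partial
#' @export
slidingWindowPi <- function(aln, window = 600L, step = 100L,
                            emitPartial = FALSE) {
  window <- as.integer(window); step <- as.integer(step)
  if (window <= 0 || step <= 0 || window < step)
    .stopf("need window >= step > 0 (got window=%d step=%d)", window, step)
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2) .stopf("need at least 2 sequences")
  nc <- ncol(m)
  if (nc < window) .stopf("alignment (%d cols) shorter than window (%d)",
                          nc, window)
  st <- .colStats(m)
  cumValid <- c(0, cumsum(st$valid))
  dp <- st$diffPairs; dp[!st$valid] <- 0
  cumDiff <- c(0, cumsum(dp))
  starts <- seq(1L, nc - window + 1L, by = step)
  ends <- starts + window - 1L
  partial <- rep(FALSE, length(starts))
  if (emitPartial) {
    nxt <- starts[length(starts)] + step
    if (nxt <= nc && (nc - nxt + 1L) >= window / 2) {
      starts <- c(starts, nxt); ends <- c(ends, nc)
      partial <- c(partial, TRUE)
    }
  }
  L <- cumValid[ends + 1L] - cumValid[starts]
  D <- cumDiff[ends + 1L] - cumDiff[starts]
  pi <- ifelse(L > 0, D / (st$totPairs * L), NA_real_)
  data.frame(window_start = starts, window_end = ends,
             midpoint = (starts + ends) / 2, pi = pi,
             valid_sites = L, partial = partial)
}

#' Rank sliding windows into a hotspot report
#'
#' @param windows output of \code{\link{slidingWindowPi}}
#' @param aln the alignment the windows came from (used to map columns to
#'   reference coordinates when \code{refTaxon} given)
#' @param refTaxon optional reference row name
#' @param structure,features optional reference structure/annotation used to
#'   name each peak's locus
#' @param n number of top windows to report
#' @return windows ordered by decreasing pi with optional ref_start,
#'   ref_end, region, locus columns
#' @export
rankHotspots <- function(windows, aln = NULL, refTaxon = NULL,
                         structure = NULL, features = NULL, n = 10L) {
  o <- order(-windows$pi, windows$window_start, na.last = TRUE)
  top <- windows[o, ][seq_len(min(n, nrow(windows))), ]
  if (!is.null(aln) && !is.null(refTaxon)) {
    m <- alignmentMatrix(aln)
    refCum <- cumsum(m[refTaxon, ] != "-")
    top$ref_start <- pmax(1L, refCum[top$window_start])
    top$ref_end <- pmax(1L, refCum[top$window_end])
    if (!is.null(structure) && !is.null(features)) {
      mid <- pmin(pmax(1L, (top$ref_start + top$ref_end) %/% 2L),
                  structure@genomeLength)
      cl <- classifyPosition(structure, features, mid)
      top$region <- cl$region
      top$locus <- ifelse(cl$context == "intergenic_spacer", cl$locus,
                          cl$locus)
    }
  }
  rownames(top) <- NULL
  top
}

#' Map reference coordinates to alignment columns
#'
#' @param aln alignment
#' @param refTaxon reference row name
#' @param refStart,refEnd 1-based closed reference interval
#' @return integer vector of alignment columns covering the interval
#'   (including internal insertion columns)
#' @export
refWindowToColumns <- function(aln, refTaxon, refStart, refEnd) {
  m <- alignmentMatrix(aln)
  if (!refTaxon %in% rownames(m))
    .stopf("reference taxon '%s' not in alignment", refTaxon)
  nonGap <- m[refTaxon, ] != "-"
  refCum <- cumsum(nonGap)
  if (refStart > refEnd) .stopf("refStart > refEnd")
  if (refEnd > refCum[length(refCum)])
    .stopf("interval [%d,%d] exceeds reference length %d",
           refStart, refEnd, refCum[length(refCum)])
  first <- which(refCum == refStart & nonGap)[1]
  last <- which(refCum == refEnd & nonGap)[1]
  first:last    # includes insertion columns strictly inside the interval
}

#' Per-region site counts and diversity in the alignment frame
#'
#' Slices the alignment into LSC/IR/SSC blocks through the reference row
#' and reports the site-count table plus pi per region and overall.
#'
#' @param aln alignment including the reference taxon
#' @param refTaxon reference row name
#' @param structure reference \code{\link{QuadripartiteStructure}}
#' @return data.frame with rows LSC, IRb, SSC, IRa, total
#' @export
regionDiversityTable <- function(aln, refTaxon, structure) {
  m <- alignmentMatrix(aln)
  regions <- list(LSC = structure@lsc, IRb = structure@irb,
                  SSC = structure@ssc, IRa = structure@ira)
  rows <- lapply(names(regions), function(rn) {
    iv <- regions[[rn]]
    cols <- refWindowToColumns(m, refTaxon, IRanges::start(iv),
                               IRanges::end(iv))
    sub <- m[, cols, drop = FALSE]
    sc <- classifySites(sub)
    pi <- tryCatch(nucleotideDiversity(sub), error = function(e) NA_real_)
    cbind(data.frame(region = rn), sc, data.frame(pi = pi))
  })
  tot <- cbind(data.frame(region = "total"), classifySites(m),
               data.frame(pi = tryCatch(nucleotideDiversity(m),
                                        error = function(e) NA_real_)))
  out <- rbind(do.call(rbind, rows), tot)
  rownames(out) <- NULL
  out
}
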