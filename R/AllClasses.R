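#' PlastomeRecord: one annotated circular chloroplast genome
#'
#' Holds the (circular) genome sequence together with its gene features.
#' Features are stored as a \code{GRanges} with one range per exon/part and
#' metadata columns \code{gene} (name), \code{kind}
#' (\code{protein_coding}/\code{tRNA}/\code{rRNA}), \code{part} (1-based rank
#' of the part along the transcript) and \code{copy_tag} (\code{""}, or
#' \code{"IRa"}/\code{"IRb"} for inverted-repeat duplicates).
#'
#' @slot taxonId single short label
#' @slot accession accession string, may be empty
#' @slot sequence \code{DNAString} over A,C,G,T,N (upper case)
#' @slot features \code{GRanges} of gene parts (1-based, closed intervals)
#' @export
setClass("PlastomeRecord",
  slots = c(taxonId = "character",
            accession = "character",
            sequence = "DNAString",
            features = "GRanges"))

setValidity("PlastomeRecord", function(object) {
  msgs <- character()
  if (length(object@taxonId) != 1 || !nzchar(object@taxonId))
    msgs <- c(msgs, "taxonId must be one non-empty string")
  n <- length(object@sequence)
  if (n < 1) msgs <- c(msgs, "sequence is empty")
  s <- as.character(object@sequence)
  if (grepl("[^ACGTN]", s))
    msgs <- c(msgs, "sequence has characters outside {A,C,G,T,N}")
  nN <- sum(Biostrings::letterFrequency(object@sequence, "N"))
  if (n > 0 && nN / n > 0.01)
    msgs <- c(msgs, sprintf("sequence is %.1f%% N (> 1%% rejected)",
                            100 * nN / n))
  ft <- object@features
  if (length(ft) > 0) {
    if (min(GenomicRanges::start(ft)) < 1 || max(GenomicRanges::end(ft)) > n)
      msgs <- c(msgs, "feature coordinates outside [1, genome length]")
    need <- c("gene", "kind", "part", "copy_tag")
    if (!all(need %in% colnames(S4Vectors::mcols(ft))))
      msgs <- c(msgs, paste("features need metadata columns:",
                            paste(need, collapse = ", ")))
    else if (!all(ft$kind %in% c("protein_coding", "tRNA", "rRNA")))
      msgs <- c(msgs, "feature kind must be protein_coding/tRNA/rRNA")
  }
  if (length(msgs)) msgs else TRUE
})

#' QuadripartiteStructure: LSC / IRb / SSC / IRa delimitation
#'
#' Intervals are 1-based closed coordinates on the canonical orientation
#' (genome starts at the LSC start; SSC follows IRb). The four intervals
#' tile the genome exactly; the IRb subsequence is the exact reverse
#' complement of the IRa subsequence.
#'
#' @slot lsc,irb,ssc,ira \code{IRanges} of length 1 each
#' @slot genomeLength integer genome size in bp
#' @slot rotationOffset 0-based rotation applied to reach the canonical
#'   orientation (new coordinate 1 sat at \code{rotationOffset + 1} in the
#'   input sequence)
#' @export
setClass("QuadripartiteStructure",
  slots = c(lsc = "IRanges", irb = "IRanges", ssc = "IRanges",
            ira = "IRanges", genomeLength = "integer",
            rotationOffset = "integer"))

setValidity("QuadripartiteStructure", function(object) {
  msgs <- character()
  ivs <- list(lsc = object@lsc, irb = object@irb,
              ssc = object@ssc, ira = object@ira)
  if (any(vapply(ivs, length, 1L) != 1))
    return("each of lsc/irb/ssc/ira must be exactly one interval")
  n <- object@genomeLength
  wids <- vapply(ivs, IRanges::width, 1L)
  if (sum(wids) != n)
    msgs <- c(msgs, sprintf("region widths sum to %d, genome is %d",
                            sum(wids), n))
  if (wids["irb"] != wids["ira"])
    msgs <- c(msgs, "IRb and IRa widths differ")
  if (wids["lsc"] <= wids["ssc"])
    msgs <- c(msgs, "LSC must be longer than SSC")
  st <- vapply(ivs, IRanges::start, 1L)
  en <- vapply(ivs, IRanges::end, 1L)
  if (st["lsc"] != 1L ||
      st["irb"] != en["lsc"] + 1L ||
      st["ssc"] != en["irb"] + 1L ||
      st["ira"] != en["ssc"] + 1L || en["ira"] != n)
    msgs <- c(msgs, "regions must tile the genome as LSC,IRb,SSC,IRa from 1")
  if (length(msgs)) msgs else TRUE
})

#' SimTruth: a simulated data set with full ground truth
#'
#' @slot ancestor the ancestral \code{PlastomeRecord}
#' @slot leaves named list of leaf \code{PlastomeRecord}s
#' @slot alignment true multiple alignment of the leaves (\code{DNAStringSet})
#' @slot events data.frame of true indel events (alignment-column spans,
#'   class, polarity, carrier leaves)
#' @slot ssrCatalog data.frame of planted SSR tracts on the ancestor
#' @slot regionLabels per-alignment-column region label (LSC/IRb/SSC/IRa)
#' @slot tree the guide tree (\code{phylo})
#' @slot params echo of the simulation parameters
#' @export
setClass("SimTruth",
  slots = c(ancestor = "PlastomeRecord", leaves = "list",
            alignment = "DNAStringSet", events = "data.frame",
            ssrCatalog = "data.frame", regionLabels = "character",
            tree = "ANY", params = "list"))

setMethod("show", "PlastomeRecord", function(object) {
  cat("PlastomeRecord:", object@taxonId,
      if (nzchar(object@accession)) sprintf("(%s)", object@accession) else "",
      "\n  length:", length(object@sequence), "bp;",
      length(unique(object@features$gene)), "genes,",
      length(object@features), "feature parts\n")
})

setMethod("show", "QuadripartiteStructure", function(object) {
  w <- function(x) IRanges::width(x)
  cat(sprintf(
    "QuadripartiteStructure (%d bp): LSC %d | IRb %d | SSC %d | IRa %d\n",
    object@genomeLength, w(object@lsc), w(object@irb),
    w(object@ssc), w(object@ira)))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d leaves, alignment %d cols, %d true indel events, %d SSR tracts\n",
    length(object@leaves), unique(Biostrings::width(object@alignment))[1],
    nrow(object@events), nrow(object@ssrCatalog)))
})
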