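#' @describeIn PlastomeRecord taxon label accessor
#' @param x,object a \code{PlastomeRecord}
#' @export
setGeneric("taxonId", function(x) standardGeneric("taxonId"))

#' @describeIn PlastomeRecord accession accessor
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @describeIn PlastomeRecord genome sequence (\code{DNAString}) accessor
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @describeIn PlastomeRecord gene-part \code{GRanges} accessor
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @describeIn PlastomeRecord genome length in bp
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @describeIn QuadripartiteStructure common inverted-repeat length in bp
#' @export
setGeneric("irLength", function(x) standardGeneric("irLength"))

#' @describeIn QuadripartiteStructure widths of LSC, IRb, SSC, IRa
#' @export
setGeneric("regionWidths", function(x) standardGeneric("regionWidths"))

setMethod("taxonId", "PlastomeRecord", function(x) x@taxonId)
setMethod("accession", "PlastomeRecord", function(x) x@accession)
setMethod("genomeSequence", "PlastomeRecord", function(x) x@sequence)
setMethod("geneFeatures", "PlastomeRecord", function(x) x@features)
setMethod("genomeLength", "PlastomeRecord", function(x) length(x@sequence))

setMethod("irLength", "QuadripartiteStructure",
          function(x) IRanges::width(x@irb))
setMethod("regionWidths", "QuadripartiteStructure", function(x)
  c(LSC = IRanges::width(x@lsc), IRb = IRanges::width(x@irb),
    SSC = IRanges::width(x@ssc), IRa = IRanges::width(x@ira)))

#' Construct a PlastomeRecord
#'
#' @param taxonId short label
#' @param sequence character scalar or \code{DNAString}
#' @param features optional \code{GRanges} of gene parts (see
#'   \code{\link{PlastomeRecord-class}}) or a data.frame with columns
#'   gene, kind, start, end, strand, part, copy_tag
#' @param accession optional accession string
#' @return a validated \code{PlastomeRecord}
#' @export
plastomeRecord <- function(taxonId, sequence, features = NULL,
                           accession = "") {
  if (is.character(sequence)) {
    sequence <- toupper(sequence)
    .assertDna(sequence, sprintf("sequence of '%s'", taxonId))
    sequence <- Biostrings::DNAString(sequence)
  }
  if (is.null(features)) {
    features <- GenomicRanges::GRanges()
    S4Vectors::mcols(features) <- S4Vectors::DataFrame(
      gene = character(), kind = character(), part = integer(),
      copy_tag = character())
  } else if (is.data.frame(features)) {
    features <- featuresToGRanges(features, taxonId)
  }
  new("PlastomeRecord", taxonId = taxonId, accession = accession,
      sequence = sequence, features = features)
}

#' Convert a feature data.frame to the GRanges layout used by PlastomeRecord
#'
#' @param df data.frame with columns gene, kind, start, end and optionally
#'   strand, part, copy_tag
#' @param taxonId seqname to use
#' @return \code{GRanges}
#' @export
featuresToGRanges <- function(df, taxonId = "genome") {
  if (nrow(df) == 0) {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      gene = character(), kind = character(), part = integer(),
      copy_tag = character())
    return(g)
  }
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$part)) df$part <- 1L
  if (is.null(df$copy_tag)) df$copy_tag <- ""
  GenomicRanges::GRanges(
    seqnames = taxonId,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    gene = df$gene, kind = df$kind, part = as.integer(df$part),
    copy_tag = df$copy_tag)
}

#' Flatten a feature GRanges back to a data.frame
#' @param gr feature \code{GRanges}
#' @return data.frame with gene, kind, start, end, strand, part, copy_tag
#' @export
featuresToDataFrame <- function(gr) {
  data.frame(gene = gr$gene, kind = gr$kind,
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             part = gr$part, copy_tag = gr$copy_tag,
             stringsAsFactors = FALSE)
}
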