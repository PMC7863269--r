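# Per-genome summary statistics (genome/region lengths, GC, gene counts)
# and position classification against the annotation.

.gcOf <- function(s) {
  # GC fraction with N excluded from the denominator
  v <- .chars(s)
  acgt <- sum(v %in% DNA_BASES)
  if (acgt == 0) return(NA_real_)
  sum(v %in% c("G", "C")) / acgt
}

#' Summarize a plastome against its quadripartite structure
#'
#' GC content is (G+C)/(A+C+G+T) per region (N excluded from the
#' denominator). Gene counts de-duplicate inverted-repeat copies: genes
#' lying wholly inside IRa are suppressed from the counts (but kept in the
#' feature set), so a fully annotated plastome yields the conventional
#' single-copy counting (e.g. 113 = 79 + 30 + 4).
#'
#' @param record a \code{\link{PlastomeRecord}} in canonical orientation
#' @param structure the matching \code{\link{QuadripartiteStructure}}
#' @return one-row data.frame: taxon, accession, total_bp, lsc_bp, ir_bp,
#'   ssc_bp, gc_total, gc_lsc, gc_ir, gc_ssc, n_genes, n_protein, n_trna,
#'   n_rrna
#' @export
summarizeGenome <- function(record, structure) {
  n <- genomeLength(record)
  if (structure@genomeLength != n)
    .stopf("structure (%d bp) does not belong to record (%d bp)",
           structure@genomeLength, n)
  s <- as.character(genomeSequence(record))
  if (structure@rotationOffset != 0L)
    s <- .rotateSeq(s, structure@rotationOffset)
  sub <- function(iv) substr(s, IRanges::start(iv), IRanges::end(iv))
  lscS <- sub(structure@lsc); irbS <- sub(structure@irb)
  sscS <- sub(structure@ssc); iraS <- sub(structure@ira)

  df <- featuresToDataFrame(geneFeatures(record))
  nGenes <- nProt <- nTrna <- nRrna <- 0L
  if (nrow(df)) {
    span <- do.call(rbind, lapply(split(df, paste(df$gene, df$copy_tag)),
      function(g) data.frame(gene = g$gene[1], kind = g$kind[1],
                             start = min(g$start), end = max(g$end),
                             stringsAsFactors = FALSE)))
    inIRa <- span$start >= IRanges::start(structure@ira) &
             span$end <= IRanges::end(structure@ira)
    kept <- span[!inIRa, , drop = FALSE]
    kept <- kept[!duplicated(kept$gene), , drop = FALSE]
    nGenes <- nrow(kept)
    nProt <- sum(kept$kind == "protein_coding")
    nTrna <- sum(kept$kind == "tRNA")
    nRrna <- sum(kept$kind == "rRNA")
  }
  data.frame(
    taxon = taxonId(record), accession = accession(record),
    total_bp = n,
    lsc_bp = IRanges::width(structure@lsc),
    ir_bp = IRanges::width(structure@irb),
    ssc_bp = IRanges::width(structure@ssc),
    gc_total = .gcOf(s), gc_lsc = .gcOf(lscS),
    gc_ir = .gcOf(paste0(irbS, iraS)), gc_ssc = .gcOf(sscS),
    n_genes = nGenes, n_protein = nProt, n_trna = nTrna, n_rrna = nRrna,
    stringsAsFactors = FALSE)
}

#' Table-1-style summary for a set of genomes
#' @param records list of \code{PlastomeRecord}
#' @param structures list of matching structures (detected when NULL)
#' @param ... passed to \code{\link{detectQuadripartite}}
#' @return data.frame with one row per genome
#' @export
genomeSummaryTable <- function(records, structures = NULL, ...) {
  if (is.null(structures))
    structures <- lapply(records, detectQuadripartite, ...)
  do.call(rbind, Map(summarizeGenome, records, structures))
}

#' Classify genome positions by genic context and region
#'
#' Context precedence is exon over intron over intergenic spacer. Spacer
#' positions are named by their flanking gene pair (upstream-downstream,
#' circular).
#'
#' @param structure a \code{\link{QuadripartiteStructure}}
#' @param features feature \code{GRanges} or data.frame (canonical frame)
#' @param position integer vector of 1-based positions
#' @return data.frame: position, region (LSC/SSC/IR), context
#'   (exon/intron/intergenic_spacer), locus (gene or flanking pair name)
#' @export
classifyPosition <- function(structure, features, position) {
  if (is(features, "GRanges")) features <- featuresToDataFrame(features)
  n <- structure@genomeLength
  if (any(position < 1 | position > n))
    .stopf("position out of range [1, %d]", n)
  region <- regionOfPosition(structure, position)

  context <- rep("intergenic_spacer", length(position))
  locus <- rep(NA_character_, length(position))
  if (nrow(features)) {
    spans <- do.call(rbind, lapply(split(features,
                                         paste(features$gene,
                                               features$copy_tag)),
      function(g) data.frame(gene = g$gene[1], start = min(g$start),
                             end = max(g$end), stringsAsFactors = FALSE)))
    for (i in seq_along(position)) {
      p <- position[i]
      inExon <- features$start <= p & features$end >= p
      if (any(inExon)) {
        context[i] <- "exon"
        locus[i] <- features$gene[which(inExon)[1]]
        next
      }
      inSpan <- spans$start <= p & spans$end >= p
      if (any(inSpan)) {
        context[i] <- "intron"
        locus[i] <- spans$gene[which(inSpan)[1]]
        next
      }
      ups <- features$end[features$end < p]
      dns <- features$start[features$start > p]
      upGene <- if (length(ups)) features$gene[features$end == max(ups)][1]
                else features$gene[which.max(features$end)]
      dnGene <- if (length(dns)) features$gene[features$start == min(dns)][1]
                else features$gene[which.min(features$start)]
      locus[i] <- paste(upGene, dnGene, sep = "-")
    }
  }
  data.frame(position = position, region = region, context = context,
             locus = locus, stringsAsFactors = FALSE)
}
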