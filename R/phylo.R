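# Distance-based phylogenetics: p-distances with pairwise deletion,
# normalized Hamming distances on binary indel characters, neighbor-joining
# (via ape) and bootstrap bipartition support by column resampling.

#' Pairwise p-distance matrix (pairwise deletion)
#'
#' d[i,j] = differing sites / sites where both rows are gap- and N-free.
#'
#' @param aln alignment (\code{DNAStringSet}/character/matrix), >= 3 rows
#' @return symmetric numeric matrix with zero diagonal
#' @export
pDistance <- function(aln) {
  m <- alignmentMatrix(aln)
  k <- nrow(m)
  if (k < 3) .stopf("need at least 3 sequences")
  ok <- !(m == "-" | m == "N")
  d <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    both <- ok[i, ] & ok[j, ]
    L <- sum(both)
    if (L == 0)
      .stopf("no comparable column between '%s' and '%s'",
             rownames(m)[i], rownames(m)[j])
    d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both]) / L
  }
  d
}

#' Distance matrix from a binary indel matrix
#'
#' Normalized Hamming distance on presence/absence characters.
#'
#' @param indelMatrix taxa x events 0/1 matrix
#'   (\code{\link{buildIndelMatrix}})
#' @return symmetric numeric matrix with zero diagonal
#' @export
indelDistance <- function(indelMatrix) {
  if (is.null(dim(indelMatrix)) || ncol(indelMatrix) < 1)
    .stopf("indel matrix needs at least one column")
  if (all(apply(indelMatrix, 2, function(v) length(unique(v)) == 1)))
    .stopf("indel matrix is constant: no phylogenetic signal")
  k <- nrow(indelMatrix)
  d <- matrix(0, k, k, dimnames = list(rownames(indelMatrix),
                                       rownames(indelMatrix)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- mean(indelMatrix[i, ] != indelMatrix[j, ])
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration on a distance matrix; negative branch lengths
#' are clamped to zero with a warning. The result is unrooted.
#'
#' @param d symmetric distance matrix (>= 3 taxa, finite entries)
#' @return an \code{ape} \code{phylo} tree
#' @export
neighborJoining <- function(d) {
  if (!all(is.finite(d))) .stopf("distance matrix has non-finite entries")
  if (nrow(d) < 3) .stopf("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) .stopf("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    .warnf("clamped %d negative NJ branch length(s) to 0",
           sum(tr$edge.length < 0))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap bipartition support by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with \code{builder}, and reports for each internal edge of the
#' base tree the fraction of replicate trees containing the same
#' bipartition (stored in \code{node.label}).
#'
#' @param aln alignment
#' @param builder function(alignment matrix) -> \code{phylo}; default NJ on
#'   \code{\link{pDistance}}
#' @param replicates number of bootstrap replicates
#' @param seed integer seed (required: supports are resampling-based)
#' @return the base tree with support fractions as node labels
#' @export
bootstrapSupport <- function(aln, builder = NULL, replicates = 100L,
                             seed = 1L) {
  if (replicates < 1) .stopf("replicates must be >= 1")
  m <- alignmentMatrix(aln)
  if (is.null(builder)) builder <- function(x) neighborJoining(pDistance(x))
  base <- builder(m)
  set.seed(seed)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[r]] <- suppressWarnings(builder(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  base$node.label <- counts / replicates
  base
}

#' Read/write trees in newick
#' @param tree a \code{phylo} object
#' @param path file path
#' @return \code{readNewick}: a \code{phylo}; \code{writeNewick}: the path
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Do two unrooted trees share the same topology?
#' @param t1,t2 \code{phylo} objects on the same leaf set
#' @return TRUE when the unrooted topologies match
#' @export
sameTopology <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  isTRUE(all.equal(
    as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0))
}

#' Export an alignment for external ML/BI programs
#'
#' Writes relaxed sequential PHYLIP or NEXUS; maximum-likelihood and
#' Bayesian inference themselves are delegated to external tools.
#'
#' @param aln alignment
#' @param path output file
#' @param format "phylip" or "nexus"
#' @return invisibly, the path
#' @export
exportAlignment <- function(aln, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  m <- alignmentMatrix(aln)
  if (format == "nexus") {
    seqs <- setNames(lapply(seq_len(nrow(m)), function(i) m[i, ]),
                     rownames(m))
    ape::write.nexus.data(seqs, file = path, interleaved = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf(" %d %d", nrow(m), ncol(m)), con)
    writeLines(sprintf("%s  %s", rownames(m),
                       apply(m, 1, paste, collapse = "")), con)
  }
  invisible(path)
}
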