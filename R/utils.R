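# Low-level helpers shared across modules. Sequences are handled as upper-case
# character strings or per-base character vectors; N is never allowed to match
# anything during exact repeat / inverted-repeat comparisons.

DNA_BASES <- c("A", "C", "G", "T")

.revcompChr <- function(x) {
  # reverse complement of a plain character scalar
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

.compVec <- function(v) chartr("ACGTN", "TGCAN", v)

.seqToInt <- function(s) {
  # A,C,G,T -> 1..4 ; N and anything else -> NA (NA == NA is NA, handled by
  # callers that must treat N as never-matching)
  v <- utf8ToInt(s)
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 1L  # A
  out[v == 67L] <- 2L  # C
  out[v == 71L] <- 3L  # G
  out[v == 84L] <- 4L  # T
  out
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.collapse <- function(v) paste(v, collapse = "")

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assertDna <- function(s, what = "sequence") {
  if (!nzchar(s)) .stopf("%s is empty", what)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad))
    .stopf("%s contains characters outside {A,C,G,T,N}: '%s'",
           what, substr(bad, 1, 10))
  invisible(TRUE)
}

#' Alignment as a base matrix
#'
#' Converts an aligned \code{DNAStringSet} (equal widths, gaps as \code{-})
#' into a character matrix with one row per taxon. IUPAC ambiguity codes
#' other than N are collapsed to N.
#'
#' @param aln a named, equal-width \code{DNAStringSet} (or character vector)
#' @return character matrix, rownames = taxa
#' @export
alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) {
    return(aln)
  } else if (is(aln, "DNAStringSet") || is(aln, "BStringSet")) {
    seqs <- as.character(aln)
  } else if (is.character(aln)) {
    seqs <- aln
  } else .stopf("unsupported alignment class '%s'", class(aln)[1])
  if (length(seqs) < 1) .stopf("empty alignment")
  w <- nchar(seqs)
  if (length(unique(w)) != 1)
    .stopf("alignment rows have unequal lengths (%s)",
           paste(unique(w), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- if (!is.null(names(seqs))) names(seqs)
                 else paste0("seq", seq_along(seqs))
  m[!(m %in% c(DNA_BASES, "-", "N"))] <- "N"
  m
}

# md5 of an in-memory object via a temporary file (used for stage caching)
.md5Of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(unname(tools::md5sum(x)))
  }
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
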