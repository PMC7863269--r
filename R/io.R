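# Reading and writing annotated plastomes.
#
# GenBank flat files are parsed with a light LOCUS/FEATURES/ORIGIN reader
# covering the location syntax organelle records actually use
# (`a..b`, `complement(...)`, `join(...)`, partial markers `<`/`>`).
# FASTA goes through Biostrings; GFF3 through a minimal 9-column reader.

.KIND_MAP <- c(CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA")

#' Read an annotated plastome
#'
#' @param path file path (GenBank flat file or FASTA)
#' @param format \code{"genbank"}, \code{"fasta"} or \code{"fasta+gff3"}
#' @param gff3 path to the GFF3 file when \code{format = "fasta+gff3"}
#' @param taxonId optional label; defaults to the record's LOCUS/FASTA name
#' @return a \code{\link{PlastomeRecord}}; for plain FASTA the feature set
#'   is empty. Feature kinds other than CDS/tRNA/rRNA are dropped with a
#'   warning.
#' @export
readPlastome <- function(path, format = c("genbank", "fasta", "fasta+gff3"),
                         gff3 = NULL, taxonId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "genbank") return(.readGenBank(path, taxonId))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) .stopf("no sequence in %s", path)
  if (length(ss) > 1)
    .warnf("%s holds %d sequences; using the first", path, length(ss))
  nm <- sub("\\s.*$", "", names(ss)[1])
  s <- toupper(as.character(ss[[1]]))
  if (!nzchar(s)) .stopf("empty sequence in %s", path)
  feats <- NULL
  if (format == "fasta+gff3") {
    if (is.null(gff3)) .stopf("format 'fasta+gff3' needs a gff3 path")
    feats <- readGff3Features(gff3)
  }
  plastomeRecord(taxonId = if (is.null(taxonId)) nm else taxonId,
                 sequence = s, features = feats)
}

.parseGbLocation <- function(loc, path, lineno) {
  loc <- gsub("[<>\\s]", "", loc, perl = TRUE)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("complement|join|order", loc))
    .stopf("parse error in %s line %d: unsupported nested location '%s'",
           path, lineno, loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3) return(as.integer(m[2:3]))
    if (grepl("^\\d+$", p)) return(rep(as.integer(p), 2))
    .stopf("parse error in %s line %d: bad location part '%s'",
           path, lineno, p)
  })
  list(strand = strand,
       start = vapply(iv, `[`, 1L, 1),
       end = vapply(iv, `[`, 1L, 2))
}

.readGenBank <- function(path, taxonId = NULL) {
  lines <- readLines(path, warn = FALSE)
  li <- grep("^LOCUS", lines)
  if (length(li) == 0) .stopf("parse error in %s: no LOCUS line", path)
  locus <- strsplit(trimws(lines[li[1]]), "\\s+")[[1]]
  name <- if (length(locus) >= 2) locus[2] else "genome"
  acc <- ""
  ai <- grep("^ACCESSION", lines)
  if (length(ai)) {
    af <- strsplit(trimws(lines[ai[1]]), "\\s+")[[1]]
    if (length(af) >= 2) acc <- af[2]
  }
  fi <- grep("^FEATURES", lines)
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0) .stopf("parse error in %s: no ORIGIN section", path)
  endi <- grep("^//", lines)
  endi <- if (length(endi)) endi[length(endi)] else length(lines) + 1L
  seqlines <- if (endi - 1L >= oi[1] + 1L) lines[(oi[1] + 1L):(endi - 1L)]
              else character()
  s <- toupper(gsub("[0-9 ]", "", paste(seqlines, collapse = "")))
  if (!nzchar(s)) .stopf("empty sequence in %s (locus %s)", path, name)

  feats <- data.frame(gene = character(), kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), part = integer(),
                      copy_tag = character(), stringsAsFactors = FALSE)
  dropped <- character()
  if (length(fi)) {
    block <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    # feature starts: 5 spaces + key; qualifiers/continuations are deeper
    keyidx <- grep("^ {5}\\S", block)
    for (k in seq_along(keyidx)) {
      i0 <- keyidx[k]
      i1 <- if (k < length(keyidx)) keyidx[k + 1] - 1L else length(block)
      fl <- block[i0:i1]
      key <- sub("^\\s+(\\S+).*$", "\\1", fl[1])
      if (key == "source" || key == "gene") next
      loctxt <- sub("^\\s+\\S+\\s+", "", fl[1])
      j <- 2
      while (j <= length(fl) && !grepl("^\\s+/", fl[j])) {
        loctxt <- paste0(loctxt, trimws(fl[j])); j <- j + 1
      }
      if (!key %in% names(.KIND_MAP)) { dropped <- c(dropped, key); next }
      qual <- fl[grepl("^\\s+/", fl)]
      gq <- grep("/gene=", qual, value = TRUE)
      gene <- if (length(gq)) sub('.*?/gene="?([^"]+)"?.*', "\\1", gq[1])
              else key
      ct <- grep("/note=.*copy", qual, value = TRUE)
      copy <- if (length(ct) && grepl("IRa", ct[1])) "IRa"
              else if (length(ct) && grepl("IRb", ct[1])) "IRb" else ""
      pl <- .parseGbLocation(loctxt, path, fi[1] + i0)
      feats <- rbind(feats, data.frame(
        gene = gene, kind = unname(.KIND_MAP[key]),
        start = pl$start, end = pl$end, strand = pl$strand,
        part = seq_along(pl$start), copy_tag = copy,
        stringsAsFactors = FALSE))
    }
  }
  if (length(dropped))
    .warnf("dropped %d feature(s) of unhandled kind(s): %s",
           length(dropped), paste(unique(dropped), collapse = ", "))
  plastomeRecord(taxonId = if (is.null(taxonId)) name else taxonId,
                 sequence = s, features = feats, accession = acc)
}

#' Read gene features from a GFF3 file
#'
#' Keeps CDS, tRNA and rRNA rows; parts of multi-exon genes are grouped by
#' their \code{gene=} (or \code{Parent=}/\code{ID=}) attribute.
#'
#' @param path GFF3 file
#' @return feature data.frame accepted by \code{\link{plastomeRecord}}
#' @export
readGff3Features <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(gene = character(), kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), part = integer(),
                      copy_tag = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9)
  if (length(bad))
    .stopf("parse error in %s line %d: expected 9 tab fields", path, bad[1])
  typ <- vapply(f, `[`, "", 3)
  keep <- typ %in% names(.KIND_MAP)
  f <- f[keep]; typ <- typ[keep]
  attr1 <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]+)"), a))[[1]]
    if (length(m) == 3) m[3] else NA_character_
  }
  rows <- lapply(seq_along(f), function(i) {
    a <- f[[i]][9]
    gene <- attr1(a, "gene")
    if (is.na(gene)) gene <- attr1(a, "Parent")
    if (is.na(gene)) gene <- attr1(a, "ID")
    if (is.na(gene)) gene <- paste0("feature", i)
    copy <- attr1(a, "copy_tag"); if (is.na(copy)) copy <- ""
    data.frame(gene = gene, kind = unname(.KIND_MAP[typ[i]]),
               start = as.integer(f[[i]][4]), end = as.integer(f[[i]][5]),
               strand = f[[i]][7], copy_tag = copy,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$gene, df$start), ]
  df$part <- stats::ave(df$start, paste(df$gene, df$copy_tag),
                        FUN = seq_along)
  df[order(df$start), c("gene", "kind", "start", "end", "strand",
                        "part", "copy_tag")]
}

#' Write a plastome's features as GFF3
#' @param record a \code{PlastomeRecord}
#' @param path output file
#' @return invisibly, the path
#' @export
writeGff3 <- function(record, path) {
  df <- featuresToDataFrame(geneFeatures(record))
  inv <- setNames(names(.KIND_MAP), .KIND_MAP)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", taxonId(record),
                     genomeLength(record)), con)
  if (nrow(df)) {
    writeLines(sprintf(
      "%s\tplastidscan\t%s\t%d\t%d\t.\t%s\t.\tID=%s.%d;gene=%s%s",
      taxonId(record), inv[df$kind], df$start, df$end, df$strand,
      df$gene, df$part, df$gene,
      ifelse(nzchar(df$copy_tag), paste0(";copy_tag=", df$copy_tag), "")),
      con)
  }
  invisible(path)
}

#' Write a plastome as a GenBank-style flat file
#' @param record a \code{PlastomeRecord}
#' @param path output file
#' @return invisibly, the path
#' @export
writeGenBank <- function(record, path) {
  s <- as.character(genomeSequence(record))
  n <- nchar(s)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     circular PLN", taxonId(record), n), con)
  writeLines(sprintf("DEFINITION  %s chloroplast genome.", taxonId(record)),
             con)
  if (nzchar(accession(record)))
    writeLines(sprintf("ACCESSION   %s", accession(record)), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  df <- featuresToDataFrame(geneFeatures(record))
  if (nrow(df)) {
    inv <- setNames(names(.KIND_MAP), .KIND_MAP)
    for (g in split(df, paste(df$gene, df$copy_tag))) {
      g <- g[order(g$part), ]
      loc <- paste(sprintf("%d..%d", g$start, g$end), collapse = ",")
      if (nrow(g) > 1) loc <- sprintf("join(%s)", loc)
      if (g$strand[1] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", inv[g$kind[1]], loc), con)
      writeLines(sprintf('                     /gene="%s"', g$gene[1]), con)
      if (nzchar(g$copy_tag[1]))
        writeLines(sprintf('                     /note="copy %s"',
                           g$copy_tag[1]), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, n, by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, n))
    grp <- substring(chunk, seq(1, nchar(chunk), 10),
                     pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(grp, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write one or more sequences as FASTA
#' @param seqs named character vector or \code{DNAStringSet}
#' @param path output file
#' @param width line width
#' @return invisibly, the path
#' @export
writeFasta <- function(seqs, path, width = 70) {
  if (is.character(seqs)) {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(paste0(">", names(seqs)[i]), con)
      s <- seqs[[i]]
      writeLines(substring(s, seq(1, nchar(s), width),
                           pmin(seq(width, nchar(s) + width - 1, width),
                                nchar(s))), con)
    }
  } else {
    Biostrings::writeXStringSet(seqs, path, width = width)
  }
  invisible(path)
}

#' Read an aligned FASTA as a DNAStringSet
#'
#' Validates that all rows have equal width and names are unique.
#' @param path aligned FASTA (gaps as \code{-})
#' @return named \code{DNAStringSet}
#' @export
readAlignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  if (length(unique(Biostrings::width(ss))) != 1)
    .stopf("alignment rows in %s have unequal widths", path)
  if (anyDuplicated(names(ss)))
    .stopf("duplicate taxon names in %s", path)
  ss
}
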