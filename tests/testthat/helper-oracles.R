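# Independent oracles and fixture builders shared across the suite.
# The oracles are deliberately naive (per-position loops, direct substring
# comparison) so they share no code path with the package implementation.

randSeq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

rcOracle <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# brute-force enumerator of maximal primitive tandem runs (the SSR oracle):
# every start x motif length is tested by direct substring comparison
bruteSSR <- function(s, minRep = c(10, 5, 4, 3, 3, 3)) {
  n <- nchar(s)
  prim <- function(m) {
    u <- nchar(m)
    for (d in seq_len(max(u - 1, 0)))
      if (u %% d == 0 && m == strrep(substr(m, 1, d), u / d)) return(FALSE)
    TRUE
  }
  out <- list()
  for (u in 1:6) {
    for (i in seq_len(max(n - 2 * u + 1, 0))) {
      unit <- substr(s, i, i + u - 1)
      if (grepl("N", unit, fixed = TRUE) || !prim(unit)) next
      # the period-u stretch must not extend left of i
      if (i > 1 && substr(s, i - 1, i - 1) == substr(s, i + u - 1, i + u - 1)
          && substr(s, i - 1, i - 1) != "N") next
      # count period-u matches rightwards base by base
      len <- u
      while (i + len <= n &&
             substr(s, i + len, i + len) == substr(s, i + len - u,
                                                   i + len - u) &&
             substr(s, i + len, i + len) != "N")
        len <- len + 1L
      count <- len %/% u
      if (count < minRep[u]) next
      out[[length(out) + 1]] <- data.frame(
        motif = unit, motif_length = as.integer(u),
        repeat_count = as.integer(count), start = as.integer(i),
        end = as.integer(i + count * u - 1), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), motif_length = integer(),
                      repeat_count = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- unique(do.call(rbind, out))
  keep <- vapply(seq_len(nrow(df)), function(i)
    !any(df$start <= df$start[i] & df$end >= df$end[i] &
           !(df$start == df$start[i] & df$end == df$end[i])), TRUE)
  df <- df[keep, ]
  df <- df[order(df$start, df$motif_length), ]
  rownames(df) <- NULL
  df
}

# pairwise pi with complete deletion, column-by-column
brutePi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  k <- nrow(m)
  valid <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  L <- sum(valid)
  tot <- 0; np <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    np <- np + 1
    tot <- tot + sum(m[i, valid] != m[j, valid]) / L
  }
  tot / np
}

bruteSiteCounts <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  variable <- informative <- valid <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (!all(col %in% c("A", "C", "G", "T"))) next
    valid <- valid + 1L
    tab <- table(col)
    if (length(tab) >= 2) variable <- variable + 1L
    if (sum(tab >= 2) >= 2) informative <- informative + 1L
  }
  c(valid = valid, variable = variable, informative = informative)
}

# construct a quadripartite circle from given region sequences; the bases
# flanking each IR arm are pinned to A so the maximal inverted repeat is
# exactly the IR by construction (A pairs with T, never with itself)
makeCircle <- function(lscS, irbS, sscS) {
  pin <- function(s) {
    substr(s, 1, 1) <- "A"
    substr(s, nchar(s), nchar(s)) <- "A"
    s
  }
  paste0(pin(lscS), irbS, pin(sscS), rcOracle(irbS))
}

rotateStr <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

# a small hand-written GenBank record: two genes, one on the minus strand
# with an intron
toyGenBank <- function(path) {
  seq <- paste0(strrep("ACGT", 60), strrep("TTGCA", 24))  # 360 bp
  writeLines(c(
    "LOCUS       toyplastome 360 bp    DNA     circular PLN",
    "DEFINITION  toy record.",
    "ACCESSION   TOY00001",
    "FEATURES             Location/Qualifiers",
    "     source          1..360",
    "     CDS             10..90",
    '                     /gene="geneA"',
    "     tRNA            complement(join(120..150,200..230))",
    '                     /gene="trnX"',
    "     misc_feature    300..320",
    '                     /note="ignored"',
    "ORIGIN",
    paste0("        1 ", tolower(substr(seq, 1, 60))),
    paste0("       61 ", tolower(substr(seq, 61, 120))),
    paste0("      121 ", tolower(substr(seq, 121, 180))),
    paste0("      181 ", tolower(substr(seq, 181, 240))),
    paste0("      241 ", tolower(substr(seq, 241, 300))),
    paste0("      301 ", tolower(substr(seq, 301, 360))),
    "//"), path)
  seq
}

# compact simulation settings for fast tests: study-like rates on a
# smaller genome
smallSimParams <- function(seed, ...) {
  simParams(lsc = 20000L, ir = 6000L, ssc = 5000L, nTracts = 15L,
            largeDelRange = c(200L, 400L),
            hotspot = list(start = NULL, width = 1200L, multiplier = 6.5),
            seed = seed, ...)
}

expectedCallerSpans <- function(truth) {
  tt <- truthEventTable(truth)
  paste(tt$col_start, tt$col_end)
}
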