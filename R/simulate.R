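# Synthetic quadripartite plastomes evolved along a known tree.
#
# The simulator operates directly on the true alignment: every indel event
# inserts or gaps alignment columns as it happens, so the ground-truth
# alignment needs no external aligner. Substitutions in IRb are mirrored
# into IRa (complemented), keeping the inverted-repeat pair byte-exact in
# every descendant; SSR tracts and indel events are restricted to the
# single-copy regions for the same reason. Every event is recorded with its
# alignment-column span, class (SSR_related via single-unit slippage /
# non_SSR), branch and polarity.

#' Simulation parameters
#'
#' Defaults emulate the comparative study regime this package targets: a
#' ~152.7 kb quadripartite genome (LSC 84 kb, IR 25 kb x2, SSC 18.7 kb), a
#' six-taxon ingroup tree with mean pairwise distance ~0.001, ~45 A/T-rich
#' SSR tracts per genome, slippage and non-SSR indel rates giving ~120
#' events (~25% SSR-related), a localized mutation-rate hotspot at the LSC
#' tail with fold-increase 6.5, and a rare ~0.4-1 kb deletion tail.
#'
#' @param lsc,ir,ssc region lengths in bp
#' @param tree newick string with branch lengths in expected
#'   substitutions/site
#' @param kappa transition:transversion rate weight
#' @param regionRateFactors relative substitution-rate factors per region
#'   (the inverted repeat evolves much more slowly than the single-copy
#'   regions, and SSC faster than LSC); scaled so the length-weighted mean
#'   is ~1 at the defaults
#' @param hotspot list(start, width, multiplier): LSC interval (ancestor
#'   coordinates) whose per-site substitution rate is multiplied; NULL
#'   start places it at the LSC tail
#' @param nTracts number of planted SSR tracts
#' @param motifWeights named numeric: sampling weights of motif classes
#' @param slipRate per-tract per-branch slippage probability
#' @param expandBias probability a slippage event expands (vs contracts)
#' @param nonSsrIndelRate per-site per-branch probability of a non-SSR indel
#' @param indelSizeP geometric parameter of the 1-bp-mode size distribution
#' @param largeDelProb probability an indel is drawn from the long tail
#' @param largeDelRange size range of long-tail deletions (bp)
#' @param gc named numeric GC content per region (LSC, IR, SSC)
#' @param seed integer seed
#' @return validated parameter list of class "SimParams"
#' @export
simParams <- function(lsc = 84000L, ir = 25000L, ssc = 18700L,
                      tree = paste0(
                        "(A_carlinoides:0.0008,(A_macrocephala:0.0005,",
                        "((A_japonica:0.0003,A_lancea:0.0003):0.0001,",
                        "(A_chinensis:0.0003,A_coreana:0.0003):0.0001)",
                        ":0.0001):0.0002);"),
                      kappa = 2,
                      regionRateFactors = c(LSC = 1.3, IR = 0.3,
                                            SSC = 1.8),
                      hotspot = list(start = NULL, width = 2200L,
                                     multiplier = 6.5),
                      nTracts = 45L,
                      motifWeights = c(monoAT = 0.70, monoGC = 0.01,
                                       di = 0.07, tri = 0.03, tetra = 0.14,
                                       penta = 0.03, hexa = 0.02),
                      slipRate = 0.067, expandBias = 0.55,
                      nonSsrIndelRate = 8.8e-5, indelSizeP = 0.55,
                      largeDelProb = 0.01, largeDelRange = c(400L, 1000L),
                      gc = c(LSC = 0.358, IR = 0.432, SSC = 0.315),
                      seed = 1L) {
  p <- list(lsc = as.integer(lsc), ir = as.integer(ir),
            ssc = as.integer(ssc), tree = tree, kappa = kappa,
            regionRateFactors = regionRateFactors, hotspot = hotspot, nTracts = as.integer(nTracts),
            motifWeights = motifWeights, slipRate = slipRate,
            expandBias = expandBias, nonSsrIndelRate = nonSsrIndelRate,
            indelSizeP = indelSizeP, largeDelProb = largeDelProb,
            largeDelRange = as.integer(largeDelRange), gc = gc,
            seed = as.integer(seed))
  if (p$lsc <= 0 || p$ir <= 0 || p$ssc <= 0)
    .stopf("region lengths must be positive")
  if (p$lsc <= p$ssc) .stopf("LSC must be longer than SSC")
  tr <- tryCatch(ape::read.tree(text = p$tree),
                 error = function(e) .stopf("bad tree: %s", e$message))
  if (is.null(tr) || ape::Ntip(tr) < 3) .stopf("tree needs >= 3 leaves")
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    .stopf("tree needs nonnegative branch lengths")
  if (p$slipRate < 0 || p$nonSsrIndelRate < 0)
    .stopf("rates must be >= 0")
  if (!all(c("LSC", "IR", "SSC") %in% names(p$regionRateFactors)) ||
      any(p$regionRateFactors < 0))
    .stopf("regionRateFactors needs nonnegative LSC, IR, SSC entries")
  if (max(p$largeDelRange) >= p$ssc)
    .stopf("long-tail deletion size (%d) must be smaller than SSC (%d)",
           max(p$largeDelRange), p$ssc)
  if (is.null(p$hotspot$start))
    p$hotspot$start <- max(1L, p$lsc - p$hotspot$width)
  if (p$hotspot$start + p$hotspot$width - 1L > p$lsc)
    .stopf("hotspot must lie inside the LSC")
  class(p) <- "SimParams"
  p
}

# ---- toy gene catalogue ----------------------------------------------------

# name, kind, size in bp, intron sizes (0 = none), fractional position
.LSC_GENES <- list(
  list("trnH",  "tRNA",           75,   integer(),    0.0005),
  list("psbA",  "protein_coding", 1062, integer(),    0.006),
  list("matK",  "protein_coding", 1530, integer(),    0.022),
  list("atpF",  "protein_coding", 555,  700L,         0.080),
  list("rpoB",  "protein_coding", 3213, integer(),    0.130),
  list("trnE",  "tRNA",           73,   integer(),    0.185),
  list("psbM",  "protein_coding", 105,  integer(),    0.270),
  list("trnD",  "tRNA",           74,   integer(),    0.285),
  list("trnR",  "tRNA",           72,   integer(),    0.320),
  list("trnT",  "tRNA",           73,   integer(),    0.345),
  list("trnL",  "tRNA",           50,   500L,         0.370),
  list("ndhC",  "protein_coding", 363,  integer(),    0.430),
  list("trnM",  "tRNA",           73,   integer(),    0.455),
  list("rbcL",  "protein_coding", 1428, integer(),    0.540),
  list("clpP",  "protein_coding", 591,  c(540L, 620L), 0.700),
  list("psbB",  "protein_coding", 1527, integer(),    0.820),
  list("rpl22", "protein_coding", 360,  integer(),    0.955),
  list("rps19", "protein_coding", 279,  integer(),    0.978))

.IR_GENES <- list(
  list("rpl2",  "protein_coding", 990,  660L,         0.003),
  list("ndhB",  "protein_coding", 1533, 680L,         0.090),
  list("rps7",  "protein_coding", 468,  integer(),    0.190),
  list("ycf2",  "protein_coding", 6800, integer(),    0.280),
  list("trnI",  "tRNA",           74,   integer(),    0.620),
  list("rrn16", "rRNA",           1490, integer(),    0.660),
  list("trnA",  "tRNA",           73,   integer(),    0.740),
  list("rrn23", "rRNA",           2810, integer(),    0.780),
  list("rrn4.5","rRNA",           103,  integer(),    0.920),
  list("rrn5",  "rRNA",           121,  integer(),    0.945),
  list("trnN",  "tRNA",           72,   integer(),    0.975))

.SSC_GENES <- list(
  list("ndhF",  "protein_coding", 2240, integer(),    0.03),
  list("rpl32", "protein_coding", 171,  integer(),    0.22),
  list("ccsA",  "protein_coding", 963,  integer(),    0.35),
  list("ndhA",  "protein_coding", 1080, 1100L,        0.55),
  list("ycf1",  "protein_coding", 5100, integer(),    0.70))

.layoutGenes <- function(genes, regionStart, regionLen) {
  # place genes sequentially at their fractional positions; shrink for
  # small toy regions; drop genes that no longer fit
  scale <- min(1, regionLen / 84000)
  rows <- list()
  prevEnd <- regionStart - 1L
  for (g in genes) {
    size <- max(45L, as.integer(round(g[[3]] * scale)))
    introns <- as.integer(round(unlist(g[[4]]) * scale))
    start <- max(as.integer(round(regionStart + g[[5]] * regionLen)),
                 prevEnd + 30L)
    total <- size + sum(introns)
    if (start + total - 1L > regionStart + regionLen - 30L) next
    nparts <- length(introns) + 1L
    psize <- diff(round(seq(0, size, length.out = nparts + 1L)))
    s <- start
    for (i in seq_len(nparts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g[[1]], kind = g[[2]], start = s,
        end = s + psize[i] - 1L, strand = "+", part = i,
        copy_tag = "", stringsAsFactors = FALSE)
      s <- s + psize[i] + if (i <= length(introns)) introns[i] else 0L
    }
    prevEnd <- start + total - 1L
  }
  do.call(rbind, rows)
}

.toyCatalog <- function(lsc, ir, ssc) {
  n <- lsc + 2L * ir + ssc
  irbStart <- lsc + 1L
  sscStart <- lsc + ir + 1L
  iraStart <- lsc + ir + ssc + 1L
  cat_lsc <- .layoutGenes(.LSC_GENES, 1L, lsc)
  cat_irb <- .layoutGenes(.IR_GENES, irbStart, ir)
  cat_ssc <- .layoutGenes(.SSC_GENES, sscStart, ssc)
  if (!is.null(cat_irb)) {
    cat_irb$copy_tag <- "IRb"
    irbEnd <- lsc + ir
    cat_ira <- cat_irb
    cat_ira$start <- iraStart + (irbEnd - cat_irb$end)
    cat_ira$end <- iraStart + (irbEnd - cat_irb$start)
    cat_ira$strand <- ifelse(cat_irb$strand == "+", "-", "+")
    cat_ira$copy_tag <- "IRa"
  } else cat_ira <- NULL
  out <- rbind(cat_lsc, cat_irb, cat_ssc, cat_ira)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# ---- ancestral sequence ----------------------------------------------------

.randomRegion <- function(len, gcFrac) {
  probs <- c(A = (1 - gcFrac) / 2, C = gcFrac / 2,
             G = gcFrac / 2, T = (1 - gcFrac) / 2)
  sample(DNA_BASES, len, replace = TRUE, prob = probs[DNA_BASES])
}

# break background tandem stretches that would meet the SSR thresholds,
# independent of the scanner (regex-based)
.breakBackgroundSSRs <- function(v, thresholds = ssrThresholds()) {
  pats <- sprintf("([ACGT]{%d})\\1{%d,}", 1:6, thresholds - 1L)
  s <- .collapse(v)
  repeat {
    changed <- FALSE
    for (pat in pats) {
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1) next
      v <- .chars(s)
      for (i in seq_along(m)) {
        mid <- m[i] + attr(m, "match.length")[i] %/% 2L
        v[mid] <- sample(setdiff(DNA_BASES, v[mid]), 1)
      }
      s <- .collapse(v)
      changed <- TRUE
    }
    if (!changed) break
  }
  .chars(s)
}

.MOTIF_POOL <- list(
  monoAT = c("A", "T"), monoGC = c("C", "G"),
  di = c("AT", "TA", "AG", "TC"),
  tri = c("AAT", "ATT", "TTA", "AAG"),
  tetra = c("TTTC", "AAAT", "ATTT", "AATT", "GAAA"),
  penta = c("AATAT", "TTTAT", "ATTTC"),
  hexa = c("AATATG", "ATTATC", "TTTATA"))
.MOTIF_MINREP <- c(monoAT = 10L, monoGC = 10L, di = 5L, tri = 4L,
                   tetra = 3L, penta = 3L, hexa = 3L)

.plantTracts <- function(v, params, singleCopyEnd, lscLen) {
  # sample tract specs, then place them (85% LSC / 15% SSC by position)
  # with >= 15 bp spacing; flanks are fixed so runs cannot extend
  n <- params$nTracts
  cls <- sample(names(params$motifWeights), n, replace = TRUE,
                prob = params$motifWeights)
  motifs <- vapply(cls, function(cl) sample(.MOTIF_POOL[[cl]], 1), "")
  counts <- .MOTIF_MINREP[cls] + rgeom(n, 0.5)
  lens <- nchar(motifs) * counts
  if (n == 0) return(list(v = v, catalog = NULL))
  rows <- list()
  used <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:200) {
      inLsc <- runif(1) < 0.85
      lo <- if (inLsc) 20L else singleCopyEnd$sscStart + 20L
      hi <- if (inLsc) lscLen - lens[i] - 20L
            else singleCopyEnd$sscEnd - lens[i] - 20L
      if (hi <= lo) next
      st <- sample(lo:hi, 1)
      en <- st + lens[i] - 1L
      if (nrow(used) &&
          any(pmax(used[, 1], st - 15L) <= pmin(used[, 2], en + 15L)))
        next
      u <- nchar(motifs[i])
      mv <- .chars(motifs[i])
      v[st:en] <- rep(mv, counts[i])
      # flanks must not continue the run (in or out of phase)
      if (st > 1 && v[st - 1L] == mv[u])
        v[st - 1L] <- sample(setdiff(DNA_BASES, mv[u]), 1)
      if (en < length(v) && v[en + 1L] == mv[1])
        v[en + 1L] <- sample(setdiff(DNA_BASES, mv[1]), 1)
      used <- rbind(used, c(st, en))
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motifs[i], motif_length = u,
        repeat_count = as.integer(counts[i]), start = st, end = en,
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) .warnf("could not place SSR tract %d; skipped", i)
  }
  if (!length(rows)) return(list(v = v, catalog = NULL))
  catalog <- do.call(rbind, rows)
  catalog <- catalog[order(catalog$start), ]
  rownames(catalog) <- NULL
  list(v = v, catalog = catalog)
}

# ---- evolution along the tree ---------------------------------------------

.mutateBase <- function(old, kappa) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")[old]
  tv <- setdiff(DNA_BASES, c(old, ts))
  sample(c(ts, tv), 1, prob = c(kappa, 1, 1) / (kappa + 2))
}

.tipsUnder <- function(tr, node) {
  K <- ape::Ntip(tr)
  if (node <= K) return(tr$tip.label[node])
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, .tipsUnder, tr = tr))
}

# splice w new columns before position P into every materialized row;
# chars go into the child row, '-' everywhere else; all column-indexed
# bookkeeping shifts accordingly
.insertCols <- function(st, P, w, chId, chars) {
  shift <- function(x) x + w * (x >= P)
  for (nm in names(st$rows)) {
    fill <- if (nm == chId) chars else rep("-", w)
    st$rows[[nm]] <- append(st$rows[[nm]], fill, after = P - 1L)
  }
  here <- min(P, st$ncol)
  st$reg <- append(st$reg, rep(st$reg[here], w), after = P - 1L)
  st$hot <- append(st$hot, rep(st$hot[here], w), after = P - 1L)
  st$mirror <- append(shift(st$mirror), rep(NA_integer_, w), after = P - 1L)
  st$bcols <- shift(st$bcols)
  st$featS <- shift(st$featS); st$featE <- shift(st$featE)
  st$trS <- shift(st$trS); st$trE <- shift(st$trE)
  st$evS <- shift(st$evS); st$evE <- shift(st$evE)
  st$ncol <- st$ncol + w
  invisible(NULL)
}

.recordEvent <- function(st, colS, colE, klass, polarity, node, seq) {
  st$evS <- c(st$evS, colS); st$evE <- c(st$evE, colE)
  st$events[[length(st$events) + 1L]] <- data.frame(
    col_start = colS, col_end = colE, length = colE - colS + 1L,
    klass = klass, polarity = polarity, node = node, seq = seq,
    stringsAsFactors = FALSE)
  invisible(NULL)
}

.nearSpan <- function(st, colS, colE, tractMargin = 15L, eventMargin = 2L) {
  (length(st$trS) &&
     any(st$trS - tractMargin <= colE & st$trE + tractMargin >= colS)) ||
  (length(st$evS) &&
     any(st$evS - eventMargin <= colE & st$evE + eventMargin >= colS))
}

#' Simulate annotated plastomes along a tree, with ground truth
#'
#' @param params from \code{\link{simParams}}
#' @return a \code{\link{SimTruth}} object
#' @export
simulatePlastomes <- function(params = simParams()) {
  if (!inherits(params, "SimParams")) params <- do.call(simParams, params)
  set.seed(params$seed)
  lsc <- params$lsc; ir <- params$ir; ssc <- params$ssc
  n0 <- lsc + 2L * ir + ssc

  # ancestor: random region sequences, IRa mirrors IRb
  vL <- .randomRegion(lsc, params$gc[["LSC"]])
  vB <- .randomRegion(ir, params$gc[["IR"]])
  vS <- .randomRegion(ssc, params$gc[["SSC"]])
  v <- c(vL, vB, vS, rev(.compVec(vB)))
  v <- .breakBackgroundSSRs(v)
  # re-mirror (background breaking may have touched one arm only)
  v[(lsc + ir + ssc + 1L):n0] <- rev(.compVec(v[(lsc + 1L):(lsc + ir)]))
  # the bases pairing across region boundaries must mismatch, so the
  # maximal inverted repeat is exactly the IR by construction
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  if (v[lsc] == comp1(v[1L]))
    v[lsc] <- sample(setdiff(DNA_BASES, c(v[lsc], comp1(v[1L]))), 1)
  sscS <- lsc + ir + 1L; sscE <- lsc + ir + ssc
  if (v[sscS] == comp1(v[sscE]))
    v[sscS] <- sample(setdiff(DNA_BASES, c(v[sscS], comp1(v[sscE]))), 1)

  planted <- .plantTracts(v, params,
                          singleCopyEnd = list(sscStart = sscS,
                                               sscEnd = sscE),
                          lscLen = lsc)
  v <- planted$v
  catalog <- .toyCatalog(lsc, ir, ssc)

  tr <- ape::reorder.phylo(ape::read.tree(text = params$tree), "cladewise")
  K <- ape::Ntip(tr)
  root <- K + 1L

  st <- new.env(parent = emptyenv())
  st$rows <- setNames(list(v), as.character(root))
  st$reg <- c(rep("LSC", lsc), rep("IRb", ir), rep("SSC", ssc),
              rep("IRa", ir))
  hs <- params$hotspot
  st$hot <- rep(FALSE, n0)
  st$hot[hs$start:(hs$start + hs$width - 1L)] <- TRUE
  st$mirror <- rep(NA_integer_, n0)
  irbIdx <- (lsc + 1L):(lsc + ir)
  iraIdx <- (lsc + ir + ssc + 1L):n0
  st$mirror[irbIdx] <- rev(iraIdx)
  st$mirror[iraIdx] <- rev(irbIdx)
  st$bcols <- c(1L, lsc, sscS, sscE)
  st$featS <- catalog$start; st$featE <- catalog$end
  if (is.null(planted$catalog)) {
    st$trS <- integer(); st$trE <- integer(); tractU <- integer()
  } else {
    st$trS <- planted$catalog$start; st$trE <- planted$catalog$end
    tractU <- planted$catalog$motif_length
  }
  st$evS <- integer(); st$evE <- integer()
  st$events <- list()
  st$ncol <- n0

  for (ei in seq_len(nrow(tr$edge))) {
    par <- as.character(tr$edge[ei, 1]); ch <- as.character(tr$edge[ei, 2])
    bl <- tr$edge.length[ei]
    st$rows[[ch]] <- st$rows[[par]]

    # substitutions (IRa excluded; IRb changes mirrored into IRa)
    if (bl > 0) {
      w <- st$rows[[ch]]
      rrf <- params$regionRateFactors
      rate <- bl * unname(rrf[c(LSC = "LSC", IRb = "IR", SSC = "SSC",
                                IRa = "IR")[st$reg]])
      rate[st$hot] <- bl * hs$multiplier
      elig <- w != "-" & w != "N" & st$reg != "IRa"
      elig[st$bcols] <- FALSE
      sites <- which(elig & runif(st$ncol) < rate)
      for (p in sites) {
        nb <- .mutateBase(w[p], params$kappa)
        w[p] <- nb
        mp <- st$mirror[p]
        if (!is.na(mp)) w[mp] <- comp1(nb)
      }
      st$rows[[ch]] <- w
    }

    # SSR slippage: +/- one unit per tract per branch
    for (t in seq_along(st$trS)) {
      if (runif(1) >= params$slipRate) next
      u <- tractU[t]
      span <- st$trS[t]:st$trE[t]
      nonGap <- span[st$rows[[ch]][span] != "-"]
      if (length(nonGap) < 2L * u) next
      if (runif(1) < params$expandBias) {
        P <- nonGap[1L]
        unitChars <- st$rows[[ch]][nonGap[seq_len(u)]]
        .insertCols(st, P, u, ch, unitChars)
        .recordEvent(st, P, P + u - 1L, "SSR_related", "insertion", ch,
                     .collapse(unitChars))
        # the insertion lies at the tract's left edge; widen the tract span
        st$trS[t] <- min(st$trS[t], P)
      } else {
        cols <- nonGap[seq_len(u)]
        if (any(diff(cols) != 1L)) next
        sq <- .collapse(st$rows[[ch]][cols])
        st$rows[[ch]][cols] <- "-"
        .recordEvent(st, cols[1L], cols[u], "SSR_related", "deletion", ch,
                     sq)
      }
    }

    # non-SSR indels in the single-copy regions
    elig <- which(st$reg %in% c("LSC", "SSC") & st$rows[[ch]] != "-")
    nEv <- rbinom(1, length(elig), params$nonSsrIndelRate)
    for (e in seq_len(nEv)) {
      elig <- which(st$reg %in% c("LSC", "SSC") & st$rows[[ch]] != "-")
      big <- runif(1) < params$largeDelProb
      size <- if (big)
        sample(params$largeDelRange[1]:params$largeDelRange[2], 1)
      else 1L + rgeom(1, params$indelSizeP)
      isDel <- if (big) TRUE else runif(1) < 0.5
      for (try in 1:30) {
        i0 <- sample.int(length(elig) - size, 1)
        cols <- elig[i0:(i0 + size - 1L)]
        if (any(diff(cols) != 1L)) next
        if (.nearSpan(st, cols[1L], cols[size])) next
        if (isDel) {
          sq <- .collapse(st$rows[[ch]][cols])
          st$rows[[ch]][cols] <- "-"
          .recordEvent(st, cols[1L], cols[size], "non_SSR", "deletion",
                       ch, sq)
        } else {
          chars <- sample(DNA_BASES, size, replace = TRUE,
                          prob = c(0.31, 0.19, 0.19, 0.31))
          P <- cols[1L]
          .insertCols(st, P, size, ch, chars)
          .recordEvent(st, P, P + size - 1L, "non_SSR", "insertion", ch,
                       .collapse(chars))
        }
        break
      }
    }
  }

  # assemble truth tables
  tips <- tr$tip.label
  leafRows <- st$rows[as.character(seq_len(K))]
  names(leafRows) <- tips
  gapAll <- Reduce(`&`, lapply(leafRows, `==`, "-"))
  if (length(st$events)) {
    # bring the per-event records up to date with the column shifts that
    # later insertions applied (tracked in evS/evE)
    for (i in seq_along(st$events)) {
      st$events[[i]]$col_start <- st$evS[i]
      st$events[[i]]$col_end <- st$evE[i]
    }
  }
  events <- if (length(st$events)) do.call(rbind, st$events) else
    data.frame(col_start = integer(), col_end = integer(),
               length = integer(), klass = character(),
               polarity = character(), node = character(),
               seq = character(), stringsAsFactors = FALSE)
  if (any(gapAll)) {
    keep <- !gapAll
    newIdx <- cumsum(keep)
    remap <- function(s, e) {
      vapply(seq_along(s), function(i) {
        wk <- which(keep[s[i]:e[i]])
        if (!length(wk)) c(NA_integer_, NA_integer_)
        else c(newIdx[s[i] + wk[1] - 1L], newIdx[s[i] + wk[length(wk)] - 1L])
      }, integer(2))
    }
    if (nrow(events)) {
      m <- remap(events$col_start, events$col_end)
      events$col_start <- m[1, ]; events$col_end <- m[2, ]
      events <- events[!is.na(events$col_start), , drop = FALSE]
      events$length <- events$col_end - events$col_start + 1L
    }
    leafRows <- lapply(leafRows, `[`, keep)
    fm <- remap(st$featS, st$featE)
    st$featS <- fm[1, ]; st$featE <- fm[2, ]
    st$reg <- st$reg[keep]
  }
  if (nrow(events)) {
    events$carriers <- vapply(events$node, function(nd)
      paste(.tipsUnder(tr, as.integer(nd)), collapse = ","), "")
    events$region <- st$reg[events$col_start]
  }

  # per-leaf records with mapped annotation
  leaves <- lapply(tips, function(tp) {
    row <- leafRows[[tp]]
    cum <- cumsum(row != "-")
    fs <- ifelse(st$featS > 1L, cum[pmax(st$featS - 1L, 1L)] + 1L, 1L)
    fe <- cum[st$featE]
    ok <- !is.na(fs) & !is.na(fe) & fe >= fs
    df <- catalog[ok, , drop = FALSE]
    df$start <- as.integer(fs[ok]); df$end <- as.integer(fe[ok])
    plastomeRecord(tp, .collapse(row[row != "-"]), df)
  })
  names(leaves) <- tips

  aln <- Biostrings::DNAStringSet(vapply(leafRows, .collapse, ""))
  rownames(events) <- NULL
  new("SimTruth",
      ancestor = plastomeRecord("ancestor", .collapse(v), catalog),
      leaves = leaves, alignment = aln, events = events,
      ssrCatalog = if (is.null(planted$catalog))
        data.frame(motif = character(), motif_length = integer(),
                   repeat_count = integer(), start = integer(),
                   end = integer()) else planted$catalog,
      regionLabels = st$reg, tree = tr, params = unclass(params))
}

#' True region lengths of each simulated leaf
#' @param truth a \code{\link{SimTruth}}
#' @return matrix leaves x (LSC, IRb, SSC, IRa)
#' @export
leafRegionLengths <- function(truth) {
  m <- alignmentMatrix(truth@alignment)
  labs <- c("LSC", "IRb", "SSC", "IRa")
  out <- t(vapply(rownames(m), function(tp)
    vapply(labs, function(lb)
      sum(m[tp, ] != "-" & truth@regionLabels == lb), 1L),
    setNames(integer(4), labs)))
  out
}

#' Expected indel-caller output for a truth set
#'
#' Translates the simulator's per-branch events into the (column span,
#' gapped-taxa set) form the caller reports, for recall scoring.
#'
#' @param truth a \code{\link{SimTruth}}
#' @return data.frame: col_start, col_end, klass, gapped (comma-sorted taxa
#'   lacking sequence over the span)
#' @export
truthEventTable <- function(truth) {
  ev <- truth@events
  tips <- names(truth@leaves)
  if (nrow(ev) == 0)
    return(data.frame(col_start = integer(), col_end = integer(),
                      klass = character(), gapped = character()))
  gapped <- vapply(seq_len(nrow(ev)), function(i) {
    cl <- strsplit(ev$carriers[i], ",", fixed = TRUE)[[1]]
    g <- if (ev$polarity[i] == "deletion") cl else setdiff(tips, cl)
    paste(sort(g), collapse = ",")
  }, "")
  data.frame(col_start = ev$col_start, col_end = ev$col_end,
             klass = ev$klass, gapped = gapped,
             stringsAsFactors = FALSE)
}

#' Write a simulated data set as analysis-ready files
#'
#' @param truth a \code{\link{SimTruth}}
#' @param dir output directory (created)
#' @return invisibly, a named list of the written paths
#' @export
writeFixture <- function(truth, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) .stopf("cannot create directory %s", dir)
  paths <- list()
  for (tp in names(truth@leaves)) {
    paths[[paste0("gb_", tp)]] <-
      writeGenBank(truth@leaves[[tp]], file.path(dir, paste0(tp, ".gb")))
  }
  seqs <- setNames(vapply(truth@leaves, function(r)
    as.character(genomeSequence(r)), ""), names(truth@leaves))
  paths$fasta <- writeFasta(seqs, file.path(dir, "genomes.fasta"))
  paths$alignment <- writeFasta(
    setNames(as.character(truth@alignment), names(truth@alignment)),
    file.path(dir, "alignment.fasta"))
  paths$events <- .writeTsv(truth@events, file.path(dir, "true_events.tsv"))
  paths$ssr <- .writeTsv(truth@ssrCatalog,
                         file.path(dir, "true_ssr_catalog.tsv"))
  paths$regions <- .writeTsv(
    data.frame(taxon = rownames(leafRegionLengths(truth)),
               leafRegionLengths(truth)),
    file.path(dir, "true_region_lengths.tsv"))
  paths$tree <- writeNewick(truth@tree, file.path(dir, "true_tree.nwk"))
  paths$ancestor <- writeGenBank(truth@ancestor,
                                 file.path(dir, "ancestor.gb"))
  invisible(paths)
}
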