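# Full-workflow orchestration: structure -> SSR -> indels -> diversity ->
# markers -> trees, from one validated configuration, with input-hash
# caching and deterministic outputs.

#' Build a run configuration
#'
#' @param genomeFiles named character vector of GenBank flat files (names =
#'   taxa), or NULL when \code{truth} is given
#' @param alignmentFile aligned FASTA of the same taxa (NULL with
#'   \code{truth})
#' @param truth optional \code{\link{SimTruth}} used directly as input
#' @param refTaxon reference taxon for indel and marker coordinates
#' @param groups named list of taxon subsets analysed separately for
#'   windowed diversity (e.g. list(A = all, B = without one taxon))
#' @param thresholds SSR thresholds (\code{\link{ssrThresholds}})
#' @param window,step sliding-window size/step in alignment columns
#' @param markers marker definitions (\code{\link{defaultMarkers}})
#' @param outDir output directory
#' @param minIr minimum inverted-repeat length for structure detection
#' @param seed integer seed (bootstrap resampling)
#' @param bootstrap bootstrap replicates for the sequence tree (0 = none)
#' @return a list of class "RunConfig"
#' @export
runConfig <- function(genomeFiles = NULL, alignmentFile = NULL,
                      truth = NULL, refTaxon, groups = NULL,
                      thresholds = ssrThresholds(), window = 600L,
                      step = 100L, markers = defaultMarkers(),
                      outDir = tempfile("plastidscan_run"),
                      minIr = 10000L, seed = 1L, bootstrap = 0L) {
  cfg <- list(genomeFiles = genomeFiles, alignmentFile = alignmentFile,
              truth = truth, refTaxon = refTaxon, groups = groups,
              thresholds = thresholds, window = as.integer(window),
              step = as.integer(step), markers = markers, outDir = outDir,
              minIr = as.integer(minIr), seed = as.integer(seed),
              bootstrap = as.integer(bootstrap))
  class(cfg) <- "RunConfig"
  cfg
}

#' Validate a run configuration
#'
#' @param cfg from \code{\link{runConfig}}
#' @return character vector of human-readable violations (empty when ok)
#' @export
validateConfig <- function(cfg) {
  v <- character()
  if (!inherits(cfg, "RunConfig")) return("not a RunConfig object")
  hasTruth <- !is.null(cfg$truth)
  if (!hasTruth) {
    if (is.null(cfg$genomeFiles) || is.null(cfg$alignmentFile))
      v <- c(v, "genomeFiles and alignmentFile are required without truth")
    miss <- cfg$genomeFiles[!file.exists(cfg$genomeFiles)]
    if (length(miss))
      v <- c(v, sprintf("missing genome file(s): %s",
                        paste(miss, collapse = ", ")))
    if (!is.null(cfg$alignmentFile) && !file.exists(cfg$alignmentFile))
      v <- c(v, sprintf("missing alignment file: %s", cfg$alignmentFile))
  }
  taxa <- if (hasTruth) names(cfg$truth@leaves) else names(cfg$genomeFiles)
  if (!is.null(taxa) && !cfg$refTaxon %in% taxa)
    v <- c(v, sprintf("reference taxon '%s' not among inputs (%s)",
                      cfg$refTaxon, paste(taxa, collapse = ", ")))
  if (!(cfg$window > 0 && cfg$step > 0 && cfg$window >= cfg$step))
    v <- c(v, sprintf("need window >= step > 0 (window=%d step=%d)",
                      cfg$window, cfg$step))
  if (!is.null(cfg$groups)) {
    for (g in names(cfg$groups)) {
      unknown <- setdiff(cfg$groups[[g]], taxa)
      if (length(unknown))
        v <- c(v, sprintf("group '%s' has unknown taxa: %s", g,
                          paste(unknown, collapse = ", ")))
    }
  }
  th <- tryCatch({ ssrThresholds(cfg$thresholds); character() },
                 error = function(e) conditionMessage(e))
  v <- c(v, th)
  v
}

.cacheStage <- function(outDir, name, inputsHash, compute, reader, writer) {
  # recompute only when the input hash changed; outputs are plain text
  manifest <- file.path(outDir, "manifest.tsv")
  path <- file.path(outDir, name)
  mf <- if (file.exists(manifest)) .readTsv(manifest) else
    data.frame(stage = character(), hash = character(),
               stringsAsFactors = FALSE)
  hit <- mf$stage == name & mf$hash == inputsHash
  if (any(hit) && file.exists(path)) return(reader(path))
  res <- compute()
  writer(res, path)
  mf <- mf[mf$stage != name, , drop = FALSE]
  mf <- rbind(mf, data.frame(stage = name, hash = inputsHash,
                             stringsAsFactors = FALSE))
  mf <- mf[order(mf$stage), , drop = FALSE]
  .writeTsv(mf, manifest)
  res
}

#' Run the full comparative-plastome workflow
#'
#' Stages: quadripartite structure and genome summaries; SSR scan and
#' tabulation; indel calling, classification and binary coding; per-region
#' and sliding-window diversity per group; marker report; NJ trees from
#' sequence and indel distances. Outputs are written as TSV/newick/BED
#' under \code{cfg$outDir}; a rerun with identical inputs reuses cached
#' stage outputs (input hashes in \code{manifest.tsv}).
#'
#' @param cfg from \code{\link{runConfig}}; must validate
#' @return a list of class "StudyReport" with the stage tables
#' @export
runPipeline <- function(cfg) {
  violations <- validateConfig(cfg)
  if (length(violations))
    .stopf("invalid config:\n- %s", paste(violations, collapse = "\n- "))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  # ---- inputs
  stage <- "load inputs"
  withStage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  records <- withStage("load genomes", {
    if (!is.null(cfg$truth)) cfg$truth@leaves
    else setNames(lapply(cfg$genomeFiles, readPlastome, format = "genbank"),
                  names(cfg$genomeFiles))
  })
  for (nm in names(records))
    if (taxonId(records[[nm]]) != nm) records[[nm]]@taxonId <- nm
  aln <- withStage("load alignment", {
    if (!is.null(cfg$truth)) cfg$truth@alignment
    else readAlignment(cfg$alignmentFile)
  })
  if (!setequal(names(records), names(aln)))
    .stopf("pipeline stage 'load alignment' failed: alignment taxa (%s) do %s",
           paste(names(aln), collapse = ","), "not match the genome set")
  m <- alignmentMatrix(aln)
  taxa <- names(records)

  # ---- structure
  structures <- withStage("structure", lapply(records, detectQuadripartite,
                                              minIr = cfg$minIr))
  summaryTab <- withStage("structure", .cacheStage(
    cfg$outDir, "genome_summary.tsv",
    .md5Of(list(lapply(records, function(r)
      as.character(genomeSequence(r))), cfg$minIr)),
    function() genomeSummaryTable(records, structures),
    .readTsv, .writeTsv))

  # ---- SSRs
  ssrTabs <- withStage("ssr", {
    loci <- lapply(taxa, function(tp) {
      can <- canonicalizePlastome(records[[tp]], structures[[tp]])
      annotateSSRs(findSSRs(genomeSequence(can$record), cfg$thresholds),
                   can$structure, geneFeatures(can$record), taxon = tp)
    })
    names(loci) <- taxa
    tabulateSSRs(loci)
  })
  .writeTsv(ssrTabs$loci, file.path(cfg$outDir, "ssr_loci.tsv"))
  .writeTsv(ssrTabs$by_region, file.path(cfg$outDir, "ssr_by_region.tsv"))
  .writeTsv(ssrTabs$by_class, file.path(cfg$outDir, "ssr_by_class.tsv"))

  # ---- indels
  refCan <- withStage("indels", canonicalizePlastome(
    records[[cfg$refTaxon]], structures[[cfg$refTaxon]]))
  events <- withStage("indels", {
    ev <- callIndels(m, cfg$refTaxon)
    ev <- classifyIndels(ev, thresholds = cfg$thresholds)
    annotateIndels(ev, refCan$structure, geneFeatures(refCan$record))
  })
  .writeTsv(events, file.path(cfg$outDir, "indel_events.tsv"))
  spectrum <- indelSpectrum(events)
  if (nrow(events)) {
    imat <- buildIndelMatrix(events)
    .writeTsv(data.frame(taxon = rownames(imat), imat,
                         check.names = FALSE),
              file.path(cfg$outDir, "indel_matrix.tsv"))
  } else imat <- NULL

  # ---- diversity
  groups <- cfg$groups
  if (is.null(groups)) groups <- list(A = taxa)
  regionTab <- withStage("diversity", regionDiversityTable(
    m, cfg$refTaxon, refCan$structure))
  .writeTsv(regionTab, file.path(cfg$outDir, "region_diversity.tsv"))
  groupMats <- lapply(groups, function(gtaxa) {
    sub <- m[gtaxa, , drop = FALSE]
    sub[, colSums(sub == "-") < length(gtaxa), drop = FALSE]
  })
  windowTabs <- withStage("diversity", lapply(
    groupMats, slidingWindowPi, window = cfg$window, step = cfg$step))
  for (g in names(windowTabs))
    .writeTsv(windowTabs[[g]],
              file.path(cfg$outDir, sprintf("window_pi_%s.tsv", g)))
  hotspots <- withStage("diversity", {
    g1 <- groupMats[[1]]
    if (cfg$refTaxon %in% rownames(g1))
      rankHotspots(windowTabs[[1]], g1, cfg$refTaxon,
                   refCan$structure, geneFeatures(refCan$record))
    else rankHotspots(windowTabs[[1]])
  })
  .writeBed(hotspots, cfg$refTaxon,
            file.path(cfg$outDir, "hotspot_windows.bed"))

  # ---- markers
  markerTab <- withStage("markers", markerReport(
    m, cfg$refTaxon, geneFeatures(refCan$record), cfg$markers))
  .writeTsv(markerTab, file.path(cfg$outDir, "marker_report.tsv"))

  # ---- trees
  seqTree <- withStage("trees", {
    if (cfg$bootstrap > 0)
      bootstrapSupport(m, replicates = cfg$bootstrap, seed = cfg$seed)
    else neighborJoining(pDistance(m))
  })
  writeNewick(seqTree, file.path(cfg$outDir, "nj_sequence.nwk"))
  indelTree <- withStage("trees", {
    if (!is.null(imat) && ncol(imat) >= 1)
      tryCatch(neighborJoining(indelDistance(imat)),
               error = function(e) NULL)
    else NULL
  })
  if (!is.null(indelTree))
    writeNewick(indelTree, file.path(cfg$outDir, "nj_indel.nwk"))
  exportAlignment(m, file.path(cfg$outDir, "alignment.phy"), "phylip")

  rep <- list(summary = summaryTab, ssr = ssrTabs, indels = events,
              indel_spectrum = spectrum, indel_matrix = imat,
              region_diversity = regionTab, windows = windowTabs,
              hotspots = hotspots, markers = markerTab,
              seq_tree = seqTree, indel_tree = indelTree,
              outDir = cfg$outDir)
  class(rep) <- "StudyReport"
  invisible(rep)
}

.writeBed <- function(hotspots, chrom, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(hotspots$ref_start)) {
    writeLines(sprintf("%s\t%d\t%d\twindow_pi\t%.6f", chrom,
                       hotspots$ref_start - 1L, hotspots$ref_end,
                       ifelse(is.na(hotspots$pi), 0, hotspots$pi)), con)
  }
  invisible(path)
}

#' Cross-footing checks of a study report
#'
#' Verifies that marginal totals are consistent across the report tables.
#'
#' @param report from \code{\link{runPipeline}}
#' @return TRUE invisibly; errors on an inconsistency
#' @export
checkReport <- function(report) {
  ssr <- report$ssr
  if (!all(ssr$by_region$total == ssr$totals$n))
    .stopf("SSR region margins do not sum to per-taxon totals")
  if (!all(ssr$by_class$total == ssr$totals$n))
    .stopf("SSR motif-class margins do not sum to per-taxon totals")
  sp <- report$indel_spectrum
  if (sp$n_events != nrow(report$indels))
    .stopf("indel spectrum count mismatch")
  if (sp$n_ssr_related + sp$n_non_ssr != sp$n_events)
    .stopf("indel classes do not partition the events")
  rt <- report$region_diversity
  tot <- rt[rt$region == "total", ]
  if (tot$variable_sites < max(rt$variable_sites[rt$region != "total"]))
    .stopf("region variable sites exceed the total")
  invisible(TRUE)
}

#' Reproduce the full analysis on deposited study genomes
#'
#' Runs the complete pipeline on a directory of user-supplied GenBank flat
#' files for the six study accessions plus an externally computed
#' whole-genome alignment (\code{alignment.fasta}). Those inputs must be
#' downloaded and aligned outside this package; nothing is fetched here.
#'
#' @param dir directory with \code{<taxon>.gb} files and
#'   \code{alignment.fasta}
#' @param refTaxon reference taxon (default "A_chinensis")
#' @param outDir where to write the report
#' @param ... passed to \code{\link{runConfig}}
#' @return a StudyReport
#' @export
reproduceDepositedStudy <- function(dir, refTaxon = "A_chinensis",
                                    outDir = file.path(dir, "report"),
                                    ...) {
  if (!dir.exists(dir))
    .stopf("deposited-genome directory not found: %s", dir)
  gbs <- list.files(dir, pattern = "\\.gb$", full.names = TRUE)
  gbs <- gbs[basename(gbs) != "ancestor.gb"]
  if (length(gbs) < 3)
    .stopf("need at least 3 .gb files in %s", dir)
  alnFile <- file.path(dir, "alignment.fasta")
  if (!file.exists(alnFile))
    .stopf("missing %s (externally aligned genomes)", alnFile)
  names(gbs) <- sub("\\.gb$", "", basename(gbs))
  cfg <- runConfig(genomeFiles = gbs, alignmentFile = alnFile,
                   refTaxon = refTaxon, outDir = outDir, ...)
  runPipeline(cfg)
}
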