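# Barcode-marker extraction and variability scoring: candidate hotspot
# markers are benchmarked against universal plant barcodes (matK, rbcL,
# trnH-psbA) on length, variable/informative sites and pi.

#' Define a marker by its anchor genes
#'
#' @param name marker label (e.g. "psbM-trnD")
#' @param genes one gene name (a genic marker) or two anchor gene names (the
#'   span between them: end of the upstream gene to start of the downstream
#'   gene, exclusive of both — a composite like rpl22-rps19-rpl2 is anchored
#'   on its outer genes and so includes everything between them)
#' @param type "gene" or "span"; inferred from the number of genes if NULL
#' @return a marker definition (list)
#' @export
markerDef <- function(name, genes, type = NULL) {
  if (is.null(type)) type <- if (length(genes) == 1) "gene" else "span"
  if (!type %in% c("gene", "span")) .stopf("type must be 'gene' or 'span'")
  if (type == "span" && length(genes) != 2)
    .stopf("span marker '%s' needs exactly 2 anchor genes", name)
  list(name = name, genes = genes, type = type)
}

#' The study's default marker panel
#'
#' Four hotspot candidates plus the three universal barcodes.
#' @return named list of marker definitions
#' @export
defaultMarkers <- function() {
  defs <- list(
    markerDef("rbcL", "rbcL"),
    markerDef("matK", "matK"),
    markerDef("trnH-psbA", c("trnH", "psbA")),
    markerDef("psbM-trnD", c("psbM", "trnD")),
    markerDef("trnR-trnT", c("trnR", "trnT")),
    markerDef("trnT-trnL", c("trnT", "trnL")),
    markerDef("rpl22-rps19-rpl2", c("rpl22", "rpl2")))
  setNames(defs, vapply(defs, `[[`, "", "name"))
}

.geneSpan <- function(features, gene) {
  if (is(features, "GRanges")) features <- featuresToDataFrame(features)
  g <- features[features$gene == gene & features$copy_tag %in% c("", "IRb"), ]
  if (nrow(g) == 0) g <- features[features$gene == gene, ]
  if (nrow(g) == 0) .stopf("anchor gene '%s' not found in annotation", gene)
  c(start = min(g$start), end = max(g$end))
}

#' Reference interval of a marker
#' @param marker from \code{\link{markerDef}}
#' @param features reference annotation
#' @return c(start, end), 1-based closed; strand-agnostic
#' @export
markerInterval <- function(marker, features) {
  if (marker$type == "gene") {
    sp <- .geneSpan(features, marker$genes)
    return(c(start = unname(sp["start"]), end = unname(sp["end"])))
  }
  s1 <- .geneSpan(features, marker$genes[1])
  s2 <- .geneSpan(features, marker$genes[2])
  if (s1["start"] > s2["start"]) { tmp <- s1; s1 <- s2; s2 <- tmp }
  st <- unname(s1["end"]) + 1L
  en <- unname(s2["start"]) - 1L
  if (st > en)
    .stopf("marker '%s': anchors overlap or abut (empty span)", marker$name)
  c(start = st, end = en)
}

#' Extract a marker sub-alignment
#'
#' Coordinates are taken on the reference annotation and mapped through the
#' reference row of the alignment (insertion columns inside the interval are
#' kept).
#'
#' @param aln alignment including the reference taxon
#' @param refTaxon reference row name
#' @param features reference annotation (\code{GRanges} or data.frame)
#' @param marker from \code{\link{markerDef}}
#' @return character matrix sub-alignment with attribute \code{ref_interval}
#' @export
extractMarker <- function(aln, refTaxon, features, marker) {
  m <- alignmentMatrix(aln)
  iv <- markerInterval(marker, features)
  cols <- refWindowToColumns(m, refTaxon, iv["start"], iv["end"])
  sub <- m[, cols, drop = FALSE]
  attr(sub, "ref_interval") <- iv
  attr(sub, "marker") <- marker$name
  sub
}

.markerRow <- function(name, sub) {
  sc <- classifySites(sub)
  pi <- tryCatch(nucleotideDiversity(sub), error = function(e) NA_real_)
  data.frame(marker = name, length = sc$aligned_length,
             variable_sites = sc$variable_sites,
             pct_variable = sc$pct_variable,
             informative_sites = sc$informative_sites,
             pct_informative = sc$pct_informative,
             pi = pi, stringsAsFactors = FALSE)
}

#' Marker variability report
#'
#' Per-marker rows plus concatenation rows for each named group, ranked so
#' hotspot candidates can be compared with universal barcodes.
#'
#' @param aln alignment including the reference taxon
#' @param refTaxon reference row name
#' @param features reference annotation
#' @param markers named list of definitions (default
#'   \code{\link{defaultMarkers}})
#' @param groups named list of marker-name vectors to concatenate; default
#'   the universal-barcode trio and the hotspot quartet
#' @return data.frame in the shape of a marker variability table (length,
#'   variable/informative site counts and percentages, pi)
#' @export
markerReport <- function(aln, refTaxon, features,
                         markers = defaultMarkers(),
                         groups = list(
                           "universal_concat" =
                             c("rbcL", "matK", "trnH-psbA"),
                           "hotspot_concat" =
                             c("psbM-trnD", "trnR-trnT", "trnT-trnL",
                               "rpl22-rps19-rpl2"))) {
  subs <- lapply(markers, function(mk)
    extractMarker(aln, refTaxon, features, mk))
  rows <- Map(.markerRow, names(subs), subs)
  grows <- lapply(names(groups), function(gn) {
    mem <- groups[[gn]]
    missing <- setdiff(mem, names(subs))
    if (length(missing))
      .stopf("group '%s' references unknown marker(s): %s", gn,
             paste(missing, collapse = ", "))
    .markerRow(gn, do.call(cbind, subs[mem]))
  })
  out <- do.call(rbind, c(rows, grows))
  rownames(out) <- NULL
  out
}
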