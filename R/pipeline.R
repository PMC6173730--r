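## End-to-end orchestration: map building -> chimera splitting -> map
## rebuilding -> scaffolding -> emission.

#' Run the full scaffolding pipeline
#'
#' Stages, in order: best-hit selection, spurious-run filtering, synteny
#' anchor construction, marker anchor construction (skipped with a warning
#' when no marker map is given), chimera detection on the pooled maps,
#' contig splitting, rebuilding of both maps on the split contigs,
#' linkage-group assignment, ordering and orientation, and emission of
#' pseudomolecule sequences, AGP and statistics. Every parameter is a
#' default, never a constant, and per-stage counts are logged and returned
#' in the run manifest.
#'
#' @param contigs DNAStringSet of contigs (or a FASTA path).
#' @param genes gene models data.frame (or a GFF3 path).
#' @param hits gene-vs-contig hits data.frame (or a tab12 path).
#' @param markers marker map data.frame (or CSV path), or NULL for a
#'   synteny-only run.
#' @param flankHits marker-flank hits data.frame (or tab12 path), or NULL.
#' @param minHits,runLength spurious-run filter parameters.
#' @param chunk minimum anchors per side for a chimera breakpoint.
#' @param weights per-map weights, e.g. \code{c(genetic = 1, synteny = 1)}.
#' @param withinGap,unplacedGap N-gap sizes (bp).
#' @param minIdentity marker flank identity floor (percent).
#' @param outDir if given, all outputs and intermediates are written there.
#' @param verbose log stage progress via \code{message()}.
#' @return list with \code{layout}, \code{sequences}, \code{agp},
#'   \code{stats}, \code{breakpoints}, \code{nameMap}, \code{map} (final
#'   pooled AnchorMap), \code{contigs} (post-split) and \code{manifest}
#'   (parameters and per-stage counts).
#' @export
runScaffoldPipeline <- function(contigs, genes, hits, markers = NULL,
                                flankHits = NULL, minHits = 3, runLength = 1,
                                chunk = 4, weights = c(genetic = 1,
                                                       synteny = 1),
                                withinGap = 100L, unplacedGap = 1000L,
                                minIdentity = 95, outDir = NULL,
                                verbose = TRUE) {
  if (is.character(contigs)) contigs <- readContigs(contigs)
  if (is.character(genes)) genes <- readGeneModels(genes)
  if (is.character(hits)) hits <- readHits(hits)
  if (is.character(markers)) markers <- readMarkerMap(markers)
  if (is.character(flankHits)) flankHits <- readHits(flankHits)
  if (is.null(markers) || is.null(flankHits)) {
    warning("no marker map given: running synteny-only")
    markers <- NULL; flankHits <- NULL
  }
  manifest <- list(parameters = list(
    min_hits_for_filter = minHits, spurious_run_length = runLength,
    chunk = chunk, weights = as.list(weights), within_gap = withinGap,
    unplaced_gap = unplacedGap, min_marker_identity = minIdentity))
  counts <- list(n_contigs = length(contigs), n_genes = nrow(genes),
                 hits_in = nrow(hits))

  buildMaps <- function(hitTab, flankTab, ctgSet) {
    best <- selectBestHits(hitTab)
    filtered <- filterSpuriousRuns(best, genes, minHits = minHits,
                                   runLength = runLength)
    syn <- buildSyntenyAnchors(filtered, genes)
    gen <- NULL
    if (!is.null(markers) && !is.null(flankTab) && nrow(flankTab) > 0)
      gen <- buildMarkerAnchors(flankTab, markers, minIdentity = minIdentity)
    list(best = best, filtered = filtered, syn = syn, gen = gen,
         pooled = if (is.null(gen)) syn else combineAnchorMaps(syn, gen))
  }

  .msg(verbose, "[map-build] %d hits in", nrow(hits))
  maps <- buildMaps(hits, flankHits, contigs)
  counts$hits_best <- nrow(maps$best)
  counts$hits_after_filter <- nrow(maps$filtered)
  counts$synteny_anchors <- nrow(anchors(maps$syn))
  counts$genetic_anchors <- if (is.null(maps$gen)) 0L
  else nrow(anchors(maps$gen))
  .msg(verbose,
       "[map-build] %d best hits, %d after run filter; %d synteny + %d genetic anchors",
       counts$hits_best, counts$hits_after_filter, counts$synteny_anchors,
       counts$genetic_anchors)

  lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  breakpoints <- detectChimericContigs(maps$pooled, chunk = chunk,
                                       contigLengths = lens)
  counts$breakpoints <- nrow(breakpoints)
  .msg(verbose, "[chimera] %d breakpoints on %d contigs",
       nrow(breakpoints), length(unique(breakpoints$contig_id)))
  split <- splitContigs(contigs, maps$pooled, breakpoints)
  contigs2 <- split$contigs
  # both maps are remade on the split contigs
  hits2 <- remapHits(hits, split$nameMap)
  flank2 <- if (is.null(flankHits)) NULL else remapHits(flankHits,
                                                        split$nameMap)
  maps2 <- buildMaps(hits2, flank2, contigs2)
  counts$anchors_after_split <- nrow(anchors(maps2$pooled))

  lens2 <- stats::setNames(Biostrings::width(contigs2), names(contigs2))
  assignment <- assignLinkageGroups(maps2$pooled, weights = weights)
  counts$contigs_assigned <- length(assignment)
  layout <- orderAndOrient(maps2$pooled, assignment, lens2,
                           weights = weights, withinGap = withinGap,
                           unplacedGap = unplacedGap)
  .msg(verbose, "[scaffold] %d contigs placed on %d groups, %d unplaced",
       nrow(placements(layout)),
       length(unique(placements(layout)$linkage_group)),
       length(unplacedContigs(layout)))
  built <- buildPseudomolecules(layout, contigs2)
  stats <- assemblyStats(contigs2, layout)
  manifest$counts <- counts

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeContigs(built$sequences, file.path(outDir, "pseudomolecules.fa"))
    writeAgp(built$agp, file.path(outDir, "assembly.agp"))
    utils::write.table(placements(layout),
                       file.path(outDir, "placements.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(breakpoints, file.path(outDir, "breakpoints.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(split$nameMap, file.path(outDir, "name_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeAnchorMap(maps2$pooled, file.path(outDir, "anchors.csv"))
    jsonlite::write_json(unclass(stats), file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(layout = layout, sequences = built$sequences, agp = built$agp,
       stats = stats, breakpoints = breakpoints, nameMap = split$nameMap,
       map = maps2$pooled, contigs = contigs2, manifest = manifest)
}
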