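## Building the two anchor maps: gene synteny and genetic markers.

#' Rank reference genes within each chromosome
#'
#' Numbers the genes of each chromosome 1..n by ascending start coordinate
#' (ties broken by gene id). This rank space is shared with the collinear
#' chain detector, which works on relative gene order rather than bp.
#'
#' @param genes data.frame from [readGeneModels()].
#' @return the input with an added integer \code{rank} column (per
#'   chromosome).
#' @export
rankReferenceGenes <- function(genes) {
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                           FUN = seq_along)
  rownames(genes) <- NULL
  genes
}

#' Keep the single best hit per gene model
#'
#' Best = maximal bitscore; ties resolved by longer alignment, then by
#' lexicographically smaller subject id. Genes without hits are simply
#' absent from the result.
#'
#' @param hits data.frame from [readHits()] (queries are first-isoform gene
#'   model ids).
#' @return one row per query id.
#' @export
selectBestHits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query_id, -hits$bitscore, -hits$aln_length,
             hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Remove spurious hits by run-length filtering
#'
#' On every contig with at least \code{minHits} best hits, hits are ordered
#' by contig position and labelled with the reference chromosome of their
#' gene; maximal runs of identical chromosome are computed once, and every
#' hit in a run of length <= \code{runLength} is removed. Isolated hits to a
#' foreign chromosome (run length 1, the default) are the classic signature
#' of a paralogous alignment rather than true synteny. Contigs with fewer
#' than \code{minHits} hits are left untouched, and the filter is a single
#' pass: removals do not merge the flanking runs for a second round.
#'
#' @param hits best-hits data.frame (one hit per gene).
#' @param genes gene models (used to label each hit with its reference
#'   chromosome).
#' @param minHits minimum hits on a contig for the filter to apply
#'   (default 3).
#' @param runLength maximal run length treated as spurious (default 1).
#' @return the filtered hits, a subsequence of the input rows.
#' @export
filterSpuriousRuns <- function(hits, genes, minHits = 3, runLength = 1) {
  stopifnot(minHits >= 1, runLength >= 0)
  if (nrow(hits) == 0 || runLength == 0) return(hits)
  chrom <- .geneChromLookup(hits$query_id, genes)
  keep <- rep(TRUE, nrow(hits))
  for (ctg in unique(hits$subject_id)) {
    idx <- which(hits$subject_id == ctg)
    if (length(idx) < minHits) next
    idx <- idx[order(hits$subject_start[idx])]
    runs <- rle(chrom[idx])
    short <- rep(runs$lengths <= runLength, runs$lengths)
    keep[idx[short]] <- FALSE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Map hit query ids to gene rows, accepting either isoform or gene ids.
.geneRowLookup <- function(queryIds, genes) {
  i <- match(queryIds, genes$isoform_id)
  miss <- is.na(i)
  i[miss] <- match(queryIds[miss], genes$gene_id)
  if (anyNA(i))
    stop("hit query id(s) absent from gene models: ",
         paste(unique(queryIds[is.na(i)]), collapse = ", "))
  i
}

.geneChromLookup <- function(queryIds, genes) {
  genes$chromosome[.geneRowLookup(queryIds, genes)]
}

#' Build the gene-synteny anchor map
#'
#' Each surviving best hit ties a contig position to the start coordinate of
#' its reference gene model; the gene's chromosome becomes the linkage
#' group. Contigs with two or more hits contribute one anchor per hit, at
#' the strand-aware subject endpoint that corresponds to the gene start.
#' Contigs with a single hit contribute two anchors (gene start and gene
#' stop, at the matching subject endpoints) so that even a one-gene contig
#' can be oriented.
#'
#' @param hits filtered best hits (see [filterSpuriousRuns()]).
#' @param genes gene models.
#' @param weight anchor weight (default 1).
#' @return An [AnchorMap-class] with \code{map_name = "synteny"} and
#'   \code{map_pos} in reference bp.
#' @export
buildSyntenyAnchors <- function(hits, genes, weight = 1) {
  if (nrow(hits) == 0) return(AnchorMap(.emptyAnchors()))
  gi <- .geneRowLookup(hits$query_id, genes)
  g <- genes[gi, ]
  nPer <- table(hits$subject_id)
  multi <- hits$subject_id %in% names(nPer)[nPer >= 2]
  # strand-aware endpoints: on "+" hits the subject start faces the gene
  # start; on "-" hits the subject end does (positions are 0-based points)
  startSide <- ifelse(hits$strand == "+", hits$subject_start,
                      hits$subject_end - 1L)
  stopSide <- ifelse(hits$strand == "+", hits$subject_end - 1L,
                     hits$subject_start)
  a1 <- data.frame(contig_id = hits$subject_id, contig_pos = startSide,
                   linkage_group = g$chromosome, map_pos = as.numeric(g$start),
                   map_name = "synteny", weight = weight)
  single <- !multi
  a2 <- data.frame(contig_id = hits$subject_id[single],
                   contig_pos = stopSide[single],
                   linkage_group = g$chromosome[single],
                   map_pos = as.numeric(g$stop[single]),
                   map_name = "synteny", weight = weight)
  AnchorMap(rbind(a1, a2))
}

.emptyAnchors <- function() {
  data.frame(contig_id = character(), contig_pos = integer(),
             linkage_group = character(), map_pos = numeric(),
             map_name = character(), weight = numeric())
}

#' Build the genetic-marker anchor map
#'
#' Each marker's flank sequence (default 200 bp around the SNP) has been
#' aligned to the contigs; markers with a unique best alignment of at least
#' \code{minIdentity} percent identity yield one anchor at the SNP position
#' on the contig, with the linkage group and centimorgan position taken from
#' the marker record. Markers that are unaligned, multi-mapping (any second
#' alignment within \code{scoreMargin} bitscore units of the best also
#' disqualifies, guarding against near-repeats), or whose SNP offset falls
#' outside the aligned span, are dropped and counted in the report attached
#' as \code{attr(, "report")}.
#'
#' @param flankHits data.frame from [readHits()], query ids = flank ids.
#' @param markers data.frame from [readMarkerMap()].
#' @param minIdentity minimum percent identity (default 95).
#' @param scoreMargin secondary alignments within this many bitscore units
#'   of the best disqualify the marker (default 10).
#' @param weight anchor weight (default 1).
#' @return An [AnchorMap-class] with \code{map_name = "genetic"} and
#'   \code{map_pos} in cM.
#' @export
buildMarkerAnchors <- function(flankHits, markers, minIdentity = 95,
                               scoreMargin = 10, weight = 1) {
  report <- c(placed = 0L, unaligned = 0L, multimapping = 0L,
              low_identity = 0L, offset_outside = 0L)
  rows <- list()
  for (i in seq_len(nrow(markers))) {
    mk <- markers[i, ]
    h <- flankHits[flankHits$query_id == mk$flank_id, , drop = FALSE]
    if (nrow(h) == 0) { report["unaligned"] <- report["unaligned"] + 1L; next }
    h <- h[order(-h$bitscore), , drop = FALSE]
    if (nrow(h) > 1 && h$bitscore[1] - h$bitscore[2] < scoreMargin) {
      report["multimapping"] <- report["multimapping"] + 1L; next
    }
    best <- h[1, ]
    if (best$pct_identity < minIdentity) {
      report["low_identity"] <- report["low_identity"] + 1L; next
    }
    offsetInAln <- mk$snp_offset - best$query_start
    alnSpan <- best$subject_end - best$subject_start
    if (offsetInAln < 0 || offsetInAln >= alnSpan) {
      warning("marker '", mk$marker_id,
              "': SNP offset outside aligned span; dropped")
      report["offset_outside"] <- report["offset_outside"] + 1L; next
    }
    pos <- if (best$strand == "+") best$subject_start + offsetInAln
    else best$subject_end - 1L - offsetInAln
    report["placed"] <- report["placed"] + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = best$subject_id, contig_pos = as.integer(pos),
      linkage_group = as.character(mk$linkage_group),
      map_pos = as.numeric(mk$cM), map_name = "genetic", weight = weight)
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else .emptyAnchors()
  out <- AnchorMap(tab)
  attr(out, "report") <- report
  out
}
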