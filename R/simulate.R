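## Seeded synthetic genomes with known contig order, orientation and
## chimera truth. The simulator emulates the observable inputs of the
## scaffolding pipeline (gene-model hit tables and marker flank alignments)
## directly, so no aligner is needed: sequence composition is arbitrary
## repeat-free random DNA, because nothing downstream realigns it.
##
## A single integer seed drives everything; each stage derives its own
## substream by a fixed offset so that stages stay reproducible even when
## run separately.

#' Simulation configuration
#'
#' Defaults describe a compact diploid-free genome: 4 chromosomes of 200
#' genes (1 kb genes, 2 kb intergenic, so 602 kb per chromosome), broken
#' into 80 contigs, 30% of them inverted, 3 chimeric joins, a 2% spurious
#' hit rate, 60 genetic markers and 10% of gene anchors missing.
#'
#' @param seed integer seed; identical seeds give bit-identical outputs.
#' @param nChromosomes,genesPerChromosome,geneLength,intergenic genome shape.
#' @param nContigs number of contigs after chimera joining.
#' @param inversionRate probability a contig is reverse-complemented.
#' @param nChimeras number of cross-chromosome mis-joins.
#' @param spuriousRate spurious hits as a fraction of total genes.
#' @param markerCount genetic-map markers across the genome.
#' @param anchorMissingRate fraction of gene hits dropped.
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, nChromosomes = 4L, genesPerChromosome = 200L,
                      geneLength = 1000L, intergenic = 2000L, nContigs = 80L,
                      inversionRate = 0.3, nChimeras = 3L, spuriousRate = 0.02,
                      markerCount = 60L, anchorMissingRate = 0.1) {
  cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
              genesPerChromosome = as.integer(genesPerChromosome),
              geneLength = as.integer(geneLength),
              intergenic = as.integer(intergenic),
              nContigs = as.integer(nContigs),
              inversionRate = inversionRate, nChimeras = as.integer(nChimeras),
              spuriousRate = spuriousRate,
              markerCount = as.integer(markerCount),
              anchorMissingRate = anchorMissingRate)
  rates <- c(cfg$inversionRate, cfg$spuriousRate, cfg$anchorMissingRate)
  stopifnot(all(rates >= 0 & rates <= 1),
            cfg$nChromosomes >= 1, cfg$genesPerChromosome >= 2,
            cfg$geneLength >= 1, cfg$intergenic >= 1,
            cfg$nContigs >= 1, cfg$nChimeras >= 0, cfg$markerCount >= 0)
  class(cfg) <- "SimConfig"
  cfg
}

.randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the reference genome, gene models and marker map
#'
#' Chromosomes carry \code{genesPerChromosome} genes at fixed spacing;
#' markers sit at uniform random gene-free (intergenic) positions, with
#' centimorgan positions proportional to bp (20 kb per cM).
#'
#' @param config a [simConfig()].
#' @return list with \code{sequences} (DNAStringSet), \code{genes}
#'   (gene-model data.frame), \code{markers}, \code{chromLengths} and the
#'   config.
#' @export
simulateReference <- function(config) {
  set.seed(config$seed + 101L)
  spacing <- config$geneLength + config$intergenic
  chromLen <- config$genesPerChromosome * spacing + config$intergenic
  chromNames <- sprintf("chr%02d", seq_len(config$nChromosomes))
  seqs <- Biostrings::DNAStringSet(
    vapply(chromNames, function(x) .randomSeq(chromLen), character(1)))
  genes <- do.call(rbind, lapply(seq_len(config$nChromosomes), function(i) {
    j <- seq_len(config$genesPerChromosome)
    start <- config$intergenic + (j - 1L) * spacing
    data.frame(gene_id = sprintf("G%02d%04d", i, j),
               isoform_id = sprintf("G%02d%04d.1", i, j),
               chromosome = chromNames[i], start = start,
               stop = start + config$geneLength,
               strand = sample(c("+", "-"), length(j), replace = TRUE),
               isoform_order = 1L)
  }))
  chromLengths <- stats::setNames(rep(chromLen, config$nChromosomes),
                                  chromNames)
  markers <- .placeMarkers(config, genes, chromLengths)
  list(sequences = seqs, genes = genes, markers = markers,
       chromLengths = chromLengths, config = config)
}

.placeMarkers <- function(config, genes, chromLengths) {
  set.seed(config$seed + 102L)
  empty <- data.frame(marker_id = character(), linkage_group = character(),
                      cM = numeric(), flank_id = character(),
                      snp_offset = integer(), flank_length = integer(),
                      pos = integer())
  if (config$markerCount == 0) return(empty)
  spacing <- config$geneLength + config$intergenic
  # one candidate slot per intergenic region (the one before each gene)
  slots <- expand.grid(chrom = seq_along(chromLengths),
                       gap = seq_len(config$genesPerChromosome))
  pick <- slots[sample(nrow(slots), min(config$markerCount, nrow(slots))), ]
  gapStart <- (pick$gap - 1L) * spacing
  pos <- gapStart + sample.int(config$intergenic, nrow(pick), replace = TRUE) - 1L
  chrom <- names(chromLengths)[pick$chrom]
  o <- order(chrom, pos)
  data.frame(marker_id = sprintf("M%03d", seq_along(pos)),
             linkage_group = chrom[o],
             cM = round(pos[o] / 20000, 4),
             flank_id = sprintf("M%03d_flank", seq_along(pos)),
             snp_offset = 100L, flank_length = 200L,
             pos = as.integer(pos[o]))
}

#' Fragment the reference into contigs with known truth
#'
#' Chromosomes are cut at random intergenic midpoints into
#' \code{nContigs + nChimeras} pieces; each piece is independently
#' reverse-complemented with probability \code{inversionRate}; then
#' \code{nChimeras} pairs of pieces from different chromosomes (each side
#' with at least 4 genes, so every simulated mis-join is detectable in
#' principle) are concatenated with the join recorded as a true breakpoint.
#'
#' @param reference from [simulateReference()].
#' @param config the same [simConfig()].
#' @return list with \code{contigs} (DNAStringSet, shuffled names) and
#'   \code{truth}: \code{$pieces} (per piece: contig, offset, source
#'   chromosome, coordinates, orientation, order index, gene count) and
#'   \code{$chimeras} (contig, true breakpoint).
#' @export
deriveTarget <- function(reference, config) {
  if (config$nContigs < config$nChromosomes)
    stop("nContigs must be >= nChromosomes")
  set.seed(config$seed + 103L)
  spacing <- config$geneLength + config$intergenic
  genes <- reference$genes
  nPieces <- config$nContigs + config$nChimeras
  nCuts <- nPieces - config$nChromosomes
  cutSlots <- expand.grid(chrom = names(reference$chromLengths),
                          gap = seq_len(config$genesPerChromosome - 1L),
                          stringsAsFactors = FALSE)
  if (nCuts > nrow(cutSlots)) stop("more pieces requested than cut sites")
  cuts <- cutSlots[sample(nrow(cutSlots), nCuts), , drop = FALSE]
  # cut in the middle of the intergenic region after gene `gap`
  cuts$pos <- cuts$gap * spacing + config$intergenic %/% 2
  pieces <- do.call(rbind, lapply(names(reference$chromLengths), function(ch) {
    bounds <- c(0L, sort(cuts$pos[cuts$chrom == ch]),
                unname(reference$chromLengths[ch]))
    data.frame(chrom = ch, chrom_start = utils::head(bounds, -1),
               chrom_end = bounds[-1],
               order_index = seq_len(length(bounds) - 1L))
  }))
  pieces$length <- pieces$chrom_end - pieces$chrom_start
  pieces$orientation <- ifelse(
    stats::runif(nrow(pieces)) < config$inversionRate, "-", "+")
  pieces$n_genes <- vapply(seq_len(nrow(pieces)), function(i) {
    sum(genes$chromosome == pieces$chrom[i] &
          genes$start >= pieces$chrom_start[i] &
          genes$stop <= pieces$chrom_end[i])
  }, integer(1))
  # pair up chimera partners: different chromosomes, >= 4 genes each side
  pieceOf <- rep(list(NULL), nrow(pieces))
  eligible <- which(pieces$n_genes >= 4L)
  pairs <- list()
  if (config$nChimeras > 0) {
    pool <- sample(eligible)
    while (length(pairs) < config$nChimeras) {
      if (length(pool) < 2)
        stop("not enough multi-gene pieces for the requested chimeras")
      a <- pool[1]
      b <- pool[which(pieces$chrom[pool] != pieces$chrom[a])[1]]
      if (is.na(b)) stop("cannot pair chimeras across chromosomes")
      pairs[[length(pairs) + 1L]] <- c(a, b)
      pool <- setdiff(pool, c(a, b))
    }
  }
  inChimera <- unlist(pairs)
  singles <- setdiff(seq_len(nrow(pieces)), inChimera)
  units <- c(as.list(singles), pairs)
  units <- units[sample(length(units))]
  names(units) <- sprintf("ctg%03d", seq_along(units))
  pieceSeq <- function(i) {
    s <- Biostrings::subseq(reference$sequences[[pieces$chrom[i]]],
                            pieces$chrom_start[i] + 1L, pieces$chrom_end[i])
    if (pieces$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
    s
  }
  contigs <- Biostrings::DNAStringSet(lapply(units, function(u) {
    if (length(u) == 1) pieceSeq(u[1])
    else Biostrings::xscat(pieceSeq(u[1]), pieceSeq(u[2]))
  }))
  truthRows <- list(); chimRows <- list()
  for (nm in names(units)) {
    u <- units[[nm]]
    offset <- 0L
    for (p in seq_along(u)) {
      i <- u[p]
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        contig_id = nm, part_index = p, offset = offset,
        length = pieces$length[i], chrom = pieces$chrom[i],
        chrom_start = pieces$chrom_start[i], chrom_end = pieces$chrom_end[i],
        orientation = pieces$orientation[i],
        order_index = pieces$order_index[i], n_genes = pieces$n_genes[i])
      offset <- offset + pieces$length[i]
    }
    if (length(u) == 2)
      chimRows[[length(chimRows) + 1L]] <- data.frame(
        contig_id = nm, breakpoint = pieces$length[u[1]])
  }
  chimeras <- if (length(chimRows) > 0) do.call(rbind, chimRows) else
    data.frame(contig_id = character(), breakpoint = integer())
  truthPieces <- do.call(rbind, truthRows)
  rownames(truthPieces) <- NULL
  rownames(chimeras) <- NULL
  list(contigs = contigs,
       truth = list(pieces = truthPieces, chimeras = chimeras),
       config = config)
}

#' Emit simulated gene-hit and marker-flank alignment tables
#'
#' One correct hit per gene that survived the drop-out draw
#' (\code{anchorMissingRate}); \code{round(spuriousRate * total genes)}
#' extra hits pairing a gene with a contig from a different chromosome at a
#' random position, given a bitscore high enough to win best-hit selection
#' (emulating a dominant paralogous alignment). Marker flanks are reported
#' at their true contig positions, clipped at piece boundaries.
#'
#' @param target from [deriveTarget()].
#' @param reference from [simulateReference()].
#' @param config the same [simConfig()].
#' @return list with \code{hits} and \code{flankHits}, both in the internal
#'   hit layout of [readHits()].
#' @export
emitObservations <- function(target, reference, config) {
  set.seed(config$seed + 104L)
  genes <- reference$genes
  pieces <- target$truth$pieces
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    hit <- which(pieces$chrom == genes$chromosome[g] &
                   pieces$chrom_start <= genes$start[g] &
                   genes$stop[g] <= pieces$chrom_end)
    if (length(hit) == 0) next
    pc <- pieces[hit[1], ]
    len <- genes$stop[g] - genes$start[g]
    if (pc$orientation == "+") {
      s <- pc$offset + (genes$start[g] - pc$chrom_start); strand <- "+"
    } else {
      s <- pc$offset + (pc$chrom_end - genes$stop[g]); strand <- "-"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = genes$isoform_id[g], subject_id = pc$contig_id,
      pct_identity = round(stats::runif(1, 98, 100), 2), aln_length = len,
      query_start = 0L, query_end = len, subject_start = as.integer(s),
      subject_end = as.integer(s + len), strand = strand, evalue = 1e-180,
      bitscore = round(1.8 * len + stats::runif(1, 0, 20), 1))
  }
  hits <- do.call(rbind, rows)
  nDrop <- round(config$anchorMissingRate * nrow(hits))
  if (nDrop > 0) hits <- hits[-sample(nrow(hits), nDrop), , drop = FALSE]
  nSpur <- round(config$spuriousRate * nrow(genes))
  if (nSpur > 0) {
    chromsOf <- split(pieces$chrom, pieces$contig_id)
    spur <- lapply(seq_len(nSpur), function(k) {
      ctg <- sample(names(chromsOf), 1)
      wrong <- genes[!genes$chromosome %in% chromsOf[[ctg]], , drop = FALSE]
      g <- wrong[sample(nrow(wrong), 1), ]
      len <- g$stop - g$start
      ctgLen <- sum(pieces$length[pieces$contig_id == ctg])
      s <- sample.int(max(1L, ctgLen - len), 1) - 1L
      data.frame(query_id = g$isoform_id, subject_id = ctg,
                 pct_identity = round(stats::runif(1, 98, 100), 2),
                 aln_length = len, query_start = 0L, query_end = len,
                 subject_start = s, subject_end = s + len,
                 strand = sample(c("+", "-"), 1), evalue = 1e-180,
                 bitscore = round(2.5 * len, 1))
    })
    hits <- rbind(hits, do.call(rbind, spur))
  }
  rownames(hits) <- NULL
  flankHits <- .emitFlankHits(reference$markers, pieces)
  list(hits = hits, flankHits = flankHits)
}

.emitFlankHits <- function(markers, pieces) {
  rows <- list()
  for (i in seq_len(nrow(markers))) {
    mk <- markers[i, ]
    hit <- which(pieces$chrom == mk$linkage_group &
                   pieces$chrom_start <= mk$pos & mk$pos < pieces$chrom_end)
    if (length(hit) == 0) next
    pc <- pieces[hit[1], ]
    fs <- mk$pos - mk$snp_offset
    fe <- fs + mk$flank_length
    ovs <- max(fs, pc$chrom_start); ove <- min(fe, pc$chrom_end)
    if (ove <= ovs) next
    if (pc$orientation == "+") {
      ss <- pc$offset + (ovs - pc$chrom_start)
      se <- pc$offset + (ove - pc$chrom_start); strand <- "+"
    } else {
      ss <- pc$offset + (pc$chrom_end - ove)
      se <- pc$offset + (pc$chrom_end - ovs); strand <- "-"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = mk$flank_id, subject_id = pc$contig_id,
      pct_identity = 100, aln_length = ove - ovs,
      query_start = as.integer(ovs - fs), query_end = as.integer(ove - fs),
      subject_start = as.integer(ss), subject_end = as.integer(se),
      strand = strand, evalue = 1e-90, bitscore = 2 * (ove - ovs))
  }
  if (length(rows) == 0)
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), aln_length = integer(),
                      query_start = integer(), query_end = integer(),
                      subject_start = integer(), subject_end = integer(),
                      strand = character(), evalue = numeric(),
                      bitscore = numeric()))
  do.call(rbind, rows)
}

#' Score a scaffolding result against simulator truth
#'
#' Placed contigs (including split parts, resolved through \code{nameMap})
#' are matched to their truth pieces by maximal overlap. Reports
#' per-chromosome Kendall tau of recovered vs true contig order, the
#' fraction of adjacent true pairs preserved in the layout, orientation
#' accuracy, chimera breakpoint precision and recall (a call within
#' \code{tol} bp of the truth on the same contig counts), and the bp
#' placement rate. With no chimeras simulated and none called, precision
#' and recall are 1 by convention.
#'
#' @param truth the \code{truth} list from [deriveTarget()].
#' @param layout the recovered [ScaffoldLayout-class].
#' @param breakpoints data.frame of called breakpoints (may be empty).
#' @param contigLengths named lengths of the (possibly split) contig set
#'   that was scaffolded.
#' @param nameMap split name map from [splitContigs()] (NULL if no split).
#' @param tol breakpoint matching tolerance in bp (default 2000, one
#'   intergenic distance).
#' @return list of recovery metrics.
#' @export
evaluateRecovery <- function(truth, layout, breakpoints = NULL,
                             contigLengths = NULL, nameMap = NULL,
                             tol = 2000) {
  p <- placements(layout)
  pieces <- truth$pieces
  matchPiece <- function(ctg) {
    if (!is.null(nameMap) && ctg %in% nameMap$new) {
      row <- nameMap[nameMap$new == ctg, ][1, ]
      old <- row$old; lo <- row$offset; hi <- row$offset + row$length
    } else {
      old <- ctg; lo <- 0; hi <- Inf
    }
    cand <- pieces[pieces$contig_id == old, , drop = FALSE]
    if (nrow(cand) == 0) return(NA_integer_)
    ov <- pmin(hi, cand$offset + cand$length) - pmax(lo, cand$offset)
    which(pieces$contig_id == old)[which.max(ov)]
  }
  idx <- vapply(p$contig_id, matchPiece, integer(1))
  ok <- !is.na(idx)
  p <- p[ok, , drop = FALSE]; idx <- idx[ok]
  p$true_chrom <- pieces$chrom[idx]
  p$true_order <- pieces$order_index[idx]
  p$true_orient <- pieces$orientation[idx]
  taus <- vapply(split(p, p$linkage_group), function(sub) {
    if (nrow(sub) < 2) return(NA_real_)
    stats::cor(sub$position, sub$true_order, method = "kendall")
  }, numeric(1))
  orientAcc <- if (nrow(p) > 0)
    mean(p$orientation == p$true_orient) else NA_real_
  # adjacent true pairs preserved in the layout; the order metric is
  # conditioned on both pieces being placed (placement loss is reported
  # separately as placement_rate)
  adjTotal <- 0L; adjOk <- 0L
  for (ch in unique(pieces$chrom)) {
    subIdx <- which(pieces$chrom == ch)
    subIdx <- subIdx[order(pieces$order_index[subIdx])]
    for (i in seq_len(length(subIdx) - 1L)) {
      ia <- which(idx == subIdx[i])
      ib <- which(idx == subIdx[i + 1L])
      if (length(ia) < 1 || length(ib) < 1) next
      ia <- ia[1]; ib <- ib[1]
      adjTotal <- adjTotal + 1L
      if (p$linkage_group[ia] == p$linkage_group[ib] &&
          p$position[ia] < p$position[ib])
        adjOk <- adjOk + 1L
    }
  }
  trueBp <- truth$chimeras
  called <- if (is.null(breakpoints)) data.frame(contig_id = character(),
                                                 position = integer())
  else breakpoints
  matchBp <- function(ctg, pos, other)
    any(other$contig_id == ctg & abs(other$position - pos) <= tol)
  if (nrow(trueBp) > 0) {
    names(trueBp)[names(trueBp) == "breakpoint"] <- "position"
    recall <- mean(vapply(seq_len(nrow(trueBp)), function(i)
      matchBp(trueBp$contig_id[i], trueBp$position[i], called), logical(1)))
  } else recall <- 1
  precision <- if (nrow(called) > 0 && nrow(trueBp) > 0)
    mean(vapply(seq_len(nrow(called)), function(i)
      matchBp(called$contig_id[i], called$position[i], trueBp), logical(1)))
  else if (nrow(called) > 0) 0 else 1
  placementRate <- if (!is.null(contigLengths))
    percentOf(sum(contigLengths[p$contig_id], na.rm = TRUE),
              sum(contigLengths), 2) else NA_real_
  list(tau = taus, mean_tau = mean(taus, na.rm = TRUE),
       orientation_accuracy = orientAcc,
       adjacent_accuracy = if (adjTotal > 0) adjOk / adjTotal else NA_real_,
       chimera_precision = precision, chimera_recall = recall,
       placement_rate = placementRate)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits \code{reference.fa}, \code{genes.gff3}, \code{contigs.fa},
#' \code{hits.tsv}, \code{flank_hits.tsv}, \code{markers.csv} and
#' \code{truth.json}.
#'
#' @param config a [simConfig()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the in-memory dataset: reference, target,
#'   observations.
#' @export
simulateDataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulateReference(config)
  target <- deriveTarget(ref, config)
  obs <- emitObservations(target, ref, config)
  writeContigs(ref$sequences, file.path(dir, "reference.fa"))
  writeGeneModels(ref$genes, file.path(dir, "genes.gff3"))
  writeContigs(target$contigs, file.path(dir, "contigs.fa"))
  writeHits(obs$hits, file.path(dir, "hits.tsv"))
  writeHits(obs$flankHits, file.path(dir, "flank_hits.tsv"))
  utils::write.csv(ref$markers, file.path(dir, "markers.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(pieces = target$truth$pieces, chimeras = target$truth$chimeras,
         config = unclass(config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(reference = ref, target = target, observations = obs))
}
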