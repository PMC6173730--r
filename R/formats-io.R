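## File I/O for every format the toolkit touches.
##
## Internal coordinate convention: 0-based half-open everywhere. GFF3, AGP
## and 12-column tabular alignments are 1-based inclusive on disk and are
## converted at this boundary, in both directions.

#' Read contig (or chromosome) sequences from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] and enforces the invariants the
#' scaffolder relies on: unique non-empty ids, non-empty sequences, case
#' folded to upper. Record order is preserved.
#'
#' @param path FASTA file (plain or gzip).
#' @return A [Biostrings::DNAStringSet] (possibly empty).
#' @export
readContigs <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(Biostrings::DNAStringSet())
  seqs <- Biostrings::readDNAStringSet(path)
  # keep only the id token, as alignment tools do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(names(seqs) == "")) stop("FASTA record with empty id")
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup) > 0)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0))
    stop("empty sequence body for id(s): ",
         paste(names(seqs)[Biostrings::width(seqs) == 0], collapse = ", "))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write sequences to FASTA
#' @param seqs DNAStringSet (or named character vector).
#' @param path output file.
#' @export
writeContigs <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
               "query_start", "query_end", "subject_start", "subject_end",
               "strand", "evalue", "bitscore")

#' Read a tabular alignment file (12-column "outfmt 6" or PAF)
#'
#' Hits on the minus strand of the subject (encoded in the 12-column dialect
#' by subject start > end) are normalized so that
#' \code{subject_start < subject_end}, with the original orientation kept in
#' the \code{strand} column. All coordinates are converted to 0-based
#' half-open.
#'
#' @param path tabular alignment file.
#' @param dialect \code{"tab12"} (qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore) or \code{"paf"}.
#' @return data.frame with columns \code{query_id, subject_id, pct_identity,
#'   aln_length, query_start, query_end, subject_start, subject_end, strand,
#'   evalue, bitscore}.
#' @export
readHits <- function(path, dialect = c("tab12", "paf")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), aln_length = integer(),
                      query_start = integer(), query_end = integer(),
                      subject_start = integer(), subject_end = integer(),
                      strand = character(), evalue = numeric(),
                      bitscore = numeric())
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "tab12") 12L else 12L
  nf <- lengths(fields)
  bad <- if (dialect == "tab12") which(nf != 12L) else which(nf < 12L)
  if (length(bad) > 0)
    stop(sprintf("line %d of '%s': expected %s columns, found %d",
                 bad[1], path,
                 if (dialect == "tab12") "12" else ">= 12", nf[bad[1]]))
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  if (dialect == "tab12") {
    sstart <- as.numeric(m[, 9]); send <- as.numeric(m[, 10])
    minus <- sstart > send
    out <- data.frame(
      query_id = m[, 1], subject_id = m[, 2],
      pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
      query_start = as.integer(m[, 7]) - 1L, query_end = as.integer(m[, 8]),
      subject_start = as.integer(ifelse(minus, send, sstart)) - 1L,
      subject_end = as.integer(ifelse(minus, sstart, send)),
      strand = ifelse(minus, "-", "+"),
      evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]))
  } else {
    alnlen <- as.numeric(m[, 11])
    out <- data.frame(
      query_id = m[, 1], subject_id = m[, 6],
      pct_identity = round(100 * as.numeric(m[, 10]) / pmax(alnlen, 1), 2),
      aln_length = as.integer(alnlen),
      query_start = as.integer(m[, 3]), query_end = as.integer(m[, 4]),
      subject_start = as.integer(m[, 8]), subject_end = as.integer(m[, 9]),
      strand = m[, 5],
      evalue = NA_real_, bitscore = as.numeric(m[, 10]))
  }
  if (any(out$aln_length < 1)) stop("alignment length < 1")
  if (any(out$pct_identity < 0 | out$pct_identity > 100))
    stop("percent identity outside [0, 100]")
  if (any(!is.na(out$evalue) & out$evalue < 0)) stop("negative e-value")
  rownames(out) <- NULL
  out
}

#' Write hits back to 12-column tabular format
#'
#' Inverse of [readHits()] for the tab12 dialect; minus-strand hits are
#' re-encoded with subject start > end.
#'
#' @param hits data.frame in the internal hit layout.
#' @param path output file.
#' @export
writeHits <- function(hits, path) {
  minus <- hits$strand == "-"
  s1 <- ifelse(minus, hits$subject_end, hits$subject_start + 1L)
  s2 <- ifelse(minus, hits$subject_start + 1L, hits$subject_end)
  tab <- data.frame(hits$query_id, hits$subject_id,
                    format(hits$pct_identity, trim = TRUE),
                    hits$aln_length, 0L, 0L,
                    hits$query_start + 1L, hits$query_end, s1, s2,
                    format(ifelse(is.na(hits$evalue), 0, hits$evalue),
                           trim = TRUE),
                    format(hits$bitscore, trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3, keeping the first isoform per gene
#'
#' Parses a GFF3 with a gene/mRNA hierarchy (gene-only files are accepted)
#' and returns exactly one model per gene: the first mRNA encountered in file
#' order, matching annotation-file isoform numbering. GFF 1-based inclusive
#' coordinates become 0-based half-open.
#'
#' @param path GFF3 file.
#' @return data.frame with columns \code{gene_id, isoform_id, chromosome,
#'   start, stop, strand, isoform_order}.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type %in% c("mRNA", "transcript")]
  if (length(genes) == 0) stop("no gene features in ", path)
  if (any(as.character(BiocGenerics::strand(genes)) == "*"))
    stop("gene feature without strand in ", path)
  gdf <- data.frame(gene_id = as.character(genes$ID),
                    chromosome = as.character(GenomicRanges::seqnames(genes)),
                    start = BiocGenerics::start(genes) - 1L,
                    stop = BiocGenerics::end(genes),
                    strand = as.character(BiocGenerics::strand(genes)))
  if (length(mrnas) > 0) {
    parent <- vapply(mrnas$Parent, function(p) p[1], character(1))
    orphan <- setdiff(parent, gdf$gene_id)
    if (length(orphan) > 0)
      stop("mRNA with no parent gene: ", paste(orphan, collapse = ", "))
    first <- !duplicated(parent)
    iso <- data.frame(gene_id = parent[first],
                      isoform_id = as.character(mrnas$ID)[first],
                      isoform_order = 1L)
    gdf <- merge(gdf, iso, by = "gene_id", all.x = TRUE, sort = FALSE)
    noiso <- is.na(gdf$isoform_id)
    gdf$isoform_id[noiso] <- gdf$gene_id[noiso]
    gdf$isoform_order[noiso] <- 1L
  } else {
    gdf$isoform_id <- gdf$gene_id
    gdf$isoform_order <- 1L
  }
  gdf[, c("gene_id", "isoform_id", "chromosome", "start", "stop",
          "strand", "isoform_order")]
}

#' Write gene models as GFF3
#'
#' Emits a gene row and one mRNA row per model (the simulator's annotation
#' writer). Internal 0-based half-open coordinates become 1-based inclusive.
#'
#' @param genes data.frame as returned by [readGeneModels()].
#' @param path output file.
#' @export
writeGeneModels <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tChromAnchor\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chromosome, g$start + 1L, g$stop, g$strand,
                       g$gene_id), con)
    writeLines(sprintf(
      "%s\tChromAnchor\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      g$chromosome, g$start + 1L, g$stop, g$strand, g$isoform_id,
      g$gene_id), con)
  }
  invisible(path)
}

## ---- AGP 2.1 ----

.AGP_COLS <- c("object", "object_beg", "object_end", "part_number",
               "component_type", "component_id", "component_beg",
               "component_end", "orientation")

#' Convert a ScaffoldLayout to AGP 2.1 rows
#'
#' W rows describe contigs, N rows the fixed scaffold gaps between them
#' (gap_type "scaffold", linkage "yes", evidence "map"). The unplaced pool is
#' emitted as one object named \code{unplacedObject}.
#'
#' @param layout a [ScaffoldLayout-class].
#' @param contigLengths named vector of contig lengths (bp).
#' @param unplacedObject object id for the pooled unplaced contigs.
#' @return data.frame of AGP rows (gap rows carry the gap length in
#'   \code{component_id} and "scaffold\\tyes\\tmap" semantics on write).
#' @export
layoutToAgp <- function(layout, contigLengths, unplacedObject = "chrUn") {
  p <- placements(layout)
  rows <- list()
  emitObject <- function(object, ids, orient, gap) {
    pos <- 1L; part <- 1L
    for (i in seq_along(ids)) {
      len <- unname(contigLengths[ids[i]])
      if (is.na(len)) stop("contig missing from sequence set: ", ids[i])
      rows[[length(rows) + 1L]] <<- data.frame(
        object = object, object_beg = pos, object_end = pos + len - 1L,
        part_number = part, component_type = "W", component_id = ids[i],
        component_beg = 1L, component_end = len, orientation = orient[i])
      pos <- pos + len; part <- part + 1L
      if (i < length(ids) && gap > 0) {
        rows[[length(rows) + 1L]] <<- data.frame(
          object = object, object_beg = pos, object_end = pos + gap - 1L,
          part_number = part, component_type = "N",
          component_id = as.character(gap), component_beg = NA_integer_,
          component_end = NA_integer_, orientation = NA_character_)
        pos <- pos + gap; part <- part + 1L
      }
    }
  }
  for (lg in sortGroups(p$linkage_group)) {
    sub <- p[p$linkage_group == lg, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    emitObject(lg, sub$contig_id, sub$orientation, layout@withinGap)
  }
  if (length(unplacedContigs(layout)) > 0)
    emitObject(unplacedObject, unplacedContigs(layout),
               rep("+", length(unplacedContigs(layout))), layout@unplacedGap)
  agp <- do.call(rbind, rows)
  rownames(agp) <- NULL
  agp
}

#' Write AGP rows to file (AGP version 2.1)
#' @param agp data.frame as from [layoutToAgp()].
#' @param path output file.
#' @export
writeAgp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (i in seq_len(nrow(agp))) {
    r <- agp[i, ]
    if (r$component_type == "W") {
      writeLines(sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s",
                         r$object, r$object_beg, r$object_end, r$part_number,
                         r$component_id, r$component_beg, r$component_end,
                         r$orientation), con)
    } else {
      writeLines(sprintf("%s\t%d\t%d\t%d\tN\t%s\tscaffold\tyes\tmap",
                         r$object, r$object_beg, r$object_end, r$part_number,
                         r$component_id), con)
    }
  }
  invisible(path)
}

#' Read an AGP file
#'
#' Validates that the rows of each object tile it contiguously from base 1.
#'
#' @param path AGP file.
#' @return data.frame in the layout of [layoutToAgp()].
#' @export
readAgp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop(sprintf("AGP line %d: expected 9 columns, found %d",
                 which(nf != 9)[1], nf[nf != 9][1]))
  m <- do.call(rbind, fields)
  isW <- m[, 5] == "W"
  cb <- rep(NA_integer_, nrow(m)); cb[isW] <- as.integer(m[isW, 7])
  ce <- rep(NA_integer_, nrow(m)); ce[isW] <- as.integer(m[isW, 8])
  agp <- data.frame(object = m[, 1],
                    object_beg = as.integer(m[, 2]),
                    object_end = as.integer(m[, 3]),
                    part_number = as.integer(m[, 4]),
                    component_type = m[, 5],
                    component_id = m[, 6],
                    component_beg = cb,
                    component_end = ce,
                    orientation = ifelse(isW, m[, 9], NA))
  for (obj in unique(agp$object)) {
    sub <- agp[agp$object == obj, ]
    sub <- sub[order(sub$part_number), ]
    expected <- c(1L, utils::head(sub$object_end, -1) + 1L)
    if (!all(sub$object_beg == expected))
      stop("AGP rows do not tile object '", obj, "'")
    w <- sub[sub$component_type == "W", ]
    if (any(w$object_end - w$object_beg != w$component_end - w$component_beg))
      stop("W-row span does not equal component span in object '", obj, "'")
  }
  agp
}

#' Reconstruct object sequences from AGP rows and component sequences
#'
#' @param agp data.frame of AGP rows.
#' @param contigs DNAStringSet of components.
#' @return DNAStringSet of assembled objects, in AGP order.
#' @export
sequencesFromAgp <- function(agp, contigs) {
  out <- lapply(unique(agp$object), function(obj) {
    sub <- agp[agp$object == obj, , drop = FALSE]
    sub <- sub[order(sub$part_number), , drop = FALSE]
    parts <- lapply(seq_len(nrow(sub)), function(i) {
      r <- sub[i, ]
      if (r$component_type == "N")
        return(Biostrings::DNAString(strrep("N", as.integer(r$component_id))))
      if (!r$component_id %in% names(contigs))
        stop("component missing from sequence set: ", r$component_id)
      seg <- Biostrings::subseq(contigs[[r$component_id]],
                                r$component_beg, r$component_end)
      if (r$orientation == "-") seg <- Biostrings::reverseComplement(seg)
      seg
    })
    do.call(Biostrings::xscat, parts)
  })
  names(out) <- unique(agp$object)
  Biostrings::DNAStringSet(out)
}

#' Recover a ScaffoldLayout from AGP rows
#'
#' Inverse of [layoutToAgp()]; gap sizes are inferred from the N rows
#' (defaults used for objects without internal gaps).
#'
#' @param agp data.frame of AGP rows.
#' @param unplacedObject object id holding the unplaced pool.
#' @inheritParams ScaffoldLayout
#' @return A [ScaffoldLayout-class].
#' @export
agpToLayout <- function(agp, unplacedObject = "chrUn",
                        withinGap = 100L, unplacedGap = 1000L) {
  rows <- list(); unplaced <- character(0)
  for (obj in unique(agp$object)) {
    sub <- agp[agp$object == obj, , drop = FALSE]
    sub <- sub[order(sub$part_number), , drop = FALSE]
    gaps <- as.integer(sub$component_id[sub$component_type == "N"])
    w <- sub[sub$component_type == "W", , drop = FALSE]
    if (obj == unplacedObject) {
      unplaced <- w$component_id
      if (length(gaps) > 0) unplacedGap <- gaps[1]
    } else {
      if (length(gaps) > 0) withinGap <- gaps[1]
      rows[[length(rows) + 1L]] <- data.frame(
        linkage_group = obj, position = seq_len(nrow(w)),
        contig_id = w$component_id, orientation = w$orientation,
        score = NA_real_, n_anchors = NA_integer_)
    }
  }
  placements <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(linkage_group = character(), position = integer(),
               contig_id = character(), orientation = character(),
               score = numeric(), n_anchors = integer())
  ScaffoldLayout(placements, unplaced, withinGap, unplacedGap)
}

## ---- marker maps, anchor maps, features, variants, blocks ----

#' Read a genetic-marker map from CSV
#'
#' Expected columns: \code{marker_id, linkage_group, cM, flank_id,
#' snp_offset} and optionally \code{flank_length} (default 200 bp, the flank
#' taken around each SNP).
#'
#' @param path CSV file.
#' @return data.frame of marker records.
#' @export
readMarkerMap <- function(path) {
  mk <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "linkage_group", "cM", "flank_id", "snp_offset")
  missing <- setdiff(need, names(mk))
  if (length(missing) > 0)
    stop("marker map missing column(s): ", paste(missing, collapse = ", "))
  if (!"flank_length" %in% names(mk)) mk$flank_length <- 200L
  if (any(mk$snp_offset < 0 | mk$snp_offset >= mk$flank_length))
    stop("snp_offset must lie within [0, flank_length)")
  mk
}

#' Write / read an anchor map as CSV
#'
#' Bit-exact round trip, rows sorted by contig then contig position.
#'
#' @param map an [AnchorMap-class].
#' @param path CSV file.
#' @export
writeAnchorMap <- function(map, path) {
  a <- anchors(map)[, .ANCHOR_COLS]
  a <- a[order(a$contig_id, a$contig_pos, a$map_name, a$map_pos), ]
  utils::write.csv(a, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAnchorMap
#' @export
readAnchorMap <- function(path) {
  AnchorMap(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read feature intervals from BED (or GFF3)
#'
#' @param path BED or GFF3 file of feature intervals.
#' @param class feature class label to attach; if \code{NA}, BED \code{name}
#'   (or GFF3 \code{type}) is used.
#' @return data.frame with columns \code{chromosome, start, end, class,
#'   strand} (0-based half-open).
#' @export
readFeatures <- function(path, class = NA) {
  fmt <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
    "gff3" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  lab <- if (!is.na(class)) class
  else if (fmt == "bed" && !is.null(gr$name)) as.character(gr$name)
  else if (fmt == "gff3") as.character(gr$type)
  else "feature"
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             class = lab,
             strand = as.character(BiocGenerics::strand(gr)))
}

#' Read small variants from a minimal VCF-like table
#'
#' Accepts either a VCF (header lines ignored, columns CHROM POS ID REF ALT
#' ...) or a bare 4-column table CHROM POS REF ALT. POS is converted from
#' 1-based to the internal 0-based convention.
#'
#' @param path file.
#' @return data.frame with columns \code{chromosome, pos, ref, alt}.
#' @export
readSmallVariants <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chromosome = character(), pos = integer(),
                      ref = character(), alt = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  vcfish <- nf[1] >= 5
  if (any(nf < 4))
    stop(sprintf("variant table line %d: fewer than 4 columns",
                 which(nf < 4)[1]))
  m <- do.call(rbind, lapply(fields, function(f) f[1:max(4, min(nf))]))
  if (vcfish)
    out <- data.frame(chromosome = m[, 1], pos = as.integer(m[, 2]) - 1L,
                      ref = m[, 4], alt = m[, 5])
  else
    out <- data.frame(chromosome = m[, 1], pos = as.integer(m[, 2]) - 1L,
                      ref = m[, 3], alt = m[, 4])
  if (any(!nzchar(out$ref)) || any(!nzchar(out$alt)))
    stop("empty REF or ALT allele")
  out
}

#' Read alignment blocks from a coords-style TSV
#'
#' A headered tab-separated table with columns \code{ref_id, ref_start,
#' ref_end, query_id, query_start, query_end, strand}, 1-based inclusive on
#' disk (as whole-genome aligners print them).
#'
#' @param path TSV file.
#' @return data.frame of blocks, 0-based half-open.
#' @export
readAlignmentBlocks <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ref_id", "ref_start", "ref_end", "query_id",
            "query_start", "query_end", "strand")
  missing <- setdiff(need, names(b))
  if (length(missing) > 0)
    stop("block table missing column(s): ", paste(missing, collapse = ", "))
  b$ref_start <- b$ref_start - 1L
  b$query_start <- b$query_start - 1L
  if (any(b$ref_start >= b$ref_end)) stop("ref_start must be < ref_end")
  b
}
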