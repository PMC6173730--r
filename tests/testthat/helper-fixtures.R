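# Fixture builders: everything generated in code, nothing stored on disk.

writeTempFasta <- function(text) {
  f <- tempfile(fileext = ".fa")
  writeLines(text, f)
  f
}

writeTempLines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A hit row in the internal (0-based half-open, strand-normalized) layout.
makeHit <- function(query, subject, sstart, send, strand = "+",
                    bitscore = 100, alnLength = abs(send - sstart),
                    pident = 99, qstart = 0, qend = alnLength,
                    evalue = 1e-50) {
  data.frame(query_id = query, subject_id = subject,
             pct_identity = pident, aln_length = alnLength,
             query_start = qstart, query_end = qend,
             subject_start = sstart, subject_end = send, strand = strand,
             evalue = evalue, bitscore = bitscore)
}

makeHits <- function(...) do.call(rbind, list(...))

# Minimal gene-model table (internal convention).
makeGenes <- function(ids, chrom, start, stop = start + 1000,
                      strand = "+") {
  data.frame(gene_id = ids, isoform_id = paste0(ids, ".1"),
             chromosome = chrom, start = start, stop = stop,
             strand = strand, isoform_order = 1L)
}

# Anchor table shortcut.
makeAnchors <- function(contig, pos, group, mapPos = pos,
                        mapName = "synteny", weight = 1) {
  AnchorMap(data.frame(contig_id = contig, contig_pos = pos,
                       linkage_group = group, map_pos = mapPos,
                       map_name = mapName, weight = weight))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Collinear "+"-strand alignment block sets with random gaps, for variant
# classification tests: consecutive blocks share (ref, query, strand).
randomBlockSet <- function(nBlocks = 6, gapRange = c(-60, 60)) {
  refPos <- 0L; qPos <- 0L
  rows <- list()
  for (i in seq_len(nBlocks)) {
    len <- sample(500:2000, 1)
    rows[[i]] <- data.frame(ref_id = "hap1", ref_start = refPos,
                            ref_end = refPos + len, query_id = "hap2",
                            query_start = qPos, query_end = qPos + len,
                            strand = "+")
    gR <- sample(gapRange[1]:gapRange[2], 1)
    gQ <- sample(gapRange[1]:gapRange[2], 1)
    refPos <- refPos + len + gR
    qPos <- qPos + len + gQ
  }
  do.call(rbind, rows)
}

# Swap reference and query roles of a block set.
swapBlockRoles <- function(blocks) {
  data.frame(ref_id = blocks$query_id, ref_start = blocks$query_start,
             ref_end = blocks$query_end, query_id = blocks$ref_id,
             query_start = blocks$ref_start, query_end = blocks$ref_end,
             strand = blocks$strand)
}
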