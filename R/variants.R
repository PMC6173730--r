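## Haplotype-variation analysis: small-variant feature densities and
## classification of large between-alignment variants.

.VARIANT_CLASSES <- c("insertion", "deletion", "repeat_expansion",
                      "repeat_contraction", "tandem_expansion",
                      "tandem_contraction")

#' Classify a large variant from its signed reference and query gaps
#'
#' Between two query-order adjacent alignment blocks of the same
#' (reference, query, strand) pair, R is the signed gap on the reference and
#' Q the signed gap on the query (negative gaps are overlaps). The class
#' follows the standard between-alignment sign table: with Q > R, a
#' non-negative R is an insertion, R < 0 <= Q a repeat expansion and Q < 0 a
#' tandem expansion; with Q < R the mirror classes deletion, repeat
#' contraction and tandem contraction apply. Q = R carries no variant. The
#' variant size is |Q - R|.
#'
#' @param R signed reference gap (bp).
#' @param Q signed query gap (bp).
#' @return list with \code{class} (or NA when Q = R) and \code{size}.
#' @examples
#' classifyLargeVariant(0, 50)    # insertion, size 50
#' classifyLargeVariant(-20, 30)  # repeat_expansion, size 50
#' @export
classifyLargeVariant <- function(R, Q) {
  if (Q == R) return(list(class = NA_character_, size = 0))
  cls <- if (Q > R) {
    if (R >= 0) "insertion"
    else if (Q >= 0) "repeat_expansion"
    else "tandem_expansion"
  } else {
    if (Q >= 0) "deletion"
    else if (R >= 0) "repeat_contraction"
    else "tandem_contraction"
  }
  list(class = cls, size = abs(Q - R))
}

#' Call large variants between consecutive alignment blocks
#'
#' Blocks are grouped by (ref_id, query_id, strand) and walked in query
#' order; each adjacent pair yields signed gaps (R, Q) which are classified
#' with [classifyLargeVariant()]. A call is retained only when
#' \code{max(|R|, |Q|) > minGap} (both gap fields at or below the small
#' variant regime carry no event) and its size is within
#' \code{(0, maxSize]} — gaps between distant blocks are alignment breaks,
#' not variants.
#'
#' @param blocks data.frame from [readAlignmentBlocks()] (0-based
#'   half-open).
#' @param minGap retain only calls with \code{max(|R|, |Q|) > minGap}
#'   (default 10 bp, the boundary with the small-variant pathway).
#' @param maxSize maximum variant size (default 10000 bp).
#' @return data.frame \code{ref_id, pos, ref_gap, query_gap, size, class}.
#' @export
largeVariantsFromBlocks <- function(blocks, minGap = 10, maxSize = 10000) {
  out <- list()
  key <- paste(blocks$ref_id, blocks$query_id, blocks$strand, sep = "\r")
  for (k in unique(key)) {
    sub <- blocks[key == k, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$query_start), , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1L)) {
      b1 <- sub[i, ]; b2 <- sub[i + 1L, ]
      Q <- b2$query_start - b1$query_end
      R <- if (b1$strand == "-") b1$ref_start - b2$ref_end
      else b2$ref_start - b1$ref_end
      cl <- classifyLargeVariant(R, Q)
      if (is.na(cl$class)) next
      if (max(abs(R), abs(Q)) <= minGap) next
      if (cl$size > maxSize) next
      pos <- if (b1$strand == "-") min(b1$ref_start, b2$ref_end)
      else min(b1$ref_end, b2$ref_start)
      out[[length(out) + 1L]] <- data.frame(
        ref_id = b1$ref_id, pos = as.integer(pos), ref_gap = R,
        query_gap = Q, size = cl$size, class = cl$class)
    }
  }
  if (length(out) == 0)
    return(data.frame(ref_id = character(), pos = integer(),
                      ref_gap = numeric(), query_gap = numeric(),
                      size = numeric(), class = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize classified large variants
#'
#' @param variants data.frame with a \code{class} column, or a named vector
#'   of class counts.
#' @return named numeric vector: the six class counts plus \code{total}.
#' @examples
#' summarizeVariants(c(deletion = 5743, insertion = 6563,
#'                     repeat_contraction = 3148, repeat_expansion = 2828,
#'                     tandem_contraction = 13, tandem_expansion = 66))
#' @export
summarizeVariants <- function(variants) {
  counts <- stats::setNames(numeric(length(.VARIANT_CLASSES)),
                            .VARIANT_CLASSES)
  if (is.data.frame(variants)) {
    tb <- table(factor(variants$class, levels = .VARIANT_CLASSES))
    counts[names(tb)] <- as.numeric(tb)
  } else {
    bad <- setdiff(names(variants), .VARIANT_CLASSES)
    if (length(bad) > 0)
      stop("unknown variant class(es): ", paste(bad, collapse = ", "))
    counts[names(variants)] <- as.numeric(variants)
  }
  c(counts, total = sum(counts))
}

#' Derive strand-aware upstream regions from locus features
#'
#' The 1,000 bp 5' of each locus (upstream of the start for "+" loci, of
#' the end for "-"), clipped at chromosome edges.
#'
#' @param loci data.frame of locus features (\code{chromosome, start, end,
#'   strand}, 0-based half-open).
#' @param width upstream width (default 1000 bp).
#' @param chromLengths named chromosome lengths for edge clipping.
#' @return data.frame of intervals with \code{class = "upstream1kb"}.
#' @export
upstreamFeatures <- function(loci, width = 1000, chromLengths = NULL) {
  start <- ifelse(loci$strand == "-", loci$end, loci$start - width)
  end <- ifelse(loci$strand == "-", loci$end + width, loci$start)
  start <- pmax(start, 0)
  if (!is.null(chromLengths))
    end <- pmin(end, unname(chromLengths[loci$chromosome]))
  keep <- end > start
  data.frame(chromosome = loci$chromosome[keep], start = start[keep],
             end = end[keep], class = "upstream1kb",
             strand = loci$strand[keep])
}

#' Small-variant density per genomic feature class in fixed bins
#'
#' Variants whose REF or ALT allele exceeds \code{maxAllele} bp are excluded
#' first (those belong to the large-variant pathway). For every bin and
#' feature class, density = variants falling inside the class's intervals
#' within the bin, divided by the class bp in the bin in kb. Bins with zero
#' feature bp are dropped; bins with feature bp but no variants count as
#' zero-density bins in the per-class median.
#'
#' @param variants data.frame from [readSmallVariants()].
#' @param features data.frame of labelled intervals (\code{chromosome,
#'   start, end, class}, 0-based half-open).
#' @param chromLengths named chromosome lengths.
#' @param binSize bin width (default 1 Mb).
#' @param maxAllele small-variant allele-length cutoff (default 10 bp).
#' @return list with \code{bins} (per bin x class: \code{feature_bp,
#'   n_variants, density}) and \code{medians} (named per-class median
#'   density, variants per kb).
#' @export
smallVariantDensity <- function(variants, features, chromLengths,
                                binSize = 1e6, maxAllele = 10) {
  unknown <- setdiff(unique(features$chromosome), names(chromLengths))
  if (length(unknown) > 0)
    stop("features on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  small <- variants[nchar(variants$ref) <= maxAllele &
                      nchar(variants$alt) <= maxAllele, , drop = FALSE]
  bins <- makeWindows(chromLengths, size = binSize)
  rows <- list()
  for (cls in unique(features$class)) {
    fc <- features[features$class == cls, , drop = FALSE]
    for (chrom in unique(fc$chromosome)) {
      ir <- IRanges::reduce(IRanges::IRanges(
        start = fc$start[fc$chromosome == chrom] + 1L,
        end = fc$end[fc$chromosome == chrom]))
      vp <- small$pos[small$chromosome == chrom] + 1L
      inFeat <- vp[IRanges::countOverlaps(
        IRanges::IRanges(vp, width = 1L), ir) > 0]
      bsub <- bins[bins$chromosome == chrom, , drop = FALSE]
      for (i in seq_len(nrow(bsub))) {
        clipped <- IRanges::restrict(ir, start = bsub$start[i] + 1L,
                                     end = bsub$end[i])
        bp <- sum(IRanges::width(clipped))
        if (bp == 0) next
        nv <- sum(inFeat > bsub$start[i] & inFeat <= bsub$end[i])
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, start = bsub$start[i], end = bsub$end[i],
          class = cls, feature_bp = bp, n_variants = nv,
          density = nv / (bp / 1000))
      }
    }
  }
  binTab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chromosome = character(), start = integer(), end = integer(),
               class = character(), feature_bp = numeric(),
               n_variants = integer(), density = numeric())
  medians <- vapply(split(binTab$density, binTab$class), stats::median,
                    numeric(1))
  list(bins = binTab, medians = medians)
}
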