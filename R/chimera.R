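## Chimeric-contig detection and splitting.
##
## A chimeric contig is an assembly artifact joining sequence from two
## chromosomes. With both anchor maps pooled, such a contig shows two long
## runs of anchors labelled with different linkage groups; the contig is cut
## between the runs.

#' Detect chimeric contigs from conflicting anchor runs
#'
#' Anchors of each contig are ordered by contig position and their
#' linkage-group labels scanned as maximal runs. Runs shorter than
#' \code{chunk} are transparent: they are skipped when looking for
#' neighbours but never merge the runs around them. Every adjacent pair of
#' runs with different groups and both lengths >= \code{chunk} yields one
#' breakpoint at the midpoint (rounded down) between the last anchor of the
#' left run and the first anchor of the right run.
#'
#' @param map [AnchorMap-class] with both maps pooled.
#' @param chunk minimum anchors supporting each side (default 4).
#' @param contigLengths optional named lengths; breakpoints at 0 or beyond
#'   the contig end are discarded.
#' @return data.frame with columns \code{contig_id, position, left_group,
#'   right_group, left_support, right_support}.
#' @export
detectChimericContigs <- function(map, chunk = 4, contigLengths = NULL) {
  stopifnot(chunk >= 2)
  a <- anchors(map)
  out <- list()
  for (ctg in unique(a$contig_id)) {
    sub <- a[a$contig_id == ctg, , drop = FALSE]
    sub <- sub[order(sub$contig_pos, sub$linkage_group), , drop = FALSE]
    runs <- rle(sub$linkage_group)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    big <- which(runs$lengths >= chunk)
    if (length(big) < 2) next
    for (k in seq_len(length(big) - 1L)) {
      i <- big[k]; j <- big[k + 1L]
      if (runs$values[i] == runs$values[j]) next
      lastLeft <- sub$contig_pos[ends[i]]
      firstRight <- sub$contig_pos[starts[j]]
      pos <- (lastLeft + firstRight) %/% 2
      if (pos <= 0) next
      if (!is.null(contigLengths) && !is.na(contigLengths[ctg]) &&
          pos >= contigLengths[ctg]) next
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg, position = as.integer(pos),
        left_group = runs$values[i], right_group = runs$values[j],
        left_support = runs$lengths[i], right_support = runs$lengths[j])
    }
  }
  if (length(out) == 0)
    return(data.frame(contig_id = character(), position = integer(),
                      left_group = character(), right_group = character(),
                      left_support = integer(), right_support = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split contigs at breakpoints and remap their anchors
#'
#' A contig with k breakpoints becomes k+1 parts named
#' \code{<id>_part1 ... <id>_part<k+1>} in coordinate order; the sequence is
#' partitioned exactly and every anchor is reassigned to the part containing
#' it, with its position shifted by the part offset. Contigs without
#' breakpoints are returned unchanged under their original name.
#'
#' @param contigs DNAStringSet.
#' @param map [AnchorMap-class] (or NULL to skip anchor remapping).
#' @param breakpoints data.frame from [detectChimericContigs()].
#' @return list with elements \code{contigs} (DNAStringSet), \code{map}
#'   (remapped [AnchorMap-class] or NULL) and \code{nameMap} (data.frame
#'   \code{old, new, offset, length}).
#' @export
splitContigs <- function(contigs, map, breakpoints) {
  nmRows <- list()
  newSeqs <- list()
  for (id in names(contigs)) {
    len <- Biostrings::width(contigs[id])
    bps <- sort(breakpoints$position[breakpoints$contig_id == id])
    if (any(bps <= 0 | bps >= len))
      stop("breakpoint at 0 or at contig length for '", id, "'")
    bounds <- c(0L, as.integer(bps), as.integer(len))
    if (length(bps) == 0) {
      newSeqs[[id]] <- contigs[[id]]
      nmRows[[length(nmRows) + 1L]] <- data.frame(
        old = id, new = id, offset = 0L, length = len)
      next
    }
    for (p in seq_len(length(bounds) - 1L)) {
      nm <- sprintf("%s_part%d", id, p)
      newSeqs[[nm]] <- Biostrings::subseq(contigs[[id]],
                                          bounds[p] + 1L, bounds[p + 1L])
      nmRows[[length(nmRows) + 1L]] <- data.frame(
        old = id, new = nm, offset = bounds[p],
        length = bounds[p + 1L] - bounds[p])
    }
  }
  nameMap <- do.call(rbind, nmRows)
  rownames(nameMap) <- NULL
  outMap <- NULL
  if (!is.null(map)) {
    a <- anchors(map)
    if (nrow(a) > 0) {
      hit <- remapPositions(a$contig_id, a$contig_pos, nameMap)
      a$contig_id <- hit$new
      a$contig_pos <- hit$pos
    }
    outMap <- AnchorMap(a)
  }
  list(contigs = Biostrings::DNAStringSet(newSeqs), map = outMap,
       nameMap = nameMap)
}

#' Remap positions through a split name map
#'
#' @param ids contig ids (pre-split names).
#' @param pos 0-based positions on those contigs.
#' @param nameMap data.frame \code{old, new, offset, length} from
#'   [splitContigs()].
#' @return data.frame \code{new, pos} with part names and shifted positions.
#' @export
remapPositions <- function(ids, pos, nameMap) {
  new <- character(length(ids)); npos <- integer(length(ids))
  for (i in seq_along(ids)) {
    parts <- nameMap[nameMap$old == ids[i], , drop = FALSE]
    if (nrow(parts) == 0) { new[i] <- ids[i]; npos[i] <- pos[i]; next }
    k <- findInterval(pos[i], parts$offset)
    k <- max(1L, min(k, nrow(parts)))
    new[i] <- parts$new[k]
    npos[i] <- pos[i] - parts$offset[k]
  }
  data.frame(new = new, pos = npos)
}

# Remap a hit table onto split contigs; hits spanning a cut are dropped
# (they cannot belong to a single part).
remapHits <- function(hits, nameMap) {
  if (nrow(hits) == 0) return(hits)
  s <- remapPositions(hits$subject_id, hits$subject_start, nameMap)
  e <- remapPositions(hits$subject_id, hits$subject_end - 1L, nameMap)
  keep <- s$new == e$new
  hits <- hits[keep, , drop = FALSE]
  hits$subject_id <- s$new[keep]
  hits$subject_end <- e$pos[keep] + 1L
  hits$subject_start <- s$pos[keep]
  rownames(hits) <- NULL
  hits
}
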