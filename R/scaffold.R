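## Assigning, ordering and orienting contigs into pseudomolecules.

#' Assign each contig to a linkage group by weighted anchor majority
#'
#' Anchor counts are weighted by the per-map weights times the per-anchor
#' weight; a contig is assigned to the group with the strict majority of
#' weighted support. An exact tie between the top groups, or a contig with
#' no anchors at all, leaves the contig unassigned (it will go to the
#' unplaced pool).
#'
#' @param map [AnchorMap-class] with both maps pooled.
#' @param weights named numeric, per-map weights
#'   (default \code{c(genetic = 1, synteny = 1)}).
#' @return named character vector contig id -> linkage group (assigned
#'   contigs only).
#' @export
assignLinkageGroups <- function(map, weights = c(genetic = 1, synteny = 1)) {
  a <- anchors(map)
  if (nrow(a) == 0) return(stats::setNames(character(0), character(0)))
  w <- a$weight * unname(weights[a$map_name])
  support <- stats::aggregate(w, by = list(contig_id = a$contig_id,
                                           linkage_group = a$linkage_group),
                              FUN = sum)
  out <- character(0)
  for (ctg in unique(support$contig_id)) {
    sub <- support[support$contig_id == ctg, , drop = FALSE]
    top <- max(sub$x)
    winners <- sub$linkage_group[sub$x == top]
    if (length(winners) == 1) out[ctg] <- winners
  }
  out
}

#' Order and orient assigned contigs within their linkage groups
#'
#' Within each linkage group the two maps' positions live on incommensurable
#' scales (reference bp vs centimorgan), so each map's \code{map_pos} values
#' are first converted to normalized ranks in (0, 1). A contig's position
#' score is the weighted mean of the normalized ranks of its anchors in its
#' assigned group; contigs are sorted by ascending score, ties broken by
#' longer contig first, then lexicographic id. Orientation is the sign of
#' the weighted rank correlation between anchor positions on the contig and
#' their normalized map ranks: a contig whose anchors run against map order
#' is flipped. Zero correlation or a single anchor defaults to "+".
#'
#' The rank-consensus score orders contigs correctly whenever their anchors
#' occupy disjoint stretches of a single map, but the two maps sample the
#' chromosome at very different densities, so quantile ranks from different
#' maps are only approximately comparable. A deterministic refinement pass
#' therefore follows the initial sort: adjacent contigs are swapped while
#' the swap strictly reduces the weighted number of discordant anchor pairs,
#' counted within each map separately (where comparisons are exact). The
#' refinement terminates at an order no adjacent swap can improve.
#'
#' @param map pooled [AnchorMap-class].
#' @param assignment contig -> group, from [assignLinkageGroups()].
#' @param contigLengths named vector of contig lengths (bp); used for tie
#'   breaks and to complete the unplaced pool.
#' @param weights per-map weights.
#' @param withinGap,unplacedGap gap sizes stored on the layout (bp of N).
#' @param refine run the discordance-minimizing adjacent-swap pass
#'   (default TRUE).
#' @return A [ScaffoldLayout-class].
#' @export
orderAndOrient <- function(map, assignment, contigLengths,
                           weights = c(genetic = 1, synteny = 1),
                           withinGap = 100L, unplacedGap = 1000L,
                           refine = TRUE) {
  a <- anchors(map)
  a$eff_w <- a$weight * unname(weights[a$map_name])
  rows <- list()
  for (lg in sortGroups(unname(assignment))) {
    ctgs <- names(assignment)[assignment == lg]
    sub <- a[a$contig_id %in% ctgs & a$linkage_group == lg, , drop = FALSE]
    if (nrow(sub) == 0) next
    # per-map normalized ranks within this linkage group
    sub$nrank <- NA_real_
    for (mp in unique(sub$map_name)) {
      sel <- sub$map_name == mp
      sub$nrank[sel] <- normalizedRank(sub$map_pos[sel])
    }
    score <- vapply(ctgs, function(ctg) {
      s <- sub[sub$contig_id == ctg, ]
      if (nrow(s) == 0) return(NA_real_)
      sum(s$eff_w * s$nrank) / sum(s$eff_w)
    }, numeric(1))
    orient <- vapply(ctgs, function(ctg) {
      s <- sub[sub$contig_id == ctg, ]
      if (nrow(s) < 2) return("+")
      # rank correlation per map (ranks across maps are not comparable),
      # combined weighted by map weight and anchor support
      total <- 0
      for (mp in unique(s$map_name)) {
        sm <- s[s$map_name == mp, ]
        if (nrow(sm) < 2) next
        rho <- weightedCor(rank(sm$contig_pos, ties.method = "average"),
                           rank(sm$map_pos, ties.method = "average"),
                           sm$eff_w)
        if (!is.na(rho)) total <- total + sm$eff_w[1] * nrow(sm) * rho
      }
      if (total >= 0) "+" else "-"
    }, character(1))
    nAnch <- vapply(ctgs, function(ctg) sum(sub$contig_id == ctg), integer(1))
    keep <- !is.na(score)
    ctgs <- ctgs[keep]; score <- score[keep]
    orient <- orient[keep]; nAnch <- nAnch[keep]
    lens <- unname(contigLengths[ctgs])
    o <- order(score, -lens, ctgs)
    ordered <- ctgs[o]
    if (refine && length(ordered) > 2)
      ordered <- .refineOrder(ordered, sub)
    io <- match(ordered, ctgs)
    rows[[length(rows) + 1L]] <- data.frame(
      linkage_group = lg, position = seq_along(ordered),
      contig_id = ordered, orientation = orient[io],
      score = score[io], n_anchors = nAnch[io])
  }
  placed <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(linkage_group = character(), position = integer(),
               contig_id = character(), orientation = character(),
               score = numeric(), n_anchors = integer())
  unplaced <- setdiff(names(contigLengths), placed$contig_id)
  ScaffoldLayout(placed, unplaced, withinGap, unplacedGap)
}

# Bubble-style local search: swap adjacent contigs while the swap strictly
# lowers the weighted count of discordant anchor pairs, where a pair of
# anchors on different contigs is discordant when their map order (within
# one map) contradicts the contig order. Terminates because the weighted
# discordance strictly decreases and is bounded below.
.refineOrder <- function(ordered, sub) {
  anch <- split(sub[, c("map_name", "map_pos", "eff_w")], sub$contig_id)
  pairCost <- function(a, b) {
    # cost of placing contig a before contig b
    cost <- 0
    for (mp in intersect(unique(a$map_name), unique(b$map_name))) {
      pa <- a$map_pos[a$map_name == mp]; wa <- a$eff_w[a$map_name == mp][1]
      pb <- b$map_pos[b$map_name == mp]
      cost <- cost + wa * sum(outer(pa, pb, ">"))
    }
    cost
  }
  repeat {
    swapped <- FALSE
    for (i in seq_len(length(ordered) - 1L)) {
      a <- anch[[ordered[i]]]; b <- anch[[ordered[i + 1L]]]
      if (is.null(a) || is.null(b)) next
      if (pairCost(b, a) < pairCost(a, b)) {
        tmp <- ordered[i]; ordered[i] <- ordered[i + 1L]; ordered[i + 1L] <- tmp
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  ordered
}

#' Emit pseudomolecule sequences and AGP rows from a layout
#'
#' Each linkage group becomes one sequence: its contigs in layout order,
#' minus-oriented contigs reverse-complemented, separated by
#' \code{withinGap} Ns. All unplaced contigs are pooled into a single
#' sequence separated by \code{unplacedGap} Ns (1 kb by default, so the pool
#' can be unambiguously re-split).
#'
#' @param layout a [ScaffoldLayout-class].
#' @param contigs DNAStringSet containing every contig in the layout.
#' @param unplacedObject name for the pooled unplaced sequence.
#' @return list with \code{sequences} (DNAStringSet) and \code{agp}
#'   (data.frame of AGP rows).
#' @export
buildPseudomolecules <- function(layout, contigs, unplacedObject = "chrUn") {
  ids <- c(placements(layout)$contig_id, unplacedContigs(layout))
  missing <- setdiff(ids, names(contigs))
  if (length(missing) > 0)
    stop("contig(s) in layout missing from sequences: ",
         paste(missing, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  agp <- layoutToAgp(layout, lens, unplacedObject = unplacedObject)
  list(sequences = sequencesFromAgp(agp, contigs), agp = agp)
}

#' Assembly and placement statistics
#'
#' N50 is the largest length L such that contigs of length >= L cover at
#' least half of the assembly; the placement rate is the percent of
#' assembled bases anchored onto linkage groups, reported to two decimals.
#'
#' @param contigs DNAStringSet of all contigs.
#' @param layout a [ScaffoldLayout-class] (optional; without it only the
#'   size statistics are computed).
#' @return list of class \code{PlacementStats}: \code{total_bp,
#'   anchored_bp, placement_rate, n_contigs, n_placed, n50,
#'   chromosome_lengths}.
#' @export
assemblyStats <- function(contigs, layout = NULL) {
  if (length(contigs) == 0) stop("empty contig set")
  lens <- stats::setNames(as.numeric(Biostrings::width(contigs)),
                          names(contigs))
  total <- sum(lens)
  out <- list(total_bp = total, n_contigs = length(lens), n50 = n50(lens))
  if (!is.null(layout)) {
    p <- placements(layout)
    anchored <- sum(lens[p$contig_id])
    perChrom <- vapply(sortGroups(p$linkage_group), function(lg) {
      k <- sum(p$linkage_group == lg)
      sum(lens[p$contig_id[p$linkage_group == lg]]) +
        max(0L, k - 1L) * layout@withinGap
    }, numeric(1))
    out$anchored_bp <- anchored
    out$placement_rate <- percentOf(anchored, total, 2)
    out$n_placed <- nrow(p)
    out$chromosome_lengths <- perChrom
  }
  class(out) <- "PlacementStats"
  out
}

#' @export
print.PlacementStats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  contigs: %d  total: %s bp  N50: %s bp\n", x$n_contigs,
              format(x$total_bp, big.mark = ","),
              format(x$n50, big.mark = ",")))
  if (!is.null(x$placement_rate))
    cat(sprintf("  placed: %d contigs, %s bp (%.2f%%) on %d chromosomes\n",
                x$n_placed, format(x$anchored_bp, big.mark = ","),
                x$placement_rate, length(x$chromosome_lengths)))
  invisible(x)
}
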