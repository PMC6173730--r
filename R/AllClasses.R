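#' @import methods
NULL

.ANCHOR_COLS <- c("contig_id", "contig_pos", "linkage_group", "map_pos",
                  "map_name", "weight")

#' AnchorMap: contig-to-chromosome anchor points
#'
#' An \code{AnchorMap} holds anchor points, the atoms of evidence used to
#' assign, order and orient contigs. Each anchor ties a position on a contig
#' (0-based bp) to a position on a linkage group: reference gene-model bp for
#' the synteny map, centimorgan for the genetic map. The two maps share one
#' container and are distinguished by \code{map_name}.
#'
#' @slot anchors \code{data.frame} with columns \code{contig_id},
#'   \code{contig_pos} (0-based bp on the contig), \code{linkage_group},
#'   \code{map_pos} (bp or cM depending on the map), \code{map_name}
#'   (\code{"synteny"} or \code{"genetic"}) and \code{weight} (positive).
#'
#' @seealso [buildSyntenyAnchors()], [buildMarkerAnchors()],
#'   [assignLinkageGroups()], [orderAndOrient()]
#' @export
setClass("AnchorMap", slots = c(anchors = "data.frame"))

setValidity("AnchorMap", function(object) {
  a <- object@anchors
  missing <- setdiff(.ANCHOR_COLS, names(a))
  if (length(missing) > 0)
    return(paste("missing anchor columns:", paste(missing, collapse = ", ")))
  if (nrow(a) == 0) return(TRUE)
  if (any(a$contig_pos < 0)) return("contig_pos must be >= 0")
  if (any(a$weight <= 0)) return("anchor weight must be > 0")
  if (!all(a$map_name %in% c("synteny", "genetic")))
    return("map_name must be 'synteny' or 'genetic'")
  TRUE
})

#' Construct an AnchorMap
#'
#' @param anchors data.frame of anchor points (see the class description).
#'   Extra columns are preserved.
#' @return An [AnchorMap-class] object.
#' @export
AnchorMap <- function(anchors) {
  if (!"weight" %in% names(anchors)) anchors$weight <- 1
  anchors <- as.data.frame(anchors)
  rownames(anchors) <- NULL
  new("AnchorMap", anchors = anchors)
}

#' ScaffoldLayout: ordered, oriented contig placements
#'
#' The result of the ordering stage: for every linkage group an ordered list
#' of (contig, orientation) placements, plus the pool of unplaced contigs.
#' Gap sizes are carried along so the layout is self-contained for sequence
#' and AGP emission.
#'
#' @slot placements \code{data.frame} with columns \code{linkage_group},
#'   \code{position} (1-based rank within the group), \code{contig_id},
#'   \code{orientation} (\code{"+"}/\code{"-"}), \code{score} and
#'   \code{n_anchors}.
#' @slot unplaced character vector of contig ids not assigned to any group.
#' @slot withinGap integer, N-gap between placed contigs (bp).
#' @slot unplacedGap integer, N-gap between pooled unplaced contigs (bp).
#' @export
setClass("ScaffoldLayout",
         slots = c(placements = "data.frame",
                   unplaced = "character",
                   withinGap = "integer",
                   unplacedGap = "integer"))

setValidity("ScaffoldLayout", function(object) {
  p <- object@placements
  need <- c("linkage_group", "position", "contig_id", "orientation")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0)
    return(paste("missing placement columns:", paste(missing, collapse = ", ")))
  ids <- c(p$contig_id, object@unplaced)
  if (anyDuplicated(ids))
    return("a contig may appear only once across placements and the unplaced pool")
  if (nrow(p) > 0 && !all(p$orientation %in% c("+", "-")))
    return("orientation must be '+' or '-'")
  if (object@withinGap < 0 || object@unplacedGap < 0)
    return("gap sizes must be non-negative")
  TRUE
})

#' Construct a ScaffoldLayout
#'
#' @param placements data.frame of placements (see the class description).
#' @param unplaced character vector of unplaced contig ids.
#' @param withinGap gap (bp of N) between contigs within a pseudomolecule.
#' @param unplacedGap gap (bp of N) between contigs in the unplaced pool.
#' @return A [ScaffoldLayout-class] object.
#' @export
ScaffoldLayout <- function(placements, unplaced = character(0),
                           withinGap = 100L, unplacedGap = 1000L) {
  placements <- as.data.frame(placements)
  rownames(placements) <- NULL
  new("ScaffoldLayout", placements = placements,
      unplaced = as.character(unplaced),
      withinGap = as.integer(withinGap), unplacedGap = as.integer(unplacedGap))
}

#' @describeIn AnchorMap-class the anchor table.
#' @param x,object an \code{AnchorMap} or \code{ScaffoldLayout}.
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname AnchorMap-class
#' @export
setMethod("anchors", "AnchorMap", function(x) x@anchors)

#' @describeIn ScaffoldLayout-class the placement table.
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))

#' @rdname ScaffoldLayout-class
#' @export
setMethod("placements", "ScaffoldLayout", function(x) x@placements)

#' @describeIn ScaffoldLayout-class ids of contigs left out of all groups.
#' @export
setGeneric("unplacedContigs", function(x) standardGeneric("unplacedContigs"))

#' @rdname ScaffoldLayout-class
#' @export
setMethod("unplacedContigs", "ScaffoldLayout", function(x) x@unplaced)

setMethod("show", "AnchorMap", function(object) {
  a <- object@anchors
  cat("AnchorMap with", nrow(a), "anchor points\n")
  if (nrow(a) > 0) {
    cat("  maps:", paste(sprintf("%s=%d", names(table(a$map_name)),
                                 as.integer(table(a$map_name))),
                         collapse = ", "), "\n")
    cat("  contigs:", length(unique(a$contig_id)),
        " linkage groups:", length(unique(a$linkage_group)), "\n")
  }
  invisible(NULL)
})

setMethod("show", "ScaffoldLayout", function(object) {
  p <- object@placements
  cat("ScaffoldLayout:", nrow(p), "contigs placed on",
      length(unique(p$linkage_group)), "linkage groups;",
      length(object@unplaced), "unplaced\n")
  cat("  gaps: within =", object@withinGap, "bp, unplaced pool =",
      object@unplacedGap, "bp\n")
  invisible(NULL)
})

#' Combine anchor maps
#'
#' Concatenates the anchor tables of several maps (typically the synteny and
#' genetic maps) into one \code{AnchorMap}.
#'
#' @param ... AnchorMap objects.
#' @return An [AnchorMap-class] with the row-bound anchor tables.
#' @export
combineAnchorMaps <- function(...) {
  maps <- list(...)
  maps <- maps[!vapply(maps, is.null, logical(1))]
  stopifnot(all(vapply(maps, function(m) is(m, "AnchorMap"), logical(1))))
  tabs <- lapply(maps, anchors)
  common <- Reduce(intersect, lapply(tabs, names))
  AnchorMap(do.call(rbind, lapply(tabs, function(t) t[, common, drop = FALSE])))
}
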