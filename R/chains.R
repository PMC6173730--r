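## Collinear gene chains in rank space and NG86 synonymous rates.

#' Score a cross-genome match from its e-value
#'
#' \code{min(50, -log10(evalue))}, capped at 50 for e-value 0, the input
#' score of the chain dynamic program.
#'
#' @param evalue alignment e-value(s).
#' @return numeric score(s) > 0.
#' @export
matchScore <- function(evalue) {
  s <- ifelse(evalue <= 0, 50, pmin(50, -log10(evalue)))
  pmax(s, .Machine$double.eps)
}

# Best chain under the gapped-collinearity DP, for matches whose y may have
# been negated (inverted search). Returns indices into m and the score.
.bestChain <- function(x, y, score, maxGap, gapPenalty) {
  n <- length(x)
  o <- order(x, y)
  x <- x[o]; y <- y[o]; score <- score[o]
  S <- score
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- 0
    for (j in seq_len(i - 1L)) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx <= 0 || dy <= 0 || dx > maxGap || dy > maxGap) next
      cand <- S[j] - gapPenalty * ((dx - 1) + (dy - 1))
      if (cand > best) { best <- cand; pred[i] <- j }
    }
    S[i] <- score[i] + max(0, best)
  }
  end <- which.max(S)
  path <- integer(0)
  i <- end
  while (!is.na(i)) {
    path <- c(i, path)
    i <- pred[i]
  }
  list(idx = o[path], score = S[end])
}

#' Detect collinear chains of cross-genome matches
#'
#' A dynamic program over matches sorted by rank: a match extends a chain
#' when both rank gaps are positive and at most \code{maxGap}, paying
#' \code{gapPenalty} per skipped rank on each axis; negative-scoring
#' prefixes are dropped (local chaining). Chains are extracted one at a
#' time by descending chain score, each match belonging to at most one
#' chain; inverted chains are found by rerunning with the y ranks negated.
#' Chains with fewer than \code{minPairs} matches are discarded.
#'
#' @param matches data.frame with columns \code{x_rank, y_rank, x_gene,
#'   y_gene, score} (duplicated (x_gene, y_gene) pairs are reduced to their
#'   best score).
#' @param maxGap maximum rank gap within a chain (default 20).
#' @param minPairs minimum matches per reported chain (default 5).
#' @param gapPenalty per-rank gap penalty (default 1).
#' @return data.frame of chained matches with added \code{chain_id,
#'   orientation, chain_score}; zero rows when nothing chains.
#' @export
chainMatches <- function(matches, maxGap = 20, minPairs = 5,
                         gapPenalty = 1) {
  stopifnot(maxGap >= 1, minPairs >= 2, gapPenalty >= 0)
  empty <- data.frame(chain_id = integer(), orientation = character(),
                      chain_score = numeric(), x_rank = integer(),
                      y_rank = integer(), x_gene = character(),
                      y_gene = character(), score = numeric())
  if (nrow(matches) == 0) return(empty)
  m <- matches[order(-matches$score), , drop = FALSE]
  m <- m[!duplicated(paste(m$x_gene, m$y_gene, sep = "\r")), , drop = FALSE]
  used <- rep(FALSE, nrow(m))
  out <- list(); chainId <- 0L
  repeat {
    rem <- which(!used)
    if (length(rem) < 2) break
    fwd <- .bestChain(m$x_rank[rem], m$y_rank[rem], m$score[rem],
                      maxGap, gapPenalty)
    inv <- .bestChain(m$x_rank[rem], -m$y_rank[rem], m$score[rem],
                      maxGap, gapPenalty)
    pick <- if (inv$score > fwd$score) inv else fwd
    orientation <- if (inv$score > fwd$score) "inverted" else "forward"
    idx <- rem[pick$idx]
    used[idx] <- TRUE
    if (length(idx) < 2) next  # isolated match: consume it, keep searching
    if (length(idx) >= minPairs) {
      chainId <- chainId + 1L
      chain <- m[idx, , drop = FALSE]
      chain <- chain[order(chain$x_rank), , drop = FALSE]
      chain$chain_id <- chainId
      chain$orientation <- orientation
      chain$chain_score <- pick$score
      out[[chainId]] <- chain
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chain_id", "orientation", "chain_score", "x_rank", "y_rank",
          "x_gene", "y_gene", "score")]
}

## ---- NG86 synonymous substitution rate ----

.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.CODON_AA <- NULL

.aaOf <- function(codon) {
  if (is.null(.CODON_AA))
    utils::assignInMyNamespace(".CODON_AA", .codonTable())
  .CODON_AA[[codon]]
}

.BASES <- c("A", "C", "G", "T")

# Per-codon count of synonymous sites: at each position, the fraction of the
# three possible substitutions that preserve the amino acid (substitutions
# creating a stop codon count as nonsynonymous).
.synSites <- function(codon) {
  aa <- .aaOf(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (.aaOf(mut) != "*" && .aaOf(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

# Synonymous / nonsynonymous substitution counts between two codons,
# averaged over all substitution orderings; pathways through stop codons are
# excluded (all-blocked pairs fall back to averaging over every pathway).
.synDiffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- .permutations(pos)
  tally <- function(allowStops) {
    tot <- c(sd = 0, nd = 0); nPaths <- 0
    for (ord in paths) {
      cur <- c1; steps <- c(sd = 0, nd = 0); ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (!allowStops && .aaOf(nxt) == "*") { ok <- FALSE; break }
        if (.aaOf(nxt) == .aaOf(cur)) steps["sd"] <- steps["sd"] + 1
        else steps["nd"] <- steps["nd"] + 1
        cur <- nxt
      }
      if (ok) { tot <- tot + steps; nPaths <- nPaths + 1 }
    }
    if (nPaths == 0) return(NULL)
    tot / nPaths
  }
  res <- tally(allowStops = FALSE)
  if (is.null(res)) res <- tally(allowStops = TRUE)
  res
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Synonymous substitution rate between two coding sequences (NG86)
#'
#' Nei-Gojobori (1986) counting with the Jukes-Cantor correction: per codon,
#' synonymous site counts are averaged over the two sequences; observed
#' synonymous differences for codons differing at several positions are
#' averaged over all substitution orderings (pathways through stop codons
#' excluded). \code{Ks = -3/4 * log(1 - 4/3 * pS)} with \code{pS = Sd / S}.
#' Saturated pairs (\code{pS >= 3/4}) and pairs violating the
#' preconditions (unequal length, length not a multiple of 3, internal stop
#' codons) are flagged rather than estimated.
#'
#' @param cds1,cds2 character strings or DNAString, equal length, in frame.
#' @return list with \code{ks, pS, S, Sd, flag} (flag one of "ok",
#'   "saturated", "length_mismatch", "not_codon_aligned",
#'   "internal_stop"); \code{ks} is NA unless flag is "ok".
#' @examples
#' ksNG86("TTTAAAGGGCCC", "TTTAAAGGGCCC")$ks  # 0
#' @export
ksNG86 <- function(cds1, cds2) {
  s1 <- toupper(as.character(cds1)); s2 <- toupper(as.character(cds2))
  bad <- function(flag) list(ks = NA_real_, pS = NA_real_, S = NA_real_,
                             Sd = NA_real_, flag = flag)
  if (nchar(s1) != nchar(s2)) return(bad("length_mismatch"))
  if (nchar(s1) %% 3 != 0 || nchar(s1) == 0) return(bad("not_codon_aligned"))
  n <- nchar(s1) / 3
  codons1 <- substring(s1, 3 * seq_len(n) - 2, 3 * seq_len(n))
  codons2 <- substring(s2, 3 * seq_len(n) - 2, 3 * seq_len(n))
  internal1 <- vapply(codons1[-n], .aaOf, character(1)) == "*"
  internal2 <- vapply(codons2[-n], .aaOf, character(1)) == "*"
  if (n > 1 && (any(internal1) || any(internal2)))
    return(bad("internal_stop"))
  S <- 0; Sd <- 0
  for (i in seq_len(n)) {
    S <- S + (.synSites(codons1[i]) + .synSites(codons2[i])) / 2
    Sd <- Sd + .synDiffs(codons1[i], codons2[i])["sd"]
  }
  if (S == 0) return(bad("saturated"))
  pS <- unname(Sd / S)
  if (pS >= 3 / 4)
    return(list(ks = NA_real_, pS = pS, S = S, Sd = unname(Sd),
                flag = "saturated"))
  list(ks = -3 / 4 * log(1 - 4 / 3 * pS), pS = pS, S = S,
       Sd = unname(Sd), flag = "ok")
}

#' Compute Ks for every matched pair in a chain table
#'
#' @param chains data.frame from [chainMatches()].
#' @param cdsX,cdsY DNAStringSets (or named character vectors) of coding
#'   sequences, indexed by \code{x_gene} / \code{y_gene}.
#' @return the chain table with added \code{ks} and \code{ks_flag} columns.
#' @export
chainKs <- function(chains, cdsX, cdsY) {
  res <- lapply(seq_len(nrow(chains)), function(i) {
    x <- chains$x_gene[i]; y <- chains$y_gene[i]
    if (!x %in% names(cdsX) || !y %in% names(cdsY))
      return(list(ks = NA_real_, flag = "missing_cds"))
    k <- ksNG86(as.character(cdsX[[x]]), as.character(cdsY[[y]]))
    list(ks = k$ks, flag = k$flag)
  })
  chains$ks <- vapply(res, function(r) r$ks, numeric(1))
  chains$ks_flag <- vapply(res, function(r) r$flag, character(1))
  chains
}

#' Per-chain and global chain summaries
#'
#' @param chains data.frame from [chainMatches()], optionally with a
#'   \code{ks} column ([chainKs()]).
#' @return list with \code{per_chain} (pair count, orientation, score,
#'   median Ks over unsaturated pairs) and \code{pairs} (dotplot-ready
#'   \code{x_rank, y_rank, ks} table); both empty when no chains exist.
#' @export
chainSummary <- function(chains) {
  if (nrow(chains) == 0)
    return(list(per_chain = data.frame(chain_id = integer(),
                                       n_pairs = integer(),
                                       orientation = character(),
                                       chain_score = numeric(),
                                       median_ks = numeric()),
                pairs = data.frame(x_rank = integer(), y_rank = integer(),
                                   ks = numeric())))
  if (!"ks" %in% names(chains)) chains$ks <- NA_real_
  per <- do.call(rbind, lapply(split(chains, chains$chain_id), function(ch) {
    ksVals <- ch$ks[!is.na(ch$ks)]
    data.frame(chain_id = ch$chain_id[1], n_pairs = nrow(ch),
               orientation = ch$orientation[1],
               chain_score = ch$chain_score[1],
               median_ks = if (length(ksVals) > 0) stats::median(ksVals)
               else NA_real_)
  }))
  rownames(per) <- NULL
  list(per_chain = per,
       pairs = chains[, c("x_rank", "y_rank", "ks")])
}

#' Synteny dotplot of chained gene pairs
#'
#' @param chains data.frame from [chainMatches()] (Ks colouring if a
#'   \code{ks} column is present).
#' @return a ggplot object.
#' @export
plotSyntenyDotplot <- function(chains) {
  p <- ggplot2::ggplot(chains,
                       ggplot2::aes(x = x_rank, y = y_rank))
  if ("ks" %in% names(chains))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = ks), size = 0.8) +
      ggplot2::scale_colour_viridis_c(na.value = "grey70")
  else
    p <- p + ggplot2::geom_point(size = 0.8)
  p + ggplot2::labs(x = "gene rank, genome X", y = "gene rank, genome Y",
                    colour = "Ks") +
    ggplot2::theme_minimal()
}
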