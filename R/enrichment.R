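## Fixed-window scan for over-represented functional gene categories.

#' Tile chromosomes into fixed windows
#'
#' Each chromosome of length L yields \code{ceiling(L / size)} half-open
#' windows; the final window is truncated at L so windows tile the
#' chromosome without overlap.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 0.5 Mb).
#' @return data.frame \code{chromosome, start, end} (0-based half-open).
#' @export
makeWindows <- function(chromLengths, size = 5e5) {
  if (size <= 0) stop("window size must be positive")
  stopifnot(all(chromLengths >= 1))
  rows <- lapply(names(chromLengths), function(chrom) {
    L <- chromLengths[[chrom]]
    starts <- seq(0, L - 1, by = size)
    data.frame(chromosome = chrom, start = starts,
               end = pmin(starts + size, L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher-test enrichment of gene categories in genomic windows
#'
#' Each gene is assigned to the window containing its start. For every
#' (window, category) pair with at least one member gene, a one-sided
#' Fisher's exact test (enrichment) is run on the 2x2 table of
#' in-window/out-of-window by in-category/out-of-category gene counts, and
#' the p-values are Holm-adjusted jointly across all tested pairs.
#' A \code{two.sided} alternative (which would also flag depletion) is
#' available but not the default, as the scan targets over-representation.
#'
#' @param genes data.frame with columns \code{gene_id, chromosome, start,
#'   category}; genes with several categories appear on several rows, genes
#'   without categories may be listed with \code{category = NA} so that they
#'   still count towards the window and genome totals.
#' @param windows data.frame from [makeWindows()].
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return data.frame with one row per tested (window, category):
#'   \code{chromosome, start, end, category, k, n, K, N, p, p_adj,
#'   significant}.
#' @export
enrichWindows <- function(genes, windows, alpha = 0.05,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  geneTab <- unique(genes[, c("gene_id", "chromosome", "start")])
  if (anyDuplicated(geneTab$gene_id))
    stop("gene(s) listed with inconsistent positions")
  widx <- integer(nrow(geneTab))
  for (i in seq_len(nrow(geneTab))) {
    hit <- which(windows$chromosome == geneTab$chromosome[i] &
                   windows$start <= geneTab$start[i] &
                   geneTab$start[i] < windows$end)
    if (length(hit) != 1)
      stop("gene '", geneTab$gene_id[i], "' falls outside all windows")
    widx[i] <- hit
  }
  names(widx) <- geneTab$gene_id
  N <- nrow(geneTab)
  n <- table(factor(widx, levels = seq_len(nrow(windows))))
  cats <- genes[!is.na(genes$category), c("gene_id", "category")]
  cats <- unique(cats)
  K <- table(cats$category)
  cats$window <- widx[cats$gene_id]
  byPair <- stats::aggregate(gene_id ~ window + category, data = cats,
                             FUN = length)
  if (nrow(byPair) == 0)
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), category = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical()))
  res <- data.frame(
    chromosome = windows$chromosome[byPair$window],
    start = windows$start[byPair$window],
    end = windows$end[byPair$window],
    category = byPair$category,
    k = byPair$gene_id,
    n = as.integer(n[as.character(byPair$window)]),
    K = as.integer(K[byPair$category]),
    N = N)
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    fisherEnrichP(res$k[i], res$n[i], res$K[i], N, alternative)
  }, numeric(1))
  res$p_adj <- stats::p.adjust(res$p, method = "holm")
  res$significant <- res$p_adj <= alpha
  o <- order(res$chromosome, res$start, res$category)
  res <- res[o, ]
  rownames(res) <- NULL
  res
}

#' Fisher's exact p for one (window, category) table
#'
#' The 2x2 table is (in window & in category, in window & not, out of
#' window & in category, out & not) = (k, n-k, K-k, N-n-K+k). With
#' \code{alternative = "greater"} the p-value equals the hypergeometric
#' upper tail at k.
#'
#' @param k category genes in the window.
#' @param n genes in the window.
#' @param K category genes genome-wide.
#' @param N genes genome-wide.
#' @param alternative passed to [stats::fisher.test()].
#' @return the p-value.
#' @export
fisherEnrichP <- function(k, n, K, N, alternative = "greater") {
  tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2)
  if (any(tab < 0)) stop("inconsistent table counts")
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Significance grid of window enrichment results
#'
#' Categories on the y axis, windows along the genome on the x axis, tiles
#' coloured by adjusted-p significance bands.
#'
#' @param results data.frame from [enrichWindows()].
#' @return a ggplot object.
#' @export
plotEnrichmentGrid <- function(results) {
  results$band <- cut(results$p_adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("<= 0.001", "<= 0.01", "<= 0.05", "n.s."))
  results$window <- paste0(results$chromosome, ":",
                           results$start %/% 1000, "k")
  ggplot2::ggplot(results, ggplot2::aes(x = window, y = category,
                                        fill = band)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c("#67000d", "#ef3b2c", "#fc9272",
                                          "grey90"), drop = FALSE) +
    ggplot2::labs(x = "genomic window", y = "functional category",
                  fill = "adjusted P") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
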