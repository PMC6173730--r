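#' Percentage of a over b
#'
#' Reporting helper used for all printed rates: placement rate, completeness
#' fraction, haplotig fraction.
#'
#' @param a numerator.
#' @param b denominator (same units as \code{a}).
#' @param digits decimals to round to (default 2).
#' @return \code{round(100 * a / b, digits)}.
#' @examples
#' percentOf(324081576, 350562179)  # 92.45
#' @export
percentOf <- function(a, b, digits = 2) {
  stopifnot(is.numeric(a), is.numeric(b), b != 0)
  round(100 * a / b, digits)
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together cover at
#' least half of the total.
#'
#' @param lengths numeric vector of sequence lengths (bp), all > 0.
#' @return The N50 (bp).
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0) stop("n50 of an empty length set is undefined")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

# Weighted Pearson correlation; returns NA when either variable is constant.
weightedCor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

# Normalized ranks in (0, 1): (rank - 0.5) / n, average ties.
normalizedRank <- function(x) {
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

# Sort linkage-group ids naturally: numeric suffixes numerically, rest lexical.
sortGroups <- function(groups) {
  groups <- unique(groups)
  num <- suppressWarnings(as.numeric(sub("^\\D*", "", groups)))
  groups[order(is.na(num), num, groups)]
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
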