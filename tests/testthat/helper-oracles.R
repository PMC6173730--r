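# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# N50 by direct definition: largest L in the length set such that lengths
# >= L sum to at least half the total.
n50Oracle <- function(lengths) {
  total <- sum(lengths)
  best <- 0
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= total / 2) best <- L
  }
  best
}

# One-sided Fisher p by hypergeometric enumeration from binomial
# coefficients (no dhyper/phyper).
hyperTailOracle <- function(k, n, K, N) {
  hi <- min(n, K)
  total <- 0
  for (i in k:hi) {
    total <- total + exp(lchoose(K, i) + lchoose(N - K, n - i) -
                           lchoose(N, n))
  }
  min(1, total)
}

# Holm step-down adjustment by its definition.
holmOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (j in seq_len(m)) {
    running <- max(running, (m - j + 1) * p[o[j]])
    adj[o[j]] <- min(1, running)
  }
  adj
}

# Kendall tau by pair counting.
kendallOracle <- function(a, b) {
  n <- length(a)
  conc <- 0; disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}

## ---- exhaustive collinear-chain search ----

# All maximal-scoring chains by explicit enumeration of every valid match
# sequence (strictly increasing x and y, gaps <= D), scored as
# sum(score) - lambda * sum((dx-1)+(dy-1)). Returns the best chain's
# indices and score.
bestChainOracle <- function(x, y, score, D, lambda) {
  n <- length(x)
  best <- list(idx = integer(0), score = -Inf)
  extend <- function(path, total) {
    if (total > best$score ||
        (total == best$score && length(path) > length(best$idx))) {
      best <<- list(idx = path, score = total)
    }
    last <- path[length(path)]
    for (j in seq_len(n)) {
      if (j %in% path) next
      dx <- x[j] - x[last]; dy <- y[j] - y[last]
      if (dx <= 0 || dy <= 0 || dx > D || dy > D) next
      extend(c(path, j), total + score[j] - lambda * ((dx - 1) + (dy - 1)))
    }
  }
  for (i in seq_len(n)) extend(i, score[i])
  best
}

# Greedy chain extraction mirroring the one-to-one membership rule, driven
# entirely by the exhaustive search above (both orientations).
chainsOracle <- function(m, D, A, lambda) {
  used <- rep(FALSE, nrow(m))
  chains <- list()
  repeat {
    rem <- which(!used)
    if (length(rem) < 2) break
    fwd <- bestChainOracle(m$x_rank[rem], m$y_rank[rem], m$score[rem],
                           D, lambda)
    inv <- bestChainOracle(m$x_rank[rem], -m$y_rank[rem], m$score[rem],
                           D, lambda)
    pick <- if (inv$score > fwd$score) inv else fwd
    orientation <- if (inv$score > fwd$score) "inverted" else "forward"
    idx <- rem[pick$idx]
    used[idx] <- TRUE
    if (length(idx) >= A)
      chains[[length(chains) + 1L]] <-
        list(idx = sort(idx), orientation = orientation,
             score = pick$score)
    if (all(used)) break
  }
  chains
}

## ---- NG86 per-codon counting oracle ----

.oracleAA <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[codon])
}

# Synonymous sites of one codon, counted by looping over the 9 possible
# single-base changes.
synSitesOracle <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- .oracleAA(codon)
  count <- 0
  chars <- strsplit(codon, "")[[1]]
  for (p in 1:3) for (b in bases) {
    if (b == chars[p]) next
    mut <- chars; mut[p] <- b
    maa <- .oracleAA(paste(mut, collapse = ""))
    if (maa == aa && maa != "*") count <- count + 1
  }
  count / 3
}

# Synonymous differences between two codons, averaged over substitution
# orders; orders passing through stop codons are excluded unless all are.
synDiffOracle <- function(c1, c2) {
  chars1 <- strsplit(c1, "")[[1]]; chars2 <- strsplit(c2, "")[[1]]
  pos <- which(chars1 != chars2)
  if (length(pos) == 0) return(0)
  orders <- if (length(pos) == 1) list(pos) else {
    perms <- list()
    rec <- function(prefix, left) {
      if (length(left) == 0) { perms[[length(perms) + 1L]] <<- prefix; return() }
      for (i in seq_along(left)) rec(c(prefix, left[i]), left[-i])
    }
    rec(integer(0), pos)
    perms
  }
  walk <- function(ord, allowStop) {
    cur <- chars1; sd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- chars2[p]
      aaN <- .oracleAA(paste(nxt, collapse = ""))
      if (!allowStop && aaN == "*") return(NULL)
      if (aaN == .oracleAA(paste(cur, collapse = ""))) sd <- sd + 1
      cur <- nxt
    }
    sd
  }
  vals <- Filter(Negate(is.null), lapply(orders, walk, allowStop = FALSE))
  if (length(vals) == 0) vals <- lapply(orders, walk, allowStop = TRUE)
  mean(unlist(vals))
}

ksOracle <- function(s1, s2) {
  n <- nchar(s1) / 3
  cods1 <- substring(s1, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cods2 <- substring(s2, 3 * seq_len(n) - 2, 3 * seq_len(n))
  S <- mean(c(sum(sapply(cods1, synSitesOracle)),
              sum(sapply(cods2, synSitesOracle))))
  Sd <- sum(mapply(synDiffOracle, cods1, cods2))
  pS <- Sd / S
  if (pS >= 3 / 4) return(list(ks = NA_real_, pS = pS, S = S, Sd = Sd))
  list(ks = -3 / 4 * log(1 - 4 / 3 * pS), pS = pS, S = S, Sd = Sd)
}

# Random in-frame stop-free coding sequence.
randomCds <- function(nCodons) {
  stops <- c("TAA", "TAG", "TGA")
  all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1, paste, collapse = "")
  ok <- setdiff(all, stops)
  paste(sample(ok, nCodons, replace = TRUE), collapse = "")
}

# Mutate a CDS with random single-base changes, keeping it stop-free.
mutateCds <- function(cds, nMut) {
  chars <- strsplit(cds, "")[[1]]
  stops <- c("TAA", "TAG", "TGA")
  for (k in seq_len(nMut)) {
    repeat {
      p <- sample(length(chars), 1)
      b <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      cand <- chars; cand[p] <- b
      cod <- (p - 1) %/% 3
      codon <- paste(cand[(3 * cod + 1):(3 * cod + 3)], collapse = "")
      if (!codon %in% stops) { chars <- cand; break }
    }
  }
  paste(chars, collapse = "")
}

# A default-sized simulated dataset plus pipeline run, shared by the
# recovery tests (computed once per test run).
runSimPipeline <- function(seed, spuriousRate, anchorMissingRate = NULL,
                           ...) {
  cfg <- if (is.null(anchorMissingRate))
    simConfig(seed = seed, spuriousRate = spuriousRate, ...)
  else simConfig(seed = seed, spuriousRate = spuriousRate,
                 anchorMissingRate = anchorMissingRate, ...)
  ref <- simulateReference(cfg)
  tgt <- deriveTarget(ref, cfg)
  obs <- emitObservations(tgt, ref, cfg)
  res <- suppressWarnings(
    runScaffoldPipeline(tgt$contigs, ref$genes, obs$hits, ref$markers,
                        obs$flankHits, verbose = FALSE))
  lens <- stats::setNames(Biostrings::width(res$contigs),
                          names(res$contigs))
  ev <- evaluateRecovery(tgt$truth, res$layout, res$breakpoints, lens,
                         res$nameMap)
  list(cfg = cfg, ref = ref, tgt = tgt, obs = obs, res = res, ev = ev)
}
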