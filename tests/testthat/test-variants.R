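test_that("the sign table classifies the canonical gap combinations", {
  expect_equal(classifyLargeVariant(0, 50),
               list(class = "insertion", size = 50))
  expect_equal(classifyLargeVariant(-20, 30),
               list(class = "repeat_expansion", size = 50))
  expect_equal(classifyLargeVariant(-30, -10),
               list(class = "tandem_expansion", size = 20))
  expect_equal(classifyLargeVariant(50, 0),
               list(class = "deletion", size = 50))
  expect_equal(classifyLargeVariant(30, -20),
               list(class = "repeat_contraction", size = 50))
  expect_equal(classifyLargeVariant(-10, -30),
               list(class = "tandem_contraction", size = 20))
  expect_true(is.na(classifyLargeVariant(25, 25)$class))
})

test_that("classification is total and deterministic off the Q=R line", {
  grid <- expand.grid(R = seq(-40, 40, by = 7), Q = seq(-40, 40, by = 7))
  for (i in seq_len(nrow(grid))) {
    out <- classifyLargeVariant(grid$R[i], grid$Q[i])
    if (grid$R[i] == grid$Q[i]) {
      expect_true(is.na(out$class))
    } else {
      expect_true(out$class %in% c("insertion", "deletion",
                                   "repeat_expansion", "repeat_contraction",
                                   "tandem_expansion", "tandem_contraction"))
      expect_equal(out$size, abs(grid$Q[i] - grid$R[i]))
      # role swap (R,Q) -> (Q,R) mirrors the class
      sw <- classifyLargeVariant(grid$Q[i], grid$R[i])
      mirror <- c(insertion = "deletion", deletion = "insertion",
                  repeat_expansion = "repeat_contraction",
                  repeat_contraction = "repeat_expansion",
                  tandem_expansion = "tandem_contraction",
                  tandem_contraction = "tandem_expansion")
      expect_equal(sw$class, unname(mirror[out$class]))
    }
  }
})

test_that("block walking applies the retention filter on absolute gaps", {
  blocks <- data.frame(ref_id = "h1",
                       ref_start = c(0, 1010, 2000),
                       ref_end = c(1000, 2000, 3000),
                       query_id = "h2",
                       query_start = c(0, 1060, 2055),
                       query_end = c(1000, 2050, 3055),
                       strand = "+")
  v <- largeVariantsFromBlocks(blocks)
  # first junction: R=10, Q=60 -> insertion of 50; second: R=0, Q=5 -> below
  expect_equal(nrow(v), 1)
  expect_equal(v$class, "insertion")
  expect_equal(v$size, 50)
})

test_that("oversized gaps are treated as alignment breaks, not variants", {
  blocks <- data.frame(ref_id = "h1", ref_start = c(0, 50000),
                       ref_end = c(1000, 51000), query_id = "h2",
                       query_start = c(0, 1100), query_end = c(1000, 2100),
                       strand = "+")
  expect_equal(nrow(largeVariantsFromBlocks(blocks)), 0)
})

test_that("variant summaries add the printed class counts to the total", {
  counts <- c(deletion = 5743, insertion = 6563,
              repeat_contraction = 3148, repeat_expansion = 2828,
              tandem_contraction = 13, tandem_expansion = 66)
  s <- summarizeVariants(counts)
  expect_equal(unname(s["total"]), 18361)
  empty <- summarizeVariants(data.frame(class = character()))
  expect_equal(unname(empty["total"]), 0)
  expect_length(empty, 7)
})

test_that("swapping haplotype roles mirrors every class count", {
  set.seed(61)
  mirror <- c(insertion = "deletion", deletion = "insertion",
              repeat_expansion = "repeat_contraction",
              repeat_contraction = "repeat_expansion",
              tandem_expansion = "tandem_contraction",
              tandem_contraction = "tandem_expansion")
  for (rep in 1:100) {
    blocks <- randomBlockSet(nBlocks = sample(3:8, 1))
    fwd <- summarizeVariants(largeVariantsFromBlocks(blocks))
    rev <- summarizeVariants(largeVariantsFromBlocks(swapBlockRoles(blocks)))
    for (cls in names(mirror))
      expect_equal(unname(fwd[cls]), unname(rev[mirror[cls]]))
    expect_equal(unname(fwd["total"]), unname(rev["total"]))
  }
})

test_that("allele-length filtering separates the small and large regimes", {
  v <- data.frame(chromosome = "chr1", pos = c(100L, 200L, 300L),
                  ref = c("A", strrep("A", 11), "AC"),
                  alt = c("T", "A", strrep("T", 11)))
  feats <- data.frame(chromosome = "chr1", start = 0L, end = 1000L,
                      class = "CDS", strand = "+")
  d <- smallVariantDensity(v, feats, c(chr1 = 1000L))
  expect_equal(d$bins$n_variants, 1L)  # only the 1-bp variant counts
})

test_that("densities are per kb of feature space within each bin", {
  v <- data.frame(chromosome = "chr1", pos = c(10L, 20L, 500L, 600L, 700L),
                  ref = "A", alt = "T")
  feats <- data.frame(chromosome = "chr1",
                      start = c(0L, 1500L), end = c(1000L, 3000L),
                      class = "CDS", strand = "+")
  d <- smallVariantDensity(v, feats, c(chr1 = 3000L), binSize = 3000)
  expect_equal(d$bins$feature_bp, 2500)
  expect_equal(d$bins$density, 5 / 2.5)
})

test_that("zero-variant bins still enter the median", {
  v <- data.frame(chromosome = "chr1", pos = 100L, ref = "A", alt = "T")
  feats <- data.frame(chromosome = "chr1", start = c(0L, 1000L, 2000L),
                      end = c(500L, 1500L, 2500L), class = "CDS",
                      strand = "+")
  d <- smallVariantDensity(v, feats, c(chr1 = 3000L), binSize = 1000)
  expect_equal(nrow(d$bins), 3)
  expect_equal(sum(d$bins$n_variants == 0), 2)
  expect_equal(unname(d$medians["CDS"]), 0)
})

test_that("features on unknown chromosomes are an error", {
  v <- data.frame(chromosome = "chr1", pos = 1L, ref = "A", alt = "T")
  feats <- data.frame(chromosome = "chrX", start = 0L, end = 10L,
                      class = "CDS", strand = "+")
  expect_error(smallVariantDensity(v, feats, c(chr1 = 100L)), "unknown")
})

test_that("upstream regions are strand-aware and edge-clipped", {
  loci <- data.frame(chromosome = "chr1", start = c(500L, 2000L),
                     end = c(1500L, 3000L), strand = c("+", "-"))
  up <- upstreamFeatures(loci, width = 1000, chromLengths = c(chr1 = 3500L))
  expect_equal(up$start, c(0L, 3000L))
  expect_equal(up$end, c(500L, 3500L))  # clipped below and above
  expect_equal(unique(up$class), "upstream1kb")
})

test_that("density is invariant under joint scaling of features and variants", {
  set.seed(62)
  pos <- sort(sample(0:999, 20))
  v1 <- data.frame(chromosome = "chr1", pos = pos, ref = "A", alt = "T")
  f1 <- data.frame(chromosome = "chr1", start = 0L, end = 1000L,
                   class = "CDS", strand = "+")
  d1 <- smallVariantDensity(v1, f1, c(chr1 = 1000L), binSize = 1000)
  # duplicate the feature space and the variants on a second chromosome
  v2 <- rbind(v1, transform(v1, chromosome = "chr2"))
  f2 <- rbind(f1, transform(f1, chromosome = "chr2"))
  d2 <- smallVariantDensity(v2, f2, c(chr1 = 1000L, chr2 = 1000L),
                            binSize = 1000)
  expect_equal(unname(d2$medians["CDS"]), unname(d1$medians["CDS"]))
})
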