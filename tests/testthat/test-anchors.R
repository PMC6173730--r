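test_that("reference genes are ranked per chromosome with id tie-breaks", {
  g <- makeGenes(c("g1", "g2", "g3"), "chr1", c(10, 5, 20), c(12, 7, 22))
  r <- rankReferenceGenes(g)
  expect_equal(r$rank[match(c("g2", "g1", "g3"), r$gene_id)], c(1L, 2L, 3L))

  tie <- makeGenes(c("gB", "gA"), "chr1", c(5, 5), c(9, 9))
  r <- rankReferenceGenes(tie)
  expect_equal(r$rank[r$gene_id == "gA"], 1L)

  two <- makeGenes(c("a1", "a2", "b1"), c("chr1", "chr1", "chr2"),
                   c(10, 20, 5))
  r <- rankReferenceGenes(two)
  expect_equal(sort(r$rank[r$chromosome == "chr1"]), c(1L, 2L))
  expect_equal(r$rank[r$chromosome == "chr2"], 1L)
})

test_that("best-hit selection maximizes bitscore with documented tie-breaks", {
  h <- makeHits(makeHit("g1.1", "cA", 0, 300, bitscore = 500),
                makeHit("g1.1", "cB", 0, 300, bitscore = 450))
  expect_equal(selectBestHits(h)$subject_id, "cA")

  h <- makeHits(makeHit("g1.1", "cA", 0, 300, bitscore = 500,
                        alnLength = 300),
                makeHit("g1.1", "cB", 0, 250, bitscore = 500,
                        alnLength = 250))
  expect_equal(selectBestHits(h)$aln_length, 300L)

  h <- makeHits(makeHit("g1.1", "cB", 0, 100, bitscore = 10,
                        alnLength = 100),
                makeHit("g1.1", "cA", 0, 100, bitscore = 10,
                        alnLength = 100))
  expect_equal(selectBestHits(h)$subject_id, "cA")

  # a gene with no hits is simply absent
  expect_false("g9.1" %in% selectBestHits(h)$query_id)
})

test_that("run-length filtering removes isolated foreign-chromosome hits", {
  genes <- makeGenes(sprintf("g%d", 1:5),
                     c("chr1", "chr1", "chr5", "chr1", "chr1"),
                     seq(1000, 5000, by = 1000))
  hits <- do.call(rbind, lapply(1:5, function(i)
    makeHit(sprintf("g%d.1", i), "ctg", i * 1000, i * 1000 + 500)))
  out <- filterSpuriousRuns(hits, genes)
  expect_equal(out$query_id, sprintf("g%d.1", c(1, 2, 4, 5)))
})

test_that("contigs below the hit threshold are never filtered", {
  genes <- makeGenes(c("g1", "g2"), c("chr1", "chr5"), c(1000, 2000))
  hits <- makeHits(makeHit("g1.1", "ctg", 100, 600),
                   makeHit("g2.1", "ctg", 1100, 1600))
  expect_equal(nrow(filterSpuriousRuns(hits, genes)), 2)
})

test_that("two isolated runs flanking a longer run are both removed", {
  genes <- makeGenes(sprintf("g%d", 1:4),
                     c("chr1", "chr5", "chr5", "chr1"),
                     seq(1000, 4000, by = 1000))
  hits <- do.call(rbind, lapply(1:4, function(i)
    makeHit(sprintf("g%d.1", i), "ctg", i * 1000, i * 1000 + 500)))
  out <- filterSpuriousRuns(hits, genes)
  expect_equal(out$query_id, c("g2.1", "g3.1"))
})

test_that("run filtering yields a subsequence and respects the threshold", {
  set.seed(31)
  for (rep in 1:20) {
    nGenes <- sample(3:30, 1)
    genes <- makeGenes(sprintf("g%d", seq_len(nGenes)),
                       sample(paste0("chr", 1:3), nGenes, replace = TRUE),
                       seq_len(nGenes) * 1000)
    hits <- do.call(rbind, lapply(seq_len(nGenes), function(i)
      makeHit(sprintf("g%d.1", i),
              sample(c("ctgA", "ctgB"), 1), i * 500, i * 500 + 400)))
    out <- filterSpuriousRuns(hits, genes)
    # subsequence: original order preserved, no duplication
    expect_true(all(match(out$query_id, hits$query_id) ==
                      sort(match(out$query_id, hits$query_id))))
    expect_lte(nrow(out), nrow(hits))
    for (ctg in unique(hits$subject_id)) {
      if (sum(hits$subject_id == ctg) < 3)
        expect_equal(sum(out$subject_id == ctg),
                     sum(hits$subject_id == ctg))
    }
  }
})

test_that("synteny anchors: one per hit, two for single-hit contigs", {
  genes <- makeGenes(sprintf("g%d", 1:4), "chr1",
                     seq(1000, 4000, by = 1000))
  multi <- do.call(rbind, lapply(1:3, function(i)
    makeHit(sprintf("g%d.1", i), "ctgM", i * 2000, i * 2000 + 900)))
  single <- makeHit("g4.1", "ctgS", 500, 1400)
  a <- anchors(buildSyntenyAnchors(rbind(multi, single), genes))
  expect_equal(sum(a$contig_id == "ctgM"), 3)
  aS <- a[a$contig_id == "ctgS", ]
  expect_equal(nrow(aS), 2)
  expect_length(unique(aS$map_pos), 2)
  expect_setequal(aS$map_pos, c(4000, 5000))  # gene start and stop
})

test_that("minus-strand single hits invert the anchor pair's contig order", {
  genes <- makeGenes("g1", "chr1", 1000, 2000)
  plus <- anchors(buildSyntenyAnchors(
    makeHit("g1.1", "ctg", 500, 1400, strand = "+"), genes))
  minus <- anchors(buildSyntenyAnchors(
    makeHit("g1.1", "ctg", 500, 1400, strand = "-"), genes))
  # on "+" the gene-start anchor sits left of the gene-stop anchor
  expect_lt(plus$contig_pos[plus$map_pos == 1000],
            plus$contig_pos[plus$map_pos == 2000])
  expect_gt(minus$contig_pos[minus$map_pos == 1000],
            minus$contig_pos[minus$map_pos == 2000])
})

test_that("synteny anchors reject hits to unknown genes", {
  genes <- makeGenes("g1", "chr1", 1000)
  expect_error(buildSyntenyAnchors(makeHit("gX.1", "ctg", 0, 900), genes),
               "absent")
})

test_that("marker anchors place the SNP, not the flank", {
  mk <- data.frame(marker_id = "m1", linkage_group = "chr1", cM = 12.5,
                   flank_id = "m1_flank", snp_offset = 100L,
                   flank_length = 200L)
  hit <- makeHit("m1_flank", "ctg", 1000, 1200, bitscore = 400,
                 qstart = 0, qend = 200)
  a <- anchors(buildMarkerAnchors(hit, mk))
  expect_equal(a$contig_pos, 1100L)
  expect_equal(a$map_pos, 12.5)
  expect_equal(a$map_name, "genetic")

  # minus strand mirrors the offset from the other end
  aM <- anchors(buildMarkerAnchors(
    makeHit("m1_flank", "ctg", 1000, 1200, strand = "-", bitscore = 400,
            qstart = 0, qend = 200), mk))
  expect_equal(aM$contig_pos, 1099L)
})

test_that("multi-mapping and unaligned markers are dropped and counted", {
  mk <- data.frame(marker_id = c("m1", "m2"), linkage_group = "chr1",
                   cM = c(1, 2), flank_id = c("m1_flank", "m2_flank"),
                   snp_offset = 100L, flank_length = 200L)
  hits <- makeHits(makeHit("m1_flank", "ctgA", 0, 200, bitscore = 300),
                   makeHit("m1_flank", "ctgB", 0, 200, bitscore = 300))
  m <- buildMarkerAnchors(hits, mk)
  expect_equal(nrow(anchors(m)), 0)
  rep <- attr(m, "report")
  expect_equal(unname(rep["multimapping"]), 1L)
  expect_equal(unname(rep["unaligned"]), 1L)
})

test_that("with zero noise every anchor points at its true chromosome", {
  cfg <- simConfig(seed = 1, spuriousRate = 0, anchorMissingRate = 0)
  ref <- simulateReference(cfg)
  tgt <- deriveTarget(ref, cfg)
  obs <- emitObservations(tgt, ref, cfg)
  best <- selectBestHits(obs$hits)
  filtered <- filterSpuriousRuns(best, ref$genes)
  a <- anchors(buildSyntenyAnchors(filtered, ref$genes))
  pieces <- tgt$truth$pieces
  for (ctg in unique(a$contig_id)) {
    trueChroms <- pieces$chrom[pieces$contig_id == ctg]
    expect_true(all(a$linkage_group[a$contig_id == ctg] %in% trueChroms))
  }
})
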