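test_that("FASTA parsing preserves order, concatenates wraps, folds case", {
  f <- writeTempFasta(c(">c1", "ACGT"))
  s <- readContigs(f)
  expect_equal(names(s), "c1")
  expect_equal(as.character(s[[1]]), "ACGT")

  f <- writeTempFasta(c(">c1", "AC", "gt", ">c2", "A"))
  s <- readContigs(f)
  expect_equal(unname(Biostrings::width(s)), c(4L, 1L))
  expect_equal(as.character(s[["c1"]]), "ACGT")

  f <- writeTempFasta(character(0))
  expect_length(readContigs(f), 0)
})

test_that("FASTA parsing rejects duplicate ids and empty bodies", {
  f <- writeTempFasta(c(">c1", "ACGT", ">c1", "GG"))
  expect_error(readContigs(f), "duplicate")
  f <- writeTempFasta(c(">c1", "", ">c2", "AA"))
  expect_error(readContigs(f), "empty")
})

test_that("FASTA write/read round trip is identity on id and sequence", {
  set.seed(11)
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(1:5, function(i) randomDna(sample(10:200, 1)),
                    character(1)), paste0("ctg", 1:5)))
  f <- tempfile(fileext = ".fa")
  writeContigs(seqs, f)
  back <- readContigs(f)
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), as.character(seqs))
})

test_that("tab12 hits normalize minus-strand subject coordinates", {
  line <- paste(c("g1", "c1", "98.5", "300", "3", "1", "1", "300",
                  "5299", "5000", "1e-100", "512.3"), collapse = "\t")
  h <- readHits(writeTempLines(line, ".tsv"))
  expect_equal(h$strand, "-")
  # normalized interval covers bases 5000..5299 (1-based), kept as min/max
  expect_equal(h$subject_start, 4999L)
  expect_equal(h$subject_end, 5299L)
  expect_equal(h$bitscore, 512.3)
  expect_type(h$bitscore, "double")
})

test_that("hit normalization preserves the subject coordinate extremes", {
  set.seed(21)
  lines <- vapply(1:20, function(i) {
    a <- sample(1e5, 1); b <- a + sample(50:500, 1)
    pair <- if (runif(1) < 0.5) c(a, b) else c(b, a)
    paste(c(sprintf("g%d", i), "ctg", "99", b - a + 1, "0", "0", "1",
            b - a + 1, pair[1], pair[2], "1e-50", "100"), collapse = "\t")
  }, character(1))
  h <- readHits(writeTempLines(lines, ".tsv"))
  expect_true(all(h$subject_start < h$subject_end))
  raw <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(h$subject_start + 1L,
               pmin(as.integer(raw[, 9]), as.integer(raw[, 10])))
  expect_equal(h$subject_end,
               pmax(as.integer(raw[, 9]), as.integer(raw[, 10])))
})

test_that("malformed hit rows are reported with their line number", {
  lines <- c(paste(rep("x", 12), collapse = "\t"),
             paste(rep("x", 11), collapse = "\t"))
  lines[1] <- paste(c("g", "c", "99", "100", "0", "0", "1", "100", "1",
                      "100", "1e-5", "50"), collapse = "\t")
  expect_error(readHits(writeTempLines(lines, ".tsv")), "line 2")
})

test_that("PAF dialect maps fields onto the common hit layout", {
  line <- paste(c("q1", "1000", "10", "510", "-", "t1", "9000", "200",
                  "700", "480", "500", "60"), collapse = "\t")
  h <- readHits(writeTempLines(line, ".paf"), dialect = "paf")
  expect_equal(h$subject_id, "t1")
  expect_equal(h$subject_start, 200L)
  expect_equal(h$strand, "-")
  expect_equal(h$pct_identity, 96)
})

test_that("gene model parsing keeps the first isoform and converts coordinates", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
           "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=g1.1;Parent=g1",
           "chr1\tsrc\tmRNA\t101\t190\t.\t+\t.\tID=g1.2;Parent=g1",
           "chr2\tsrc\tgene\t501\t900\t.\t-\t.\tID=g2",
           "chr2\tsrc\tmRNA\t501\t900\t.\t-\t.\tID=g2.1;Parent=g2")
  g <- readGeneModels(writeTempLines(gff, ".gff3"))
  expect_equal(nrow(g), 2)
  expect_equal(g$isoform_id[g$gene_id == "g1"], "g1.1")
  expect_equal(g$start[g$gene_id == "g1"], 100L)
  expect_equal(g$stop[g$gene_id == "g1"], 200L)
  expect_setequal(g$chromosome, c("chr1", "chr2"))
})

test_that("gene model parsing rejects orphan mRNAs", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
           "chr1\tsrc\tmRNA\t301\t400\t.\t+\t.\tID=gX.1;Parent=gX")
  expect_error(readGeneModels(writeTempLines(gff, ".gff3")),
               "no parent gene")
})

test_that("gene models written as GFF3 read back identically", {
  genes <- makeGenes(c("gA", "gB"), c("chr1", "chr2"), c(1000, 5000))
  f <- tempfile(fileext = ".gff3")
  writeGeneModels(genes, f)
  back <- readGeneModels(f)
  expect_equal(back[order(back$gene_id), names(genes)],
               genes[order(genes$gene_id), ], ignore_attr = TRUE)
})

test_that("AGP rows tile objects and round-trip through files", {
  layout <- ScaffoldLayout(
    data.frame(linkage_group = "chr1", position = 1:2,
               contig_id = c("c1", "c2"), orientation = c("+", "-"),
               score = c(0.1, 0.9), n_anchors = c(3L, 3L)),
    unplaced = character(0), withinGap = 100L)
  agp <- layoutToAgp(layout, c(c1 = 100L, c2 = 100L))
  expect_equal(agp$component_type, c("W", "N", "W"))
  expect_equal(agp$object_beg, c(1L, 101L, 201L))
  expect_equal(agp$object_end, c(100L, 200L, 300L))

  f1 <- tempfile(fileext = ".agp")
  writeAgp(agp, f1)
  back <- readAgp(f1)
  f2 <- tempfile(fileext = ".agp")
  writeAgp(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  lay2 <- agpToLayout(back)
  expect_equal(placements(lay2)$contig_id, c("c1", "c2"))
  expect_equal(placements(lay2)$orientation, c("+", "-"))
})

test_that("sequence reconstruction from AGP reverse-complements minus rows", {
  contigs <- Biostrings::DNAStringSet(c(c1 = "AAAACCCC", c2 = "ACGT"))
  layout <- ScaffoldLayout(
    data.frame(linkage_group = "chr1", position = 1:2,
               contig_id = c("c1", "c2"), orientation = c("+", "-"),
               score = c(0, 1), n_anchors = c(1L, 1L)),
    withinGap = 2L)
  agp <- layoutToAgp(layout, c(c1 = 8L, c2 = 4L))
  seqs <- sequencesFromAgp(agp, contigs)
  expect_equal(as.character(seqs[["chr1"]]), "AAAACCCCNNACGT")
})

test_that("non-tiling AGP rows are rejected", {
  lines <- c("##agp-version\t2.1",
             "chr1\t1\t100\t1\tW\tc1\t1\t100\t+",
             "chr1\t150\t250\t2\tW\tc2\t1\t101\t+")
  expect_error(readAgp(writeTempLines(lines, ".agp")), "tile")
})

test_that("small-variant tables parse in both minimal and VCF layouts", {
  vcf <- c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT",
           "chr1\t100\t.\tA\tT", "chr1\t200\t.\tAC\tA")
  v <- readSmallVariants(writeTempLines(vcf, ".vcf"))
  expect_equal(v$pos, c(99L, 199L))
  expect_equal(v$alt, c("T", "A"))

  min4 <- c("chr1\t100\tA\tT")
  v2 <- readSmallVariants(writeTempLines(min4, ".tsv"))
  expect_equal(v2$ref, "A")
})

test_that("marker maps validate the SNP offset against the flank", {
  csv <- c("marker_id,linkage_group,cM,flank_id,snp_offset",
           "m1,chr1,10.5,m1_flank,100")
  mk <- readMarkerMap(writeTempLines(csv, ".csv"))
  expect_equal(mk$flank_length, 200L)
  bad <- c("marker_id,linkage_group,cM,flank_id,snp_offset,flank_length",
           "m1,chr1,10.5,m1_flank,250,200")
  expect_error(readMarkerMap(writeTempLines(bad, ".csv")), "snp_offset")
})
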