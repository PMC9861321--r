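test_that("superfamily classification handles precedence, prefixes and junk", {
  expect_equal(classify_superfamily("LTR/ERVL-MaLR"), "ERVL-MaLR")
  expect_equal(classify_superfamily("LTR/ERVL"), "ERVL")
  expect_equal(classify_superfamily("LTR/ERVK"), "ERVK")
  expect_equal(classify_superfamily("LTR/ERV1"), "ERV1")
  expect_equal(classify_superfamily("LTR/Gypsy"), "Gypsy")
  expect_equal(classify_superfamily("ltr/ervl-malr"), "ERVL-MaLR")
  expect_equal(classify_superfamily(""), "unclassified")
  expect_equal(classify_superfamily("LINE/L1"), "unclassified")
  # total function over arbitrary strings: always one of the six bins
  set.seed(11)
  junk <- replicate(200, paste(sample(c(LETTERS, "/", "-", ""), 8, TRUE),
                               collapse = ""))
  out <- classify_superfamily(junk)
  expect_true(all(out %in% c("ERV1", "ERVL", "ERVK", "Gypsy", "ERVL-MaLR",
                             "unclassified")))
})

test_that("GTF genes convert 1-based inclusive to 0-based half-open", {
  path <- write_tmp(gtf_lines(), ".gtf")
  genes <- read_gene_annotation(path, "gtf")
  g1 <- genes[genes$gene_id == "G1", ]
  expect_equal(g1$start, 1000)
  expect_equal(g1$end, 2000)
  expect_equal(g1$strand, "+")
  # Ensembl-style bare chromosome name unified to UCSC dialect
  g2 <- genes[genes$gene_id == "G2", ]
  expect_equal(g2$chrom, "chr2")
  expect_equal(c(g2$start, g2$end), c(500, 900))
})

test_that("GTF without gene lines uses the min/max span per gene_id", {
  path <- write_tmp(gtf_exons_only(), ".gtf")
  genes <- read_gene_annotation(path, "gtf")
  expect_equal(nrow(genes), 1L)
  expect_equal(genes$start, 1000)
  expect_equal(genes$end, 2000)
})

test_that("BED genes are read as-is and empty files warn", {
  path <- write_tmp("chr2\t500\t900\tG2\t0\t-", ".bed")
  genes <- read_gene_annotation(path, "bed")
  expect_equal(genes$gene_id, "G2")
  expect_equal(c(genes$start, genes$end), c(500, 900))
  expect_equal(genes$strand, "-")
  empty <- write_tmp(character(0), ".bed")
  expect_warning(res <- read_gene_annotation(empty, "bed"), "empty")
  expect_equal(nrow(res), 0L)
})

test_that("RepeatMasker tables parse with strand C and family mapping", {
  path <- write_tmp(rmsk_lines(), ".out")
  expect_warning(hervs <- read_herv_annotation(path, "rmsk_out"), "non-LTR")
  expect_equal(nrow(hervs), 3L)
  the1b <- hervs[grepl("THE1B", hervs$locus_id), ]
  expect_equal(the1b$superfamily, "ERVL-MaLR")
  expect_equal(c(the1b$start, the1b$end), c(1000, 1600))
  mer <- hervs[grepl("MER41B", hervs$locus_id), ]
  expect_equal(mer$strand, "-")
  expect_equal(mer$superfamily, "ERV1")
  l1 <- hervs[grepl("L1MB7", hervs$locus_id), ]
  expect_equal(l1$superfamily, "unclassified")
})

test_that("BED round-trip preserves intervals, strands and families", {
  set.seed(3)
  hervs <- data.frame(
    locus_id = paste0("H", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, TRUE),
    start = s <- sample.int(1e5, 20),
    end = s + sample(100:5000, 20, TRUE),
    strand = sample(c("+", "-"), 20, TRUE),
    family_name = sample(c("LTR/ERV1", "LTR/ERVL-MaLR", "LTR/Gypsy"), 20, TRUE),
    stringsAsFactors = FALSE)
  hervs$superfamily <- classify_superfamily(hervs$family_name)
  path <- tempfile(fileext = ".bed")
  write_bed(hervs, path)
  back <- read_herv_annotation(path, "bed")
  back <- back[match(hervs$locus_id, back$locus_id), ]
  expect_equal(back$start, hervs$start)
  expect_equal(back$end, hervs$end)
  expect_equal(back$strand, hervs$strand)
  expect_equal(back$family_name, hervs$family_name)
  expect_equal(back$superfamily, hervs$superfamily)
})

test_that("count matrix reading validates design and entries", {
  path <- write_tmp(c("feature_id\ts1\ts2\ts3\ts4",
                      "G1\t10\t20\t5\t6",
                      "G2\t0\t1\t2\t3",
                      "H1\t7\t8\t9\t10"), ".tsv")
  design <- c(s1 = "treated", s2 = "treated", s3 = "control", s4 = "control")
  cm <- read_counts(path, design)
  expect_s3_class(cm, "count_matrix")
  expect_equal(dim(cm$counts), c(3L, 4L))
  expect_equal(unname(cm$condition["s3"]), "control")
  expect_error(read_counts(path, c(design, s9 = "treated")), "s9")
  neg <- write_tmp(c("feature_id\ts1\ts2", "G1\t-1\t2"), ".tsv")
  expect_error(read_counts(neg, c(s1 = "a", s2 = "b")), "negative")
  frac <- write_tmp(c("feature_id\ts1\ts2", "G1\t1.5\t2"), ".tsv")
  expect_error(read_counts(frac, c(s1 = "a", s2 = "b")), "non-integer")
})

test_that("genome_annotation enforces container invariants", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                      start = c(0, 100), end = c(50, 200), strand = "+",
                      gene_name = NA_character_, stringsAsFactors = FALSE)
  hervs <- data.frame(locus_id = "H1", chrom = "chr1", start = 10, end = 20,
                      strand = "-", family_name = "LTR/ERV1",
                      superfamily = "ERV1", stringsAsFactors = FALSE)
  ann <- genome_annotation(c(chr1 = 1000), genes, hervs)
  expect_s3_class(ann, "genome_annotation")
  expect_error(genome_annotation(c(chr1 = 150), genes, hervs), "beyond")
  expect_error(genome_annotation(c(chr1 = 1000), rbind(genes, genes[1, ]),
                                 hervs), "duplicate")
  bad <- transform(hervs, chrom = "chrZ")
  expect_error(genome_annotation(c(chr1 = 1000), genes, bad), "unknown")
})
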