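test_that("interval distance: gap, overlap, trans-chromosomal", {
  a <- genomic_interval("chr1", 1000, 2000, "+")
  expect_equal(interval_distance(a, genomic_interval("chr1", 2500, 3000)), 500)
  expect_equal(interval_distance(a, genomic_interval("chr1", 1500, 1800)), 0)
  expect_true(is.na(interval_distance(a, genomic_interval("chr2", 1000, 2000))))
})

test_that("pattern classification covers the four combinations, rejects ns", {
  expect_equal(classify_pattern("up", "up"), "both_up")
  expect_equal(classify_pattern("down", "up"), "herv_down_gene_up")
  expect_equal(classify_pattern("up", "down"), "herv_up_gene_down")
  expect_equal(classify_pattern("down", "down"), "both_down")
  expect_error(classify_pattern("ns", "up"), "up.*down|'up' or 'down'")
})

make_toy <- function() {
  hervs <- data.frame(locus_id = "H1", chrom = "chr1", start = 200000,
                      end = 201000, strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("Gnear", "Gfar", "Gminus", "Gout"),
    chrom = "chr1",
    start = c(211000, 291000, 195000, 301001),
    end = c(212000, 292000, 196000, 302000),
    strand = c("+", "+", "-", "+"),
    gene_name = NA_character_, stringsAsFactors = FALSE)
  list(hervs = hervs, genes = genes,
       herv_de = make_de("H1", 2, 0.001),
       gene_de = make_de(genes$gene_id, c(2, 2, 2, 2), rep(0.001, 4)))
}

test_that("pairing filters strand and applies the window inclusively", {
  toy <- make_toy()
  p <- find_pairs(toy$hervs, toy$genes, toy$herv_de, toy$gene_de,
                  window = 100000)
  # Gnear at 10 kb and Gfar at 90 kb pair; the minus-strand gene does not;
  # Gout sits at gap 100,001 bp, one past the inclusive boundary
  expect_setequal(p$gene_id, c("Gnear", "Gfar"))
  expect_equal(p$pattern, rep("both_up", 2))
  # a gene at exactly 100,000 bp is included
  toy$genes$start[4] <- 301000
  toy$genes$end[4] <- 302000
  p2 <- find_pairs(toy$hervs, toy$genes, toy$herv_de, toy$gene_de,
                   window = 100000)
  expect_true("Gout" %in% p2$gene_id)
  expect_equal(p2$distance_bp[p2$gene_id == "Gout"], 100000)
})

test_that("nearest-only mode keeps minimum-distance genes with ties", {
  toy <- make_toy()
  p <- find_pairs(toy$hervs, toy$genes, toy$herv_de, toy$gene_de,
                  window = 100000, nearest_only = TRUE)
  expect_equal(p$gene_id, "Gnear")
  # add a tie at the same distance on the same strand
  toy$genes <- rbind(toy$genes,
                     data.frame(gene_id = "Gtie", chrom = "chr1",
                                start = 211000, end = 212000, strand = "+",
                                gene_name = NA_character_))
  toy$gene_de <- make_de(toy$genes$gene_id, rep(2, 5), rep(0.001, 5))
  p2 <- find_pairs(toy$hervs, toy$genes, toy$herv_de, toy$gene_de,
                   window = 100000, nearest_only = TRUE)
  expect_setequal(p2$gene_id, c("Gnear", "Gtie"))
})

test_that("non-positive window and unstranded records are handled", {
  toy <- make_toy()
  expect_error(find_pairs(toy$hervs, toy$genes, toy$herv_de, toy$gene_de,
                          window = 0), "positive")
  toy$hervs$strand <- "."
  expect_message(
    p <- find_pairs(toy$hervs, toy$genes, toy$herv_de, toy$gene_de),
    "unstranded")
  expect_equal(nrow(p), 0L)
})

test_that("indexed pairing equals the brute-force scan on random instances", {
  for (seed in 1:25) {
    inst <- random_pair_instance(seed)
    fast <- find_pairs(inst$hervs, inst$genes, inst$herv_de, inst$gene_de,
                       window = inst$window)
    slow <- brute_force_pairs(inst$hervs, inst$genes, inst$herv_de,
                              inst$gene_de, inst$window)
    expect_equal(pair_key(fast), pair_key(slow), info = paste("seed", seed))
    if (nrow(fast) > 0) {
      m <- merge(fast, slow, by = c("herv_id", "gene_id"))
      expect_equal(m$distance_bp.x, m$distance_bp.y)
    }
  }
})

test_that("dropping a feature's DE status removes exactly its pairs", {
  inst <- random_pair_instance(42)
  full <- find_pairs(inst$hervs, inst$genes, inst$herv_de, inst$gene_de,
                     window = inst$window)
  expect_gt(nrow(full), 0)
  victim <- full$herv_id[1]
  de2 <- inst$herv_de
  de2$is_de[de2$feature_id == victim] <- FALSE
  reduced <- find_pairs(inst$hervs, inst$genes, de2, inst$gene_de,
                        window = inst$window)
  expect_equal(pair_key(reduced),
               setdiff(pair_key(full),
                       pair_key(full[full$herv_id == victim, ])))
})

test_that("pair summaries count patterns and distinct members", {
  p <- data.frame(herv_id = c("H1", "H1", "H2"),
                  gene_id = c("G1", "G2", "G1"),
                  pattern = c("both_up", "both_up", "herv_up_gene_down"))
  s <- summarize_pairs(p)
  expect_equal(s$n_pairs, 3L)
  expect_equal(s$n_herv_loci, 2L)
  expect_equal(s$n_genes, 2L)
  expect_equal(unname(s$pattern_counts["both_up"]), 2L)
  expect_equal(s$consistent_fraction, 2 / 3)
  expect_true(s$n_herv_loci <= s$n_pairs && s$n_genes <= s$n_pairs)
  empty <- summarize_pairs(p[0, ])
  expect_equal(empty$n_pairs, 0L)
  expect_true(is.na(empty$consistent_fraction))
})

test_that("pair intersection matches naive set intersection, ignores pattern", {
  a <- data.frame(herv_id = c("H1", "H2"), gene_id = c("G1", "G2"),
                  pattern = c("both_up", "both_up"))
  b <- data.frame(herv_id = "H1", gene_id = "G1", pattern = "both_down")
  out <- intersect_pairs(list(A = a, B = b))
  expect_equal(out$n_common, 1L)
  expect_equal(out$common$herv_id, "H1")
  disjoint <- intersect_pairs(list(
    A = data.frame(herv_id = "H1", gene_id = "G1"),
    B = data.frame(herv_id = "H2", gene_id = "G2"),
    C = data.frame(herv_id = "H3", gene_id = "G3")))
  expect_equal(disjoint$n_common, 0L)
  expect_error(intersect_pairs(list(A = a)), "two contrasts")
  # random sets vs Reduce(intersect, ...) oracle
  for (seed in 1:20) {
    set.seed(seed)
    sets <- lapply(1:3, function(i) {
      n <- sample(5:30, 1)
      data.frame(herv_id = paste0("H", sample.int(15, n, TRUE)),
                 gene_id = paste0("G", sample.int(15, n, TRUE)))
    })
    names(sets) <- c("KO1", "KO2", "N")
    res <- intersect_pairs(sets)
    oracle <- Reduce(intersect,
                     lapply(sets, function(s) unique(paste(s$herv_id,
                                                           s$gene_id))))
    expect_setequal(paste(res$common$herv_id, res$common$gene_id),
                    oracle)
    expect_equal(sum(res$venn), length(unique(unlist(
      lapply(sets, function(s) unique(paste(s$herv_id, s$gene_id)))))))
  }
})
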