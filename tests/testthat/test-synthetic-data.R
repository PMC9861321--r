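small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 300, n_hervs = 400,
         paired_fraction = 0.1, de_fraction_genes = 0.05),
    list(...))
  do.call(generator_config, args)
}

test_that("the generator is deterministic under a fixed seed", {
  e1 <- generate_experiment(small_cfg(seed = 99))
  e2 <- generate_experiment(small_cfg(seed = 99))
  expect_identical(e1$annotation$genes, e2$annotation$genes)
  expect_identical(e1$annotation$hervs, e2$annotation$hervs)
  expect_identical(e1$counts$counts, e2$counts$counts)
  expect_identical(e1$truth$true_pairs, e2$truth$true_pairs)
  e3 <- generate_experiment(small_cfg(seed = 100))
  expect_false(identical(e1$counts$counts, e3$counts$counts))
})

test_that("strand probability 1 puts every locus on the plus strand", {
  ann <- generate_annotation(small_cfg(seed = 2, plus_strand_prob = 0.999999))
  expect_true(all(ann$hervs$strand == "+"))
})

test_that("locus placement is proportional to chromosome length", {
  cfg <- generator_config(seed = 3, n_hervs = 4000, n_genes = 200,
                          paired_fraction = 0,
                          chrom_lengths = c(chr1 = 1e6, chr2 = 2e6,
                                            chr3 = 3e6, chr4 = 4e6,
                                            chr5 = 5e6))
  ann <- generate_annotation(cfg)
  obs <- table(factor(ann$hervs$chrom, levels = names(cfg$chrom_lengths)))
  p <- cfg$chrom_lengths / sum(cfg$chrom_lengths)
  expected <- 4000 * p
  sd3 <- 3 * sqrt(4000 * p * (1 - p))
  expect_true(all(abs(as.integer(obs) - expected) < sd3))
})

test_that("genes never overlap and all intervals respect chromosome ends", {
  ann <- generate_annotation(small_cfg(seed = 4))
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start), ]
  by_chr <- split(g, g$chrom)
  for (d in by_chr) {
    if (nrow(d) > 1)
      expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_true(all(ann$hervs$end <= ann$chrom_lengths[ann$hervs$chrom]))
  expect_error(generate_annotation(
    generator_config(seed = 1, n_genes = 5000, n_hervs = 10,
                     chrom_lengths = c(chr1 = 1e6))), "capacity")
})

test_that("truth pairs satisfy the window and strand constraints", {
  e <- generate_experiment(small_cfg(seed = 5))
  tp <- e$truth$true_pairs
  expect_gt(nrow(tp), 0)
  h <- e$annotation$hervs[match(tp$herv_id, e$annotation$hervs$locus_id), ]
  g <- e$annotation$genes[match(tp$gene_id, e$annotation$genes$gene_id), ]
  expect_true(all(h$strand == g$strand))
  expect_true(all(h$chrom == g$chrom))
  gap <- pmax(0, pmax(h$start, g$start) - pmin(h$end, g$end))
  expect_true(all(gap <= e$truth$config$window))
  # concordance flag is consistent with the signed truth effects
  hl <- e$truth$true_de_hervs$lfc[match(tp$herv_id,
                                        e$truth$true_de_hervs$locus_id)]
  gl <- e$truth$true_de_genes$lfc[match(tp$gene_id,
                                        e$truth$true_de_genes$gene_id)]
  expect_equal(tp$concordant, sign(hl) == sign(gl))
})

test_that("a null experiment yields only alpha-level false positives", {
  cfg <- small_cfg(seed = 6, de_fraction_genes = 0, paired_fraction = 0,
                   background_de_fraction = 0)
  e <- generate_experiment(cfg)
  res <- nb_wald_test(e$counts, e$contrasts$N)
  expect_lt(mean(res$is_de), 0.05)
  expect_equal(nrow(e$truth$true_pairs), 0L)
})

test_that("strongly induced ISG-like genes are recovered as upregulated", {
  cfg <- generator_config(seed = 7, n_genes = 500, n_hervs = 200,
                          de_fraction_genes = 0.1, de_up_prob = 1,
                          lfc_min = 6, lfc_max = 6, paired_fraction = 0,
                          n_replicates = 5)
  e <- generate_experiment(cfg)
  expect_equal(nrow(e$truth$true_de_genes), 50L)
  res <- nb_wald_test(e$counts, e$contrasts$N)
  hit <- res$direction[match(e$truth$true_de_genes$gene_id, res$feature_id)]
  expect_gte(sum(hit == "up"), 45L)
})

test_that("written experiments round-trip through the file readers", {
  e <- generate_experiment(small_cfg(seed = 8))
  dir <- tempfile()
  write_experiment(e, dir)
  genes <- read_gene_annotation(file.path(dir, "genes.bed"), "bed")
  hervs <- read_herv_annotation(file.path(dir, "hervs.bed"), "bed")
  expect_equal(nrow(genes), nrow(e$annotation$genes))
  expect_equal(sort(hervs$locus_id), sort(e$annotation$hervs$locus_id))
  expect_equal(hervs$superfamily[match(e$annotation$hervs$locus_id,
                                       hervs$locus_id)],
               e$annotation$hervs$superfamily)
  cm <- read_counts(file.path(dir, "counts.tsv"),
                    file.path(dir, "design.yaml"))
  expect_equal(cm$counts, e$counts$counts)
  expect_equal(cm$condition, e$counts$condition)
})
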