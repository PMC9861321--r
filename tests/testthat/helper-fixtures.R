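# In-code fixtures and independent oracles shared across test files.

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal GTF with gene feature lines (1-based inclusive)
gtf_lines <- function() c(
  'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "G1"; gene_name "Alpha";',
  'chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tgene_id "G1";',
  '2\tsrc\tgene\t501\t900\t.\t-\t.\tgene_id "G2";'
)

# GTF without gene lines: span must be min-start/max-end over the rows
gtf_exons_only <- function() c(
  'chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tgene_id "G1";',
  'chr1\tsrc\texon\t1801\t2000\t.\t+\t.\tgene_id "G1";'
)

rmsk_lines <- function() c(
  "   SW   perc perc perc  query     position in query    matching repeat",
  "score   div. del. ins.  sequence  begin  end   (left)  repeat    class/family  begin end (left) ID",
  "",
  "  463   11.5  0.0  0.0  chr1      1001   1600  (0)  +  THE1B     LTR/ERVL-MaLR  1  600  (0)  1",
  "  281    8.2  0.1  0.0  chr2      5001   5400  (0)  C  MER41B    LTR/ERV1       1  400  (0)  2",
  "  120   20.0  0.0  0.0  chr2      9001   9800  (0)  +  L1MB7     LINE/L1        1  800  (0)  3"
)

# a tiny screened DE table from explicit values
make_de <- function(ids, lfc, p, alpha = 0.05, thr = 1, padj = NULL) {
  df <- data.frame(feature_id = ids, base_mean = 10, log2fc = lfc,
                   pvalue = p,
                   padj = if (is.null(padj)) stats::p.adjust(p, "BH") else padj,
                   stringsAsFactors = FALSE)
  apply_screen(df, alpha = alpha, lfc = thr)
}

# brute-force all-pairs oracle: nested loops, no interval index
brute_force_pairs <- function(hervs, genes, herv_de, gene_de, window) {
  hd <- herv_de[herv_de$is_de, ]
  gd <- gene_de[gene_de$is_de, ]
  out <- list()
  for (i in seq_len(nrow(hervs))) {
    if (!hervs$locus_id[i] %in% hd$feature_id) next
    if (!hervs$strand[i] %in% c("+", "-")) next
    for (j in seq_len(nrow(genes))) {
      if (!genes$gene_id[j] %in% gd$feature_id) next
      if (genes$chrom[j] != hervs$chrom[i]) next
      if (genes$strand[j] != hervs$strand[i]) next
      gap <- max(0, max(hervs$start[i], genes$start[j]) -
                   min(hervs$end[i], genes$end[j]))
      if (gap <= window)
        out[[length(out) + 1L]] <- c(hervs$locus_id[i], genes$gene_id[j], gap)
    }
  }
  if (!length(out))
    return(data.frame(herv_id = character(), gene_id = character(),
                      distance_bp = numeric()))
  m <- do.call(rbind, out)
  df <- data.frame(herv_id = m[, 1], gene_id = m[, 2],
                   distance_bp = as.numeric(m[, 3]),
                   stringsAsFactors = FALSE)
  df[order(df$herv_id, df$gene_id), ]
}

# random instance for pairing oracle-equivalence tests
random_pair_instance <- function(seed, n_hervs = 15, n_genes = 15,
                                 span = 400000) {
  set.seed(seed)
  mk <- function(n, prefix) {
    start <- sample.int(span, n)
    width <- sample(100:8000, n, replace = TRUE)
    data.frame(id = paste0(prefix, seq_len(n)),
               chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = start, end = start + width,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  h <- mk(n_hervs, "H"); names(h)[1] <- "locus_id"
  g <- mk(n_genes, "G"); names(g)[1] <- "gene_id"
  de <- function(ids) {
    lfc <- sample(c(-1, 1), length(ids), TRUE) * runif(length(ids), 1.1, 4)
    p <- ifelse(runif(length(ids)) < 0.7, 0.001, 0.5)
    make_de(ids, lfc, p)
  }
  list(hervs = h, genes = g, herv_de = de(h$locus_id), gene_de = de(g$gene_id),
       window = 50000)
}

pair_key <- function(p) sort(paste(p$herv_id, p$gene_id, sep = "|"))
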