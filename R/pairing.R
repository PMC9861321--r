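PATTERNS <- c("both_up", "both_down", "herv_up_gene_down", "herv_down_gene_up")

#' Construct a genomic interval
#'
#' Plain container for a 0-based half-open stranded interval, used by
#' [interval_distance()].
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp); must exceed `start`.
#' @param strand `"+"`, `"-"`, or `"."` for unstranded.
#' @return a list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(nzchar(chrom), start >= 0, start < end,
            strand %in% c("+", "-", "."))
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), strand = strand),
            class = "genomic_interval")
}

#' Gap between two genomic intervals
#'
#' Returns `NA` when the intervals lie on different chromosomes, `0` when
#' they overlap (or abut), and otherwise the hull gap
#' `max(start) - min(end)` in bp. Strand is ignored here; strand filtering
#' is the pairing step's job.
#'
#' @param a,b `genomic_interval` objects (or any list with `chrom`,
#'   `start`, `end`).
#' @return integer gap in bp, or `NA` for trans-chromosomal input.
#' @export
interval_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_real_)
  max(0, max(a$start, b$start) - min(a$end, b$end))
}

# vectorized hull gap for same-chromosome interval columns
.gap_vec <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Classify the expression pattern of a HERV-gene pair
#'
#' Maps the two screened directions onto the four co-expression patterns:
#' `both_up`, `both_down`, `herv_up_gene_down`, `herv_down_gene_up`.
#' `"ns"` is a contract violation: non-significant features never reach
#' the pairing stage.
#'
#' @param herv_direction,gene_direction character vectors of `"up"`/`"down"`.
#' @return character vector of pattern labels.
#' @export
classify_pattern <- function(herv_direction, gene_direction) {
  if (any(!herv_direction %in% c("up", "down")) ||
      any(!gene_direction %in% c("up", "down")))
    stop("classify_pattern: directions must be 'up' or 'down'")
  ifelse(herv_direction == "up",
         ifelse(gene_direction == "up", "both_up", "herv_up_gene_down"),
         ifelse(gene_direction == "up", "herv_down_gene_up", "both_down"))
}

#' Find HERV-gene pairs among differentially expressed features
#'
#' Pairs every screened-significant HERV locus with every
#' screened-significant gene on the same strand of the same chromosome
#' whose hull gap is at most `window` bp (inclusive; overlap counts as
#' distance 0). With `nearest_only = TRUE` only each HERV's
#' minimum-distance gene(s) are kept (ties retained). Unstranded (`"."`)
#' records are excluded with a message. Candidate pairs are generated with
#' an indexed overlap query ([GenomicRanges::findOverlaps()] on
#' window-padded loci) and then filtered on the exact gap.
#'
#' @param hervs HERV annotation table (see [read_herv_annotation()]).
#' @param genes gene annotation table (see [read_gene_annotation()]).
#' @param herv_de,gene_de screened `de_result` tables covering the HERV
#'   loci and genes respectively (one combined table may be passed to both
#'   arguments).
#' @param window maximum gap in bp (default 100000); must be positive.
#' @param contrast contrast label stamped on the output rows.
#' @param nearest_only keep only minimum-distance gene(s) per HERV.
#' @return data.frame with one row per pair: `contrast`, `herv_id`,
#'   `gene_id`, `chrom`, `strand`, `herv_start`, `herv_end`, `gene_start`,
#'   `gene_end`, `distance_bp`, `herv_log2fc`, `gene_log2fc`,
#'   `herv_direction`, `gene_direction`, `pattern`.
#' @export
find_pairs <- function(hervs, genes, herv_de, gene_de, window = 100000,
                       contrast = "", nearest_only = FALSE) {
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("window must be a positive number of bp")
  h_de <- herv_de[herv_de$is_de, c("feature_id", "log2fc", "direction")]
  g_de <- gene_de[gene_de$is_de, c("feature_id", "log2fc", "direction")]
  h <- merge(hervs, h_de, by.x = "locus_id", by.y = "feature_id")
  g <- merge(genes, g_de, by.x = "gene_id", by.y = "feature_id")

  uns <- sum(!h$strand %in% c("+", "-")) + sum(!g$strand %in% c("+", "-"))
  if (uns > 0)
    message(uns, " unstranded record(s) excluded from pairing")
  h <- h[h$strand %in% c("+", "-"), , drop = FALSE]
  g <- g[g$strand %in% c("+", "-"), , drop = FALSE]

  empty <- data.frame(
    contrast = character(), herv_id = character(), gene_id = character(),
    chrom = character(), strand = character(),
    herv_start = numeric(), herv_end = numeric(),
    gene_start = numeric(), gene_end = numeric(), distance_bp = numeric(),
    herv_log2fc = numeric(), gene_log2fc = numeric(),
    herv_direction = character(), gene_direction = character(),
    pattern = character(), stringsAsFactors = FALSE)
  if (nrow(h) == 0L || nrow(g) == 0L) return(empty)

  # indexed query: pad HERV hulls by window + 1 so a gap of exactly
  # `window` still overlaps, then exact-gap filter
  lev <- union(unique(h$chrom), unique(g$chrom))
  hg <- GenomicRanges::GRanges(
    factor(h$chrom, lev),
    IRanges::IRanges(pmax(h$start - window - 1, 0) + 1L, h$end + window + 1),
    strand = h$strand)
  gg <- GenomicRanges::GRanges(factor(g$chrom, lev),
                               IRanges::IRanges(g$start + 1L, g$end),
                               strand = g$strand)
  ov <- GenomicRanges::findOverlaps(hg, gg, ignore.strand = FALSE)
  hi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  if (length(hi) == 0L) return(empty)

  d <- .gap_vec(h$start[hi], h$end[hi], g$start[gi], g$end[gi])
  keep <- d <= window
  hi <- hi[keep]; gi <- gi[keep]; d <- d[keep]
  if (length(hi) == 0L) return(empty)

  pairs <- data.frame(
    contrast = contrast,
    herv_id = h$locus_id[hi], gene_id = g$gene_id[gi],
    chrom = h$chrom[hi], strand = h$strand[hi],
    herv_start = h$start[hi], herv_end = h$end[hi],
    gene_start = g$start[gi], gene_end = g$end[gi],
    distance_bp = d,
    herv_log2fc = h$log2fc[hi], gene_log2fc = g$log2fc[gi],
    herv_direction = h$direction[hi], gene_direction = g$direction[gi],
    stringsAsFactors = FALSE)
  if (nearest_only) {
    dmin <- stats::ave(pairs$distance_bp, pairs$herv_id, FUN = min)
    pairs <- pairs[pairs$distance_bp == dmin, , drop = FALSE]
  }
  pairs$pattern <- classify_pattern(pairs$herv_direction, pairs$gene_direction)
  pairs <- pairs[order(pairs$herv_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Summarize a pair set
#'
#' @param pairs data.frame from [find_pairs()] (one contrast).
#' @return list of class `pair_summary`: `n_pairs`, `n_herv_loci`,
#'   `n_genes`, `pattern_counts` (all four patterns, zero-filled), and
#'   `consistent_fraction` = (both_up + both_down) / n_pairs (`NA` when
#'   the set is empty).
#' @export
summarize_pairs <- function(pairs) {
  pc <- table(factor(pairs$pattern, levels = PATTERNS))
  n <- nrow(pairs)
  structure(list(
    n_pairs = n,
    n_herv_loci = length(unique(pairs$herv_id)),
    n_genes = length(unique(pairs$gene_id)),
    pattern_counts = stats::setNames(as.integer(pc), PATTERNS),
    consistent_fraction = if (n > 0)
      unname((pc[["both_up"]] + pc[["both_down"]]) / n) else NA_real_
  ), class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat("pair_summary:", x$n_pairs, "pairs over", x$n_herv_loci,
      "HERV loci and", x$n_genes, "genes\n")
  if (x$n_pairs > 0) {
    print(x$pattern_counts)
    cat(sprintf("consistent fraction: %.3f\n", x$consistent_fraction))
  }
  invisible(x)
}

#' Intersect pair sets across contrasts
#'
#' A pair identity is the `(herv_id, gene_id)` tuple; the pattern label is
#' ignored, so a pair may intersect even when its direction pattern differs
#' between contrasts. Returns the pairs common to every contrast, the full
#' Venn region cardinalities, and the distinct locus/gene counts of the
#' common set.
#'
#' @param pair_sets named list (one element per contrast) of pair
#'   data.frames from [find_pairs()].
#' @return list with `common` (data.frame `herv_id`, `gene_id`),
#'   `n_common`, `n_herv_loci`, `n_genes`, and `venn` (named integer
#'   vector, one entry per non-empty contrast combination, names joined
#'   with `&`).
#' @export
intersect_pairs <- function(pair_sets) {
  if (length(pair_sets) < 2L) stop("need at least two contrasts to intersect")
  if (is.null(names(pair_sets)) || any(!nzchar(names(pair_sets))))
    stop("pair_sets must be a named list")
  keys <- lapply(pair_sets, function(p) unique(paste(p$herv_id, p$gene_id,
                                                     sep = "\r")))
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(keys)))
  combo <- apply(member, 1, function(row)
    paste(names(pair_sets)[row], collapse = "&"))
  venn <- table(combo)
  common_keys <- all_keys[rowSums(member) == length(pair_sets)]
  parts <- strsplit(common_keys, "\r", fixed = TRUE)
  common <- data.frame(
    herv_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE)
  common <- common[order(common$herv_id, common$gene_id), , drop = FALSE]
  rownames(common) <- NULL
  list(common = common,
       n_common = nrow(common),
       n_herv_loci = length(unique(common$herv_id)),
       n_genes = length(unique(common$gene_id)),
       venn = stats::setNames(as.integer(venn), names(venn)))
}

#' Write a pair table as TSV
#'
#' @param pairs data.frame from [find_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
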