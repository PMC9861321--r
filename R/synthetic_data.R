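# representative raw class/family labels per superfamily; chosen so that
# classify_superfamily() recovers the superfamily from the raw string
FAMILY_LABELS <- c(
  "ERV1" = "LTR/ERV1",
  "ERVL" = "LTR/ERVL",
  "ERVK" = "LTR/ERVK",
  "Gypsy" = "LTR/Gypsy",
  "ERVL-MaLR" = "LTR/ERVL-MaLR",
  "unclassified" = "LTR"
)

#' Configuration for the synthetic experiment generator
#'
#' Defaults emulate an interferon-beta stimulation experiment in a
#' receptor-intact line, a receptor-knockout line, and a partially
#' receptor-deficient line, each with duplicate libraries, on a toy
#' five-chromosome genome. The plus-strand bias (0.638) and the
#' superfamily mixture (about one third ERVL-MaLR, one third ERV1, one
#' quarter ERVL, 1.5% ERVK, remainder split between Gypsy and
#' unclassified) mirror the composition typically reported for
#' interferon-responsive HERV loci.
#'
#' @param seed integer random seed (mandatory; the generator has no hidden
#'   global state).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_genes,n_hervs feature counts.
#' @param plus_strand_prob probability a HERV locus is placed on the plus
#'   strand.
#' @param superfamily_mix probability vector over the six superfamilies
#'   (named; must sum to 1).
#' @param de_fraction_genes fraction of genes that respond to interferon.
#' @param de_up_prob probability a responsive gene is upregulated.
#' @param lfc_min,lfc_max range of absolute log2 fold changes (effects up
#'   to ~6, so strongly induced ISG-like genes exist).
#' @param concordance_rho probability that a HERV anchored within the
#'   window of a responsive gene shares its direction; with probability
#'   `(1 - concordance_rho)/2` it takes the opposite direction, else no
#'   effect.
#' @param paired_fraction fraction of HERV loci deliberately placed within
#'   `window` bp of a responsive gene on the same strand.
#' @param nb_mean_log_mu,nb_mean_log_sigma log-normal parameters of
#'   baseline expression means.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_replicates libraries per condition (default 2, duplicate-scale).
#' @param window pairing window in bp.
#' @param mt2_attenuation residual interferon pathway activity of the
#'   partially deficient (IFNAR2-mutant-like) line, in [0, 1].
#' @param background_de_fraction fraction of features with cell-line
#'   background effects in each engineered line (independent of
#'   interferon); drives the knockout contrasts' excess DE counts.
#' @param min_de_gene_gap minimum same-strand hull gap enforced between
#'   responsive genes so each anchored HERV sits in the window of exactly
#'   one responsive gene.
#' @param gene_width,herv_width length-2 vectors, uniform width ranges (bp).
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             chrom_lengths = c(chr1 = 10e6, chr2 = 8e6,
                                               chr3 = 6e6, chr4 = 4e6,
                                               chr5 = 2e6),
                             n_genes = 2000,
                             n_hervs = 4000,
                             plus_strand_prob = 0.638,
                             superfamily_mix = NULL,
                             de_fraction_genes = 0.075,
                             de_up_prob = 0.8,
                             lfc_min = 1.2,
                             lfc_max = 6,
                             concordance_rho = 0.9,
                             paired_fraction = 0.125,
                             nb_mean_log_mu = 5,
                             nb_mean_log_sigma = 1,
                             nb_dispersion = 0.1,
                             n_replicates = 2,
                             window = 100000,
                             mt2_attenuation = 0.3,
                             background_de_fraction = 0.08,
                             min_de_gene_gap = 250000,
                             gene_width = c(2000, 20000),
                             herv_width = c(300, 10000)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(superfamily_mix)) {
    superfamily_mix <- c("ERV1" = 1 / 3, "ERVL" = 1 / 4, "ERVK" = 0.015,
                         "Gypsy" = 0.034, "ERVL-MaLR" = 1 / 3,
                         "unclassified" = NA)
    superfamily_mix["unclassified"] <- 1 - sum(superfamily_mix, na.rm = TRUE)
  }
  stopifnot(
    length(seed) == 1L, seed == round(seed),
    all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
    n_genes >= 1, n_hervs >= 1,
    plus_strand_prob > 0, plus_strand_prob < 1,
    setequal(names(superfamily_mix), SUPERFAMILIES),
    abs(sum(superfamily_mix) - 1) < 1e-8, all(superfamily_mix >= 0),
    de_fraction_genes >= 0, de_fraction_genes <= 1,
    de_up_prob >= 0, de_up_prob <= 1,
    lfc_min > 0, lfc_max >= lfc_min,
    concordance_rho >= 0, concordance_rho <= 1,
    paired_fraction >= 0, paired_fraction <= 1,
    nb_dispersion > 0, n_replicates >= 1,
    window > 0, mt2_attenuation >= 0, mt2_attenuation <= 1,
    background_de_fraction >= 0, background_de_fraction <= 1,
    length(gene_width) == 2L, length(herv_width) == 2L
  )
  structure(as.list(environment()), class = "generator_config")
}

# uniform non-overlapping placement of n widths on [0, L):
# offsets are order statistics of U(0, free), shifted by cumulative widths
.place_nonoverlap <- function(n, widths, L) {
  free <- L - sum(widths)
  if (n == 0L) return(numeric(0))
  if (free < 0) stop("requested features exceed placeable capacity")
  u <- sort(stats::runif(n, 0, free))
  floor(u + cumsum(c(0, widths[-n])))
}

#' Generate a synthetic genome annotation
#'
#' Genes are placed uniformly without overlap, with random strands; HERV
#' loci land on chromosomes with probability proportional to chromosome
#' length and on the plus strand with probability `plus_strand_prob`;
#' a `paired_fraction` of HERVs is instead placed within `window` bp of an
#' interferon-responsive gene on the HERV's strand (these anchored loci are
#' the generator's truth pairs). Superfamilies are drawn from
#' `superfamily_mix`.
#'
#' The responsive-gene set and HERV anchor map are stored in the
#' `"ifn_genes"` and `"herv_anchor"` attributes for [generate_counts()].
#'
#' @param config a [generator_config()].
#' @return a [genome_annotation()].
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cl <- config$chrom_lengths
  chroms <- names(cl)

  # --- genes, uniform without overlap, chromosome share proportional to length
  n_per <- as.vector(stats::rmultinom(1, config$n_genes, cl / sum(cl)))
  genes <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    n <- n_per[i]
    if (n == 0L) return(NULL)
    w <- floor(stats::runif(n, config$gene_width[1], config$gene_width[2]))
    s <- .place_nonoverlap(n, w, cl[i])
    data.frame(chrom = chroms[i], start = s, end = s + w,
               strand = ifelse(stats::runif(n) < 0.5, "+", "-"),
               stringsAsFactors = FALSE)
  }))
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
  genes$gene_name <- genes$gene_id
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "gene_name")]

  # --- interferon-responsive genes, spaced so anchored HERV windows are clean
  n_de <- round(config$de_fraction_genes * nrow(genes))
  de_idx <- integer(0)
  for (i in sample.int(nrow(genes))) {
    if (length(de_idx) >= n_de) break
    same <- de_idx[genes$strand[de_idx] == genes$strand[i] &
                     genes$chrom[de_idx] == genes$chrom[i]]
    if (length(same)) {
      gap <- .gap_vec(genes$start[i], genes$end[i],
                      genes$start[same], genes$end[same])
      if (any(gap < config$min_de_gene_gap)) next
    }
    de_idx <- c(de_idx, i)
  }
  if (length(de_idx) < n_de)
    warning("only ", length(de_idx), " of ", n_de,
            " responsive genes placeable at the requested spacing")
  ifn_genes <- data.frame(
    gene_id = genes$gene_id[de_idx],
    lfc = ifelse(stats::runif(length(de_idx)) < config$de_up_prob, 1, -1) *
      stats::runif(length(de_idx), config$lfc_min, config$lfc_max),
    stringsAsFactors = FALSE)

  # --- HERV loci
  n_paired <- round(config$paired_fraction * config$n_hervs)
  hw_all <- floor(stats::runif(config$n_hervs,
                               config$herv_width[1], config$herv_width[2]))
  strand_all <- ifelse(stats::runif(config$n_hervs) < config$plus_strand_prob,
                       "+", "-")
  anchor <- rep(NA_character_, config$n_hervs)
  chrom_h <- character(config$n_hervs)
  start_h <- numeric(config$n_hervs)

  de_genes <- genes[de_idx, , drop = FALSE]
  for (j in seq_len(n_paired)) {
    cand <- which(de_genes$strand == strand_all[j])
    if (length(cand) == 0L)
      stop("no responsive gene on strand ", strand_all[j], " to anchor to")
    gidx <- cand[sample.int(length(cand), 1L)]
    g <- de_genes[gidx, ]
    w <- hw_all[j]
    L <- cl[[g$chrom]]
    lo <- max(0, g$start - config$window - w)
    hi <- min(L - w, g$end + config$window)
    start_h[j] <- floor(stats::runif(1, lo, hi))
    chrom_h[j] <- g$chrom
    anchor[j] <- g$gene_id
  }
  if (config$n_hervs > n_paired) {
    rest <- (n_paired + 1L):config$n_hervs
    chrom_h[rest] <- sample(chroms, length(rest), replace = TRUE,
                            prob = cl / sum(cl))
    start_h[rest] <- floor(stats::runif(length(rest)) *
                             (cl[chrom_h[rest]] - hw_all[rest]))
  }
  sf <- sample(SUPERFAMILIES, config$n_hervs, replace = TRUE,
               prob = config$superfamily_mix[SUPERFAMILIES])
  hervs <- data.frame(
    locus_id = sprintf("HERV%05d", seq_len(config$n_hervs)),
    chrom = chrom_h, start = start_h, end = start_h + hw_all,
    strand = strand_all,
    family_name = unname(FAMILY_LABELS[sf]),
    superfamily = sf,
    stringsAsFactors = FALSE)

  ann <- genome_annotation(cl, genes, hervs)
  attr(ann, "ifn_genes") <- ifn_genes
  attr(ann, "herv_anchor") <- stats::setNames(anchor, hervs$locus_id)
  ann
}

#' Generate synthetic count matrices and ground truth
#'
#' Simulates the four-condition design — interferon-treated receptor-intact
#' (`IFNB_N`), interferon-treated receptor-knockout (`IFNB_KO1`),
#' interferon-treated partially deficient (`IFNB_MT2`), and untreated
#' (`N`) — with `n_replicates` libraries each. Interferon effects are
#' present at full strength in `IFNB_N`, at `mt2_attenuation` strength in
#' `IFNB_MT2`, and absent in `IFNB_KO1` and `N`. A HERV anchored to a
#' responsive gene takes the gene's direction with probability
#' `concordance_rho`, the opposite direction with probability
#' `(1 - concordance_rho)/2`, and no effect otherwise; effect magnitudes
#' are drawn independently from the gene effect distribution. Each
#' engineered line additionally carries cell-line background effects on a
#' `background_de_fraction` of features. Counts are negative binomial
#' around log-normal baselines.
#'
#' @param annotation output of [generate_annotation()] (must carry its
#'   truth attributes).
#' @param config the same [generator_config()].
#' @return list with `counts` (a [count_matrix()]), `design` (sample ->
#'   condition), `contrasts` (list of [contrast_spec()]: KO1, KO2, N, each
#'   treated = interferon-treated intact line), and `truth` (list:
#'   `true_de_genes`, `true_de_hervs`, `true_pairs` with `concordant`
#'   flag, `background`, `config`).
#' @export
generate_counts <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "generator_config"))
  ifn_genes <- attr(annotation, "ifn_genes")
  anchor <- attr(annotation, "herv_anchor")
  if (is.null(ifn_genes) || is.null(anchor))
    stop("annotation lacks generator truth attributes; ",
         "use generate_annotation()")
  set.seed(config$seed + 1L)

  feat <- c(annotation$genes$gene_id, annotation$hervs$locus_id)
  nf <- length(feat)
  baseline <- stats::rlnorm(nf, config$nb_mean_log_mu, config$nb_mean_log_sigma)

  # interferon effect per feature
  ifn_lfc <- stats::setNames(rep(0, nf), feat)
  ifn_lfc[ifn_genes$gene_id] <- ifn_genes$lfc
  anchored <- names(anchor)[!is.na(anchor)]
  u <- stats::runif(length(anchored))
  sign_gene <- sign(ifn_lfc[anchor[anchored]])
  herv_sign <- ifelse(u < config$concordance_rho, sign_gene,
                      ifelse(u < config$concordance_rho +
                               (1 - config$concordance_rho) / 2,
                             -sign_gene, 0))
  herv_mag <- stats::runif(length(anchored), config$lfc_min, config$lfc_max)
  ifn_lfc[anchored] <- herv_sign * herv_mag

  # cell-line background effects (independent of interferon)
  bg <- lapply(c(KO1 = "KO1", MT2 = "MT2"), function(line) {
    n_bg <- round(config$background_de_fraction * nf)
    idx <- sample.int(nf, n_bg)
    data.frame(feature_id = feat[idx],
               lfc = ifelse(stats::runif(n_bg) < 0.5, 1, -1) *
                 stats::runif(n_bg, config$lfc_min, config$lfc_max),
               stringsAsFactors = FALSE)
  })
  bg_vec <- lapply(bg, function(b) {
    v <- stats::setNames(rep(0, nf), feat)
    v[b$feature_id] <- b$lfc
    v
  })

  conditions <- c("IFNB_N", "IFNB_KO1", "IFNB_MT2", "N")
  activity <- c(IFNB_N = 1, IFNB_KO1 = 0, IFNB_MT2 = config$mt2_attenuation,
                N = 0)
  samples <- as.vector(t(outer(conditions, seq_len(config$n_replicates),
                               paste, sep = "_")))
  design <- stats::setNames(rep(conditions, each = config$n_replicates),
                            samples)
  counts <- matrix(0L, nf, length(samples),
                   dimnames = list(feat, samples))
  for (s in samples) {
    cond <- design[[s]]
    lmu <- log2(baseline) + ifn_lfc * activity[[cond]] +
      (if (cond == "IFNB_KO1") bg_vec$KO1 else 0) +
      (if (cond == "IFNB_MT2") bg_vec$MT2 else 0)
    counts[, s] <- stats::rnbinom(nf, mu = 2^lmu, size = 1 / config$nb_dispersion)
  }

  true_pairs <- data.frame(
    herv_id = anchored, gene_id = unname(anchor[anchored]),
    concordant = herv_sign == sign_gene,
    stringsAsFactors = FALSE)
  true_pairs <- true_pairs[herv_sign != 0, , drop = FALSE]
  rownames(true_pairs) <- NULL

  treated <- samples[design == "IFNB_N"]
  contrasts <- list(
    KO1 = contrast_spec("KO1", treated, samples[design == "IFNB_KO1"]),
    KO2 = contrast_spec("KO2", treated, samples[design == "IFNB_MT2"]),
    N = contrast_spec("N", treated, samples[design == "N"])
  )
  list(
    counts = count_matrix(counts, design),
    design = design,
    contrasts = contrasts,
    truth = list(
      true_de_genes = ifn_genes,
      true_de_hervs = data.frame(
        locus_id = anchored[herv_sign != 0],
        lfc = (herv_sign * herv_mag)[herv_sign != 0],
        stringsAsFactors = FALSE),
      true_pairs = true_pairs,
      background = bg,
      config = config
    )
  )
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: [generate_annotation()] followed by
#' [generate_counts()].
#'
#' @param config a [generator_config()].
#' @return list with `annotation`, `counts`, `design`, `contrasts`,
#'   `truth`.
#' @export
generate_experiment <- function(config) {
  ann <- generate_annotation(config)
  out <- generate_counts(ann, config)
  c(list(annotation = ann), out)
}

#' Write a synthetic experiment to disk
#'
#' Emits the same formats the pipeline reads: `genes.bed`, `hervs.bed`,
#' `counts.tsv`, `design.yaml`, plus `truth.json`.
#'
#' @param exp output of [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(exp$annotation$genes, file.path(dir, "genes.bed"))
  write_bed(exp$annotation$hervs, file.path(dir, "hervs.bed"))
  cnt <- data.frame(feature_id = rownames(exp$counts$counts),
                    exp$counts$counts, check.names = FALSE)
  utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(as.list(exp$design), file.path(dir, "design.yaml"))
  truth <- exp$truth
  truth$config <- unclass(truth$config)
  truth$config$chrom_lengths <- as.list(truth$config$chrom_lengths)
  truth$config$superfamily_mix <- as.list(truth$config$superfamily_mix)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
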