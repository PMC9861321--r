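#' Configure an end-to-end pipeline run
#'
#' Either `simulate` (a [generator_config()]) or the four input paths
#' (`counts`, `design`, `gene_annotation`, `herv_annotation`) must be
#' given. File inputs are validated to exist up front, before any stage
#' runs.
#'
#' @param counts path to a counts TSV/CSV (features x samples).
#' @param design path to a design file or named sample -> condition vector.
#' @param gene_annotation path to a gene GTF/BED.
#' @param herv_annotation path to a HERV GTF/BED/RepeatMasker table.
#' @param contrasts named list; each element either a
#'   [contrast_spec()] or a list/vector with `treated` and `control`
#'   entries naming condition labels (expanded to sample IDs via the
#'   design).
#' @param alpha,lfc,use_adjusted screen parameters (see [apply_screen()]).
#' @param window pairing window in bp.
#' @param nearest_only pairing mode (see [find_pairs()]).
#' @param out_dir output directory for TSV/JSON artifacts (optional; no
#'   files are written when `NULL`).
#' @param simulate optional [generator_config()]; when given, inputs are
#'   generated in memory and the file arguments are ignored.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, design = NULL,
                            gene_annotation = NULL, herv_annotation = NULL,
                            contrasts = NULL, alpha = 0.05, lfc = 1,
                            use_adjusted = FALSE, window = 100000,
                            nearest_only = FALSE, out_dir = NULL,
                            simulate = NULL) {
  if (is.null(simulate)) {
    for (p in c(counts, gene_annotation, herv_annotation))
      if (!file.exists(p)) stop("input file not found: ", p)
    if (is.null(contrasts) || is.null(names(contrasts)))
      stop("contrasts must be a named list")
    if (anyDuplicated(names(contrasts))) stop("contrast names must be unique")
  } else {
    stopifnot(inherits(simulate, "generator_config"))
  }
  structure(list(counts = counts, design = design,
                 gene_annotation = gene_annotation,
                 herv_annotation = herv_annotation, contrasts = contrasts,
                 alpha = alpha, lfc = lfc, use_adjusted = use_adjusted,
                 window = window, nearest_only = nearest_only,
                 out_dir = out_dir, simulate = simulate),
            class = "pipeline_config")
}

.annot_format <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
  else if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
  else "rmsk_out"
}

.expand_contrasts <- function(contrasts, design) {
  lapply(names(contrasts), function(nm) {
    cs <- contrasts[[nm]]
    if (inherits(cs, "contrast_spec")) return(cs)
    tr <- cs[["treated"]]; co <- cs[["control"]]
    if (all(tr %in% design)) tr <- names(design)[design %in% tr]
    if (all(co %in% design)) co <- names(design)[design %in% co]
    contrast_spec(nm, tr, co)
  }) |> stats::setNames(names(contrasts))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate inputs; differential-expression test
#' over all features (genes and HERV loci together) for every contrast;
#' significance screen; strand-aware pairing of significant loci with
#' significant genes; cross-contrast pair intersection; strand,
#' chromosome-distribution and superfamily summaries of the significant
#' loci. Artifacts are written under `out_dir` (`de/`, `pairs/`, `stats/`,
#' `report.json`) when configured. The run is deterministic given the
#' config (and generator seed).
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`; see [write_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(config$simulate)) {
    exp <- generate_experiment(config$simulate)
    ann <- exp$annotation
    cm <- exp$counts
    contrasts <- exp$contrasts
  } else {
    genes <- read_gene_annotation(config$gene_annotation,
                                  .annot_format(config$gene_annotation))
    hervs <- read_herv_annotation(config$herv_annotation,
                                  .annot_format(config$herv_annotation))
    chrom_lengths <- tapply(c(genes$end, hervs$end),
                            c(genes$chrom, hervs$chrom), max)
    ann <- genome_annotation(chrom_lengths, genes, hervs)
    design <- read_design(config$design)
    cm <- read_counts(config$counts, design)
    contrasts <- .expand_contrasts(config$contrasts, cm$condition)
  }

  in_counts <- rownames(cm$counts)
  unplaced <- setdiff(in_counts, c(ann$genes$gene_id, ann$hervs$locus_id))
  if (length(unplaced))
    message(length(unplaced),
            " feature(s) in the count matrix have no annotation; ",
            "tested for DE but excluded from pairing")

  sf <- size_factors(cm)
  de <- lapply(contrasts, function(cs)
    nb_wald_test(cm, cs, alpha = config$alpha, lfc = config$lfc,
                 use_adjusted = config$use_adjusted, sf = sf))
  pairs <- lapply(names(contrasts), function(nm) {
    d <- de[[nm]]
    find_pairs(ann$hervs, ann$genes,
               herv_de = d[d$feature_id %in% ann$hervs$locus_id, ],
               gene_de = d[d$feature_id %in% ann$genes$gene_id, ],
               window = config$window, contrast = nm,
               nearest_only = config$nearest_only)
  })
  names(pairs) <- names(contrasts)
  venn <- if (length(pairs) >= 2L) intersect_pairs(pairs) else NULL

  per_contrast <- lapply(names(contrasts), function(nm) {
    d <- de[[nm]]
    deherv <- ann$hervs[ann$hervs$locus_id %in%
                          d$feature_id[d$is_de], , drop = FALSE]
    degene <- d[d$feature_id %in% ann$genes$gene_id & d$is_de, , drop = FALSE]
    ss <- strand_summary(deherv[deherv$strand %in% c("+", "-"), , drop = FALSE])
    corr <- tryCatch(
      chrom_size_correlation(ss$per_chrom, ann$chrom_lengths),
      error = function(e) NULL)
    list(
      de_counts = list(
        herv_up = sum(deherv$locus_id %in% d$feature_id[d$direction == "up"]),
        herv_down = sum(deherv$locus_id %in% d$feature_id[d$direction == "down"]),
        gene_up = sum(degene$direction == "up"),
        gene_down = sum(degene$direction == "down")),
      pair_summary = summarize_pairs(pairs[[nm]]),
      strand = ss,
      chrom_correlation = corr,
      superfamily = superfamily_tally(deherv))
  })
  names(per_contrast) <- names(contrasts)

  report <- structure(list(
    contrasts = per_contrast,
    venn = if (!is.null(venn))
      venn[c("n_common", "n_herv_loci", "n_genes", "venn")] else NULL,
    screen = list(alpha = config$alpha, lfc = config$lfc,
                  use_adjusted = config$use_adjusted,
                  window = config$window,
                  nearest_only = config$nearest_only),
    n_features_tested = length(in_counts),
    n_unannotated = length(unplaced),
    version = as.character(utils::packageVersion("ervpairscan")),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_report")
  attr(report, "de") <- de
  attr(report, "pairs") <- pairs
  attr(report, "common_pairs") <- if (!is.null(venn)) venn$common else NULL

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    for (d in c("de", "pairs", "stats"))
      dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
    for (nm in names(contrasts)) {
      write_de_table(de[[nm]], file.path(out, "de", paste0(nm, ".tsv")))
      write_pairs_tsv(pairs[[nm]], file.path(out, "pairs", paste0(nm, ".tsv")))
      jsonlite::write_json(.report_to_list(report)$contrasts[[nm]],
                           file.path(out, "stats", paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    write_report(report, file.path(out, "report.json"), "json")
  }
  report
}

.report_to_list <- function(report) {
  out <- unclass(report)
  out$contrasts <- lapply(out$contrasts, function(pc) {
    pc$pair_summary <- unclass(pc$pair_summary)
    pc$pair_summary$pattern_counts <- as.list(pc$pair_summary$pattern_counts)
    pc$strand <- unclass(pc$strand)
    pc$strand$per_chrom <- NULL
    pc$superfamily <- list(
      counts = as.list(pc$superfamily$counts),
      fractions = as.list(pc$superfamily$fractions))
    pc
  })
  if (!is.null(out$venn)) out$venn$venn <- as.list(out$venn$venn)
  out
}

#' Write a run report
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output file path.
#' @param format `"json"` (machine-readable) or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(.report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    lines <- c("# ervpairscan run report", "")
    for (nm in names(report$contrasts)) {
      pc <- report$contrasts[[nm]]
      ps <- pc$pair_summary
      lines <- c(lines,
        sprintf("## Contrast %s", nm),
        sprintf("- DE loci: %d up / %d down; DE genes: %d up / %d down",
                pc$de_counts$herv_up, pc$de_counts$herv_down,
                pc$de_counts$gene_up, pc$de_counts$gene_down),
        sprintf("- pairs: %d over %d loci and %d genes; consistent fraction %s",
                ps$n_pairs, ps$n_herv_loci, ps$n_genes,
                ifelse(is.na(ps$consistent_fraction), "NA",
                       sprintf("%.3f", ps$consistent_fraction))),
        sprintf("- strand: %d plus (%s%%) / %d minus, exact binomial p = %.3g",
                pc$strand$n_plus, pc$strand$pct_plus, pc$strand$n_minus,
                pc$strand$pvalue),
        "")
    }
    if (!is.null(report$venn)) {
      lines <- c(lines, "## Intersection",
                 sprintf("- common pairs: %d (%d loci, %d genes)",
                         report$venn$n_common, report$venn$n_herv_loci,
                         report$venn$n_genes), "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", length(x$contrasts), "contrast(s)\n")
  for (nm in names(x$contrasts)) {
    pc <- x$contrasts[[nm]]
    cat(sprintf("  %s: %d DE loci, %d DE genes, %d pairs\n", nm,
                pc$de_counts$herv_up + pc$de_counts$herv_down,
                pc$de_counts$gene_up + pc$de_counts$gene_down,
                pc$pair_summary$n_pairs))
  }
  if (!is.null(x$venn))
    cat(sprintf("  common pairs: %d (%d loci, %d genes)\n",
                x$venn$n_common, x$venn$n_herv_loci, x$venn$n_genes))
  invisible(x)
}
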