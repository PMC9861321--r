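SUPERFAMILIES <- c("ERV1", "ERVL", "ERVK", "Gypsy", "ERVL-MaLR", "unclassified")

#' Map a repeat class/family label to an ERV superfamily
#'
#' Collapses raw RepeatMasker/Dfam-style repeat family labels (e.g.
#' `"LTR/ERVL-MaLR"`, `"LTR/ERV1"`) into the six ERV superfamily bins used
#' throughout the package: ERV1, ERVL, ERVK, Gypsy, ERVL-MaLR, and
#' unclassified. Matching is case-insensitive substring matching on the
#' family component after stripping a leading `"LTR/"` class prefix;
#' `"ERVL-MaLR"` is tested before `"ERVL"` so the longer label wins.
#' Anything that matches none of the five named superfamilies (including
#' non-LTR elements and the empty string) maps to `"unclassified"`.
#'
#' @param family_field character vector of raw repeat family labels.
#' @return character vector of the same length, each element one of the six
#'   superfamily labels.
#' @examples
#' classify_superfamily(c("LTR/ERVL-MaLR", "LTR/ERVK", "LINE/L1", ""))
#' @export
classify_superfamily <- function(family_field) {
  x <- toupper(sub("^LTR/", "", as.character(family_field), ignore.case = TRUE))
  out <- rep("unclassified", length(x))
  out[grepl("GYPSY", x, fixed = TRUE)] <- "Gypsy"
  out[grepl("ERVK", x, fixed = TRUE)] <- "ERVK"
  out[grepl("ERVL", x, fixed = TRUE)] <- "ERVL"
  out[grepl("ERV1", x, fixed = TRUE)] <- "ERV1"
  out[grepl("ERVL-MALR", x, fixed = TRUE)] <- "ERVL-MaLR"
  out[is.na(family_field)] <- "unclassified"
  out
}

#' Normalize chromosome names between UCSC and Ensembl dialects
#'
#' @param chrom character vector of chromosome names.
#' @param style `"ucsc"` adds a `"chr"` prefix where missing (the default,
#'   so `"1"` and `"chr1"` unify as `"chr1"`); `"ensembl"` strips it;
#'   `"none"` leaves names untouched.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(chrom, style = c("ucsc", "ensembl", "none")) {
  style <- match.arg(style)
  chrom <- as.character(chrom)
  if (style == "ucsc") {
    ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  } else if (style == "ensembl") {
    sub("^chr", "", chrom)
  } else {
    chrom
  }
}

# Internal: GRanges (1-based inclusive) -> 0-based half-open columns
.granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

.check_intervals <- function(df, what) {
  bad <- df$start < 0 | df$start >= df$end
  if (any(bad)) {
    stop(sprintf("%s: %d interval(s) violate 0 <= start < end (first: %s:%d-%d)",
                 what, sum(bad), df$chrom[bad][1], df$start[bad][1], df$end[bad][1]))
  }
  invisible(df)
}

#' Read a gene annotation from GTF or BED
#'
#' Coordinates are stored 0-based half-open internally; GTF input is 1-based
#' inclusive and converted on read, BED is taken as-is. For GTF, one record
#' per distinct `gene_id` is produced from that gene's `gene` feature line,
#' or from the min-start/max-end span over its lines when no `gene` line is
#' present.
#'
#' @param path file path.
#' @param format `"gtf"` or `"bed"` (BED6, name field = gene_id).
#' @param chrom_style chromosome-name normalization (see [normalize_chrom()]).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `gene_name`.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed"),
                                 chrom_style = "ucsc") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (.file_is_empty(path)) {
    warning("empty annotation file: ", path)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), gene_name = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = toupper(format))
  df <- .granges_to_df(gr)
  if (format == "gtf") {
    if (is.null(gr$gene_id)) stop("GTF has no gene_id attribute: ", path)
    df$gene_id <- as.character(gr$gene_id)
    df$gene_name <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else NA_character_
    type <- as.character(gr$type)
    if (any(type == "gene")) {
      keep <- df[type == "gene", , drop = FALSE]
      # union span per gene_id, in case of duplicated gene lines
      df <- .span_by_gene(keep)
    } else {
      df <- .span_by_gene(df)
    }
  } else {
    df$gene_id <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
    df$gene_name <- NA_character_
    dup <- duplicated(df$gene_id)
    if (any(dup)) stop("duplicate gene_id in BED: ", df$gene_id[dup][1])
  }
  df$chrom <- normalize_chrom(df$chrom, chrom_style)
  df <- df[, c("gene_id", "chrom", "start", "end", "strand", "gene_name")]
  rownames(df) <- NULL
  .check_intervals(df, "gene annotation")
  df
}

# union span of possibly multiple GTF lines per gene; conflicting strand or
# chromosome within one gene_id is a validation error
.span_by_gene <- function(df) {
  sp <- split(df, df$gene_id)
  out <- lapply(sp, function(d) {
    if (length(unique(d$strand)) > 1L)
      stop("gene_id ", d$gene_id[1], " has conflicting strands")
    if (length(unique(d$chrom)) > 1L)
      stop("gene_id ", d$gene_id[1], " spans multiple chromosomes")
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end), strand = d$strand[1],
               gene_name = if ("gene_name" %in% names(d)) d$gene_name[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.file_is_empty <- function(path) {
  lines <- readLines(path, n = 100L, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  length(lines) == 0L
}

#' Read a HERV locus annotation from GTF, BED, or RepeatMasker .out
#'
#' The raw repeat family label is taken from the `family` (or
#' `repeat_family`) GTF attribute, from the BED name-field convention
#' `locus_id|family`, or from the class/family column of a RepeatMasker
#' `.out` table. The superfamily bin is filled by [classify_superfamily()].
#' A missing family label yields `family_name = ""` and superfamily
#' `"unclassified"` with a warning; non-LTR elements (e.g. `LINE/L1`) also
#' land in `"unclassified"` with a warning.
#'
#' @param path file path.
#' @param format `"gtf"`, `"bed"`, or `"rmsk_out"`.
#' @param chrom_style chromosome-name normalization (see [normalize_chrom()]).
#' @return data.frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `family_name`, `superfamily`.
#' @export
read_herv_annotation <- function(path, format = c("gtf", "bed", "rmsk_out"),
                                 chrom_style = "ucsc") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "rmsk_out") {
    df <- .read_rmsk_out(path)
  } else {
    if (.file_is_empty(path)) {
      warning("empty annotation file: ", path)
      return(data.frame(locus_id = character(), chrom = character(),
                        start = integer(), end = integer(), strand = character(),
                        family_name = character(), superfamily = character(),
                        stringsAsFactors = FALSE))
    }
    gr <- rtracklayer::import(path, format = toupper(format))
    df <- .granges_to_df(gr)
    if (format == "gtf") {
      id <- if (!is.null(gr$locus_id)) gr$locus_id else gr$gene_id
      if (is.null(id)) stop("GTF has neither locus_id nor gene_id attribute")
      fam <- if (!is.null(gr$family)) gr$family else gr$repeat_family
      if (is.null(fam)) {
        warning("no family attribute in ", path, "; superfamily set to unclassified")
        fam <- ""
      }
      df$locus_id <- as.character(id)
      df$family_name <- as.character(fam)
    } else {
      nm <- if (!is.null(gr$name)) as.character(gr$name) else
        paste0("herv", seq_along(gr))
      has_fam <- grepl("|", nm, fixed = TRUE)
      if (!all(has_fam)) {
        warning(sum(!has_fam), " BED record(s) without 'locus|family' name; ",
                "superfamily set to unclassified")
      }
      df$locus_id <- sub("\\|.*$", "", nm)
      df$family_name <- ifelse(has_fam, sub("^[^|]*\\|", "", nm), "")
    }
  }
  df$family_name[is.na(df$family_name)] <- ""
  df$superfamily <- classify_superfamily(df$family_name)
  nonltr <- df$family_name != "" & df$superfamily == "unclassified" &
    !grepl("^LTR\\b", df$family_name, ignore.case = TRUE)
  if (any(nonltr)) {
    warning(sum(nonltr), " record(s) with non-LTR repeat family (e.g. ",
            df$family_name[nonltr][1], ") classified as 'unclassified'")
  }
  dup <- duplicated(df$locus_id)
  if (any(dup)) stop("duplicate locus_id: ", df$locus_id[dup][1])
  df$chrom <- normalize_chrom(df$chrom, chrom_style)
  df <- df[, c("locus_id", "chrom", "start", "end", "strand",
               "family_name", "superfamily")]
  rownames(df) <- NULL
  .check_intervals(df, "HERV annotation")
  df
}

# RepeatMasker .out: 3 header lines, whitespace-aligned columns:
# score div del ins query begin end (left) strand repeat class/family ...
.read_rmsk_out <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  # header rows are the ones not starting with a numeric SW score
  lines <- lines[grepl("^\\s*\\d", lines)]
  if (length(lines) == 0L) {
    warning("empty RepeatMasker table: ", path)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), locus_id = character(),
                      family_name = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  n_ok <- vapply(fields, length, 1L) >= 11L
  if (any(!n_ok)) {
    stop("malformed RepeatMasker line ", which(!n_ok)[1], ": fewer than 11 columns")
  }
  m <- do.call(rbind, fields)
  strand <- ifelse(m[, 9] == "C", "-", m[, 9])
  data.frame(
    chrom = m[, 5],
    start = as.integer(m[, 6]) - 1L,  # rmsk is 1-based inclusive
    end = as.integer(m[, 7]),
    strand = strand,
    locus_id = paste0(m[, 10], "_", m[, 5], "_", m[, 6]),
    family_name = m[, 11],
    stringsAsFactors = FALSE
  )
}

#' Assemble a validated genome annotation
#'
#' Bundles chromosome lengths with gene and HERV tables and checks the
#' container invariants: unique IDs within each table, known chromosomes,
#' and every interval inside its chromosome's stated length.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param genes data.frame as returned by [read_gene_annotation()].
#' @param hervs data.frame as returned by [read_herv_annotation()].
#' @return an object of class `genome_annotation` (a list with elements
#'   `chrom_lengths`, `genes`, `hervs`).
#' @export
genome_annotation <- function(chrom_lengths, genes, hervs) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  for (tab in list(list(genes, "gene_id", "genes"),
                   list(hervs, "locus_id", "hervs"))) {
    df <- tab[[1]]; idcol <- tab[[2]]; what <- tab[[3]]
    if (anyDuplicated(df[[idcol]]))
      stop("duplicate ", idcol, " in ", what)
    unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
    if (length(unknown))
      stop(what, " reference unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    over <- df$end > chrom_lengths[df$chrom]
    if (any(over))
      stop(what, ": interval beyond chromosome end (", df[[idcol]][over][1], ")")
    .check_intervals(df, what)
  }
  structure(list(chrom_lengths = chrom_lengths, genes = genes, hervs = hervs),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_lengths), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$hervs), "HERV loci\n")
  invisible(x)
}

#' Write genes or HERV loci as BED6
#'
#' Genes are written with the gene_id as name; HERV loci use the
#' `locus_id|family` name convention so that [read_herv_annotation()] can
#' round-trip them.
#'
#' @param df gene or HERV table (recognized by its `gene_id`/`locus_id`
#'   column).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if ("locus_id" %in% names(df)) {
    paste0(df$locus_id, "|", df$family_name)
  } else {
    df$gene_id
  }
  out <- data.frame(df$chrom, df$start, df$end, name, 0L, df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample-to-condition design
#'
#' Accepts a YAML mapping (`sample: condition`), a two-column TSV/CSV with
#' header columns `sample` and `condition`, or a named character vector
#' passed through unchanged.
#'
#' @param design file path or named character vector.
#' @return named character vector, sample -> condition.
#' @export
read_design <- function(design) {
  if (is.character(design) && length(design) == 1L && file.exists(design)) {
    if (grepl("\\.ya?ml$", design)) {
      lst <- yaml::read_yaml(design)
      return(vapply(lst, as.character, ""))
    }
    df <- utils::read.table(design, header = TRUE, sep = "",
                            stringsAsFactors = FALSE)
    if (!all(c("sample", "condition") %in% names(df)))
      stop("design table needs 'sample' and 'condition' columns")
    return(stats::setNames(df$condition, df$sample))
  }
  if (is.null(names(design)) || any(names(design) == ""))
    stop("design must be a file path or a named sample -> condition vector")
  design
}

#' Read a feature count matrix
#'
#' Reads a TSV/CSV with feature IDs in the first column and one column per
#' sample, keeps the samples named in the design, and validates that all
#' entries are non-negative integers.
#'
#' @param path counts file (TSV or CSV; delimiter sniffed from the header).
#' @param design sample -> condition map (anything [read_design()] accepts).
#' @return an object of class `count_matrix`: a list with `counts` (integer
#'   matrix, features x samples) and `condition` (named character vector).
#' @export
read_counts <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path)
  design <- read_design(design)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  missing <- setdiff(names(design), names(df))
  if (length(missing))
    stop("sample(s) in design absent from counts file: ",
         paste(missing, collapse = ", "))
  m <- as.matrix(df[, names(design), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count entries in ", path)
  if (any(m < 0)) stop("negative count entries in ", path)
  if (any(m != round(m))) stop("non-integer count entries in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  count_matrix(m, design)
}

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   row and column names.
#' @param condition named character vector mapping every sample (column)
#'   to its condition label.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  miss <- setdiff(colnames(counts), names(condition))
  if (length(miss))
    stop("sample(s) without condition label: ", paste(miss, collapse = ", "))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature IDs in count matrix")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, condition = condition[colnames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples;", length(unique(x$condition)), "conditions\n")
  invisible(x)
}
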