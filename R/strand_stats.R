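#' Exact two-sided binomial test probability
#'
#' P-value of the exact binomial test of `k` successes in `n` trials
#' against success probability `p0`, two-sided by the minimum-likelihood
#' method: the sum of probabilities of all outcomes whose point probability
#' does not exceed that of the observed outcome (up to a 1 + 1e-7 relative
#' tolerance, guarding against floating-point ties).
#'
#' @param k observed count of successes.
#' @param n number of trials.
#' @param p0 null success probability (default 0.5).
#' @return p-value in (0, 1].
#' @export
binom_exact_p <- function(k, n, p0 = 0.5) {
  stopifnot(n >= 1, k >= 0, k <= n, p0 > 0, p0 < 1)
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

#' Format a proportion as a percentage at one decimal place
#'
#' Half-up rounding at one decimal, the convention used for all reported
#' percentages in this package (so 0.638448 prints as `"63.8"`).
#'
#' @param x proportion(s) in [0, 1].
#' @return character vector of percentages without the `%` sign.
#' @export
format_percent <- function(x) {
  sprintf("%.1f", floor(x * 1000 + 0.5) / 10)
}

#' Strand distribution of differentially expressed HERV loci
#'
#' Counts plus- and minus-strand loci (overall and per chromosome) and
#' tests the split against a 50:50 null with the exact two-sided binomial
#' test ([binom_exact_p()]). A chi-square goodness-of-fit p-value is also
#' reported as an alternative.
#'
#' @param hervs HERV table with `chrom` and `strand` columns (typically
#'   the DE-screened subset); all records must be stranded.
#' @return list of class `strand_summary`: `n_plus`, `n_minus`,
#'   `frac_plus`, `pct_plus` (1-decimal string), `pvalue` (exact binomial),
#'   `pvalue_chisq`, `per_chrom` (data.frame `chrom`, `n_plus`, `n_minus`).
#' @export
strand_summary <- function(hervs) {
  if (any(!hervs$strand %in% c("+", "-")))
    stop("strand_summary requires stranded records")
  np <- sum(hervs$strand == "+")
  nm <- sum(hervs$strand == "-")
  n <- np + nm
  per <- if (n > 0) {
    tab <- table(hervs$chrom, factor(hervs$strand, levels = c("+", "-")))
    data.frame(chrom = rownames(tab), n_plus = as.integer(tab[, "+"]),
               n_minus = as.integer(tab[, "-"]), stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), n_plus = integer(), n_minus = integer())
  }
  structure(list(
    n_plus = np, n_minus = nm,
    frac_plus = if (n > 0) np / n else NA_real_,
    pct_plus = if (n > 0) format_percent(np / n) else NA_character_,
    pvalue = if (n > 0) binom_exact_p(np, n, 0.5) else NA_real_,
    pvalue_chisq = if (n > 0)
      stats::pchisq((np - nm)^2 / n, df = 1, lower.tail = FALSE) else NA_real_,
    per_chrom = per
  ), class = "strand_summary")
}

#' @export
print.strand_summary <- function(x, ...) {
  cat(sprintf("strand_summary: %d plus (%s%%) / %d minus; exact binomial p = %.3g\n",
              x$n_plus, x$pct_plus, x$n_minus, x$pvalue))
  invisible(x)
}

#' Correlation between per-chromosome locus counts and chromosome size
#'
#' Pearson (with two-sided p) and Spearman correlation between the number
#' of loci per chromosome and chromosome length, excluding the sex and
#' mitochondrial chromosomes by default. Chromosomes absent from
#' `per_chrom_counts` contribute a zero count.
#'
#' @param per_chrom_counts named numeric vector or the `per_chrom`
#'   data.frame of a [strand_summary()] (plus and minus counts are summed).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param exclude chromosomes left out (default chrX, chrY, chrM and their
#'   unprefixed spellings).
#' @return list: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n_chromosomes`.
#' @export
chrom_size_correlation <- function(per_chrom_counts, chrom_lengths,
                                   exclude = c("chrX", "chrY", "chrM",
                                               "X", "Y", "MT")) {
  if (is.data.frame(per_chrom_counts)) {
    per_chrom_counts <- stats::setNames(
      per_chrom_counts$n_plus + per_chrom_counts$n_minus,
      per_chrom_counts$chrom)
  }
  chroms <- setdiff(names(chrom_lengths), exclude)
  if (length(chroms) < 3L)
    stop("need at least 3 chromosomes after exclusion")
  cnt <- per_chrom_counts[chroms]
  cnt[is.na(cnt)] <- 0
  len <- chrom_lengths[chroms]
  if (stats::sd(cnt) == 0) {
    # zero covariance: report r = 0 rather than cor.test's error path
    return(list(pearson_r = 0, pearson_p = 1, spearman_rho = 0,
                spearman_p = 1, n_chromosomes = length(chroms)))
  }
  pe <- stats::cor.test(len, cnt, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(len, cnt, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n_chromosomes = length(chroms))
}

#' Superfamily composition of a HERV locus set
#'
#' @param hervs HERV table with a `superfamily` column.
#' @return list of class `superfamily_tally`: `counts` and `fractions`,
#'   both named over all six superfamilies (zero-filled); fractions are
#'   `NA` for an empty set.
#' @export
superfamily_tally <- function(hervs) {
  cnt <- table(factor(hervs$superfamily, levels = SUPERFAMILIES))
  n <- sum(cnt)
  structure(list(
    counts = stats::setNames(as.integer(cnt), SUPERFAMILIES),
    fractions = if (n > 0) stats::setNames(as.numeric(cnt) / n, SUPERFAMILIES)
      else stats::setNames(rep(NA_real_, length(SUPERFAMILIES)), SUPERFAMILIES)
  ), class = "superfamily_tally")
}

#' @export
print.superfamily_tally <- function(x, ...) {
  cat("superfamily_tally:\n")
  print(x$counts)
  invisible(x)
}
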