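#' Median-of-ratios size factors
#'
#' Per-sample library scaling factors: each sample's factor is the median,
#' over features whose geometric mean across samples is positive, of the
#' ratio count / geometric mean. The `"total"` fallback scales by column
#' totals (normalized to geometric mean 1) and is intended for sparse
#' matrices where no feature is expressed in every sample.
#'
#' @param cm a [count_matrix()] (or a bare counts matrix).
#' @param method `"median_ratio"` (default) or `"total"`.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(cm, method = c("median_ratio", "total")) {
  method <- match.arg(method)
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (method == "total") {
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total count")
    return(tot / exp(mean(log(tot))))
  }
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    stop("no feature with nonzero counts in every sample; ",
         "use method = \"total\"")
  }
  sf <- apply(counts, 2, function(x) exp(stats::median(log(x[ok]) - loggeo[ok])))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factor estimated")
  sf
}

#' Define a treated-vs-control contrast
#'
#' @param name contrast label (e.g. `"KO1"`, `"KO2"`, `"N"`).
#' @param treated,control disjoint, non-empty character vectors of sample
#'   IDs. Two samples per side (as in duplicate-only designs) are accepted
#'   but trigger a low-replication warning.
#' @return object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, treated, control) {
  stopifnot(length(treated) >= 1L, length(control) >= 1L)
  if (length(intersect(treated, control)))
    stop("treated and control samples overlap")
  if (length(treated) < 3L || length(control) < 3L)
    message("contrast ", name, ": fewer than 3 replicates per side; ",
            "dispersion estimates will be fragile")
  structure(list(name = name, treated = treated, control = control),
            class = "contrast_spec")
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' For each feature, counts are normalized by median-of-ratios size factors;
#' a per-feature NB dispersion is estimated by the method of moments on
#' normalized counts pooled within conditions, floored at 1e-8 and shrunk
#' toward the across-feature median with weight 0.25; the log2 fold change
#' is \eqn{\log_2((\bar{k}_T + 0.5)/(\bar{k}_C + 0.5))} with a 0.5
#' pseudo-count on both group means; the Wald statistic (fold change over
#' its delta-method standard error) is referred to a t distribution with
#' residual-plus-prior degrees of freedom (n - 2 + 4, the prior df
#' reflecting the information borrowed by the dispersion shrinkage), which
#' keeps the type-I error near nominal at the duplicate-scale replication
#' this package targets. P-values are Benjamini-Hochberg adjusted over all
#' tested features. Features with all-zero counts in both groups are
#' reported with missing p-values and direction `"ns"`.
#'
#' @param cm a [count_matrix()].
#' @param contrast a [contrast_spec()].
#' @param alpha,lfc,use_adjusted screen parameters passed to
#'   [apply_screen()].
#' @param sf optional precomputed size factors for all samples of `cm`.
#' @return data.frame of class `de_result` with columns `feature_id`,
#'   `base_mean`, `log2fc`, `pvalue`, `padj`, `direction`, `is_de`.
#' @export
nb_wald_test <- function(cm, contrast, alpha = 0.05, lfc = 1,
                         use_adjusted = FALSE, sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(contrast, "contrast_spec"))
  samp <- c(contrast$treated, contrast$control)
  miss <- setdiff(samp, colnames(cm$counts))
  if (length(miss))
    stop("contrast sample(s) absent from count matrix: ",
         paste(miss, collapse = ", "))
  counts <- cm$counts[, samp, drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts) else sf <- sf[samp]
  k <- sweep(counts, 2, sf, "/")
  ti <- seq_along(contrast$treated)
  ci <- length(contrast$treated) + seq_along(contrast$control)
  n1 <- length(ti); n2 <- length(ci)
  m1 <- rowMeans(k[, ti, drop = FALSE])
  m2 <- rowMeans(k[, ci, drop = FALSE])
  v1 <- if (n1 > 1) apply(k[, ti, drop = FALSE], 1, stats::var) else rep(0, nrow(k))
  v2 <- if (n2 > 1) apply(k[, ci, drop = FALSE], 1, stats::var) else rep(0, nrow(k))

  testable <- m1 + m2 > 0
  # moment dispersion pooled across conditions, df-weighted
  a1 <- (v1 - m1) / m1^2
  a2 <- (v2 - m2) / m2^2
  w1 <- n1 - 1L; w2 <- n2 - 1L
  a <- (w1 * ifelse(is.finite(a1), a1, 0) + w2 * ifelse(is.finite(a2), a2, 0)) /
    max(w1 + w2, 1L)
  a <- pmax(a, 1e-8)
  a <- 0.75 * a + 0.25 * stats::median(a[testable])

  log2fc <- log2((m1 + 0.5) / (m2 + 0.5))
  se2 <- ((m1 + a * m1^2) / n1 / (m1 + 0.5)^2 +
          (m2 + a * m2^2) / n2 / (m2 + 0.5)^2) / log(2)^2
  df <- n1 + n2 - 2L + 4L
  pvalue <- 2 * stats::pt(-abs(log2fc / sqrt(se2)), df = df)
  pvalue[!testable] <- NA_real_
  log2fc[!testable] <- 0
  padj <- rep(NA_real_, length(pvalue))
  padj[testable] <- stats::p.adjust(pvalue[testable], method = "BH")

  res <- data.frame(
    feature_id = rownames(counts),
    base_mean = (m1 * n1 + m2 * n2) / (n1 + n2),
    log2fc = log2fc,
    pvalue = pvalue,
    padj = padj,
    stringsAsFactors = FALSE
  )
  res <- apply_screen(res, alpha = alpha, lfc = lfc, use_adjusted = use_adjusted)
  attr(res, "contrast") <- contrast$name
  res
}

#' Apply the significance screen to a DE result table
#'
#' A feature is called differentially expressed when its screened p-value
#' is strictly below `alpha` AND its absolute log2 fold change is strictly
#' above `lfc` (so p = alpha exactly, or |log2fc| = lfc exactly, is not
#' called). `direction` is `"up"`/`"down"` by the sign of `log2fc` for
#' called features and `"ns"` otherwise.
#'
#' @param res data.frame with columns `feature_id`, `log2fc`, `pvalue`,
#'   and (if `use_adjusted`) `padj`.
#' @param alpha p-value cutoff (default 0.05, strict).
#' @param lfc absolute log2-fold-change cutoff (default 1, strict).
#' @param use_adjusted screen on `padj` instead of `pvalue`.
#' @return the input with recomputed `is_de` and `direction` columns,
#'   classed `de_result`.
#' @export
apply_screen <- function(res, alpha = 0.05, lfc = 1, use_adjusted = FALSE) {
  p <- if (use_adjusted) res$padj else res$pvalue
  is_de <- !is.na(p) & p < alpha & abs(res$log2fc) > lfc
  res$direction <- ifelse(is_de & res$log2fc > 0, "up",
                          ifelse(is_de & res$log2fc < 0, "down", "ns"))
  res$is_de <- is_de
  attr(res, "screen") <- list(alpha = alpha, lfc = lfc,
                              use_adjusted = use_adjusted)
  class(res) <- unique(c("de_result", class(res)))
  res
}

#' Import an externally computed DE table
#'
#' Lets genuine DESeq2 (or other) output stand in for the built-in test.
#' Requires columns `feature_id` (or a first ID column), `log2FoldChange`
#' (or `log2fc`) and `pvalue`; `padj` is recomputed by Benjamini-Hochberg
#' when absent.
#'
#' @param path TSV file path.
#' @inheritParams apply_screen
#' @return a screened `de_result` data.frame.
#' @export
import_de_table <- function(path, alpha = 0.05, lfc = 1, use_adjusted = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  if (!"feature_id" %in% nm) {
    names(df)[1] <- "feature_id"
    nm <- names(df)
  }
  if ("log2FoldChange" %in% nm) df$log2fc <- df$log2FoldChange
  if (!"log2fc" %in% names(df))
    stop("DE table lacks a log2FoldChange/log2fc column: ", path)
  if (!"pvalue" %in% nm) stop("DE table lacks a pvalue column: ", path)
  if (!"padj" %in% nm || all(is.na(df$padj))) {
    df$padj <- stats::p.adjust(df$pvalue, method = "BH")
  } else if (anyNA(df$padj)) {
    df$padj[is.na(df$padj)] <-
      stats::p.adjust(df$pvalue, method = "BH")[is.na(df$padj)]
  }
  if (!"base_mean" %in% names(df)) {
    df$base_mean <- if ("baseMean" %in% nm) df$baseMean else NA_real_
  }
  out <- df[, c("feature_id", "base_mean", "log2fc", "pvalue", "padj")]
  apply_screen(out, alpha = alpha, lfc = lfc, use_adjusted = use_adjusted)
}

#' Write a DE result table as TSV
#'
#' @param res a `de_result` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(res, path) {
  utils::write.table(
    res[, c("feature_id", "base_mean", "log2fc", "pvalue", "padj", "direction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
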