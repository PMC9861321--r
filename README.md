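# ervpairscan

Human endogenous retroviruses (HERVs) are retroviral remnants fixed in the
germline, most of them reduced to solitary long terminal repeats (LTRs) that
still carry promoter and enhancer motifs. Under type I interferon signaling,
many HERV loci change expression alongside interferon-stimulated genes
(ISGs), suggesting a cis-regulatory relationship between a locus and its
genomic neighborhood. `ervpairscan` is an R package for asking that question
quantitatively from bulk RNA-seq count matrices: which HERV loci and genes
respond to a treatment, which significant loci sit near significant genes on
the same strand, and whether those neighbors move in the same direction.

It is aimed at transcriptomics analysts who already have locus-level HERV
counts (e.g. from a RepeatMasker-derived annotation) and gene counts, and
want the co-expression screen, its summary statistics, and a simulation
harness to validate the whole chain.

## What it computes

1. **Differential expression screen.** For each contrast (treated vs
   control) every feature — gene or HERV locus alike — is tested with a
   negative-binomial Wald test: median-of-ratios size factors
   \(s_j\), moment-estimated dispersion \(\alpha_i\) shrunk toward the
   across-feature median, fold change
   \(\widehat{\mathrm{LFC}}_i = \log_2\frac{\bar k_{iT} + 0.5}{\bar k_{iC} + 0.5}\)
   on normalized counts \(k_{ij} = c_{ij}/s_j\), and a moderated-t
   reference for the Wald statistic. A feature is significant when
   \(p < 0.05\) and \(|\widehat{\mathrm{LFC}}| > 1\) (both strict;
   `use_adjusted = TRUE` screens on the Benjamini–Hochberg adjusted
   p-value instead). Genuine DESeq2 output can be imported in place of the
   built-in test (`import_de_table()`).
2. **Strand-aware pairing.** Every significant HERV locus is paired with
   every significant gene on the same strand of the same chromosome whose
   interval gap is at most 100 kb (inclusive; overlap counts as 0). Each
   pair is classified into one of four patterns (`both_up`, `both_down`,
   `herv_up_gene_down`, `herv_down_gene_up`); the consistent fraction is
   the share of same-direction pairs. Pair sets are intersected across
   contrasts on `(locus, gene)` identity to find the shared core.
3. **Descriptive statistics.** Strand distribution of significant loci
   with an exact two-sided binomial test against a 50:50 null,
   per-chromosome counts and their Pearson/Spearman correlation with
   chromosome length (sex/mitochondrial chromosomes excluded by default),
   and composition over the six ERV superfamilies (ERV1, ERVL, ERVK,
   Gypsy, ERVL-MaLR, unclassified) mapped from raw RepeatMasker/Dfam
   family labels.
4. **Synthetic experiments.** A generator builds a toy genome, places HERV
   loci with a configurable plus-strand bias, plants a known set of
   interferon-responsive genes and anchored loci with a configurable
   direction-concordance, simulates NB counts for a four-condition design
   (treated/untreated × receptor-intact/deficient lines), and returns the
   ground truth so every stage can be checked end to end.

## Worked example

```r
library(ervpairscan)

cfg <- generator_config(seed = 1)          # defaults: 2000 genes, 4000 loci
report <- run_pipeline(pipeline_config(simulate = cfg, use_adjusted = TRUE))
print(report)
#> run_report: 3 contrast(s)
#>   KO1: 661 DE loci, 274 DE genes, 788 pairs
#>   KO2: 600 DE loci, 249 DE genes, 620 pairs
#>   N: 404 DE loci, 135 DE genes, 352 pairs
#>   common pairs: 214 (213 loci, 92 genes)

report$contrasts$N$strand
#> strand_summary: 252 plus (62.4%) / 152 minus; exact binomial p = 7.44e-07
report$contrasts$N$pair_summary
#> pair_summary: 352 pairs over 341 HERV loci and 119 genes
#>           both_up         both_down herv_up_gene_down herv_down_gene_up
#>               282                40                 8                22
#> consistent fraction: 0.915
```

The three contrasts compare the interferon-treated intact line against the
treated knockout line (`KO1`), the treated partially deficient line
(`KO2`), and the untreated intact line (`N`). In this simulation the
generator planted a 0.638 plus-strand bias (recovered: 62.4%, binomial
p ≈ 7e-7), a direction-concordance of 0.9 among anchored locus–gene pairs
(recovered consistent fraction 0.915; the detectable-pair expectation is
2ρ/(1+ρ) ≈ 0.947, see the vignette), and 214 pairs survive intersection
across all three contrasts. File-based runs take a counts TSV, a design
file, and GTF/BED/RepeatMasker annotations instead of `simulate`; a thin
command-line wrapper with `simulate`/`de`/`pairs`/`stats`/`run`
subcommands is installed under `inst/cli/erv-pairscan.R`.

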