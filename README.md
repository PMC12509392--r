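# tmtquant

Quantitative analysis of isobaric TMTpro 16-plex proteomics data from
laser-capture-microdissected, formalin-fixed (FFPE) tissue — the setting in
which two small patient cohorts (for example 8 young vs 8 old nephrectomy
patients) are compared on a single multiplexed run, starting from a
PSM-level reporter-ion table rather than raw spectra.

The package implements the full post-search pipeline:

- **Reporter-ion isotope impurity correction** — each PSM's 16 observed
  reporter intensities are un-mixed by solving the linear system
  `M x = observed`, where column *j* of `M` gives the distribution of true
  channel *j*'s signal across observed channels (vendor-style −2/−1/+1/+2
  isotope tables are converted by `impurity_from_isotopes()`).
- **Isolation-interference filtering** — PSMs whose co-isolation fraction
  exceeds 50% are removed (a PSM at exactly 0.50 is retained).
- **Protein rollup** — summed reporter intensities over each protein's
  unique peptides; shared peptides are excluded.
- **Missingness filtering** — proteins missing ≥ 50% of values in either
  group are removed, with no imputation, followed by log2 transform and
  per-sample median subtraction.
- **iBAQ abundance** — `iBAQ = Σ(peptide intensities) / n_theoretical`,
  where `n_theoretical` counts distinct fully tryptic peptides of 6–30
  residues from an in-silico digest (K/R cleavage, proline suppression).
- **Moderated differential expression** — per-protein least squares of
  log2 abundance on group, sex, and hypertension status; empirical-Bayes
  pooling of residual variances toward an assay-wide prior,
  `s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, with `(d₀, s₀²)` estimated by moment
  matching of `log s²` (digamma/trigamma inversion); moderated t with
  `d + d₀` degrees of freedom; tail-area FDR (π₀-scaled Benjamini–Hochberg
  q-values) with significance at adjusted p < 0.05.
- **Downstream summaries** — PCA biplot tables (scores, loadings, top-10
  loading proteins), Z-score heatmaps of the top-50 differential proteins
  with hierarchical clustering, per-group box-plot statistics, and
  annotation overlap/coverage counts.
- **Clinical tables** — mean (SD) and count (%) group summaries with
  two-sided Fisher's exact tests (exact hypergeometric enumeration) and
  rank-sum/Welch tests.
- **Synthetic data generator** — ground-truthed PSM-level 16-plex datasets
  (log-normal abundances, peptide ionization factors, reporter noise,
  impurity mixing, co-isolation interference, missingness) so every stage
  is testable without any raw data.

## Worked example

```r
library(tmtquant)

cfg <- sim_config(n_proteins = 300, seed = 42)   # 8 young vs 8 old, 10% DE
ds  <- simulate_dataset(cfg)
res <- quantify_psms(ds$psms, ds$impurity, ds$design)
res$report
#>                       step removed remaining
#> 1               input_psms      NA      3627
#> 2      interference_filter      73      3554
#> 3          shared_peptides       0        NA
#> 4       proteins_rolled_up      NA       300
#> 5 group_missingness_filter       0        NA
#> 6      proteins_quantified      NA       300

de <- run_de(res$quant, ds$design)
#> 32 significant of 300 proteins (FDR tail_area, pi0 = 0.92)
#> EB prior: d0 = 3.8, s0^2 = 0.0178
head(de[order(de$p_adjusted), c("protein", "logFC", "t", "p_value", "p_adjusted")], 5)
#>   protein logFC     t  p_value p_adjusted
#>  PROT0024  1.64  26.6 1.57e-14   2.37e-12
#>  PROT0227 -1.55 -26.4 1.71e-14   2.37e-12
#>  PROT0243  1.71  24.5 5.68e-14   5.25e-12
#>  PROT0003  1.27  22.2 2.60e-13   1.33e-11
#>  PROT0080  1.41  21.7 3.68e-13   1.33e-11
```

`logFC` is the old-minus-young log2 fold change adjusted for sex and
hypertension; `t` the variance-moderated statistic; `p_adjusted` the
tail-area q-value. 32 proteins pass q < 0.05 — the 30 simulated
differential proteins plus the tail of false positives the FDR level
tolerates. Co-isolation interference (here Beta(2, 8)-distributed)
compresses the estimated |logFC| below the simulated effect of 2, the
expected behaviour of co-isolated background in TMT data.

```r
ib <- ibaq_rank_table(ibaq_from_psms(correct_impurities(ds$psms, ds$impurity), ds$db))
attr(ib, "median_ibaq_log10")
#> median iBAQ (log10): 7.03; span 6.2 orders

fisher_exact_2x2(matrix(c(0, 8, 4, 4), 2, 2, byrow = TRUE))
#> Fisher exact, hypertension 0/8 vs 4/8: p = 0.077
```

A thin command-line wrapper with `simulate`, `quantify`, `ibaq`, `de` and
`clinical` subcommands is installed at `inst/cli/tmtquant.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tmtquant.R", package = "tmtquant"))')" \
    simulate --out-dir demo --n-proteins 500 --seed 1
```

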