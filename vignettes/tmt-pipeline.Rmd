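---
title: "Methods: TMT reporter-ion quantitation and moderated differential expression"
author: "tmtquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMT reporter-ion quantitation and moderated differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtquant)
```

## The problem

Isobaric labeling with 16-plex TMTpro reagents lets sixteen samples — here,
laser-capture-microdissected tubulointerstitium from 8 young and 8 old
nephrectomy patients — be quantified in one mass-spectrometry run: every
identified peptide-spectrum match (PSM) carries sixteen reporter-ion
intensities, one per sample channel. Two physical artifacts corrupt these
intensities. First, the reagents are isotopically impure, so a few percent
of each channel's signal is observed in neighbouring channels. Second,
narrow isolation windows co-isolate other peptides, whose reporter ions are
an "average proteome" background that compresses fold changes toward 1
(ratio compression). This package implements the complete post-search
analysis for such data, from a PSM-level table to differential-expression
and descriptive summaries, together with a ground-truthed simulator used to
validate every stage.

## Quantitation model and processing rules

**Impurity correction.** With the column convention — column $j$ of the
$16\times16$ matrix $M$ is the distribution of true channel $j$'s signal
across observed channels — the observed reporters of a PSM are
$o = M s$, and correction solves $Ms = o$ per PSM. Vendor data sheets give
rows of −2/−1/+1/+2 isotope percentages; `impurity_from_isotopes()`
converts them, treating offsets as positions in reporter mass order and
dropping mass that falls outside the plex. One fixed internal convention
with an explicit converter avoids silent transposition errors. Negative
solution components can occur at low signal; they are physically
meaningless, are clipped to zero, and — being indistinguishable from
not-detected — recorded as missing. Only fully observed PSMs are corrected
by default (`partial = TRUE` solves the observed sub-system instead).
Validation requires column sums in $[0.8, 1.05]$ and a finite condition
number; correction and the interference filter commute under this model,
and the pipeline corrects first.

**Filtering and rollup.** PSMs *exceeding* 50% isolation interference are
excluded, so the boundary value 0.50 is retained; the threshold is
configurable. Protein abundance per channel is the *sum* of corrected
reporter intensities over the protein's PSMs — the dominant TMT convention
— with absent values contributing nothing and a cell missing only when all
of its PSMs are absent. Peptides mapping to more than one protein are
excluded (razor-peptide assignment is out of scope). Proteins with
$\ge 50\%$ missing values in either group are removed; the boundary is
inclusive ("missing 50% … removed") with an `inclusive = FALSE` switch, and
no imputation is ever performed: downstream fits simply use each protein's
observed samples. Zero intensities are coerced to missing before the log2
transform (zero is indistinguishable from not-detected, and this avoids
$-\infty$).

**Normalization.** Median subtraction per sample column equalizes loading:
after `median_normalize()` every column's median over present values is
zero. One caveat matters for simulation studies: when channels are already
on a common scale, the per-column sample median is itself an estimate with
sampling error of order $1/(m f(0))$ standard errors ($m$ proteins, $f$
the abundance density at the median). Subtracting it displaces *every*
protein's group contrast by one common constant. With real biological
between-patient variability this is negligible; in near-noiseless
simulations it can exceed the measurement noise and dominate the null
statistics. The operating-characteristic scenarios below therefore run the
pipeline without the normalization step — their simulated channels are
equal-loading by construction — and the normalization contract is verified
separately by its defining property.

## iBAQ

Intensity-based absolute quantification divides a protein's summed
quantified peptide intensity by its number of theoretical tryptic
peptides. The digest cleaves C-terminal to K/R except before proline;
the denominator counts *distinct* fully cleaved peptides of 6–30 residues
(the original iBAQ definition; window and missed cleavages configurable),
because the denominator is a property of the sequence, not of spectral
counting. The numerator sums impurity-corrected, pre-normalization
reporter totals across all channels — iBAQ here describes overall
abundance across the experiment, not per-channel abundance. Proteins with
a zero denominator or zero intensity have undefined iBAQ and are excluded
from rank tables.

## Moderated differential expression

Each protein's log2 abundances are regressed on an intercept, the
old-vs-young indicator (young reference), sex (female reference) and
hypertension status (absent reference), using the samples present for that
protein; a protein is untestable when its reduced design loses full rank
or residual degrees of freedom. With residual variances $s_g^2$ on $d_g$
degrees of freedom, the empirical-Bayes model places a scaled inverse
chi-square prior $\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ over true
variances. The hyperparameters are estimated once, assay-wide, by moment
matching: with $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the excess
of $\mathrm{var}(e)$ over the sampling floor $\psi'(d/2)$ determines $d_0$
through trigamma inversion (Newton iteration), and the corrected mean of
$e$ determines $s_0^2$. When the spread is at or below the floor,
$d_0 = \infty$; in the degenerate case of exactly equal input variances
the common value is returned as $s_0^2$. The moderated statistic uses the
posterior variance $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$,
is referred to a t distribution on $d_g + d_0$ degrees of freedom (normal
when $d_0 = \infty$), and reduces to the ordinary t at $d_0 = 0$. The test
suite cross-checks the whole engine against an independent implementation
(limma) to $10^{-6}$.

**Tail-area FDR.** Adjusted p-values are Storey-type q-values:
$q_{(i)} = \hat\pi_0 \, m \, p_{(i)}/i$ monotonized by a cumulative
minimum from the largest p down, with
$\hat\pi_0 = \mathrm{mean}_\lambda \#\{p > \lambda\}/((1-\lambda)m)$
averaged over $\lambda \in \{0.2, \dots, 0.8\}$ and capped to $[0,1]$ — a
spline-free estimator that is stable at moderate protein counts. Pure
Benjamini–Hochberg ($\pi_0 = 1$) is available and is the automatic choice
below 200 proteins, where $\hat\pi_0$ is noisy. Significance is declared
at adjusted p < 0.05.

Hypertension is absent in all young patients in the motivating design, so
it is partially confounded with age group; the full design remains full
rank because hypertension varies within the old group, and per-protein
rank diagnostics flag any protein whose observed subset breaks this.

## The synthetic-data generator

`simulate_dataset()` emulates the experiment the analysis assumes:

- **Abundances.** Base log2 abundance $\sim N(20, 3^2)$ per protein —
  about six orders of magnitude of dynamic range in log10 across a
  proteome, matching deep-coverage tissue experiments.
- **Differential structure.** `round(de_fraction × n)` proteins (default
  10%) are shifted by ±`effect_size_log2` (default 2) in old samples only,
  half up and half down, the odd one up.
- **PSM counts.** One PSM per sampled peptide, with the per-protein
  peptide count $1 + \mathrm{Poisson}(11)$ (mean 12); the distribution is
  a free choice exposed in the configuration, as protein-level evidence
  depth varies widely between experiments.
- **Measurement model.** Peptide ionization factors are log-normal
  (sdlog 1) and constant across channels within a PSM, so within-PSM
  reporter ratios are abundance-driven — the TMT measurement model.
  Multiplicative reporter noise is log-normal with mean 1 and CV
  `reporter_noise_cv` (default 0.1). Observed reporters are impurity-mixed
  through a supplied matrix, then blended with a background at the PSM's
  interference fraction $f \sim \mathrm{Beta}(2, 8)$:
  $o' = (1-f)\,o + f\,b$, where $b$ is the average of all proteins'
  channel profiles scaled to the PSM's total intensity — the simplest
  model that biases ratios toward 1, which is the known effect of
  co-isolation.
- **Missingness.** Completely at random at rate 0.05 by default; an
  intensity-dependent left-censoring mode is available because the
  mechanism in real data is not known.

What the generator does *not* emulate: biological between-patient
variability beyond the group shift, peptide detectability differences,
retention-time or fractionation structure, and search-engine errors.
Passing tests therefore demonstrate the correctness and calibration of the
computations, not robustness to everything real data can do.

A protein-level shortcut, `simulate_protein_matrix()`, adds Gaussian log2
noise directly to the true matrix, optionally with per-protein variances
drawn from the scaled inverse chi-square prior — i.e. exactly the
moderated-t hierarchical model — and is used for calibration studies where
the noise law must be exact.

## Validation scenarios and problem sizes

The packaged scenarios (also recomputed by `scripts/acceptance.R`) are the
package's chosen study conditions:

- **Null calibration** — 20,000 proteins, 8 vs 8, no differential
  proteins, variances from the $d_0 = 4$, $s_0^2 = 0.05$ prior: the
  fraction of raw moderated-t p-values below 0.05 should sit in the 99%
  binomial band around 0.05, and essentially nothing should pass FDR.
- **Power / FDR / recovery** — 20 replicates of 500 proteins at 10%
  differential with $|\log_2 \mathrm{FC}| = 2$ and reporter CV 0.1 pushed
  through the full PSM-level pipeline. Co-isolation is set to zero and
  missingness to zero in this scenario: interference deterministically
  compresses ratios (see above), so effect-size recovery to ±0.05 is a
  property of the pipeline without that bias; interference behaviour is
  exercised by its own tests. The mean sign-corrected estimated log-FC
  over true differential proteins is compared to the configured effect.
- **Hyperparameter recovery** — 20,000 variances drawn at known
  $(d_0, s_0^2)$ and re-estimated.
- **Round trips and oracles** — 1,000 random PSMs forward-mixed and
  corrected (max error ≤ 1e−9); 500 random sequences digested against a
  character-by-character brute-force oracle; a 12-PSM toy table exercising
  the two 50% rules with exact survivor counts.

These sizes keep the full suite around ten seconds on one CPU while
leaving Monte-Carlo error well inside the asserted bands.

## Numerical choices and edge cases

- Impurity systems are solved by LU (`solve`); singularity is reported
  with the condition number. Random near-stochastic systems round-trip to
  1e−9 when no clipping triggers.
- Ties in the top-k selection for heatmaps break by smaller adjusted p,
  then larger |logFC|, then accession, making the selection deterministic.
- iBAQ rank tables break ties by accession for a stable order.
- Quantiles in box-plot summaries use linear interpolation (type 7).
- Z-scoring uses the sample SD over present values; constant rows map to
  zero rather than NaN.
- Fisher's two-sided p sums hypergeometric masses $\le$ the observed mass
  inflated by $1+10^{-7}$, the convention under which the 0/8 vs 4/8
  hypertension table prints 0.077; degenerate margins give p = 1.
- Percentages in clinical tables round half-up (37.5% → 38%).
- The exact Wilcoxon path is used up to combined n = 20 without ties;
  with ties the normal approximation with tie correction applies.
- PCA uses complete-case proteins with per-row centering and, by default,
  unit scaling (mixed molecule classes live on different variance
  scales); scaling is configurable, and zero-variance rows are dropped
  when scaling.
- All simulation entry points take integer seeds and are byte-reproducible;
  sub-stages derive distinct fixed offsets from the configured seed so the
  same numbers are never reused across draws.

## Known limitations

Shared-peptide handling is exclusion, not razor assignment; PSM-level FDR
and protein inference are assumed done upstream. The tail-area $\pi_0$
estimator is unstable below a few hundred tests (hence the automatic BH
fallback). The generator's interference model blends a single average
background rather than sampling individual co-isolated peptides. Clinical
continuous-variable testing defaults to the exact rank-sum test; the
choice of test for such rows is reported alongside the p-value because
conventions differ between studies.
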