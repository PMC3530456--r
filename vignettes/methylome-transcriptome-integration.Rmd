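---
title: "Methylome-transcriptome concordance: models, defaults and design choices"
author: "epiConcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome-transcriptome concordance: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiConcord)
```

# Overview

epiConcord integrates two-group CpG methylation (Infinium-style beta
values) and expression-array (log2 intensity) profiles to find genes
whose methylation and expression change in concordant directions:
hypo-methylated and up-regulated, or hyper-methylated and down-regulated.
This vignette is the package's own account of the statistics it
implements, the assumptions behind its synthetic-data generator, and the
places where the design was genuinely open.

# Differential methylation

## Data model and masking

A `BetaSet` holds a probe-by-sample matrix of beta values
$\beta \in [0,1]$ (the methylation fraction at a CpG) and a paired matrix
of per-entry detection p-values. Entries with detection $p > 0.05$ are
treated as missing — the comparison is strict, so a boundary value of
exactly 0.05 is retained. After masking, a probe needs at least 3 usable
samples per group (configurable) to stay in the analysis; a pooled
variance from fewer observations is too unstable to test. The number of
dropped probes is recorded in the object metadata and in the pipeline
manifest, so attrition is auditable.

## Per-probe test and DiffScore

Each autosomal probe is tested case vs control with an equal-variance
two-sample t-test on beta values. The platform's native significance
score for differential methylation is reported alongside the p-value:

$$\mathrm{DiffScore} = 10\,\mathrm{sgn}(\Delta\beta)\,(-\log_{10} p),$$

with $\Delta\beta = \bar\beta_\mathrm{case} - \bar\beta_\mathrm{ctrl}$.
Under this transformation $p = 0.05, 0.01, 0.001$ map to
$|\mathrm{DiffScore}| = 13.01, 20, 30$, which is why the conventional
calling gate is $|\mathrm{DiffScore}| \ge 13$ (treated in the array
literature as equivalent to a 5% FDR). The transformation is monotone and
invertible (`diffScoreToP()`); at $p = 0$ or numerical underflow the
score is capped at $\pm 350$, mirroring the usual software output
ceiling (configurable). $\Delta\beta = 0$ gives score 0 by convention.

The original analysis tool's internal test ("Illumina Custom") is
proprietary and unspecified; the pooled t on beta preserves the monotone
p-to-DiffScore relationship all downstream logic relies on. Because beta
values near the boundaries have compressed variance, a logit
(M-value) variant — test on $\log_2(\beta/(1-\beta))$, effects still
reported on the beta scale — is available via `testProbeDM(m_value =
TRUE)`, but is not the default: the headline effect statistic

$$\Delta 5mC\% = 100\,|\bar\beta_\mathrm{case} -
\bar\beta_\mathrm{ctrl}| / \bar\beta_\mathrm{ctrl}$$

is defined on raw beta, and the default keeps test and effect on one
scale. BH q-values across probes are reported next to the DiffScore so
users can gate on an explicit FDR column instead of the ±13 convention.
Group means (and therefore $\Delta 5mC\%$) are computed after masking;
table output rounds to one decimal, half away from zero.

## Gene-level calls

A gene is differentially methylated iff at least one of its autosomal
probes passes the gate. Direction is taken from the probe with maximal
$|\mathrm{DiffScore}|$ — how the original analyses aggregated probes to
genes is not stated anywhere we could find, so this maximal-evidence rule
is a documented package assumption. If two probes tie at the maximal
magnitude with opposite signs, the gene is marked `ambiguous` and
excluded from concordance analysis rather than silently resolved. Probes
annotated to several genes (possible in real annotations, not produced
by the simulator) contribute their statistics to every listed gene.

# Differential expression

The expression matrix is consumed already summarised per gene and
log2-scaled; normalisation of raw arrays is upstream of this package.
`quantileNormalize()` exists to condition synthetic data (columns are
mapped onto the row-mean reference distribution with first-occurrence
tie assignment, making the defining property — identical sorted column
multisets — exact).

## Intensity-based moderated t

With a handful of samples per group, per-gene variance estimates are
noisy, and on expression arrays the variance depends systematically on
intensity. The moderated test borrows strength across genes *locally in
intensity*:

1. pooled per-gene variances $s_g^2$ (residual df $d = n_1 + n_2 - 2$)
   are smoothed against mean intensity $A_g$ by tricube-weighted local
   linear regression (`loess`, span 0.3, degree 1) of $\log s_g^2$;
2. the fitted curve is bias-corrected by the mean of a log chi-square
   variate to give the prior curve $s_0^2(A)$;
3. the prior degrees of freedom $d_0$ come from moment matching on the
   log scale: $\mathrm{Var}[\log s_g^2 - \log s_0^2(A_g)] =
   \psi'(d/2) + \psi'(d_0/2)$, solved by Newton inversion of the
   trigamma function. When the observed spread does not exceed the
   chi-square noise floor, $d_0 = \infty$: the data carry no evidence of
   gene-specific variance beyond the trend, and the prior curve is used
   alone.

The moderated statistic is
$\tilde t_g = \Delta\bar x_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ with
$\tilde s_g^2 = (d_0 s_0^2(A_g) + d s_g^2)/(d_0 + d)$ and $d_0 + d$
degrees of freedom. Two limits anchor the implementation and are tested
numerically: $d_0 = 0$ recovers the ordinary pooled t exactly, and
$d_0 \to \infty$ uses only the prior curve. The span (0.3) and all
constants are arguments, not magic numbers. The suite also cross-checks
the p-values against an independent established empirical-Bayes
implementation (limma with an intensity trend) at rank-correlation level;
the two methods differ in smoother details, so exact agreement is neither
expected nor asserted.

Genes are called at BH FDR $\le$ 10% (`callDEGs`), the conventional
discovery threshold for this design. Fold changes are reported both as
$\log_2$ differences and in the signed array-table convention
(`signedFoldChange`): the linear ratio $r$ when $r \ge 1$, otherwise
$-1/r$, so magnitudes are always $\ge 1$ and down-regulation reads as a
negative fold. This convention is fixed by the published validation
tables the package reproduces (e.g. a ratio of 0.35/1.38 printing as
−3.9). Table rounding is one decimal, half away from zero.

# Concordance

Genes called in both layers are joined by exact, case-sensitive symbol
match — no aliasing service is consulted, because none was specified for
the original analyses; a warning can list one-layer-only symbols. The
2×2 direction mapping is total: hypo+up → `hypo_up`, hyper+down →
`hyper_down` (concordant), hyper+up and hypo+down (same-direction). The
same-direction classes are retained in output with their labels rather
than dropped — same-direction genes are a recognised biological
phenomenon (intragenic methylation, hydroxymethylation that beta arrays
cannot distinguish) and discarding them would hide over half the common
genes in a typical run. Only `hypo_up`/`hyper_down` count as concordant.
Concordance uses calling-time thresholds; nothing is re-thresholded at
integration.

# Enrichment

Over-representation uses the hypergeometric upper tail $P(X \ge k)$ for
an overlap of $k$ query genes with a $K$-gene set in a universe of $N$;
the universe defaults to the genes on the assay annotation — the standard
background for array studies, since only assayed genes could have been
called. BH correction across tested terms at $\alpha = 0.05$. Some
annotation tools instead use the deliberately conservative EASE variant
($k - 1$ in the tail); it is available behind `ease = TRUE` but is not
the default, because the plain tail is the textbook test and the original
tool's database-dependent p-values are not reproducible anyway. A
two-sided Fisher exact test (`fisher2x2`) covers 2×2 frequency
comparisons such as literature-citation rates.

# Targeted validation statistics

* `iqrOutlierFilter`: the default window is **median ± 1.5×IQR**, exactly
  as the motivating assay figure states — note this is narrower than the
  conventional Tukey fences ($Q_1/Q_3 \pm 1.5\,\mathrm{IQR}$), which are
  available behind a flag. Quartiles use linear interpolation (type 7);
  the convention matters because the exclusion set can depend on it. The
  rule is applied once, not iterated: re-filtering a filtered vector can
  remove further points (the window shrinks with the IQR), so iterated
  application would not terminate at the first pass and is deliberately
  not implied.
* `twoSampleT` / `twoSampleTSummary`: equal-variance two-sided t from raw
  values or from published mean/SEM/n summaries; the two agree to
  numerical precision on the same data. The summary form assumes equal
  variances with pooled df $n_1 + n_2 - 2$ (Welch behind a flag).
* `ddctFoldChange`: $2^{-\Delta\Delta Ct}$ with per-sample replicate
  averaging before $\Delta Ct$; exact on noiseless input by
  construction.
* `regionMeanMethylation`: mean across CpG sites per sample, then group
  mean ± SEM, plus per-site summaries.

# The synthetic-data generator

No raw arrays from the motivating study are deposited, so the simulator
is the package's test bed: it emulates the *structure* of such a study
with known planted truth.

Defaults are the study conditions where those are known, and generic
Infinium-like values where the study gives none (per-probe beta
distributions are never published at that granularity, so they cannot be
calibrated to it):

* 12 cases vs 11 controls; 1.9 probes per gene (the 27K platform's
  27,578 CpG / 14,495 gene density); 5% of genes on sex chromosomes.
* Baseline betas from a three-mode Beta mixture (low ≈ 0.1, high ≈ 0.85,
  minor intermediate ≈ 0.5; weights 0.55/0.35/0.10, configurable) —
  the characteristic bimodality of Infinium data that any caller must
  tolerate. Per-sample draws are Beta with concentration 50.
* Planted effects are additive on the beta scale ($\Delta\beta = 0.15$ by
  default), not on logits, because $\Delta 5mC\%$ is defined on raw
  beta. Effects that would push a mean outside (0, 1) are clipped and the
  realised effect recorded in the truth. 15% of autosomal probes carry
  effects (the study's reported fraction of significant CpGs), planted
  gene-wise so gene-level truth is unambiguous and only on autosomal
  genes — non-autosomal probes are excluded from calling by design, so
  planting there would make truth unrecoverable by construction rather
  than by method failure.
* Detection failures are independent across entries at rate 0.01;
  probe-level correlated failure is out of scope of the generator.
* Expression: baselines uniform over `expr_base_mean` ± 4 on the log2
  scale; residual SD $0.5\,e^{-0.1(A - \bar A)}$, giving the decreasing
  variance-intensity trend the moderated t's prior must learn; planted
  $|\log_2 FC| = 1$ on 10% of genes.
* 10% of genes are concordant (half hypo_up, half hyper_down); the extra
  DM-only and DE-only genes are disjoint, so the planted concordant set
  is exactly the set of genes carrying both effects and recovery scoring
  is unambiguous.
* One RNG stream per modality, derived from the master seed, so
  modalities can be regenerated independently; identical configuration
  and seed give byte-identical output.

What passing the recovery tests shows — and what it does not: the
generator has no batch effects, no probe-type (Infinium I/II) chemistry,
no cell-type mixture, no correlated detection failure, and Gaussian
expression noise. Recovery of ≥ 80% of planted concordant genes with
≤ 20% false concordance (at 2,000 probes / 1,000 genes / 12 vs 12, the
scale the test suite runs) demonstrates the pipeline's logic and power
under clean conditions; it does not certify performance on real tissue
data, where those unmodelled features dominate.

# Numerical choices and degenerate inputs

* Zero pooled variance in a t-test: $p = 1$ when the means agree;
  when they differ the probe-level test assigns the smallest
  representable p (the DiffScore cap absorbs it) and the standalone
  `twoSampleT` raises an error, since a scalar "infinite t" would be
  misleading.
* $\beta_\mathrm{ctrl} = 0$ makes $\Delta 5mC\%$ undefined: NA with a
  warning, never Inf.
* BH ties take the maximum rank within a tie block (standard step-up);
  the implementation is checked against a brute-force evaluation of the
  definition for every short vector.
* Rounding for table reproduction is half-away-from-zero
  (`roundHalfAway`), matching how published tables print 4.375 as 4.4;
  R's default banker's rounding would print 4.4 differently.
* All seeds are plain integers below $2^{31}$; per-modality seeds are
  derived by small offsets from the master seed.

# Scope and limitations

* The package consumes summarised matrices: no IDAT/CEL parsing, RMA,
  probe-set remapping or array-QC exclusion, and no normalisation of
  intensities to beta values.
* Beta arrays of this generation cannot distinguish 5mC from 5hmC; the
  "methylation" direction is the composite signal.
* The genome-scale counts reported in the motivating study (thousands of
  called genes) are not reproducible without its undeposited raw arrays;
  the package's fixtures are the published per-gene tables, and
  everything genome-scale is exercised on synthetic data.
* Enrichment results depend entirely on the user-supplied GMT; no
  annotation database ships with the package.
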