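---
title: "Signature activity scores and targeted lipidomics QC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature activity scores and targeted lipidomics QC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siglip)
```

# Scope

siglip implements two analysis tracks that recur in studies relating a gene's
expression to pathway activity in tumor cohorts and to metabolic adaptation in
cell models: per-sample gene-signature activity scoring for bulk RNA-seq, and
post-acquisition quality control for targeted (MRM) lipidomics. Both tracks
come with seeded simulators that generate data with the exact statistical
structure the methods assume, so that every stage can be tested against known
ground truth.

# The AR signaling score

A sample's androgen-receptor signaling activity is summarized as the Pearson
correlation between its log2(FPKM) expression over a fixed set of AR-regulated
genes and a *reference vector* — the expression profile those genes take in an
androgen-stimulated reference condition. Writing $x_{gi}$ for the log2
expression of signature gene $g$ in sample $i$ and $\rho_g$ for the reference
entry,

$$ \mathrm{AR}_i = \mathrm{cor}\big( (x_{gi})_{g \in S},\; (\rho_g)_{g \in S} \big), $$

so $\mathrm{AR}_i \in [-1, 1]$: a sample whose signature profile matches the
stimulated reference scores near 1, and one whose androgen-repressed genes are
up while induced genes are down scores negative. The score is invariant to
per-sample affine rescaling $a x + b$ ($a > 0$) of the expression values and
flips sign when $a < 0$; the test suite asserts this exactly.

Assumptions worth keeping in mind: the score uses the *shape* of the profile,
not its level, so global normalization differences between samples are
harmless, but it presumes the reference vector's sign structure transfers to
the cohort's platform. Missing signature genes are dropped pairwise (gene and
reference entry together) and recorded per sample in `flags`; by default at
least 80% of the signature (`ceiling(0.8 * n)`, i.e. 24 of 30 genes) must be
present, else scoring aborts with the missing genes named. No re-standardization
of expression across samples is applied before scoring — the definition does
not call for any.

The 30-gene signature shipped in `example_ar_signature()` is a **synthetic
fixture**: the gene symbols are well-known AR-regulated genes (KLK3, KLK2,
TMPRSS2, FKBP5, ... with OPRK1 and SERPINI1 androgen-repressed), but the
reference values are invented for testing and do not reproduce any published
vector. Real analyses should load their signature with `read_signature()`.

# The mTOR activation score

Per sample, a two-sample t statistic contrasts the sample's log2 expression of
genes *up-regulated on mTOR pathway activation* against genes *down-regulated
on activation* — the genes, not the samples, are the observations:

$$ t_i = \frac{\bar{x}_{U,i} - \bar{x}_{D,i}}{\mathrm{se}}, \qquad
   \mathrm{mTOR}_i = |t_i|. $$

Two design choices are deliberately configurable because the originating
definition of the score leaves them open:

* **t variant.** The default is the pooled (Student) statistic; Welch is
  available via `variant = "welch"`. When exactly one gene group has zero
  variance the pooled statistic is undefined, and the implementation falls
  back to Welch with a flag. When both groups are constant and equal the score
  is 0 with flag `degenerate_variance`.
* **Absolute value.** The published convention takes $|t|$, which makes high
  scores ambiguous between strong activation and strong suppression. The
  signed statistic is therefore always retained in the `signed_score` column,
  and simulation-recovery checks correlate the *signed* score with the latent
  activity.

The up/down sets in `example_mtor_sets()` are likewise synthetic: a
growth/biosynthesis up set and an autophagy–lysosomal (TFEB program) down set,
plausible in membership but not any published list.

# Association statistics

`correlate()` reports the Pearson coefficient, its square, and the Spearman
rank coefficient (average ranks at ties) after pairwise deletion; the
two-sided p-value for the requested coefficient uses
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. At very small $n$
this t approximation deviates from the exact permutation null; the test suite
compares it against an exhaustive permutation oracle at $n \le 7$ and treats
the two as agreeing when they make the same accept/reject call at
$\alpha = 0.05$, excusing only boundary cases where both p-values lie within
0.03 of the threshold — at $n \le 7$ the permutation null is granular
($\ge 2/n!$) and the approximation does not claim to order boundary cases.

`group_ttest()` is a thin, validated wrapper around the standard two-sample t
test (Welch by default, matching common practice for unequal-variance group
comparisons) that additionally reports group means and the fold change of
means. Fold changes are ratios of means, not means of ratios. The degenerate
zero-variance case (which `stats::t.test()` refuses) is defined by its limit:
equal means give $t = 0, p = 1$.

`fold_change_ddct()` implements relative qPCR quantification,
$\mathrm{fold} = 2^{-\Delta\Delta C_t}$ with
$\Delta C_t = \overline{C_t}^{\mathrm{target}} - \overline{C_t}^{\mathrm{housekeeper}}$
per condition; replicate SDs propagate through the means into a fold range.
`densitometry_normalize()` encodes the Western-blot convention
$(\mathrm{band}/\mathrm{hk}) / (\mathrm{band}_{\mathrm{ctrl}}/\mathrm{hk}_{\mathrm{ctrl}})$,
which maps the control lane to exactly 1 and is scale-invariant. No
multiple-testing correction is applied in this layer; per-lipid BH q-values
live in the lipidomics track, where many hypotheses are tested at once.

# The lipidomics QC chain

The pipeline takes long-format MRM peak-area tables (feature × injection) with
sample-type annotations and processes them in a fixed order:

1. **Pooled-QC drift correction.** Pooled QC samples injected periodically
   (every 5–6 samples, plus run-start and run-end brackets) trace instrument
   sensitivity over time. Per feature, a smoother — LOWESS by default, a cubic
   smoothing spline as alternative — is fitted to QC peak area versus
   injection index, and every row's area is divided by
   $\hat{f}(\mathrm{index}) / \mathrm{median}(\mathrm{QC})$. Outside the
   bracketing QCs the nearest fitted value is held (no extrapolation), factors
   are floored at a configurable epsilon, and features with fewer than 4 QCs
   pass through flagged `uncorrectable`.

   Two numerical guards matter here. Local fits always span at least 4 QC
   points (`f_eff = max(span, 4/n_qc)`): with narrower windows the smoother
   interpolates the QC measurements exactly, the corrected QC dispersion
   collapses to zero, and the downstream CV filter is blinded. And robustness
   iterations are disabled: at these window widths they treat genuine drift
   curvature as outliers and leave isolated drifted features uncorrected.
   Screening erratic features is the CV filter's job, not the smoother's.

2. **CV filter.** Per feature, the coefficient of variation of the (corrected)
   QC areas — sample SD over mean, raw scale, as is conventional for
   metabolomics QC — is compared to a 30% threshold. Removal uses a strict
   inequality: a feature at exactly 30.0% is retained. Features with fewer
   than 2 QCs cannot be assessed and are retained with a flag.

3. **Dilution linearity.** A diluted-QC series (100, 50, 25, 12.5, 6.25% of
   pooled QC) probes response linearity. The traditional visual inspection is
   operationalized as Pearson $r \ge 0.9$ with positive slope on at least 4
   points; the threshold is configurable and the full per-feature report is
   written, so a reviewer can still inspect it.

4. **Protein normalization.** Biological sample areas are divided by the
   sample's total protein (µg), making units area/µg; pooled QCs have no
   per-sample protein value and are exempt. Because all stages are
   multiplicative, protein normalization and drift correction commute to
   floating-point tolerance (asserted in tests).

5. **Aggregation and differential abundance.** Lipid names are parsed by the
   shorthand grammar (`"PI 38:4"` sum composition; `"PI(18:0/20:4)"` chain
   level, chains summing to the total), class totals are per-sample sums over
   member species, and two-group comparisons report the fold change of group
   means, percent change, a two-sided t test (Student by default here,
   matching the originating study's stated statistics; Welch available) and
   BH q-values across keys. Class rows additionally summarize member species:
   the mean per-species percent change and the count of species with fold
   > 1. Both the class-total fold and the species-average percent change are
   reported because the two summaries answer different questions (the former
   weights abundant species, the latter weights species equally) and need not
   agree.

# The simulators

`gen_expression()` draws per-sample latent activities
$a_i, m_i \sim \mathcal{N}(0,1)$ and builds genes as
$\mu_g + \lambda_g a_i + \varepsilon$ (signature genes, loadings proportional
to the reference entries so the reference is the noiseless activated profile),
$\mu_g \pm m_i + \varepsilon$ (mTOR up/down genes), a focal gene
$\mu - \gamma a_i + \varepsilon$ with a planted *negative* AR coupling
(default $\gamma = 0.8$), and pure-noise background genes. Defaults
$\varepsilon \sim \mathcal{N}(0, 0.5^2)$ and baselines
$\mu_g \sim \mathcal{N}(5, 1)$ are typical log2(FPKM) magnitudes for
moderately expressed genes. In the noiseless limit the per-sample score is a
strictly increasing function of $a_i$, so rank recovery is exact — a property
the tests assert. Presets `"tcga-like"` (n = 333) and `"su2c-like"` (n = 149)
mirror common primary and metastatic cohort sizes.

`gen_lipid_run()` emulates the run design end to end: randomized sample
injection order; pooled QCs (true value: mean of the pooled samples' extract
amounts) every `qc_every` ∈ {5, 6} samples plus brackets; a five-point
dilution series appended at the run end; per-feature smooth drift; and
mean-one lognormal measurement noise. Drift curves are a linear ramp plus one
low-frequency (one cycle per run) sinusoid on a fixed exponent scale, so
`drift_amplitude` *bounds* the max/min sensitivity ratio; a per-feature
rescaling to the exact ratio was rejected because it turns near-flat raw
curves into fast oscillations that no QC schedule could track. Irreproducible
features are constructed with an *alternating* multiplicative QC pattern
standardized to log-SD $\sqrt{\log(1 + \mathrm{CV}^2)}$: alternation is
orthogonal to every smooth drift curve, which is exactly what "irreproducible
by construction" must mean — i.i.d. noise would be partially absorbed by any
smoother.

The `"lncap-lipid-like"` preset generates the full 273-species panel with six
replicates per condition (complete medium versus androgen deprivation), 2×
drift and 5% noise, and plants the class effect the emulated study reports:
six of the seven PI species increase and one decreases, with per-species folds
(0.85, 2.2, 2.4, 2.6, 2.8, 3.0, 3.02) whose percent changes average exactly
+141%. The seven PI species are excluded from the irreproducible draw, since
the emulated design has all assessed PI species surviving QC.

What the simulators do *not* emulate: count-level sampling noise and
library-size effects in RNA-seq; gene–gene correlation beyond the two latent
factors; batch structure; retention-time shifts, co-elution, or
detector-saturation nonlinearity in LC-MS; and missing (non-detected) peaks.
Passing recovery tests therefore demonstrates correctness of the computations
under the generative model, not robustness to every artifact of real data.

# Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to make each property identifiable
at desk scale: oracle equivalence on 1000 random small instances; latent
recovery on 20 replicates of the n = 333 preset; the drift/CV checks on a run
with 15 samples per group, which yields 8 pooled QCs — enough for LOWESS at
span 0.5 to fit 4-point windows — while the fold-recovery check keeps the
emulated study's 6 replicates per group. In the drift-reduction check,
"drifted" means a realized QC-range drift ratio of at least 1.2 (about 95% of
the panel); features whose drawn curves happen to be near-flat carry no drift
signal to remove. Expression input uses a pseudocount of 1.0 before log2
(standard for FPKM; configurable, since published pipelines differ). Gene
identifiers are matched case-insensitively after trimming. Correction factors
are floored at $10^{-6}$; fold changes divide means, so groups with zero mean
yield `NA` rather than infinities.

# Known limitations

* The AR score presumes the cohort's expression is on (or monotone with)
  log2(FPKM); mixing quantification units across samples distorts scores.
* $|t|$ as an activation score cannot distinguish activation from
  suppression; use `signed_score` when direction matters.
* The CV filter's strict-inequality boundary and the 30% threshold are
  conventions, not optimality claims; both are parameters.
* Dilution linearity by Pearson r rewards any monotone response at high r and
  can pass mildly saturating features; the slope and the full series are
  reported for inspection.
* Regioisomeric phosphoinositides (e.g. PI-4,5-P2 versus PI-3,4-P2) are not
  resolvable from MRM class/composition names and are out of scope.

# A worked desk-scale example

```{r example}
sim <- gen_expression(n_samples = 50, seed = 1)
ar <- ar_signature_score(sim$expr, example_ar_signature())
cor(ar$score, sim$truth$latent_ar, method = "spearman")

correlate(sim$expr$values["PIP4K2A", ], ar$score,
  x_name = "PIP4K2A", y_name = "ar_score"
)[, c("r", "spearman_rho", "p_value")]

run <- lipid_preset("lncap-lipid-like", seed = 1)
res <- run_lipidomics_pipeline(
  list(table = run$table, group_a = "CA", group_b = "CA_AD"),
  file.path(tempdir(), "vignette-run")
)
res$class_diff[res$class_diff$key == "PI",
  c("key", "mean_fold", "avg_species_percent_change",
    "n_species_increased", "n_species", "p_value")]
```
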