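---
title: "Multi-batch TMT differential expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-batch TMT differential expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtpipe)
```

# The analysis problem

Isobaric TMT labelling quantifies up to 11 samples in one LC-MS/MS run, but
a case-control study of 45 subjects (say 15 PSP, 15 PD, 15 healthy
controls) does not fit in one run: it must be split into multiple batches,
here 5 batches of 11-plex. Two channels of every batch are spent on
bridging and diagnostics — a master pool (MP, an equal-amount mixture of
all subject samples) and a pooled QC aliquot — leaving 9 subject channels
per batch. Reporter-ion intensities are comparable *within* a run but not
*across* runs, so the central statistical problem is to put five batches on
one scale, quantify what technical variation remains, and then test ~2,000
complete-case proteins for differential abundance without drowning in
false positives.

`tmtpipe` implements that full chain as composable stages with a strict
scale ordering (`raw -> mp_ratio -> median_ratio -> log2 -> zscore ->
batch_corrected`), each stage asserting its input scale so illegal
compositions fail loudly.

# Normalization chain

1. **MP-ratio bridging** (`mp_normalize`). Every subject and QC value is
   divided by its own batch's MP value for the same protein. Because the
   MP is the same physical sample in every batch, this removes run-level
   intensity differences. Division by a missing or zero MP propagates
   missingness rather than inventing a value.
2. **Per-protein median scaling** (`median_scale`): each protein row is
   divided by its median relative abundance, centering every protein at 1.
3. **log2 and z-score** (`log2_zscore`): log2, then per-protein centering
   and scaling to sample SD 1 (denominator n − 1, the Perseus convention).
   Non-positive cells cannot be log-transformed and become missing with a
   warning; constant rows become all-zero with a warning rather than NaN.
4. **Complete-case filter** (`filter_missing`): proteins with any missing
   value across the retained samples (QC included) are dropped. The
   pipeline never imputes: in batch-level TMT missingness a protein absent
   from one run is absent from all 11 of its channels, and imputing a
   whole batch would manufacture 20% of the data for that protein.
5. **Empirical-Bayes batch correction** (`combat_correct`), below.

One ordering in this chain was genuinely open: whether z-scoring precedes
or follows batch correction. We apply z-scoring first and correct the
z-scored matrix, the order in which the stages are stated for the study
design this pipeline models; since both operations are per-protein
location-scale adjustments, the group-difference statistics downstream are
hardly affected.

# Batch correction

`combat_correct` is an in-package implementation of the parametric
empirical-Bayes location-scale model of Johnson et al.: per protein $i$
and batch $b$,

$$ y_{ibs} = \alpha_i + X\beta_i + \gamma_{ib} + \delta_{ib}\,\epsilon_{ibs}, $$

where $\gamma_{ib}$ and $\delta^2_{ib}$ are protein-specific additive and
multiplicative batch effects shrunk toward batch-level normal and
inverse-gamma priors, estimated by iterating the conditional posterior
means to convergence (tolerance $10^{-6}$ on the largest absolute change,
cap 1000 iterations; the fit typically converges in < 15). The fitted
`BatchCorrectionModel` (per-batch gamma/delta estimates, raw and shrunken,
plus the EB hyperparameters) is returned and can be dumped with
`write_combat_model` — one reason the algorithm is implemented here rather
than delegated: the model internals are part of the package's contract,
and the test suite cross-checks the corrected matrices against the
reference `sva::ComBat` implementation to < 1e-3.

Two choices are deliberate defaults rather than forced:

* `preserve_groups = TRUE` puts the biological group factor into the
  covariate design so that group differences are not absorbed into batch
  terms. With a randomized, balanced channel layout the difference is
  small, but preserving the design is the safer default.
* The parametric (not nonparametric) EB variant is used: it is closed-form
  testable and is the overwhelmingly common default in practice.
* QC channels are diagnostics, not biology: they are excluded from the
  correction design and dropped from the corrected matrix, which therefore
  contains exactly the subject samples.

A single-batch input is returned unchanged — with one batch there is
nothing to correct, and the EB machinery is degenerate there by
construction.

# QC metrics

* `qc_cv`: per-protein CV (SD/mean) across the QC replicates, computed on
  the *linear* relative-abundance stage (`median_ratio`) — a CV of
  log-scale or z-scored values is meaningless because the mean is ~0.
* `qc_sn`: per-protein signal-to-noise, SD(subjects)/SD(QCs), computed on
  the log2 scale where SDs are variance-stabilized. The ratio is invariant
  to per-protein rescaling, so z-scored input gives identical values.
* `pca_batch_check`: sample-space PCA with `batch_eta2`, the between-batch
  share of the PC1–PC2 score variance — a single number summarizing the 2D
  PCA plot one draws before and after correction. It is computed on the
  first two PCs only, mirroring how batch effects are visually assessed.

The stage on which CV and S/N are computed is exposed rather than hidden
because different software reports these on different stages; the defaults
above are the ones under which each metric is interpretable.

# Differential expression, twice

Both procedures run per contrast on the corrected matrix and are seeded,
so every number is reproducible.

## SAM-style moderated t with permutation FDR

`sam_qvalues` computes the moderated statistic
$d_i = \bar{x}_{iA} - \bar{x}_{iB} \,/\, (s_i + s_0)$ with the pooled
standard error $s_i$ and fudge factor $s_0$ (default 0.1, the common
volcano default; $s_0 = 0$ recovers the ordinary t exactly, which the
tests assert). The null is built from random relabelings of the pooled
samples; for every observed threshold $\theta$,

$$ \widehat{FDR}(\theta) =
   \frac{\mathrm{median}_{perm}\,\#\{|d^*| \ge \theta\}}
        {\#\{|d| \ge \theta\}} \wedge 1 , $$

and a protein's q-value is the minimum $\widehat{FDR}$ over thresholds at
or below its own $|d|$ — monotone non-increasing in $|d|$ by
construction. The median (not mean) across permutations makes the
numerator robust to occasional extreme permutations; both are standard,
the median is the default here. If more permutations are requested than
distinct relabelings exist, all distinct relabelings are enumerated
instead (the suite verifies the 3-vs-3 case against exhaustive
enumeration). `sam_boundary` exports the curved volcano significance
frontier $|fc| = d_{cut}(s + s_0)$ in (log2FC, −log10 p) coordinates.

## Bootstrap-ROC

`broc_qvalues` computes, per protein, the Mann–Whitney AUC (midrank ties)
under stratified bootstrap resampling — mean and SD over resamples — on
both the observed labels and label-permuted data, then converts the two
AUC distributions into q-values by a threshold sweep from the extremes
inward: $q(\theta) = N_{null}(\theta)/N_{obs}(\theta)$, clipped to [0, 1]
and made monotone toward AUC = 0.5; up- (AUC > 0.5) and down-lists are
swept separately, and AUC = 0.5 exactly gets q = 1. Two things are worth
stating explicitly:

* The ratio is null-over-observed counts, the standard empirical-FDR
  direction. Written the other way around the quantity would *grow* as
  thresholds loosen and could not be used with a q < 0.05 cut.
* The null arm uses the same bootstrap machinery as the observed arm
  (default one permutation pass, configurable with count averaging over
  passes), keeping the two arms symmetric.

Inside the matrix sweep, one stratified resample of the sample columns per
bootstrap iteration is shared across proteins; each protein's marginal
bootstrap distribution is identical to per-protein independent resampling
(which `bootstrap_auc` still does for single proteins), and the sharing is
what makes 2,000-protein runs with hundreds of resamples practical.

## Consensus

`consensus_select` intersects the two significant sets
(`sig_consensus = sig_sam & sig_broc`, default q < 0.05 for both) and
reports the Venn decomposition. Requiring agreement between a
location-shift test and a rank-separation statistic guards against
type-I calls that only one view of the data supports.

# Overrepresentation

`enrich` is a generic GMT-based overrepresentation test: per set, the
count of differential genes, `ph` (set size within the background
universe), `percent = 100·count/ph`, and a one-sided Fisher exact
p-value; the conservative EASE variant (overlap decremented by one under
the same hypergeometric margins) is a flag. The universe defaults to all
quantified proteins' gene symbols (upper-cased, duplicates collapsed) —
testing brain-derived proteins against a whole-genome background would
inflate every neuronal pathway. Raw p-values are reported by default
(Benjamini–Hochberg via `p_adjust = TRUE`) because the printed tables this
mirrors report raw p.

# Power and sample size

`sample_size` solves the two-sided two-sample t-test power equation on the
exact noncentral t distribution: power
$= P(|T'_{2n-2}(d\sqrt{n/2})| > t_{1-\alpha/2,\,2n-2})$, root-found in $n$
(fractional df during solving, as standard power software does) to a power
error below $10^{-8}$. At the design point of this pipeline's motivating
study — $\alpha = 10^{-4}$, power 0.8, $\sigma = 0.208$,
$\delta = \log_2 1.5 = 0.585$, so $d = 2.81$ — the solution is $n = 9.4$
per group, the calculation behind a 15-per-group design. The exact
noncentral t matters: a normal approximation misses this value at such a
small $\alpha$.

# The synthetic-data generator

`simulate_tmt` emulates the 5-batch 11-plex design so every downstream
stage is testable with known truth: per protein and subject,
$y = \mu_i + \beta_i(g) + \gamma_{ib} + \delta_b e$, with planted effects
$|\beta| = \delta$ present with probability `frac_de` per non-reference
group (random sign), protein-specific additive batch effects
$\gamma_{ib}$, batch-level noise scale factors $\delta_b$, batch-level
dropout (a protein missing from a batch loses all 11 channels), the MP
channel as the exact linear-scale pooled mean, the QC channel as a pooled
replicate with technical noise only, and randomized channel assignment
(MP fixed in the 11th channel). All draws come from one seeded stream.

Defaults are the study conditions: 15 subjects per group in 3 groups, 5
batches, `delta = 0.585`, `sigma = 0.208`. Values the design does not pin
down were chosen once as realistic for this platform and are not tuned:

* `batch_shift_sd = 0.3`, `batch_scale_sd = 0.1` — moderate batch effects
  of the size that MP bridging visibly fails to remove in practice.
* `p_batch_dropout = 0.05` — under independent batch-level dropout this
  reproduces the characteristic common-to-per-batch identification ratio
  (~0.8) of a 5-batch TMT study. Absolute identification counts would
  need *correlated* missingness (abundant proteins are seen everywhere),
  which the batch-level Bernoulli model deliberately does not attempt.
* `sigma_tech = 0.10` — QC technical noise below the biological+technical
  subject SD of 0.208, so S/N ratios sit above 1 as they do in a healthy
  experiment.

The additive batch effect is drawn per protein×batch — the ComBat
generative model — rather than as one scalar per batch. A scalar shared by
all channels of a batch would be cancelled *exactly* by the MP-ratio step
(subject/MP division removes any common term), leaving the correction
stage untestable; protein-specific effects are also what MP bridging
demonstrably fails to remove in real multi-batch TMT data.

What the generator does **not** emulate: peptide-level quantitation,
ratio compression from co-isolation interference, isotopic impurity,
intensity-dependent missingness, or non-normal heavy-tailed residuals.
Passing recovery tests on this generator therefore demonstrates
correctness of the statistical machinery under its assumed model, not
robustness to every pathology of real reporter-ion data.

# Numerical choices and degenerate inputs

* Missing is `NA`, distinct from a measured 0; zero/missing MP values
  propagate missingness.
* Ties in AUC use midranks, so `auc(A,B) + auc(B,A) = 1` exactly.
* Zero pooled variance: t = 0, p = 1 with a warning (not NaN).
* Zero QC SD: S/N reported as `Inf`, kept distinct from large finite
  ratios.
* All-zero-variance PCA input degrades to zero scores with a warning.
* EB iteration: absolute-change tolerance 1e-6, cap 1000.
* q-values are clipped to [0, 1] and made monotone by cumulative extremes
  in the sweep direction, so thresholding at any level gives nested sets.
* Seeds: every stochastic stage takes an explicit seed; `run_pipeline`
  derives independent per-stage substreams from one master seed, so stage
  re-runs do not depend on execution order and a fixed seed yields
  byte-identical summary output.

# Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
assertions sharp while keeping a full run in tens of seconds: null
calibration at 2,000 proteins with 250 permutations and 200 bootstrap
resamples (scaled down from the 1,000 resamples a production run would
use); effect recovery at 1,000 proteins with 30% planted effects at the
design point; batch-correction checks at 600 proteins with
`batch_shift_sd = 0.5`; determinism on a 400-protein end-to-end run. These
are the package's own choices of simulation size and are stated here so
the reported operating characteristics can be tied to the exact
conditions that produced them.

# Known limitations

* The correction stage requires a complete matrix; studies with heavy
  batch dropout lose those proteins entirely (no imputation by design).
* The bootstrap-ROC q-value is an empirical count ratio: its resolution is
  limited by the number of proteins in each direction list, and with a
  single permutation pass the null counts are themselves noisy (raise
  `n_permutation_passes` for stability).
* Enrichment p-values are conditional on the chosen universe; with the
  quantified-proteins default, terms poorly covered by the platform are
  untestable rather than significant.
* Only balanced two-group contrasts of the pooled-variance form are
  implemented; no paired, multi-class, or covariate-adjusted designs.
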