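---
title: "Modelling the genomic determinants of 5'UTR length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the genomic determinants of 5'UTR length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrlen)
```

## The question and the model

The 5' untranslated region (5'UTR) of a eukaryotic mRNA sits between the
transcription start site and the main start codon. Its length is shaped by two
opposing forces: stochastic gain and loss of transcription initiation signals
tends to lengthen or shorten it drift-wise, while selection against deleterious
sequence content — above all upstream AUGs and upstream open reading frames
(uORFs), which depress translation of the main coding sequence — constrains
elongation. `utrlen` quantifies how much of the within-species variation in
5'UTR length a small set of per-sequence composition features can explain.

The response is $Y = \log_{10} L$, the log length of each 5'UTR, and the model
is ordinary multiple linear regression

$$Y = \beta_0 + \sum_{i=1}^{9} \beta_i X_i + \varepsilon,$$

where the candidate predictors $X_i$ are: the G+C content; the
observed-to-expected (OE) ratios of the start trinucleotide AUG and the three
stop trinucleotides UGA, UAA, UAG; and the OE ratios of the dinucleotides CG
(methylation-prone), UG (a mutational sink of CG and a codon precursor), and
UU/UA (targets of mRNA-destabilising ribonucleases). A tenth indicator, uORF
presence/absence, can be appended.

For a motif with bases $b_1 \dots b_k$, the expected count in a sequence of
length $L$ with base frequencies $f$ is $L \prod_j f_{b_j}$ (for AUG,
$L f_A f_U f_G$), and

$$\mathrm{OE} = \frac{\text{observed overlapping count}}{L \prod_j f_{b_j}}.$$

OE near 1 means the motif occurs at chance rates; below 1 suggests depletion,
i.e. selection against the motif. Frequencies are per-sequence, because the OE
ratios serve as per-UTR regressors. A closely related statistic,
`minimal_length()`, solves "expected count = 1" for $L$: the shortest sequence
in which the motif is expected at all. Below that length a motif's absence is
uninformative — the motivation for the data-cleaning rule below.

## Feature measurement choices

* **Expected counts use $L$ windows, not $L-k+1$.** The defining formula is
  $L\prod f$; the window-count variant is available via
  `expected_count(..., convention = "windows")` for sensitivity analysis. The
  difference is $O(k/L)$ and negligible at realistic 5'UTR lengths.
* **Overlapping occurrences all count**, the standard convention for CpG-style
  OE statistics.
* **OE is defined as 0 when the expectation is 0** (a required base absent
  from the sequence, which forces the observed count to 0 as well).
* **uORFs**: an AUG, the *first* in-frame stop codon downstream of it
  (ribosome-termination semantics), and at least one non-stop codon in between
  (`stop_start - start >= 6`). uORFs whose stop codon lies in the downstream
  CDS cannot be detected from 5'UTR sequence alone and are deliberately out of
  scope. Coordinates are 0-based half-open; BED export follows BED
  conventions.
* **Alphabet**: DNA input is transparently converted to RNA (T to U); records
  containing ambiguity codes are dropped whole (masking positions would make
  the per-sequence $f_i$ ill-defined) and tallied in a drop report. Records
  shorter than 3 nt cannot support a trinucleotide window and are excluded.
* **One transcript per gene**, chosen uniformly at random under an explicit
  recorded seed, so that genes with many annotated transcripts are not
  over-weighted. Uniform choice is an assumption; the selection happens
  *before* filtering, so the filter sees one row per gene.

## The zero-OE filter

Short 5'UTRs frequently lack one or more of the four start/stop
trinucleotides entirely. A zero OE ratio is then uninformative: it cannot be
told apart whether the motif is absent because of selection or because the
sequence is too short for it to arise by chance. The cleaning rule retains
only rows with **at most one** zero among the four trinucleotide OE ratios
(`apply_zero_oe_filter()`); dinucleotide OEs are never consulted, as
dinucleotide zeros are rare and not the target of the rule.

An alternative hard length cutoff (`apply_length_filter()`, default 30 nt)
exists for comparison: truncating the length distribution visibly skews
log-lengths away from normality, which `length_distribution_report()`
quantifies through a Shapiro–Francia-type statistic (the correlation of the
sorted log10 lengths with standard normal quantiles). The zero-OE rule keeps
the log-length distribution closer to the normality the regression assumes,
which is why it is the default.

## Regression, selection, and importance statistics

Fitting is by QR-decomposition least squares (`stats::lm` under the hood);
rank-deficient designs raise an error naming the collinear columns rather than
silently dropping them. Backward elimination (`backward_select()`) removes one
predictor per step — the one with the largest t-test p value — while that p
value exceeds `alpha = 0.05`, and records every step in a trace. p-value-based
elimination with a single removal per step is the conventional reading of
"standard backward selection"; the threshold is configurable. No
multiple-testing correction is applied across the nine candidates.

Three diagnostics accompany the fit:

* **VIF** (`vif()`): $1/(1-R^2_j)$ from regressing predictor $j$ on the
  others; values above 10 are flagged as uninterpretable collinearity. VIFs
  are computed on the full candidate set (a screen), and again on the final
  model for reporting.
* **Partial correlations** (`partial_correlation()`): the correlation of the
  two residual vectors after regressing response and target on the controls.
  The implementation is the residual method; the identity
  $r = t/\sqrt{t^2 + \mathrm{df}}$ with the joint-model t statistic is kept as
  an internal consistency check in the test suite, not as the implementation.
  By default partial correlations are reported for the selected predictor
  set (eliminated predictors appear as `ns`, mirroring the usual reporting
  convention); the all-candidates variant is a configuration option.
* **RCVE** (`rcve()`): the relative contribution to variability explained,
  $(R^2_{\mathrm{full}} - R^2_{\mathrm{reduced},j})/R^2_{\mathrm{full}}$, with
  the reduced model refit on the same rows after removing predictor $j$.
  Unadjusted $R^2$ is used in both terms (adjusted $R^2$ is reported
  separately for the overall model); an adjusted-$R^2$ variant exists for
  sensitivity analysis and can legitimately be negative.

## The synthetic generator: what it emulates, and what it does not

Real curated 5'UTR collections are not bundled, so validation runs on
synthetic data whose ground truth is known (`synthetic_spec()`,
`generate_dataset()`). The generative model is exactly the regression's
functional form:

1. Per gene, draw G+C content from Beta(10, 10) (mean 0.5, sd ≈ 0.11) and a
   per-sequence modifier $s_m$ for any configured motif from its range.
2. Set $\log_{10} L = \beta_0 + \sum_k \beta_k x_k + \varepsilon$ with
   $\varepsilon \sim N(0, 0.4)$, and round ($L \ge 3$ enforced; a spec whose
   draws fall below 3 nt more than 1% of the time is rejected).
3. Emit sequences of exactly those lengths: bases iid with
   $P(G)=P(C)=\mathrm{gc}/2$, then occurrences of each modified motif are
   thinned toward $s_m \times$ the neutral rate (each occurrence is tested
   once and kept with probability $s_m$; rejected windows are redrawn and only
   the perturbed neighbourhoods rescanned, with a capped number of passes) or
   planted at Poisson rates for $s_m > 1$. $s_m = 0$ is enforced exactly.
   Realized counts of modified motifs are recorded, not assumed.

Defaults: intercept $\log_{10} 160$ and noise sd 0.4 (log10 scale), so half
the sequences are shorter than 160 nt and the raw length distribution is
right-skewed with a heavy upper tail — the shape typical of curated
5'UTR sets. All modifiers default to 1, which reproduces the iid model
exactly.

The generator does **not** emulate: phylogenetic relatedness between species
(species differences are just different parameter sets), gain/loss dynamics of
transcription initiation signals, secondary structure, codon-level
constraints, or database curation artefacts. Passing tests on synthetic data
therefore demonstrate the correctness and calibration of the *measurement and
modelling machinery*, not the biological conclusions one would draw from any
particular real dataset.

## Attenuation: why recovered coefficients are smaller than planted ones

Effects are planted on the *generative covariates* (the G+C parameter, the
modifier $s_m$), but the model regresses on features *re-measured from the
realized sequences*: measured G+C differs from the parameter by binomial
noise, and a motif's OE ratio is a noisy, nonlinear image of its modifier.
Classical errors-in-variables attenuation follows: OLS converges to shrunken
projection coefficients, not to the planted values. This mirrors the real
analysis, where features are measured, not known.

`estimate_attenuation()` quantifies the shrinkage empirically: it pools
replicate datasets generated from the same spec (pilot seeds offset by 10^5
from the spec seed so they never collide with study replicates), runs the same
measurement pipeline, fits the full model once on the pooled table, and
reports $\lambda_j = \hat\beta_{\mathrm{pooled},j} / \beta_{\mathrm{planted},j}$.
Recovery is then assessed against $\lambda_j \beta_{\mathrm{planted},j}$. In
the package's validation study (planted G+C effect $+1.5$, AUG and UAG
modifier effects $-1.0$, chosen so the per-replicate $|t|$ statistics exceed
~10 at $n = 5000$ and sign recovery is essentially certain), $\lambda$ is
about 0.9 for G+C and about 0.2 for the motif-modifier effects — the OE
measurement is noisy, so its attenuation is strong. The validation suite runs
500 replicates of $n = 5000$ genes and checks sign recovery and 2-standard-
error coverage against the attenuation-corrected reference.

## A measurement caveat: OE features are not null even under the null

Two mechanisms couple *measured* features to length even when nothing is
planted:

* **Finite-length measurement bias.** An OE ratio computed from a sequence of
  length $L$ has $O(1/L)$ bias (window counting and plug-in base frequencies),
  so OE features drift systematically with $L$ across a length-varying
  dataset.
* **Filter truncation.** The zero-OE rule retains a *short* sequence only if
  it happens to contain at least three of the four (A/U-rich) trinucleotides.
  Retention therefore depends jointly on length and composition, and among
  retained rows G+C and the OE features correlate with length even under the
  generative null.

Both effects are real properties of the measurement process, not bugs: on a
null synthetic dataset the feature-level regression retains a small but
clearly nonzero $R^2$ (of order 0.1 after filtering at $n$ in the hundreds),
far below planted-effect levels but far above zero. The test suite asserts
this behaviour explicitly. Consequently, the *type-I calibration* of backward
elimination is assessed where the null actually holds — regressing measured
log10 length on the nine generative covariates (G+C parameter and eight
applied motif modifiers) with all planted coefficients zero. There each
covariate survives selection at close to the nominal 5% rate and the median
selected model is intercept-only. The practical reading for real data: weak
effects attributed to OE features of *short* 5'UTRs should be interpreted
with caution, since part of such signal can be mechanical.

## Numerical and degenerate-input choices

* OE with zero expectation is 0 by definition; sequences shorter than the
  motif give 0 with a `degenerate` attribute.
* `fit_ols` requires more observations than coefficients and a full-rank
  design; ties in backward elimination (identical maximal p values) are
  broken by candidate order.
* `partial_correlation` rejects targets whose residual variance after
  controls is numerically zero (relative tolerance $10^{-10}$).
* RCVE asserts nested-model monotonicity ($R^2$ cannot increase when a
  predictor is removed) on every call and refuses a full model with
  $R^2 \le 0$.
* The motif-thinning loop caps resampling passes (default 10); exact-zero
  modifiers are subsequently enforced by breaking any remaining occurrence at
  its middle base.
* All stochastic steps (transcript choice, generation, pilot pooling) draw
  from explicitly seeded streams and restore the caller's RNG state.

## Problem sizes used in the validation suite

The shipped tests exercise: 1000 random sequences (lengths 3–2000) for the
OE-oracle equivalence; 1000 iid uniform 500-nt sequences for neutrality; 500
replicates of 5000 genes for coefficient recovery; 1000 replicates of 500
genes for null calibration; and a 20-replicate pooled pilot for attenuation.
These sizes give Monte-Carlo error comfortably below the asserted tolerances
(e.g. a ±0.05 band on a mean OE whose per-sequence sd is ≈ 0.4 at
$n = 1000$, and a ±0.02 band on survival rates estimated from 1000
replicates).

## Known limitations

* Only strictly-upstream uORFs are visible; overlapping uORFs require CDS
  sequence.
* The OE expectation assumes iid bases within a sequence; real 5'UTRs have
  local composition structure the generator does not reproduce.
* The zero-OE filter trades sample size for informativeness and induces the
  length-conditional selection described above; conclusions about *short*
  5'UTRs are outside the model's comfortable range.
* Backward elimination inherits the usual caveats of stepwise procedures;
  the package reports the full-model fit, the trace and the diagnostics so
  that no conclusion needs to rest on the selected set alone.
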