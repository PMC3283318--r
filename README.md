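# utrlen — genomic determinants of 5'UTR length

`utrlen` is an R package for asking how much of the within-species variation
in 5' untranslated region (5'UTR) length can be explained by the sequence
content of the 5'UTRs themselves. It is aimed at molecular-evolution and
regulatory-genomics analysts working with curated 5'UTR collections (one
FASTA record per transcript), and at anyone who needs a tested, reproducible
implementation of the observed-to-expected (OE) motif-ratio machinery and the
regression/importance statistics that usually surround it.

## The model

For each 5'UTR the package measures G+C content, the OE ratios of the start
trinucleotide AUG, the stop trinucleotides UGA/UAA/UAG, and the dinucleotides
CG, UG, UU, UA, and the presence of an upstream ORF. For a motif with bases
b₁…bₖ in a sequence of length L with base frequencies f,

    expected count = L · ∏ⱼ f(bⱼ)        (for AUG: L · f_A · f_U · f_G)
    OE = observed overlapping count / expected count

OE ≈ 1 is the neutral expectation; OE < 1 suggests the motif is selected
against. Log10 length is then modelled by multiple linear regression

    log10 L = β₀ + Σᵢ βᵢ Xᵢ + ε

over the nine composition features, after a cleaning rule that removes
5'UTRs with more than one zero trinucleotide OE ratio (zeros on short
sequences are uninformative). Backward elimination (α = 0.05) prunes
non-significant features; variance inflation factors screen for collinearity
(flag at VIF > 10); partial correlations and RCVE — the relative contribution
to variability explained, (R²_full − R²_reduced)/R²_full — rank the
surviving features. A seeded synthetic 5'UTR generator with planted
length–feature relationships makes every stage testable without any external
database. See the methods vignette (`vignettes/utr-length-determinants.Rmd`)
for the full account, including the attenuation and null-calibration
subtleties.

## Worked example

Analyse a synthetic species with known planted structure — a positive G+C
effect (+1.5) and suppression-linked negative effects of the AUG and UAG
modifiers (−1.0 each) on log10 length:

```r
library(utrlen)

spec <- synthetic_spec(
  n_genes = 3000, seed = 42,
  motif_modifiers = list(AUG = c(0.3, 1), UAG = c(0.3, 1)),
  planted_beta = c("(Intercept)" = 2.75, gc = 1.5, s_aug = -1, s_uag = -1))

report <- run_pipeline(run_config(synthetic_spec = spec,
                                  include_uorf = FALSE,
                                  out_dir = "utrlen_demo"))
print(report)
#> 5'UTR length analysis run
#>   input records: 3000 (io dropped 0, extra transcripts 0, short 0)
#>   filter (zero_oe): 880 removed, 2120 retained
#>   selected predictors: gc_content, oe_aug, oe_uga, oe_uaa, oe_uag
#>   adjusted R^2 = 0.3255
```

880 of 3000 5'UTRs had two or more uninformative (zero) trinucleotide OE
ratios and were excluded. Backward elimination kept G+C content and the four
trinucleotide OEs and discarded the four dinucleotide OEs — exactly the
features that carried planted effects (the UGA/UAA OEs respond indirectly,
because suppressing AUG/UAG changes stop-codon statistics and length). The
model explains ~33% of the length variance; the planted coefficients come
back attenuated (G+C 1.28 vs 1.5 planted; see the vignette for why measured
features shrink estimates):

```r
print(report$model$full)
#>         term estimate std_error  t_value    p_value
#>  (Intercept)  2.19251   0.09356  23.4333 3.991e-108
#>   gc_content  1.27540   0.06733  18.9419  5.055e-74
#>       oe_aug -0.20380   0.01457 -13.9833  1.472e-42
#>       oe_uag -0.20906   0.01620 -12.9031  1.018e-36
#>       ...
#> R^2 = 0.3277, adjusted R^2 = 0.3248

round(report$model$rcve, 3)
#> gc_content     oe_aug     oe_uga     oe_uaa     oe_uag      oe_cg ...
#>      0.349      0.190      0.051      0.026      0.162      0.000 ...
```

G+C content contributes the most explained variance (RCVE 0.35), followed by
the AUG and UAG OE ratios — the planted hierarchy. All outputs (feature
table, filter report, Table-style coefficient and partial-correlation
reports, VIF and RCVE tables, selection trace, JSON run summary) are written
to `utrlen_demo/`.

For real data, point the pipeline at a FASTA instead:

```r
report <- run_pipeline(run_config(input = "my_utrs.fasta",
                                  rule = header_rule(delim = "|"),
                                  seed = 1, out_dir = "results"))
```

A command-line wrapper with the same options ships in
`inst/scripts/utrlen-run.R`.

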