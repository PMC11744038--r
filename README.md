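# ervscan

Subfamily-level expression analysis of endogenous retroviruses (ERVs)
from bulk RNA-seq.

ERVs are LTR retrotransposons fixed in the host germline; aberrant ERV
transcription can activate innate immunity ("viral mimicry") and has
been reported in infectious and inflammatory disease. `ervscan`
implements the full analysis chain needed to ask, in any two-condition
cohort, *which ERV subfamilies are transcriptionally upregulated, and
are those subfamilies evolutionarily young?* Its intended users are
transcriptomics analysts working from coordinate-sorted alignments and
a RepeatMasker annotation.

## What it computes

1. **Annotation**: parse RepeatMasker `.out` (per-copy divergence
   `div.` retained) and a gene GTF; keep ERV copies by class/family
   prefix (`LTR/ERV*` by default); drop every copy overlapping a gene
   body by ≥ 1 bp, so the quantified signal is attributable to the
   repeat itself; summarise each subfamily (copy counts, merged
   intergenic length, mean divergence).
2. **Quantification**: fragment counting over subfamily
   *meta-features* — all copies of a subfamily count as one feature. A
   fragment is assigned iff it overlaps ≥ 1 bp of ≥ 1 copy and is
   strand-compatible (reverse-stranded library by default); fragments
   compatible with ≥ 2 subfamilies are ambiguous and dropped. Filters:
   primary alignments, MAPQ ≥ 20, duplicates ignored. Expression is
   FPKM: `fpkm = count · 10⁹ / (merged_length_bp · assigned_total)`.
3. **Differential expression**: per feature, a Welch *t*-test
   (Welch–Satterthwaite df) of case vs control FPKM, Holm step-down
   adjustment over the tested family, and a pseudocounted fold-change
   `FC = (mean_case + ε)/(mean_control + ε)`, ε = 0.01 FPKM. A
   subfamily is *up* iff adjusted *p* < 0.05 **and** FC > 2. A severity
   contrast (ICU vs non-ICU cases, unadjusted Welch *t*) runs when the
   sample sheet carries severity labels.
4. **Evolutionary age**: two-tailed Mann–Whitney U test (exact by
   enumeration when `n_a·n_b ≤ 400` and tie-free, else tie-corrected
   normal approximation with continuity correction) comparing the mean
   RepeatMasker divergence of upregulated subfamilies against the
   remaining tested subfamilies; lower divergence ⇒ younger. Upregulated
   sets from several tissues can be intersected
   (`intersect_upregulated()`).
5. **Synthetic data**: a generator producing RepeatMasker/GTF/SAM
   fixtures and negative-binomial count matrices with planted,
   age-tier-confined upregulation — used throughout the test suite to
   verify the pipeline recovers known truth.

## Worked example

Simulate a platelet-style cohort (10 cases vs 5 controls, 120
subfamilies, 8 young-tier subfamilies planted at fold-change 8), then
run the count-level analysis:

```r
library(ervscan)
cfg <- sim_config(seed = 42, n_subfamilies = 120, n_planted = 8,
                  planted_age_tier = "young", fold_change = 8)
sim  <- simulate_counts(cfg)
fpkm <- compute_fpkm(sim$counts, sim$truth$merged_length_bp,
                     colSums(sim$counts))
de   <- call_differential(fpkm, sim$samples$condition)
de
#> Differential expression: covid (n = 10) vs control (n = 5)
#>   120 features tested; adjust = holm, alpha = 0.05, min FC = 2
#>   up: 8  down: 0  ns: 112
age <- compare_divergence(de, data.frame(
  subfamily = sim$truth$subfamily,
  mean_divergence_pct = sim$truth$mean_divergence_pct))
age
#> Divergence comparison: upregulated vs remainder
#>   upregulated: n = 8, median div = 3.12%
#>   remainder:   n = 112, median div = 15.89%
#>   Mann-Whitney U = 113, two-sided p = 0.000433 (normal) -> younger
```

All 8 planted subfamilies are recovered as *up* with no false
positives, and the age test reports them significantly younger than the
remainder — the result the analysis is designed to detect.

For real data, `run_pipeline(pipeline_config(rmsk = ..., gtf = ...,
sample_sheet = ..., alignments = ...), out_dir)` executes
annotate → count → FPKM → DE → severity → age in one deterministic run,
writing stage TSVs and a checksum manifest; `inst/scripts/ervscan.R` is
a thin command-line wrapper. See the methods vignette
(`vignettes/erv-subfamily-analysis.Rmd`) for the statistical model,
parameter defaults and design rationale.

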