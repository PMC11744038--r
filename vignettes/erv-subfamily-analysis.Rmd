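---
title: "ERV subfamily expression, differential calling and evolutionary age"
author: "ervscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERV subfamily expression, differential calling and evolutionary age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervscan)
```

## The analysis

Endogenous retroviruses (ERVs) persist in the genome as families of
related copies ("subfamilies" in RepeatMasker nomenclature: LTR7Y,
MLT2A1, MER48, ...). Because individual copies are repetitive and often
poorly distinguishable by short reads, this package quantifies
expression at *subfamily* resolution: all copies of a subfamily form
one meta-feature and a fragment touching any copy counts once toward
the subfamily. Three restrictions make the signal interpretable:

* **Intergenic copies only.** A copy overlapping any annotated gene
  body (≥ 1 bp, either strand) is excluded, so subfamily counts are not
  confounded by read-through of host transcripts. This is the
  strictest simple reading of "intergenic"; the gene mask is whatever
  GTF the user supplies, and the rule is deliberately strand-blind —
  an antisense ERV inside a gene still sits in a transcribed locus.
* **Strand-compatible fragments.** The default library model is
  reverse-stranded (read 1 antisense to the transcript), so a fragment
  is compatible with a copy when its inferred strand is *opposite* the
  copy strand. Strand compatibility is applied before ambiguity:
  a fragment overlapping a compatible copy of one subfamily and an
  incompatible copy of another is assigned, not ambiguous.
* **Unique, confident alignments.** Primary records with MAPQ ≥ 20,
  duplicates ignored. "Uniquely mapped" is operationalized purely by
  the MAPQ threshold — no NH-tag inspection — because the MAPQ filter
  is what a standard featureCounts-style invocation applies.

Expression is FPKM with the subfamily's *merged* intergenic copy
length (union of intervals, so overlapping annotations are not
double-counted) and the per-sample total of assigned fragments as the
denominator:

$$\mathrm{FPKM}_{fs} = \frac{c_{fs}\cdot 10^9}{L_f\, N_s}.$$

The per-sample denominator is configurable (pass any totals vector to
`compute_fpkm()`); the assigned-fragment total is the default because
it is the quantity the counting step itself produces. Fold-changes are
always relative to the control group of the same cohort, which removes
subfamily-specific mapping-efficiency effects from the contrast.

## Differential calling

Per feature the package runs a Welch two-sample *t*-test on FPKM
values,

$$t=\frac{\bar x-\bar y}{\sqrt{s_x^2/n_x+s_y^2/n_y}},\qquad
\nu=\frac{(s_x^2/n_x+s_y^2/n_y)^2}
        {\frac{(s_x^2/n_x)^2}{n_x-1}+\frac{(s_y^2/n_y)^2}{n_y-1}},$$

followed by Holm's step-down adjustment over all features tested in the
run (one cohort = one family; cohorts are never pooled, because the
public cohorts the design targets were produced under incompatible
conditions). A feature is called **up** when the adjusted *p* is below
`alpha` (0.05) *and* the pseudocounted fold-change
$(\bar x_{case}+\varepsilon)/(\bar x_{ctrl}+\varepsilon)$ exceeds
`min_fold_change` (2). The two criteria are intersected — the standard
volcano-plot reading of a horizontal and a vertical threshold line; a
union rule would label near-zero-fold-change features "up", which is
not a defensible notion of upregulation. The pseudocount
$\varepsilon = 0.01$ FPKM keeps log fold-changes finite and enters only
the ratio, never the *t*-test.

Tests run on raw FPKM by default because the upstream pipeline defines
no variance-stabilising transformation; `de_thresholds(log_transform =
TRUE)` switches the *t*-test to $\log_2(\mathrm{FPKM}+\varepsilon)$ for
users who prefer it (fold-changes stay on the raw scale either way).
Degenerate features are handled by convention rather than error:
all-zero features are excluded before testing (they carry no signal and
would only dilute the Holm family), and a feature constant within both
groups yields $t=0,\,p=1$ when the means agree.

The severity contrast (ICU vs non-ICU cases) uses the same machinery
with `adjust = "none"` by default — it is a small, targeted two-group
comparison, reported with healthy-control means alongside as
description, not as a third test arm.

## Evolutionary age

RepeatMasker's per-copy `div.` (percent substitution from the
subfamily consensus) is the standard age proxy: the older the
insertion, the more substitutions it has accumulated. A subfamily's age
is summarised as the unweighted mean divergence over its intergenic
copies — the copies actually quantified; a length-weighted mean is
available (`weighted = TRUE`) but is not the default since the unit of
the age claim is the copy, not the base.

`compare_divergence()` asks whether the upregulated subfamilies are
younger than the rest with a two-tailed Mann–Whitney U test. The
"remainder" is the *tested* subfamilies not called up — the
expression-eligible universe, not the full genomic roster, because the
comparison should not be confounded by subfamilies that could never
have been called in either direction (`roster =` overrides this). The
U statistic counts pairs $a_i > b_j$ with ties at ½. The *p*-value is
exact — the null distribution computed by subset-sum dynamic
programming over rank sums — for tie-free samples with
$n_a n_b \le 400$, a cutoff balancing fidelity and runtime; otherwise
a normal approximation with tie-corrected variance and a 0.5 continuity
correction is used. At $n_a = n_b = 15$ the two routes agree within
0.02. With zero upregulated subfamilies the result is flagged
degenerate (direction `none`, *p* = NA) rather than raising an error,
so cohort sweeps do not abort on a negative tissue.

The statistical kernels (`welch_t_test()`, `holm_adjust()`,
`mann_whitney_u()`) are implemented in the package and cross-checked in
the test suite against `stats::t.test()`, `stats::p.adjust()`,
`stats::wilcox.test()` and against full enumeration of rank
assignments; the two routes are kept separate so each can falsify the
other.

## The synthetic-data generator

`sim_config()` fixes the study conditions the tests assume; the
defaults are chosen once to mirror a platelet-style cohort and realistic
bulk RNA-seq:

| parameter | default | rationale |
|---|---|---|
| group sizes | 10 cases vs 5 controls | unequal-n design of the targeted cohorts (see `covid_cohort_sizes()`) |
| subfamily baseline mean | log-uniform [50, 500] | moderately-to-well expressed features, the regime where subfamily DE is readable |
| NB dispersion | 0.1 | typical bulk RNA-seq biological CV ≈ 0.3 |
| size factors | log-normal, sdlog 0.15 | ±30 % library-depth variation |
| divergence tiers | young U[0.5, 8] %, old U[8, 30] % | young/old split at 8 % divergence; tiers disjoint by construction |
| young fraction | 0.3 | minority of subfamilies are recent insertions |
| planted fold-change | 8 | strong, unambiguous planted effect |
| fragment geometry | 100 bp reads, 250 ± 30 bp inserts | generic short-read library |

Counts follow
$c_{fs}\sim\mathrm{NB}(\mu = \beta_f\,\phi_{fs}\,\sigma_s,\ \mathrm{disp})$
with $\phi_{fs}$ the planted fold-change for planted subfamilies in
case samples and 1 otherwise. Every output is a pure function of the
configuration (seed included): generation runs under a saved-and-
restored RNG state, so fixed seeds give byte-identical files without
disturbing the caller's random stream.

The read-level generator writes valid SAM per sample: properly paired
fragments wholly inside a chosen intergenic copy, antisense to the copy
strand so reverse-stranded counting must assign them. Intergenic copies
are placed mutually disjoint, which makes read-level truth exact — a
fragment inside one copy cannot graze a copy of another subfamily.
Spike-ins with recorded expected outcomes (low-MAPQ, duplicate-flagged,
sense-strand, cross-subfamily straddling fragments) exercise each
filter individually.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: sequence content and alignment error
(MAPQ values are assigned, not computed), multi-mapping ambiguity
between near-identical copies, transcript structure (fragments are
uniform within copies), GC and length biases, batch effects, and any
single-cell structure. Recovery results on synthetic data bound what
the statistics can do when the counting model holds; they cannot
validate the upstream aligner.

## Validation under the study conditions

The acceptance suite (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) recomputes, at the problem sizes named below:

* cohort bookkeeping — the eight targeted cohorts sum to 124 COVID-19
  and 53 control samples;
* counting-oracle equivalence — indexed counting equals a quadratic
  per-fragment × per-copy scan exactly on five fixtures up to 10⁴
  fragments × 10³ copies;
* kernel fidelity — Welch and Holm within 10⁻¹⁰ of the reference
  implementations on 100 random instances; exact Mann–Whitney equal to
  full enumeration for all group sizes up to 8;
* null calibration — with 578 subfamilies, 10 vs 5, dispersion 0.1 and
  no planted effect, the unadjusted rejection fraction at 0.05 stays
  within 3 binomial SE, and the Holm family-wise error rate over 200
  replicates stays within 3 SE of 0.05;
* planted-effect recovery — fold-change 8 in 10 of 500 subfamilies:
  mean sensitivity ≥ 0.9 with zero false positives in ≥ 18 of 20
  replicates; young-tier-confined planting yields a significant
  "younger" age call in ≥ 90 of 100 replicates while tier-agnostic
  planting stays at the null rate;
* route equivalence — the SAM route and the count-matrix route produce
  byte-identical DE and age tables on a spike-in-free fixture.

These problem sizes keep the whole suite within a few minutes on one
CPU while leaving each check statistically meaningful.

## Numerical conventions and edge cases

* Intervals are held in `GRanges` (1-based, closed) throughout;
  coordinate conversion happens only in parsers and writers
  (RepeatMasker/GTF are 1-based inclusive, BED is 0-based half-open).
* Welch with both groups constant: $t=0, p=1$ if means agree, $p=0$
  otherwise; rows hitting this in the vectorised path follow the same
  convention.
* Holm ties are broken stably; adjusted values are monotone in the
  sorted order and capped at 1.
* Mann–Whitney with all values identical returns $p=1$.
* A sample with zero assigned fragments is an error (its FPKM is
  undefined), as is a zero-length feature with nonzero counts.
* Orphaned mates become single-read fragments, counted once; mates
  split across chromosomes are treated as orphans on each.

## Limitations

Locus-level (per-copy) expression, EM-style multimapper rescue,
dispersion-modelling DE (DESeq2-style shrinkage), batch correction and
molecular-clock dating in years are all out of scope: the package
implements a deliberately transparent subfamily-level design —
filtered unique-alignment counting, Welch/Holm calling, rank-based age
comparison — whose every step is checkable against an independent
oracle, and that is the property the test suite certifies.
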