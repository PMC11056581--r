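---
title: "Methods: gene-centric analysis of H3K4me3/H3K27me3 dynamics under cold stress"
author: "coldmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centric histone methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldmark)
```

## The problem

Short cold exposure reprograms the transcriptome of *Arabidopsis thaliana*
within hours, and the histone marks H3K4me3 (associated with active
chromatin) and H3K27me3 (the Polycomb repressive mark) are redistributed
at individual loci without detectable genome-wide shifts. coldmark
implements the gene-centric analysis layer for this kind of experiment:
it starts *after* alignment and peak calling, from per-condition peak
files and gene-body read counts, and answers the questions a chromatin
biologist asks of such data — which genes carry each mark, which genes
gain or lose it after 3 h or 3 d in the cold, how stable those changes
are, and how they relate to differential expression measured on the same
material.

Everything below is testable against synthetic data with planted ground
truth; the package ships the generator as first-class, tested code.

## Data model and conventions

All genomic intervals are 0-based half-open internally (the BED
convention). GFF3/GTF input is converted on read; BED, broadPeak and
bedGraph are native. Half-open means book-ended features do not overlap:
a peak ending at position 1000 contributes nothing to a gene starting at
1000. The gene body is the full TSS-to-TES interval of the `gene`
feature; transcript structure is ignored throughout. Genes on organellar
chromosomes (`ChrM`, `ChrC`, `Mt`, `Pt` by default; configurable) are
flagged non-nuclear and excluded from DEG sets by default.

Peak sets are reduced to disjoint interval covers on load (overlapping
or book-ended intervals are merged). This makes target calling
well-defined regardless of how the peak caller split its output, and
makes the "split a peak file and reload" invariance hold trivially.

## Target calling

A gene is a **target** of a mark if at least 150 bp of its body lies
within a *single* peak of that mark in at least one condition. Both
choices deserve comment:

* *Single peak, not cumulative.* Reading the criterion literally, the
  required coverage must come from one peak. With merged peak sets the
  two interpretations differ only for genes spanned by several distinct
  peaks; a `cumulative = TRUE` switch exists for sensitivity analysis.
* *Any condition.* The target universe is defined across all loaded
  conditions and reused for every contrast, so per-contrast DM counts
  are fractions of one fixed denominator per mark. A per-contrast
  universe would make gain/loss counts incomparable across timepoints.
* The 150 bp threshold is inclusive ("at least").

## Normalization and fold changes

Library-size normalization is median-of-ratios: for sample $j$,

$$\hat s_j = \mathrm{median}_{i \in R}\; \frac{c_{ij}}{(\prod_k c_{ik})^{1/m}}$$

over the reference set $R$ of genes with strictly positive counts in
every sample (the geometric mean is undefined otherwise). With an even
reference the median is the midpoint of the two central ratios. One
practical subtlety the test suite encodes: because the geometric-mean
reference includes every sample, scaling one library by $c$ multiplies
its raw factor by $c^{(m-1)/m}$ and all others by $c^{-1/m}$; the clean
invariant is that factors *relative to an unscaled sample* change by
exactly $c$. Normalized counts, which only depend on relative factors,
behave as expected.

Fold changes are unshrunk and pseudocounted:
$\log_2\!\big((\bar n_B + 0.5)/(\bar n_A + 0.5)\big)$ with cold in the
numerator and naive in the denominator. No shrinkage estimator is
applied: the pseudocounted ratio is deterministic, has no prior to tune,
and keeps the DM criterion a pure function of the data. The pseudocount
(default 0.5) guarantees finite values for all-zero genes.

RPKM is $c_{ij} \times 10^9 / (L_i \cdot N_j)$; library sizes $N_j$
default to column sums when external totals are not supplied.

## Differential methylation

A target gene is **DM** for a contrast when its gene-body
$|\log_2 FC| \ge 0.5$ (inclusive), `gain` or `loss` by sign. No
significance test is attached — the call is deliberately a
coverage-gated fold-change criterion, so the only tunables are the two
thresholds. An important consequence, which the acceptance suite
measures rather than hides: at the synthetic design conditions
(dispersion 0.05, 2 ChIP replicates, mean depth 200) the per-gene
fold-change noise SD is about 0.34, so a *null* target gene crosses the
0.5 threshold with probability ≈ 0.14. A pure threshold rule at these
noise levels therefore has high sensitivity (≈ 1.0 for planted
$|\log_2 FC| = 1.5$ effects) but a substantial false-discovery
proportion when true DM genes are a minority; the suite reports both.

Genes induced by cold (up-DEGs at any timepoint) that carry a mark are
categorized `gain` / `loss` / `non_DM` over the two timepoints; a gene
gaining at one timepoint and losing at the other gets an explicit
`both` label rather than being silently folded into either class, so
any downstream convention can be reconstructed from the counts.

## Differential expression

The DE engine is a deliberately transparent two-group negative-binomial
Wald test, not a reimplementation of a full GLM framework:

1. per-gene method-of-moments dispersion from normalized counts,
   $\hat\alpha = \max\!\big(10^{-8}, (s^2 - \bar\mu)/\bar\mu^2\big)$,
   with optional (off by default) shrinkage toward the median of
   similarly expressed genes;
2. Wald statistic = pseudocounted $\log_2 FC$ divided by its
   delta-method SE under $\mathrm{Var} = \mu + \alpha\mu^2$ at the
   plug-in group means;
3. two-sided p-value from a **Student t with $n_A + n_B - 2$ degrees of
   freedom**, not the normal. With 2–3 replicates the dispersion (hence
   the SE) is estimated with very few degrees of freedom, and the
   normal-referenced plug-in Wald test is anticonservative by more than
   a factor of two (empirical size ≈ 0.12 at nominal 0.05 in the
   suite's null simulation); the t reference restores calibration
   (measured size ≈ 0.05, inside [0.03, 0.07]).
4. Benjamini–Hochberg adjustment; a DEG has $|\log_2 FC| \ge 1$
   (inclusive) and adjusted $p < 0.05$ (strict), restricted to
   nuclear-encoded genes by default.

The t reference trades tail power for size: at genome scale the BH
threshold lands at raw $p \sim 10^{-3}$, where the heavy t(4) tails are
demanding, so moderate-effect genes at modest depth may be missed even
though the raw-p power at the nominal level is ≈ 0.99. The end-to-end
tests assert exactly this pair of properties (raw-p power and
BH-set precision) rather than pretending the adjusted call set should
equal the planted set. Genes with zero counts in all samples get
$p = 1$. No independent filtering of low-count genes is applied by
default (every tested gene receives an adjusted p-value); an optional
mean-count filter can be added upstream by subsetting the count matrix.

## Integration

* **Intersections.** Cross-mark DM overlap at a timepoint uses
  exclusive (UpSet-style) signatures over the four sets
  {mark} × {gain, loss}; counts over signatures sum to the union. Genes
  DM for both marks are tallied as same-direction (gain/gain,
  loss/loss) or opposite-direction.
* **Persistence.** For a mark and direction, the headline fraction is
  $|S_{3h} \cap S_{3d}| / |S_{3h} \cup S_{3d}|$. The union denominator
  is symmetric in the timepoints; because the choice matters for small
  sets, per-timepoint fractions ($|S_{3h} \cap S_{3d}|/|S_{3h}|$ and
  $/|S_{3d}|$) are always emitted alongside.
* **Correlation.** Spearman's rho, computed as the Pearson correlation
  of mid-ranks (average ranks for ties). The two-sided p-value is an
  exact permutation enumeration up to $n = 8$ (40,320 permutations) and
  the t approximation above; the gene sets actually correlated are in
  the hundreds, far inside the approximation's comfort zone, and the
  exact mode exists mainly so the small-n behaviour is testable against
  full enumeration. The correlated set is restricted to genes that are
  DE at the considered expression timepoint *and* targets of the mark;
  all four (methylation timepoint × expression timepoint) combinations
  are computed for the cross-timepoint matrix.
* **Group comparisons.** Two-sided Wilcoxon rank-sum tests, exact when
  the smaller group has ≤ 8 observations and there are no ties, normal
  approximation with tie correction otherwise. Pairwise comparisons
  among the induced-gene categories exclude `both` (reported
  separately) and flag pairs with a singleton category untestable.

## Metagene profiles

Coverage comes from bedGraph tracks (the text-exact stand-in for
bigwig). Each gene is mapped to 300 bins: 50 upstream-flank bins at
native 10 bp, 200 body bins with the body scaled to 2000 bp, 50
downstream-flank bins. Body resampling is **length-weighted averaging**
of the underlying step function — each scaled bin's value is the
integral of coverage over its (fractional) genomic span divided by the
span — implemented with prefix integrals. Unlike nearest-neighbour
interpolation this conserves the mean body signal exactly (to numerical
precision), which the tests assert at 1e-9. Minus-strand genes are
reversed so bin 1 is always the most 5' position; flanks beyond
chromosome ends contribute zero. Aggregation over a gene set is the
bin-wise arithmetic mean; note mean-of-profiles equals
profile-of-means only for constant tracks, and the suite carries a
counterexample to guard against that shortcut.

## Physiological assays

**LT50.** Electrolyte-leakage curves are fitted with the four-parameter
logistic
$$L(T) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + 10^{\,s\,(LT_{50} - T)}}$$
by least squares **on temperature directly**. The GraphPad convention of
fitting "log(agonist) vs response" presumes a positive dose on a log
axis; freezing temperatures are negative °C, so a literal log transform
is undefined, and the raw-temperature logistic is the mathematically
coherent equivalent (same sigmoid family, LT50 at the inflection).
Initialization is a deterministic 8-point multistart grid (slope in
{-1, -0.25, 0.25, 1} × LT50 at the lower/upper quartile of the measured
range); the lowest-SSE fit wins, ties to the first, so the fit has no
random state. The 4PL is invariant under
(bottom, top, s) → (top, bottom, -s); fits are canonicalized to
bottom < top. Technical replicates are averaged per temperature before
fitting. LT50 outside the measured range is flagged, not rejected.

**qPCR.** Transcript abundance is $2^{-\Delta C_t}$ with
$\Delta C_t = C_t^{target} - \overline{C_t^{HK}}$ over the housekeeping
set (ACTIN2, PDF, TIP41 by default); adding any constant to all Ct
values of a sample cancels exactly.

## The synthetic-data generator

`sim_config()` encodes the study design the analysis assumes: two marks
× three conditions (naive, 3 h, 3 d cold) × 2 ChIP replicates, RNA-seq
with 3 replicates, NB-distributed gene-body counts. Defaults were fixed
once, from the study conditions where stated and otherwise at values a
practitioner would call realistic for this system:

| parameter | default | provenance |
|---|---|---|
| genes / chromosomes | 5000 / 3 (+ ChrM, ChrC, ~1% of genes) | scaled-down genome, seconds-scale runs |
| gene lengths | log-normal, median 2 kb | typical plant gene body |
| ChIP / RNA replicates | 2 / 3 | study design |
| target probability | K4 0.64, K27 0.30 | 17.4k vs 8.1k targets of ~27k genes |
| DM fraction of targets (3h, 3d) | K4 0.21/0.13, K27 0.09/0.11 | observed DM rates |
| gain : loss split | 2 : 1 | observed gain skew |
| persistence (both / union) | K4 0.11, K27 0.45 | observed stability difference |
| planted effects | meth 1.5, expr 2.0 (log2) | clear but not trivial effects |
| NB dispersion / mean depth | 0.05 / 200 | replicate-level biological noise |
| coupling rho | K4 0.3 (up→gain), K27 0.15 (up→loss) | induced genes' DM preference |
| true size factors | log-uniform [0.5, 2] | realistic library-size spread |

Peaks are constructed to make planted target status exactly recoverable
(targets get a peak covering 80% of the body; a third of non-targets get
a 100 bp decoy below the threshold, so the gate is genuinely exercised).
Counts are drawn at gene level — no reads or alignments are simulated.
Coverage tracks are background-plus-peak step functions. Everything is
reproducible byte-for-byte from config + seed, and no generator function
touches global random state.

What the generator does **not** emulate: realistic peak shapes and
widths, chromatin-state spatial autocorrelation along chromosomes,
GC/mappability bias, sample-specific dispersion, partial or
heterogeneous effect sizes, and any coupling between a gene's
methylation level and its expression *level* (only change-change
coupling via rho). Passing recovery tests therefore demonstrates the
pipeline's correctness and calibration under its own statistical
assumptions, not performance on real libraries.

## Numerical and design choices, in brief

* Coordinates: 0-based half-open everywhere internally.
* Median with even counts: midpoint of the central pair.
* Boundary conventions: $|\log_2 FC|$ thresholds inclusive, p-value
  thresholds strict.
* Spearman exact-permutation cutoff at $n = 8$: the next sizes would
  cost 0.36–3.6 M permutations per call in pure R for no practical
  benefit at study-scale n.
* One peak file per (mark, condition): whether peaks were called on
  pooled replicates is upstream of this package; the interface takes
  the files as given.
* Config files are YAML (with a `simulate:` block for generator
  fields); every simulated dataset directory carries its resolved
  configuration and a file manifest as JSON for provenance.
* Problem sizes in the test suite — 5,000-gene datasets, 10,000-gene
  null simulations, 100-seed noise studies — were chosen as the
  smallest sizes at which the measured quantities are stable; the whole
  suite runs in a few minutes on one CPU.

## Known limitations

* The DM caller's false-discovery proportion is untestable from real
  data (no truth) and, at the simulated noise level, is driven almost
  entirely by the fold-change threshold; an optional count-based test
  could gate calls but is off by default to keep the published
  criterion.
* The DE engine handles two-group contrasts only — no multi-factor
  designs, likelihood-ratio tests, or outlier handling. It is isolated
  behind `nb_wald_test()`/`de_test()` so a full GLM engine could be
  swapped in.
* RPKM library sizes default to column sums of the counted genes, a
  proxy for total mapped reads.
* Metagene profiles assume the mean statistic within scaled bins.
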