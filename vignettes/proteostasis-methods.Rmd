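---
title: "Inferring synthesis- versus degradation-driven proteome changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring synthesis- versus degradation-driven proteome changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ProteoTurn)
```

## The question the package answers

A difference in a protein's steady-state abundance between two conditions
can arise from more (or less) synthesis or from less (or more) degradation,
and abundance measurements alone cannot distinguish the two. ProteoTurn
combines two measurement types to resolve this ambiguity:

* **label-free quantification (LFQ)**: chromatographic peak areas per
  protein per sample, yielding abundance fold changes (Δabundance);
* **heavy-water (D₂O) metabolic labeling**: per-peptide time courses of the
  newly synthesized ("fraction new") pool, yielding turnover-rate fold
  changes (Δturnover).

The sign pair (Δabundance, Δturnover) then identifies the regulatory mode:
(+, +) increased synthesis, (+, −) decreased degradation, (−, +) increased
degradation, (−, −) decreased synthesis. Because individual protein
measurements are noisy, the inference is drawn at the level of functional
ontology terms (GO, KEGG, Reactome, WikiPathways), where a coherent shift
of many related proteins is far stronger evidence than any single protein.

## Kinetic model and assumptions

Each protein is modeled with zero-order synthesis and first-order
degradation,

$$\frac{d[P]}{dt} = k_{syn} - k_{deg}[P],$$

so at homeostasis $[P] = k_{syn}/k_{deg}$. When the free amino-acid pool is
deuterated at $t = 0$, pre-existing protein decays as
$(k_{syn}/k_{deg})e^{-k_{deg}t}$ while labeled protein accumulates as its
complement; the total is constant and the measurable labeled fraction is

$$f(t) = 1 - e^{-k_{deg}t}.$$

The turnover rate is defined as the mean of the per-molar synthesis rate
and the degradation rate constant,
$k_{turnover} = \tfrac12(k_{syn}/[P] + k_{deg})$, which reduces to
$k_{deg}$ exactly at homeostasis. The model assumes steady state during
the measurement, a large precursor pool (so synthesis is the bottleneck),
a well-mixed pool with unregulated (concentration-proportional)
degradation, and negligible import/export and aggregation. These
assumptions are reasonable for healthy adult tissue but are known to fail
for proteins undergoing regulated aggregation, subunit exchange in stable
complexes, or non-random degradation; results for such proteins should be
read cautiously.

## Rate fitting and quality control

`fitPeptideRate()` fits $f(t) = 1 - e^{-kt}$ with the asymptote fixed at 1
(appropriate for proteins; lipids with multiple pools need a free
asymptote, which is out of scope). The problem is one-dimensional, so the
fit is a bounded minimization of the sum of squared residuals over
$k \in [10^{-6}, 50]\,\mathrm{d^{-1}}$ (golden-section/parabolic search,
then a Newton polish on the gradient to machine-level accuracy). This is
deterministic with no starting-point sensitivity; a noise-free curve is
recovered to better than $10^{-6}$ relative error, and the minimizer
agrees with an exhaustive SSE grid search on noisy data.

Quality gates, applied in this order:

* **peptide level** — at least 3 distinct non-zero labeling timepoints;
  RMS residual ("measurement deviation", on the fraction scale) below 0.1;
  an optimizer pinned at a search bound (e.g. an all-zero labeling signal)
  is reported as non-converged. An optional gate on the peptide's
  deuterium-accessible-position count (`min_n_value`, default off) is
  available for rate tables whose extraction step did not already apply
  it.
* **protein level** (`filterRateFits()`) — pooled $R^2 \ge 0.6$, more than
  one unique peptide, strictly positive combined rate. Rejections are
  counted by the first criterion failed, in that order.

The peptide-to-protein combiner is the median of accepted peptide rates,
with $R^2$ and deviation recomputed on the pooled points at the combined
rate. The median is robust to a single aberrant peptide; a joint fit over
pooled points is a defensible alternative and gives near-identical results
when peptides agree, which is exactly when both are trustworthy.

Per comparison, each protein's accepted rates are averaged within cohort,
the fold change is the difference of the log2 mean rates, and the cohort's
fold-change vector is **auto scaled** ($(x-\bar x)/s$, sample sd) before
ontology aggregation.

## The LFQ normalization chain

Each of the eight datasets (sex × block × subcellular fraction) is
processed independently, never sharing information across datasets:

1. **missingness filter** — keep proteins with at most one missing area
   per genotype (with 4 samples per genotype this guarantees the minimum
   of three measurements per cohort that every reported fold change must
   rest on);
2. **log2 + mean centering** — removes per-sample multiplicative factors
   (loading, injection) exactly;
3. **slope normalization** — the least-squares slope through the origin of
   each sample's centered values on the across-sample mean profile
   equalizes distribution widths;
4. **KNN imputation** — each missing cell takes the mean of the two
   nearest neighbour proteins' values in that sample, with nan-aware
   Euclidean distance rescaled by the fraction of mutually present
   samples (the convention of the widely used scikit-learn imputer).
   Present values are never altered.

Differential testing is gated by a two-sided F-test at $\alpha = 0.05$
(a value the source methodology leaves unstated; 0.05 is the conventional
choice): equal-variance t-test when the F-test is insignificant, Welch
otherwise. The per-protein log2 fold changes are averaged, unweighted,
over the datasets in which the protein qualifies, and the comparison's
fold-change vector is **range scaled** ($(x-\bar x)/(x_{max}-x_{min})$).
Range scaling keeps every protein's change interpretable relative to the
comparison's full dynamic range; auto scaling is used for turnover, whose
smaller, noisier cohort benefits from variance standardization.

Note that both scalings subtract the cohort mean, so ontology-level signs
are relative to the comparison-wide average change. With an approximately
balanced proteome (up- and down-regulation both present, most proteins
unchanged) the cohort mean is near zero and signs carry their intuitive
meaning; under a globally one-sided shift they would not, which is a
limitation inherited from the scaling definitions.

## Ontology aggregation

Terms come from a StringDB-multiprotein-style export restricted to GO
Process/Function/Component, KEGG, Reactome and WikiPathways. Terms need
**coverage** (observed/background gene count) of at least 25%, so that a
term mean reflects the measured proteome rather than a small biased
subset. Per term, the scaled fold changes of member proteins are averaged
(abundance and turnover separately); the abundance values are tested
against zero with a one-sample t-test, and the p-values of all tested
terms in a comparison form one Benjamini–Hochberg family, with
significance called at adjusted p < 0.05. Turnover means are descriptive
only — the turnover cohort is sparser, and testing it would change the
inference from "which functions shift" to "which functions shift in both
assays", a different question. Terms with fewer than two members carrying
an abundance fold change, or zero spread, are reported untested.

Near-duplicate significant terms (row-wise protein overlap above 75%, a
configurable convention; "highly similar" has no canonical threshold) are
collapsed to the member-richest term, ties broken lexicographically, and
dropped terms recorded with their representative. Classification into the
four regulation modes uses the signs of the two term means; an optional
dead zone `epsilon` (default 0) maps near-zero means to indeterminate, as
is any term without turnover coverage.

## What the synthetic data emulate — and what they do not

`simulationConfig()` fixes the study design: 3 genotypes (E2/E3/E4, E3
control), 8 datasets with 4 samples per genotype each, labeling at 0,
0.25, 1, 4, 16 and 32 days, 1–5 peptides per protein (so the
unique-peptide filter has real effect). Default noise: log2 abundance sd
0.25, fraction-new sd 0.03, 5% missing cells, per-sample offset sd 0.1
log2. Two further knobs exist so the normalization stages are genuinely
exercised rather than vacuous: a per-dataset offset (sd 0.2 log2) and a
per-sample distribution-width factor (sd 0.05 log2) that only slope
normalization can undo.

Regulation classes are realized as coordinated $(k_{syn}, k_{deg})$
changes so that all four quadrants occur: degradation classes move
$k_{deg}$ alone (abundance and turnover counter-move); synthesis classes
move $k_{syn}$ by 1.5× and $k_{deg}$ by 0.5× the log2 effect, so
abundance moves by the full effect and turnover co-moves by half. A pure
$k_{syn}$ change would move abundance with *zero* turnover change and
could never populate the synthesis quadrants.

The generator does **not** emulate: peptide-level abundance variation and
protein rollup, isotope-envelope extraction noise, retention-time drift,
batch-correlated (non-independent) missingness, heavy-tailed or
intensity-dependent noise, or disagreement between peptides of one
protein beyond independent Gaussian noise. Passing the end-to-end checks
therefore demonstrates that the analysis machinery is correct and
well-calibrated under its own model — not that real LC-MS data satisfy
that model.

## Numerical conventions and degenerate inputs

* Time is in days (6 h = 0.25). Fraction-new values in $[-0.2, 1.2]$ are
  admitted as measurements.
* $R^2$ may be negative for terrible fits; the 0.6 threshold applies
  regardless. A zero-spread response leaves $R^2$ undefined (NA), which
  fails the filter.
* Replicate measurements at one timepoint all enter the SSE unweighted.
* Constant vectors are rejected by both scalings (degenerate); a sample
  slope below $10^{-6}$ in magnitude is an error rather than a silent
  division.
* KNN ties resolve by row order; with fewer than `k` eligible neighbours
  the available ones are used, with none the sample mean is used (with a
  warning).
* The stage slot of `AbundanceExperiment` makes the normalization order
  (raw → centered → slope-normalized → imputed) explicit and
  irreversible; each transform validates its input stage.
* All simulation randomness derives from one user seed; identical
  configurations reproduce results bit for bit.

## Problem sizes used in the shipped checks

The packaged validation runs use 250–400 simulated proteins, 1000 null
ontology terms for calibration checks, and 100 pipeline replicates for the
noisy quadrant-recovery estimate — sizes at which the binomial confidence
bands are tight enough to be informative while a full validation pass
stays comfortable on a laptop. Scaling the generator up changes none of
the code paths.

## Known limitations

* Scaled fold changes are relative to the cohort mean (see above).
* The one-sample t-test treats member proteins as independent; proteins
  shared between correlated complexes violate this mildly.
* No background-based enrichment statistic is computed: the package
  aggregates fold changes over a fixed membership table, it does not
  re-run enrichment, traverse the GO graph, or query any live service.
* Protein-level abundance p-values are reported per dataset and not
  combined; significance is assessed at ontology level only.
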