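# ProteoTurn

Is a protein more abundant because the cell makes more of it, or because it
degrades less? Abundance measurements alone cannot tell. ProteoTurn answers
the question by joining two orthogonal proteomics readouts:

* **label-free quantification (LFQ)** — protein peak areas across samples,
  giving abundance fold changes (Δabundance);
* **heavy-water (D₂O) metabolic labeling** — time courses of the newly
  synthesized protein fraction, giving turnover-rate fold changes
  (Δturnover).

It is written for quantitative proteomics analysts comparing genotypes,
treatments or disease states across multi-dataset study designs (blocks,
sexes, subcellular fractions), and ships a full synthetic-data generator so
every stage is testable without instrument data.

## The model

Each protein follows zero-order synthesis and first-order degradation,
`d[P]/dt = k_syn − k_deg·[P]`, so at homeostasis `[P] = k_syn/k_deg`. After
the precursor pool is deuterated at *t* = 0, the measurable labeled
fraction follows `f(t) = 1 − exp(−k_deg·t)`, and the turnover rate is
`k_turnover = ½(k_syn/[P] + k_deg)` (equal to `k_deg` at homeostasis).
Because `[P]` fixes only the *ratio* of the rates while `f(t)` tracks their
*magnitude*, the sign pair (Δabundance, Δturnover) identifies the
regulatory mode:

| Δabundance | Δturnover | mode                 |
|-----------:|----------:|----------------------|
| +          | +         | synthesis up         |
| +          | −         | degradation down     |
| −          | +         | degradation up       |
| −          | −         | synthesis down       |

The inference is drawn at functional-ontology level (GO, KEGG, Reactome,
WikiPathways): member proteins' scaled fold changes are averaged per term,
tested against zero with a one-sample t-test, Benjamini–Hochberg corrected
(significant at adjusted p < 0.05), and classified by quadrant.

The pipeline stages: peptide-level exponential curve fitting with quality
gates (≥3 non-zero timepoints, RMS deviation < 0.1; protein-level
R² ≥ 0.6, >1 unique peptide, rate > 0) → per-cohort rate averaging and
log2 fold changes with auto scaling; LFQ missingness filtering (≤1 missing
value per genotype), log2 + mean centering, per-sample slope
normalization, 2-nearest-neighbour imputation, F-test-gated t-tests,
cross-dataset averaging and range scaling; coverage-filtered (≥25%)
ontology aggregation with redundancy resolution.

## Worked example

Simulate a study (3 genotypes, 8 datasets, 6 labeling timepoints) in which
60% of 200 proteins are regulated, 15% per mode, then run everything:

```r
library(ProteoTurn)

cfg <- simulationConfig(n_proteins = 200, seed = 42,
    class_fractions = c(synthesis_up = 0.15, degradation_down = 0.15,
                        degradation_up = 0.15, synthesis_down = 0.15))
res <- runPipeline(cfg)
res$comparisons$E2vsE3
#> ComparisonResult: E2vsE3
#>   proteins with abundance FC: 200
#>   proteins with turnover FC:  156
#>   ontology terms: 40 (significant, non-redundant: 7 )
```

All 200 proteins get an abundance fold change; only 156 pass the stricter
turnover quality gates (proteins with a single detected peptide are
excluded, mirroring the sparser coverage of kinetic data). The
ontology summary ranks the significant terms:

```r
ont <- ontologySummary(res$comparisons$E2vsE3)
sig <- ont[ont$significant & is.na(ont$representative_of),
           c("term_id", "n_abund", "mean_dabundance", "mean_dturnover",
             "bh_pv", "regulation_class")]
head(sig[order(sig$bh_pv), ], 5)
#>                        term_id n_abund mean_dabundance mean_dturnover    bh_pv
#>      DES:E2vsE3:synthesis_up:1      20           0.417          0.727 4.30e-21
#>  DES:E2vsE3:degradation_down:2      19           0.402         -1.693 4.73e-19
#>      DES:E2vsE3:synthesis_up:2      14           0.416          0.714 1.34e-17
#>    DES:E2vsE3:synthesis_down:2      15          -0.436         -0.762 1.54e-16
#>    DES:E2vsE3:degradation_up:2      13          -0.421          1.558 3.87e-14
#>  regulation_class
#>      synthesis_up
#>  degradation_down
#>      synthesis_up
#>    synthesis_down
#>    degradation_up
```

Each row is one functional term: `n_abund` members with an abundance fold
change, the two scaled means whose signs give the quadrant, and the
adjusted p-value of the abundance test. Every designed term lands in the
regulation mode it was constructed from:

```r
rec <- evaluateClassRecovery(res)
sum(rec$correct); nrow(rec)
#> [1] 16
#> [1] 16
```

`runPipeline(cfg, outdir = "out")` additionally writes fold-change TSVs,
ontology CSVs, a run manifest, and the figures (proteostasis quadrant
scatter, per-term Δabundance/Δturnover bars, protein-overlap heatmap) as
SVG and PNG. Real data enter through `readTimeCourses()`,
`readAbundanceTable()` and `parseEnrichmentTable()` in place of the
simulators.

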