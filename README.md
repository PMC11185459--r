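# metaboPost

Post-processing, annotation and quality control for untargeted LC-MS
metabolomics feature tables, in R.

Preprocessors (Asari, XCMS, MZmine, vendor software) turn raw LC-MS runs
into a *feature table*: one row per aligned m/z–retention-time signal,
one intensity column per acquisition. Everything that happens between
that table and a biologically interpretable result — removing
contamination and failed injections, normalizing, grouping the many
degenerate ions of each metabolite, attaching identities at explicit
confidence levels, and exporting something downstream tools can read —
is what this package does. It is aimed at bioinformaticians who receive
feature tables from a metabolomics core and need a reproducible,
scriptable path to an annotated, QC'd result.

## What is in the box

**Curation.** The recommended stage order is blank masking → outlier
sample removal → normalization → infrequent-feature removal →
imputation:

- `blankMask()` keeps a feature only when its mean study intensity is at
  least 3× (configurable) its mean intensity in blank acquisitions.
- `dropOutlierSamples()` removes samples with |Z| > 2.5 on the
  feature-count metric, where Z = (x − mean)/σ_pop. `sampleZscores()`
  also offers missing-count and median inter-sample Pearson correlation
  metrics; `detectFailedInjections()` flags the one-sided low tail,
  which is how failed injections present.
- `normalizeTIC()` scales each sample by median(TIC)/TIC_s, with TIC
  computed over *conserved* features (present in ≥ 90% of samples). In
  two-pass mode samples are first scaled within their batch, then the
  batches are scaled to one another by their median TICs.
- `dropInfrequentFeatures()`, `imputeMissing()` (each missing cell
  becomes 0.5 × the feature's minimum observed intensity), and
  `batchCorrect()` (a ComBat wrapper, run after imputation).

**Pre-annotation.** `buildEmpiricalCompounds()` groups degenerate
features — isotopologues (M+1 ≈ +1.003355 Da per ¹³C) and adducts
(M+H⁺, M+Na⁺, M+NH₄⁺, …) — into *empirical compounds*. Features link
when they co-elute (|Δrt| ≤ 2 s) and their m/z difference matches an
isotope step or adduct-pair difference within 5 ppm; connected
components are laid onto an isotope × adduct grid around a consensus
neutral mass M, each member implying M = m/z·|z| − offset. The
empirical compound is the unit that carries annotations, so databases
are queried once per compound instead of once per degenerate feature.

**Annotation** at explicit confidence levels, all hits retained:

| level | evidence |
|-------|----------|
| 1a | MS² match to an authentic-standard spectrum |
| 1b | m/z + retention-time match to an authentic standard |
| 2 | MS² match to a public spectral library |
| 4 | neutral-mass match to a compound database |

MS² spectra (extracted from centroided mzML via `extractMS2()`, or read
from MSP/MGF) are mapped to empirical compounds through an
interval-tree precursor index (`buildPrecursorIndex()`), and scored
with a greedy cosine: peak pairs within 0.01 Da are taken in order of
descending intensity product, each peak used once, and
score = Σ I_q·I_r / (‖I_q‖‖I_r‖).

**Output.** `empcpdsToJSON()` writes a chainable empirical-compound
JSON (schema in `inst/extdata/empcpd-schema-1.0.json`);
`emitThreeTables()` writes the standardized three-table export (feature
table, one-row-per-annotation table, sample metadata);
`assembleReport()` renders a PDF with PCA, log TICs, correlation
clustermaps, missing-feature Z-scores, annotation accounting, a
timestamp and the full command timeline.

**Synthetic experiments.** `makeSyntheticExperiment()` generates
feature tables with planted compounds, ion ladders, batch effects,
blanks, contamination, failed injections, MS² spectra and annotation
sources, and `scoreRecovery()` scores grouping against that truth — so
the whole pipeline is testable without instrument data.

## A worked example

Three features measured in two samples: the protonated ion of a
180.063389 Da compound, its ¹³C isotopologue, and its sodium adduct.

```r
library(metaboPost)

mat <- matrix(c(52000, 13400, 15800, 49600, 12700, 16100), 3, 2,
              dimnames = list(c("F187", "F188", "F241"),
                              c("sampleA", "sampleB")))
ft <- FeatureTable(mat,
                   mz    = c(181.070665, 182.074020, 203.052609),
                   rtime = c(100.0, 100.3, 99.8))
empcpds <- buildEmpiricalCompounds(ft, defaultIonTable("pos"),
                                   mzTolPpm = 5, rtTolS = 2)
empcpds[[1]]
#> EmpiricalCompound E00001 (pos): 3 member(s), M = 180.063390
#>   F187[M0,M+H+] F188[13C/3C1,M+H+] F241[M0,M+Na+]
#>   MS2 spectra: 0  annotations: 0
```

The three ions collapse into one empirical compound; the neutral mass
is the mean of the member back-calculations (181.070665 − 1.007276,
182.074020 − 2.010631, 203.052609 − 22.989218). Querying a compound
database appends level-4 annotations — both glucose and fructose,
because mass alone cannot separate isomers, which is exactly what the
level is meant to express:

```r
db <- data.frame(name = c("glucose", "fructose"),
                 neutral_mass = c(180.06339, 180.06339))
annotated <- annotateLevel4(empcpds, db, mzTolPpm = 5)
for (a in annotations(annotated[[1]]))
  cat(sprintf("level %s  %-8s  ppm error %+.2f\n",
              a$level, a$candidate_name, a$evidence$ppm_error))
#> level 4  glucose   ppm error -0.00
#> level 4  fructose  ppm error -0.00
```

A chainable command-line interface over the same functions ships in
`inst/scripts/metaboPost` (subcommands `assemble`, `blank_masking`,
`drop_outliers`, `normalize`, `drop_infrequent`, `impute`,
`build_empcpds`, `l4_annotate`, `l1b_annotate`, `l2_annotate`, `qaqc`,
`report`, `finish`, each taking
`--experiment DIR --input-moniker X --output-moniker Y`).

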