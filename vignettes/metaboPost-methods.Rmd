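---
title: "Methods: curation, pre-annotation and multi-level annotation of LC-MS feature tables"
author: "metaboPost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, pre-annotation and multi-level annotation of LC-MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter, the numerical choices made
where a published description leaves room, and what the synthetic test
bed does and does not demonstrate about real data.

## The data model

A `FeatureTable` is a `SummarizedExperiment` whose single `intensity`
assay holds one row per feature (an m/z–retention-time signal aligned
across samples) and one column per acquisition, with `mz` (Daltons) and
`rtime` (seconds) in the row metadata. Two conventions hold everywhere:

- **Missing = 0.** A zero intensity encodes a missing measurement.
  Preprocessor outputs commonly use this convention, and adopting a
  single one end-to-end prevents stages from silently double-handling
  `NA` versus 0. The cost is that a true measured zero cannot be
  represented; for peak-integrated LC-MS intensities this case does not
  meaningfully occur.
- **Seconds throughout.** Retention-time tolerances are quoted in
  seconds everywhere; tables declaring minutes are converted once, at
  the reader boundary (`tableDialect(rtimeUnit = "minutes")`), to
  avoid 60× unit bugs in the middle of a workflow.

An `EmpiricalCompound` is a group of degenerate features — the
isotopologues and adducts of one tentative compound — carrying an
inferred neutral mass and a *list* of annotation records. The list is
append-only by design: annotation tools chain, each adding candidates
with an explicit confidence level, and nothing is suppressed. Ranking
(`rankAnnotations()`) orders by level precedence 1a > 1b > 2 > 4 and
then score, but ordering is presentation, not selection. The JSON
serialization (`empcpdsToJSON()`, schema
`inst/extdata/empcpd-schema-1.0.json`) writes numbers at 17
significant digits so that deserialization inverts serialization
exactly; the schema is versioned because the document is an
interoperability contract, not an internal cache.

## Curation stages

The recommended order is blank masking, outlier sample removal,
normalization, infrequent-feature removal, imputation — each stage
removes a bias the next one would otherwise absorb (e.g. contaminated
features inflate TICs; failed injections distort the TIC median;
normalization before imputation keeps imputed values on the corrected
scale).

**Blank masking.** A feature is kept when
mean(study, nonmissing) ≥ *r* × mean(blank, missing-as-0), default
*r* = 3. The named stage is standard practice; this ratio-of-means
formula is this package's concrete definition of it, chosen because it
is monotone in *r* (raising the threshold can only shrink the retained
set, which the tests assert) and treats features absent from all
blanks as trivially clean. Study means are taken over nonmissing
values so that a feature's prevalence does not dilute its evidence;
blank means count missing as zero so that sporadic blank carryover is
averaged, not ignored.

**Z-scores.** All sample quality metrics are standardized as
Z = (x − mean)/σ with the *population* σ (n divisor). The choice is
deliberate: with the sample σ the small worked examples used in the
tests (feature counts [100,100,100,100,40] → Z = −2.0; nine 100s and
one 10 → Z = −3.0) would not come out to round numbers, and nothing
downstream depends on the distinction at realistic n. Outlier *removal*
(`dropOutlierSamples`) is two-sided at |Z| > 2.5 on feature count —
the pipeline default. Failed-injection *detection*
(`detectFailedInjections`) is one-sided low, because an injection
failure can only lose features; a sample with anomalously many features
is suspicious but not a failed injection. Z-scores are computed once on
the input table, not recomputed iteratively after each removal, so the
operation is a single deterministic pass. The correlation metric uses
Pearson correlation of log10(intensity + 1) over features observed in
both samples of a pair; the log stabilizes the correlation against the
heavy right tail of intensity distributions, and restricting to shared
observations keeps structural missingness from masquerading as
dissimilarity.

**TIC normalization.** The TIC of a sample is the summed intensity of
the *conserved* features — those observed in at least 90% of samples
(default `conservedFraction`). Restricting to conserved features keeps
the normalizer from being driven by features that drop in and out.
One-pass mode scales every sample by median(TIC)/TIC_s. Two-pass mode
first scales samples to their batch-median TIC, then scales each batch
by global-median(pass-1 TICs)/batch-median. After either mode all
conserved-feature TICs are equal to the applicable median, and the
tests assert equality within relative 1e-9 (the residual is floating
point, not method). A planted pure batch-scale effect (×k on every
intensity of a batch) is removed exactly, up to one global factor
common to all samples — between-batch structure is what normalization
can and should remove; the absolute scale is arbitrary. A sample with
zero TIC is a hard error naming the sample: it is a failed injection
that should have been dropped, and silently dividing by zero or
skipping it would hide a data-quality problem.

**Filtering and imputation.** `dropInfrequentFeatures` keeps features
present in ≥ 50% of samples (inclusive bound; the boundary case is
tested). `imputeMissing` replaces each zero with 0.5 × the feature's
minimum observed intensity — the scalar-minimum scheme; it touches only
zeros, hence is idempotent, and refuses features with no observed value
(those belong to the filter stage). The default scalar 0.5 places
imputed values just below the observed detection floor. The term
"interpolation" sometimes used for this step is treated as synonymous
with imputation; no separate interpolation stage exists.

**Batch correction.** `batchCorrect` is a thin contract wrapper around
`sva::ComBat` on log2 intensities: shape and identities preserved,
≥ 2 batches of ≥ 2 samples required, missing values refused (run it
after imputation — the empirical Bayes fit is not defined on the
zeros-as-missing convention). The algorithm itself is intentionally
external.

## Pre-annotation: the isotope × adduct grid

Feature pairs are linked when (a) they co-elute within `rtTolS`
(default 2 s) and (b) their m/z difference matches an isotope step
(+1.003355, +2.006710 Da) or a pairwise difference of adduct offsets
(e.g. Na−H = 21.981942 Da) within `mzTolPpm` (default 5 ppm). Three
choices here are package definitions where the published descriptions
are silent:

- **Tolerance on the heavier member.** "Within 5 ppm" of a *difference*
  needs a reference mass; this package uses the heavier member's m/z,
  documented so results are reproducible. The 2 s grouping tolerance
  is a package default for modern UHPLC peak alignment, not an
  inherited value.
- **Isotope plausibility gate.** An isotope link additionally requires
  the sample-wise median intensity ratio heavier/lighter (over samples
  observing both) to be ≤ 1.5. A ¹³C M+1 isotopologue of a small
  molecule cannot plausibly exceed its M0; the 1.5 ceiling leaves
  room for noise and moderately carbon-rich species while rejecting
  coincidental mass matches. Adduct links carry no such gate —
  relative adduct response is genuinely compound-dependent.
- **Combined offsets do not link.** A pair differing by isotope step
  *plus* adduct difference (e.g. M+1+Na vs M0+H) is not linked
  directly; connectivity through the intermediate ions joins such
  features into one component anyway, and keeping the candidate set
  small keeps the false-link rate down.

Connected components are then laid onto an isotope × adduct grid. For
every (feature, cell) combination the implied neutral mass is
M = |z|·m/z − iso_offset − |z|·adduct_offset; the consensus mass is the
candidate supported by the most features (within `mzTolPpm` of their
best cell). Ties in support break to the smallest total ppm error —
which systematically favors the lowest-offset interpretation, because a
grid translated to higher-offset cells scores the same absolute errors
against a smaller mass — and exact ties break to the larger mass, i.e.
anchoring at M0 and the lowest adduct. Two features claiming one cell
keep the one with the smaller ppm error; the loser becomes a singleton.
Features fitting no cell become singletons of unknown ion species with
no neutral mass. The returned compounds always partition the input
feature set — no feature is lost or duplicated, which is asserted as a
property test. Only singly charged ions are considered by default;
`maxCharge = 2` adds half-spaced isotope links and interprets the grid
at z = 2, which covers the common doubly protonated case but is not a
full multi-charge deconvolution.

The neutral mass of a compound is the mean of its members' implied
masses. When members disagree by more than the tolerance the mean is
kept and the compound flagged (`massDiscordant`), rather than erroring:
discordance is diagnostic information about a questionable grid, not a
reason to drop data.

## Annotation

Level assignment is a pure function of evidence type: neutral-mass
database match → 4; m/z + retention-time match to an authentic standard
(both gates required, defaults 5 ppm and 5 s) → 1b; MS² similarity → 2
against public libraries, 1a against authentic-standard spectra. The
ppm and second tolerances for standards matching and the MS² defaults
(fragment tolerance 0.01 Da, score cutoff 0.7, minimum 3 matched peaks,
precursor window 5 ppm, spectrum-to-compound retention tolerance 30 s)
are package defaults, stated here rather than inherited from any
particular instrument configuration; all are exposed as arguments.

The MS² score is a greedy cosine on raw intensities: candidate peak
pairs within the fragment tolerance are consumed in order of
descending intensity product, each peak used at most once, and the
score is Σ I_q·I_r over pairs divided by the product of the intensity
norms. Raw (unweighted) intensities are the simplest defensible
default; square-root or m/z weighting are common variants and the
scoring routine is isolated so they can be added without touching the
annotation logic. Matches with fewer than the minimum paired peaks are
reported with their score but flagged below threshold, so the caller
decides; the annotation stage skips them. The score is symmetric,
bounded in [0, 1], and exactly 1 for spectra identical up to scaling —
all asserted as property tests.

Precursor lookup uses an interval index: one window
[mz·(1 − tol), mz·(1 + tol)] per member feature, held exactly and
mirrored into an integer interval forest at micro-Dalton resolution
(IRanges) used as an overlap prefilter. Every prefilter hit is
re-checked against the exact bounds, so query results are identical to
a linear scan by construction — and the tests assert that identity on
randomized instances rather than trusting the argument. Because
annotation targets empirical compounds, a database is queried once per
compound, not once per degenerate feature; `annotateLevel4` exposes its
query count so the tests can assert this efficiency property.

## The synthetic test bed

`makeSyntheticExperiment` plants compounds with known neutral masses
(uniform 120–800 Da), retention times (60–1140 s), and per-compound
abundances (log-normal around 10⁶), then emits the full ion ladder per
compound with multiplicative Gaussian m/z noise (default 2 ppm
standard deviation), log-normal intensity noise (default CV 0.2),
per-batch scale factors, a configurable missing rate (default 5%),
blank acquisitions whose contamination compounds exceed their study
levels, failed injections retaining under 10% of features, and planted
MS² spectra (5% intensity noise on the library peaks) and
authentic-standard entries for configurable fractions of compounds.
The M+1 intensity is 0.25 × M0 — a mid-sized organic molecule's
carbon envelope — so the isotope plausibility gate is exercised
realistically. Everything derives from one seed; identical inputs are
reproduced bit-for-bit, which is itself a test.

Recovery scoring (`scoreRecovery`) calls a feature correctly assigned
when it lies in its compound's *representative* empirical compound: the
one containing only that compound's features and a strict majority of
them. A compound split down the middle has no representative and all
its features count as wrong; merged compounds count wholly wrong;
recovered singletons of multi-ion compounds count wrong but do not
void the majority group. Neutral-mass accuracy is evaluated on
representative compounds only — an isolated adduct pair of M+1 ions is
*correctly* re-anchored at the wrong mass by an algorithm that cannot
know the M0 ions were lost, and charging that to mass accuracy would
measure the scorer, not the method.

What the synthetic bed does **not** emulate: correlated m/z drift
(noise is i.i.d. per feature, while real calibration error drifts
slowly), retention-time drift between samples (features carry one
retention time with small jitter), chromatographic peak-shape
artifacts, in-source fragments, real fragmentation chemistry (planted
MS² peaks are random), and compound-class-dependent adduct propensity.
Passing tests therefore demonstrate algorithmic correctness under the
stated noise model, not field performance on any particular instrument.

## Problem sizes and numerics

The test suite and the acceptance script run, by choice, at desk scale:
grouping recovery on 50 compounds × 4 ions × 20 samples;
failed-injection detection over 20 replicate experiments;
interval-index equivalence on 1000 members × 1000 queries; oracle
equivalence of the linking stage on 100 random instances of ≤ 12
features against a naive pair-enumeration-plus-closure implementation
written independently of the package internals; serialization fidelity
on 100 random instances. These sizes exercise every code path with
comfortable statistical margins while keeping the whole suite fast
enough to run on every change.

Numerical conventions: TSV and JSON writers emit 17 significant digits
(the minimum that round-trips IEEE doubles); normalization equality is
asserted at relative 1e-9; cosine symmetry at 1e-12; empty tables,
header-only outputs, all-zero features, constant metrics (Z defined as
all zeros), and single-batch or single-blank degenerate inputs each
have a defined behavior (documented per function) rather than an
incidental one.

## Known limitations

- Grid conflict resolution keeps the mass-accurate feature and ejects
  the other; the full ring-topology resolution of the khipu algorithm
  is out of scope.
- Charge states above 2 are not interpreted.
- No retention-time drift correction or QC-pool-based (LOESS) signal
  drift correction; normalization addresses scale, not drift.
- `batchCorrect` requires complete data and ≥ 2 samples per batch; no
  reference-batch or covariate-preserving variants.
- The MSP/MGF readers cover the common NAME/PRECURSORMZ/peak-list
  dialects, not every vendor extension.
- t-SNE is not bundled; the QC summary reserves a slot for downstream
  embedding tools, and PCA (deterministic) is the projection used in
  reports.
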