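---
title: "Methods: behavioral endpoint segmentation and metaproteomic community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral endpoint segmentation and metaproteomic community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`vamrbiome` implements two analysis tracks that meet in one study design:
(i) segmentation of per-second larval zebrafish motor-activity traces from a
staged visual/acoustic assay into 25 behavioral endpoints, tested with a
pooled bootstrap on median differences; and (ii) proteome-weighted
community-structure and KEGG pathway-function analysis of a defined
eight-species gut consortium cultured in bioreactors, anchored by
acceptable-daily-intake dose arithmetic. A seeded synthetic-data module
generates both data types with known injected effects, so every stage has a
closed-loop test surface. This vignette explains the models, the parameters
that matter, the numerical conventions, and what the synthetic tests do and
do not demonstrate about real data.

## The assay timeline and the 25 endpoints

The assay is modeled as an explicit schedule of half-open `[start, end)`
windows in whole seconds, 0-based from assay start. The default protocol is:
21 min dark acclimation; 10 min light; 20 min dark; five low-intensity
acoustic stimuli at 1-min spacing; a 1-min rest; five high-intensity stimuli;
a 1-min rest; five habituation bouts of 30 high-intensity stimuli (1-s
stimulus, 1-s gap; bout length 60 s) delivered 1 min apart; a 3-min rest; and
a final block of five high-intensity stimuli. Every 1-s activity bin maps to
at most one window, and the windows plus declared buffers tile the full
4,623-s assay — an integer identity asserted in the tests.

Two timeline ambiguities were resolved as package conventions:

* The 21-min acclimation holds four 5-min baseline intervals (BSL1–BSL4)
  anchored at assay start, where the plate-transfer activity peak falls; the
  remaining minute (seconds 1200–1260) is a declared unassigned buffer rather
  than an extension of BSL4.
* Habituation-bout stimuli are placed at a 2-s period (1-s tone, 1-s gap),
  giving a 60-s bout; the first acoustic stimulus follows the last dark-phase
  interval back-to-back.

Each well's trace is summarized per endpoint: interval endpoints (BSL1–4,
VMR1–5, ISI1–3, IEI1–3, IBI) as mean activity per second over their pooled
windows; startle endpoints (VSR1/2, ASR1–3) as the activity in each stimulus
second, ASR blocks averaged across their five trials. The ratio metrics are:

* **ASH1** (within-bout habituation, bout 1): `last10 / (first10 + last10)`
  on sums over stimulus seconds. 0.5 means no habituation, 0 complete
  habituation. The scaling to the combined first and last sets absorbs
  individual baseline startle differences. A variant using the last-10 mean
  over the mean of the combined sets (a factor of 2 in the denominator
  contribution) is exposed for sensitivity analysis.
* **ASH1/5** (potentiation of habituation): final-bout total over
  initial-plus-final bout totals, on full 60-s bout windows — deliberately a
  different base than ASH1, mirroring the distinction between stimulus-level
  and bout-level motor activity.
* **ASHsum**: total activity across all five bout windows.
* **ASR2/3** (memory retention): `ASR3 / (ASR2 + ASR3)` on block means. The
  alternative reading `ASR3 / mean(ASR2, ASR3)` differs by a factor of 2
  only; the bounded form was chosen so all three ratios share the symmetric
  convention (0.5 under exact symmetry) and the `[0, 1]` range.

All three ratios return a missing value on `0/0` — never 0 or 0.5 — and
missing values are excluded from statistics with a logged count.

## The pooled median-difference bootstrap

For each endpoint and each group versus the control, the observed statistic
is the absolute difference in group medians (even-sized medians are the mean
of the two central order statistics). Under the null, the two groups are
pooled; each of B resamples (default 10,000) draws `n_A + n_B` values with
replacement from the pool and assigns the first `n_A` to pseudo-A,
respecting the observed group sizes. The two-sided p-value is the proportion
of bootstrap statistics that meet or exceed the observed one, so the
smallest reportable p is 0; a `(r+1)/(B+1)` variant is available behind a
flag. Pooling enforces the null; an unpooled location-shift variant
(per-group resampling, statistic centred at the observed difference) is
available as an option. All endpoint-by-comparison tests of one assay run
form a single Benjamini–Hochberg family by default — the most conservative
plate-level reading — and the family is configurable. Percentile bootstrap
confidence intervals for per-bin medians use 1,000 resamples and the
2.5th/97.5th percentiles (type-7 quantiles).

Reproducibility: one master seed; each test derives a deterministic
substream from (seed, endpoint, comparison), so results do not depend on
execution order. Inputs are sorted before resampling, making results
bit-identical under permutation of values within a group.

**Known calibration property.** The pooled bootstrap of a median difference
is mildly conservative at moderate group sizes: in the package's null
simulations (45 + 45 wells, continuous data), the raw-p rejection rate at
α = 0.05 is ≈ 0.033–0.035 rather than 0.05, stable across B and input
distributions and not attributable to tie handling. This reflects the lumpy,
slightly over-dispersed bootstrap distribution of a sample median at finite
n; the test errs on the safe side. Consequently, a location shift of one
pooled SD of the endpoint (on the median scale) at 45 wells per group is
detected through the 125-test BH family only in a minority-to-half of
simulation replicates — the acceptance suite computes and reports both
rates, and the weaker recovery property (the affected comparison attains
the smallest raw p of its endpoint family in the majority of seeds) holds
throughout.

## Proteome-weighted community structure and pathway function

Species shares are computed per sample as summed species-assigned
protein-group intensity over total species-assigned intensity; rows labelled
`unassigned` (species-ambiguous protein groups, assumed pre-resolved
upstream where possible) are excluded from the denominator and their mass
fraction logged. Shares sum to 1 per sample to within 1e-9.

Phase comparisons of species shares follow the phase-level design: values
are first averaged to one mean per bioreactor per phase; a tie-corrected
Kruskal–Wallis test across phases is followed by Dunn's pairwise z tests
(joint midranks, tie-corrected variance, two-sided normal p) with BH
adjustment across the phase pairs within each species. Dunn's test is
implemented in the package and checked against manual rank arithmetic. Fully
degenerate inputs (every value identical) return H = 0 and p = 1 rather
than NaN.

Pathway aggregation consumes KEGG-ortholog annotations: a pathway's
intensity in a sample is the summed intensity of protein groups whose KO
belongs to the pathway. A KO shared by several pathways counts fully toward
each (no splitting; configurable by supplying a reduced map). Pathways are
retained only with functional coverage ≥ 15% and ≥ 5 distinct mapped
protein groups; the coverage denominator is the pathway's KO count (the
alternative — reference-proteome protein count — is not computable from the
inputs this pipeline takes). Fold changes between phases are computed on
relative functional abundances (pathway intensity over total KO-assigned
intensity per sample) as `log2(mean_B / mean_A)`, and a pathway is flagged
when `|Log2FC| ≥ 0.2` and a Kruskal–Wallis test across the two phases gives
p < 0.05. Zero phase means yield a missing fold change with a degeneracy
flag, never ±Inf. Both filters are monotone: relaxing a threshold never
removes a retained pathway.

Ordination statistics: Bray–Curtis dissimilarities
(`sum|x_i − x_j| / sum(x_i + x_j)`, via vegan); one-way PERMANOVA with the
pseudo-F from total and within-group sums of squared dissimilarities,
p-values from label permutations as `(#{F* ≥ F} + 1)/(n_perm + 1)`, with an
exhaustive-enumeration mode for small designs; pairwise PERMANOVA p-values
adjusted with Hochberg's step-up (BH is used everywhere else). PCA is
column-centred, unscaled, with each component's sign fixed so its
largest-magnitude loading is positive. Note that permutations that preserve
the group partition (within-group reorders, and the group swap for equal
sizes) preserve F, so the attainable p floor for, e.g., a 3 + 3 design is
0.1 — not `1/(n_perm + 1)`.

## Dose arithmetic

The bioreactor concentration is anchored to the acceptable daily intake:
`daily mass = ADI × fraction × body weight`, delivered into one daily
medium-exchange volume. With ADI 0.2 mg/kg/day, 10% of ADI, 70 kg and
250 ml this gives 0.0056 mg/ml; with a molar mass of 403.4 g/mol that is
13.88 µM, reported as 13.8 µM when truncated to one decimal. The design
enumerators count 2 cohorts × 3 exposure groups × 10 flasks = 60 flasks and
8 strains × 1e9 = 8e9 inoculum cells.

## The synthetic-data generators

The behavioral generator builds a deterministic per-group mean curve on the
schedule — baseline level; an exponentially decaying dark-phase surge
starting at the light-to-dark transition (height 20, time constant 120 s);
startle spikes of amplitude 15 (low) or 40 (high) exactly in stimulus
seconds; within-bout responses decaying geometrically
(`amplitude × decay^((i−1) × accel)`, decay 0.9) — then multiplies the whole
curve by a per-well lognormal factor and adds per-bin Gaussian noise
rectified at zero (activity is non-negative; the rectification is the
documented deviation from a pure Gaussian). Two choices deserve emphasis:

* **Habituation acceleration scales the decay exponent.** A plain
  multiplicative factor on all responses cannot change the habituation
  ratio, which is scale-invariant; exponent scaling is the minimal
  modification that actually accelerates within-bout decline.
* **Per-well lognormal multiplier (sdlog 0.6, CV ≈ 80%).** Individual
  larvae differ widely in overall motility, and endpoint values averaged
  over multi-minute windows would otherwise be nearly identical across
  wells, leaving no meaningful between-well dispersion scale. The value was
  fixed as a realism choice before any acceptance measurement and not
  revisited.

The proteome generator draws intensities as
`total × species share × phase effect × bioreactor effect × pathway effect ×
protein weight × lognormal noise`, with 30 protein groups per species
(triangular weight profile), a generated pathway map (12 pathways × 10 KOs,
30% of KOs detected, 2 protein groups per detected KO), lognormal bioreactor
random effects (sdlog 0.1) and intensity noise (sdlog 0.2), 5%
species-unassigned mass, and default sampling of 4 bioreactors across
stabilization (3 d), exposure (7 d) and recovery (4 d). Ground truth
(expected renormalized shares per phase, effects, per-well multipliers) is
always emitted as a separate record; tests never reverse-engineer it from
the data.

What the generators do not emulate: plate-position and time-of-day effects,
burst/bout kinematics within a second, zero-inflated non-responders,
mass-spectrometry missingness and dynamic-range compression, and
peptide-to-protein inference ambiguity. Passing tests therefore demonstrate
the correctness of the computations under known effects — not that the
statistical pipeline is well-powered for any particular real dataset.

## Problem sizes and numerical conventions

The test suite exercises the study-scale design (6 groups × 45 wells, 25
endpoints) with reduced resample counts: B = 500 for the null-calibration
simulation (100 replicates) and effect-detection runs (50 seeds), B = 10,000
for single-test oracle comparisons, 1,000 for confidence intervals. The
acceptance script uses 40 null replicates and 20 detection seeds. Exhaustive
oracles (4^4 pooled resamples; 4! label permutations) back the Monte Carlo
machinery at toy sizes. Medians of even samples are averages of central
order statistics; quantiles are type 7; permutation and bootstrap
comparisons use a 1e-12 tolerance on the ≥ comparison to absorb floating
error; BH/Hochberg go through `stats::p.adjust`. Seeds are 32-bit; derived
substreams hash labels into `[0, 2^31)`.

## Limitations

* The ASH1 formalization and the ASR2/3 denominator follow the stated
  conventions above; the original workflow's exact formulas are not public,
  so both alternatives are exposed as options rather than asserted.
* The pooled-null reading of the bootstrap ("accounting for the number of
  observations per group") is the default; a location-shift bootstrap is
  available but untested against the original.
* Linear mixed-effects time-course comparisons are intentionally out of
  scope; the pipeline exposes per-phase tables so standard mixed-model
  tooling can be applied downstream.
* The bootstrap test's mild conservatism (above) means borderline real
  effects may require larger groups than nominal power calculations at
  α = 0.05 would suggest.
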