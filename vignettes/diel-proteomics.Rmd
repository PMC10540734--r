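---
title: "Methods: diel rhythm analysis of proteomes and phosphoproteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel rhythm analysis of proteomes and phosphoproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielprot)
```

`dielprot` analyses label-free time-course proteomics and
phosphoproteomics from entrained light–dark (diel) experiments: six
Zeitgeber times (ZT 0, 4, 8, 12, 16, 20 h after lights-on) with five
biological replicates, plus an optional dark-adaptation (DA) series at
ZT 24–96 in constant darkness. This vignette explains the statistical
models, the tunable parameters and the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Phosphopeptide motifs and variant merging

Label-free quantification reports the same phosphorylation event many
times: across charge states (2+ to 4+), missed tryptic cleavages, and
co-modifications such as methionine oxidation or N-terminal
acetylation. The unit of biological interest is the *phosphopeptide
motif*: the set of all peptide species sharing phosphorylation of a
particular residue set on a protein. `merge_variants()` groups
variants by the key (protein locus, exact set of 1-based phospho
positions) and sums their abundances per sample. Two consequences of
the exact-set key are deliberate: a doubly phosphorylated S10+S14
species is a *different* motif from the singly phosphorylated S10, and
site sets are never partially pooled.

Ambiguously localized sites are resolved first
(`resolve_ambiguous_sites()`) by cross-referencing an independent
table of most-probable site predictions keyed by (sequence, charge,
modification count). A matching prediction replaces the variant's
assignment (`reassigned`); without a match the variant keeps its sites
and is flagged `unconfirmed` (kept by default; `ambiguous = "drop"`
discards them). When predictions tie at the highest confidence and
disagree, the original assignment is retained — ties carry no
information either way. Peptides matching several proteins are
discarded (reason `shared`) to avoid double counting.

Merging conserves mass: per sample, summed motif abundance equals
summed variant abundance minus explicitly discarded variants (tested
to 1e-9 relative). It is idempotent and invariant to input order.

## Preprocessing

* `mean_normalize()` rescales each sample column so all column means
  equal the grand mean, absorbing loading differences. Idempotent.
* `arcsinh_transform()` applies `ln(x + sqrt(x^2+1))` — behaves like a
  log for large intensities but is defined at zero, which matters for
  phospho data with occasional zero-intensity cells. The `transformed`
  flag guards against double application; rhythm p-values are computed
  on this scale to stabilize variance, fold changes on the normalized,
  untransformed scale.
* `detect_outlier_replicates()` computes, per replicate, the Pearson
  correlation of its feature abundances to the per-feature median of
  all replicates at that timepoint, and flags samples with
  r² < 0.8. Correlation is computed on the transformed scale (it is
  scale-invariant anyway, but the transformed scale keeps a few
  intense features from dominating). Flagged replicates are removed,
  not down-weighted. Features with missing values at a timepoint are
  skipped for that timepoint's median; at least three replicates per
  timepoint are required for a stable median.
* `rollup_protein()` sums the unique (non-shared) peptides of a locus;
  proteins with fewer than `min_peptides = 2` quantifying peptides are
  dropped and reported. The threshold is configurable because "two or
  more" is a reporting convention, not a biological constant.

## Rhythmicity: cubic polynomial regression

For one cycle of data at six timepoints, period-estimation methods are
unreliable; instead each feature is tested by ordinary least squares
of `value ~ 1 + t + t² + t³` over all replicate observations, with an
F-test (df 3, n−4) against the intercept-only null. A cubic over a
single 24 h window can represent exactly one interior peak and one
trough — the waveform a diel rhythm should show — while tolerating
monotone drifting baselines. The time covariate is raw ZT hours 0–20
without wrap-around; duplicating ZT0 at 24 would fabricate an
observation. An intercept-only null is the default (`null = "linear"`
is available; a linear null asks a subtly different question, namely
curvature beyond drift).

Multiple testing is controlled by Benjamini–Hochberg adjustment, and a
feature is called rhythmic when `q < 0.05` *and* its peak/trough fold
change exceeds 1.5. The fold gate protects against the situation where
tiny-amplitude but consistent wobbles reach significance in
well-replicated data. Peak and trough are simply the timepoints with
the extreme within-timepoint means (ties break toward the earlier ZT,
for deterministic reporting); no phase interpolation is attempted at
4 h sampling resolution.

Zero-variance series get p = 1 by convention. A minimum-mean of zero
makes the fold infinite and is flagged rather than silently capped.

## Equivalence: exhaustive pairwise TOST

Non-significance is not evidence of non-change, so stably expressed
features are identified positively by equivalence testing: for every
pair of timepoints, two one-sided t-tests ask whether the mean
difference (transformed scale) is within ±ε, with ε = 0.3. The pair
p-value is the larger of the two one-sided p-values and the feature's
equivalence p-value is the *maximum* over all 15 pairs — the hardest
pair must pass. Pooled-variance t is the default (Welch available via
`var_equal = FALSE`). At ε = 0.3 and fold gate 1.5 no feature can be
simultaneously rhythmic and equivalent; the suite checks this
consistency on simulated data.

## Temporal patterns

`pca_profiles()` decomposes per-feature mean profiles (features are
observations, ZTs variables) after zero-centring each feature, so
components capture shape, not level. Components come from the SVD, and
each component's sign is fixed so its largest-magnitude loading is
positive — otherwise the sign is arbitrary and runs are not
comparable.

`cluster_profiles()` z-scales profiles, uses `1 − Pearson r` distance
and Ward linkage, and cuts the dendrogram with a hybrid rule
implemented in this package: branches are evaluated top-down, and a
join is split when its height exceeds the cut ceiling (default 100, on
the raw Ward height scale; a ceiling above the tree height leaves the
whole tree eligible) or exceeds `split_factor = 4` times the internal
height of its taller child — an adaptive criterion that separates
well-isolated branches without slicing homogeneous ones. Surviving
branches smaller than `min_cluster_size = 20` are left unassigned
rather than force-merged; no reassignment of unlabelled features to
the nearest cluster is performed. The cluster count is therefore an
outcome, not an input.

`category_enrichment()` treats annotations as flat term→feature sets:
Fisher's exact test on the 2×2 membership table for discrete
partitions (clusters, peak bins), or a two-sample Kolmogorov–Smirnov
test on absolute PCA loadings when the question is whether a term's
members carry systematically more weight in a component. No ontology
propagation is attempted.

## Light-regulated translation model

Protein dynamics are simulated as

$$\frac{dP}{dt} = \big((k_{syn}-1)L(t)+1\big)\,m(t) - k_{deg}P(t),
\qquad m(t) = \cos\!\big(2\pi(t-\varphi)/24\big)+1,$$

with $L(t)=1$ during the light interval and 0 at night. Defaults:
$k_{deg} = 0.1\,h^{-1}$, $k_{syn} = 4$ (synthesis four-fold faster in
light), 12 h photoperiod. The light window within each cycle is
(0, 12] h. Growth dilution is omitted (it is an order of magnitude
smaller than $k_{deg}$); a constant `dilution` term is available for
sensitivity analysis.

Numerics: lsoda with rtol 1e-9, integrated piecewise between the
light–dark switch times so the discontinuity in synthesis is never
smoothed across; 240 h of settling (transients decay as
$e^{-k_{deg}t}$, i.e. to ~4e-11 of their initial size) before the
final cycle is sampled at 0.01 h. Steady-state periodicity
(|P(240) − P(264)| relative to the cycle maximum) is checked to 1e-6.
With $k_{syn}=1$ the model is linear and the trajectory is verified
against the closed-form steady state, whose peak lags $\varphi$ by
$\arctan(\omega/k_{deg})/\omega = 4.606$ h.

`peak_time_distribution()` runs $\varphi$ over a uniform 0.1 h grid,
bins each protein peak to the nearest sampled ZT (circular, ties to
the earlier timepoint) and reports the fraction at the daytime
timepoints {ZT4, ZT8, ZT12}. With defaults this fraction is ~96%: the
light gating funnels proteins from uniformly phased mRNAs into daytime
peaks. The alternative operationalization — peak falling in the
continuous light interval, no binning — is available via
`mode = "continuous"`.

## Protein turnover from partial ¹⁵N labelling

The labelled fraction follows $f(t) = E(1 - e^{-kt})$ under three
assumptions: labelling efficiency constant over time, shared by all
proteins, and equal turnover of heavy and light pools. The efficiency
is chosen as the maximum labelled fraction observed for any protein
plus 0.01, capped at 1 (`choose_efficiency()`); the per-protein rate
is then the least-squares $k \in [10^{-5}, 10]\,h^{-1}$, located by a
log-spaced coarse grid (60 points) and golden-section refinement in
the best bracket — the 1-D objective is smooth and this recovers
noise-free rates to 1e-6 without derivative bookkeeping.

`da_fold_change()` compares DA endpoint means (ZT96 vs ZT24 by
default; the endpoints are an interpretation of "level after dark
adaptation", and other pairs can be requested).
`classify_da_change()` labels proteins changing more than the average
as those whose |log2 fold| exceeds the proteome mean |log2 fold| — an
explicit interpretation of an informal criterion.
`correlate_kdeg_fold()` reports Pearson r, p and n for the full set
and for named exclusions only: outlier exclusions are an audit-trail
input, never automatic, with a leave-one-out leverage report to
surface candidates.

## Phospho-motif sequence enrichment

`extract_windows()` takes the ±7 window (15 residues) around each
phospho-site, padding beyond the termini with `_`, which never enters
any count. `binomial_logo()` scores each (position, residue) cell by
exact binomial tails against the background per-position frequencies:
over-representation by $P(X \ge k)$, under-representation by
$P(X \le k)$, displayed as $\pm\log_{10} p$ with p floored at 1e-300.
The significance line is Bonferroni over 20 residues × 15 positions:
$-\log_{10}(0.05/300) = 3.78$. Position 0 is excluded from testing —
it is conditioned on (S/T/Y), not tested. The recommended background
is all detected sites, so enrichment reflects regulation rather than
detectability.

Kinase consensus classes are declarative patterns over the window:
proline-directed ([pS/pT]P), CDK-like ([pS/pT]PXX[K/R]), acid-directed
(D/E at any of +1..+3) and hydrophobic-directed (A/I/L/M/F/V at −5 and
+4); the hydrophobic set is configurable because the property, not the
set, is canonical. These are approximations of kinase-specific
predictors and are labelled as such. `phase_motif_enrichment()`
crosses the classes with peak-phase bins of the rhythmic motifs,
scores each cell binomially against the all-detected background rate,
and BH-adjusts across cells.

## The synthetic-data generator

`generate_ld_dataset()` emulates the study design: 6 ZTs × 5
replicates, cosine profiles `baseline × (1 + A·cos(2π(t−φ)/24))` with
`A = (fold−1)/(fold+1)` so the requested peak/trough fold is exact,
multiplicative lognormal replicate noise (right-skewed, like LC-MS
intensities — the reason the pipeline arcsinh-transforms), per-sample
loading factors, and baselines log-uniform over four decades to
exercise normalization and the peptide-count rule. Default scale
follows the study (855 proteins; 1472 motifs are requested where
needed). `generate_phospho_variants()` splits motifs into 1–6
technical variants (Dirichlet weights, constant across samples, so
merging is exactly invertible); `inject_outlier_replicate()` permutes
a severity fraction of one sample's cells so the outlier detector has
a planted, detectable target; `generate_labeling_course()` and
`generate_da_dataset()` give the turnover analyses a ground truth;
`generate_protein_sequences()` plants consensus context at stated
rates for the enrichment tests.

Everything is a pure function of its specification and seed.

What the generator does *not* emulate: identification error, missing
values not-at-random, retention-time or batch structure, correlated
noise between co-eluting peptides, or annotation bias. Passing tests
therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to every artefact of real LC-MS
data.

## Problem sizes and runtime choices

The test suite uses 2000 features for null calibration of the rhythm
test (standard error of a 5% rate ≈ 0.5 pp), 1000 for power and phase
recovery, 240 mRNA phases for the translation model (the full 0.1 h
grid), and 100 proteins for turnover recovery — sizes at which the
checked tolerances are statistically meaningful while the whole suite
runs in well under a minute.

## Known limitations

* Six timepoints of a single cycle cannot distinguish circadian from
  diel (light-driven) rhythmicity; the statistics quantify *daily*
  variation only.
* The cubic polynomial is not periodic; it is a detection device for
  one cycle, and its coefficients are not phase estimates.
* Peak assignment has 4 h resolution, limiting the phase-divergence
  analyses to that granularity.
* The hybrid tree cut is a simplified implementation of the published
  idea (height ceiling, branch criterion, minimum size) and omits the
  optional nearest-cluster reassignment stage.
* The turnover model assumes first-order decay with shared labelling
  efficiency; proteins violating these assumptions (e.g. multi-pool
  proteins) will fit poorly, visible in their SSE.
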