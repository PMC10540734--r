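# dielprot

Analysis of diel (light–dark cycle) time-course proteomics and
phosphoproteomics in R, built around the 6-timepoint × 5-replicate
label-free design used for entrained microalgal and plant cultures:
samples at Zeitgeber times ZT 0, 4, 8, 12, 16, 20 (ZT0 = dawn), with
an optional dark-adaptation series (ZT 24–96 in constant darkness).

The package is aimed at proteomics groups asking which proteins and
phosphorylation sites cycle over the day, when they peak, whether
phosphorylation tracks or diverges from protein level, and whether
light-stimulated translation or protein turnover can explain the
observed peak-phase distributions.

## What it does

* **Phosphopeptide motif merging** — collapses technical variant
  redundancy (charge states 2+–4+, missed cleavages,
  oxidation/acetylation co-modifications) into uniquely keyed,
  summed *phosphopeptide motifs*: the set of species sharing
  phosphorylation of the same residue set on a protein. Ambiguous
  site assignments are resolved against independent site predictions.
* **Preprocessing** — mean normalization, arcsinh transform
  (ln(x + √(x²+1))), replicate outlier detection by Pearson r² < 0.8
  against the per-timepoint median, and peptide→protein rollup with a
  minimum-peptide rule.
* **Rhythm statistics** — per-feature cubic polynomial regression
  (`value ~ 1 + t + t² + t³`, F-test with df 3, n−4) on the
  transformed scale, Benjamini–Hochberg FDR, and a rhythmic call at
  q < 0.05 with peak/trough fold > 1.5; equivalence of non-changing
  features by exhaustive pairwise TOST (margin ε = 0.3, feature
  p-value = max over all timepoint pairs).
* **Patterns** — shape PCA of mean profiles, Ward clustering on
  1 − Pearson distance with a dynamic hybrid tree cut (height ceiling
  100, minimum cluster size 20), peak-phase distributions, and
  protein/phospho-motif peak pairing.
* **Light-regulated translation model** — the ODE
  `dP/dt = ((k_syn−1)L+1)·m(t) − k_deg·P` with
  `m(t) = cos(2π(t−φ)/24)+1`, `L = 1` in the light;
  defaults k_deg = 0.1 h⁻¹, k_syn = 4. Simulated over a uniform
  0.1 h grid of mRNA phases φ to predict the distribution of protein
  peak times.
* **Turnover** — degradation rates from partial ¹⁵N incorporation
  courses, `f(t) = E(1 − e^(−kt))` with efficiency `E` chosen as the
  observed maximum + 0.01, and correlation of rates with
  dark-adaptation fold changes under explicit, named outlier
  exclusions.
* **Motif enrichment** — ±7 sequence windows, position-specific
  binomial (pLogo-style) residue heights with the Bonferroni line
  −log₁₀(0.05/300) = 3.78, grouped-residue binomials, and
  phase-specific kinase-consensus enrichment (proline-directed,
  CDK-like, acid-directed, hydrophobic-directed).
* **Synthetic data** — generators for every input (cosine diel
  tables, technical phospho variants, labelling courses, DA decay
  series, protein sequences with planted consensus), all pure
  functions of a spec + seed, so the full pipeline is testable
  without any download.

## Worked example

```r
library(dielprot)

# a synthetic diel study: 500 features, 30% rhythmic at fold 3, CV 10%
sim  <- generate_ld_dataset(sim_spec(n_features = 500, frac_rhythmic = 0.3,
                                     fold = 3, cv = 0.1, seed = 42))
norm <- mean_normalize(sim$table)
res  <- rhythm_analysis(norm, fdr = 0.05, fold_threshold = 1.5)
sum(res$rhythmic)
#> [1] 150
head(res[res$rhythmic, c("feature","p","q","fold","peak_zt","trough_zt")], 3)
#>  feature            p            q     fold peak_zt trough_zt
#>    f0001 2.306070e-13 1.077603e-12 2.598666       4        16
#>    f0002 3.455127e-15 2.742165e-14 3.102664       4        16
#>    f0003 1.218834e-13 6.094171e-13 2.737186      20         8
```

150 of 500 features are called rhythmic — the planted 30% fraction —
with q the BH-adjusted p-value, `fold` the max/min of within-timepoint
means, and peak/trough the ZTs of the extreme means.

```r
peak_time_distribution(translation_params())   # k_deg 0.1, k_syn 4
#> translation_sim: 240 mRNA phases; 95.8% of protein peaks at daytime timepoints
#>  zt count   fraction
#>   0     3 0.01250000
#>   4    59 0.24583333
#>   8    53 0.22083333
#>  12   118 0.49166667
#>  16     0 0.00000000
#>  20     7 0.02916667
```

Although the simulated mRNA peak phases are uniform around the clock,
light-gated synthesis concentrates ~96% of protein peaks at the
daytime timepoints (ZT4–12) — the model's explanation for
daytime-heavy protein peak distributions in measured diel proteomes.

An end-to-end demonstration on synthetic data, writing per-stage
outputs (`qc/`, `merge/`, `rhythm/`, `patterns/`, `translation/`,
`turnover/`, `motifs/`) and a run manifest:

```r
run_pipeline(out_dir = "demo_run")
```

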