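# rhythmshift

Tools for asking how a zeitgeber manipulation — here, inverting the feeding
schedule of nocturnal rodents so food arrives in the rest phase — re-times
diurnal rhythms across omics layers. Given feature-by-sample abundance
matrices (RNA-seq expression, metabolite intensities, lipid abundances)
sampled around the clock under two conditions, the package detects rhythmic
features, compares rhythm parameters between conditions, folds the
between-condition phase shift onto a circular 0–12 h window, classifies each
feature's entrainment status, and asks which pathways or target-gene sets
move together on the phase circle. A seeded synthetic-data generator with
ground-truth labels makes every stage testable without any external data.

It is written for chronobiologists and computational biologists analysing
time-restricted-feeding (or any two-condition zeitgeber) designs: typically
6 timepoints at 4-h spacing over 24 h, a few replicates per timepoint, and
two condition labels such as NRF (night-restricted, control) and DRF
(day-restricted, inverted feeding).

## The model

Each feature is fit by a cosinor at period τ:

    y(t) = M + A·cos(2π(t − φ)/τ) + ε

with mesor M, amplitude A ≥ 0, and acrophase φ ∈ [0, τ). Rhythmicity is
decided by an ensemble p-value combining the cosinor F-test, the
single-frequency Lomb–Scargle test, and a cosine-template Kendall rank test
through Fisher's statistic, with the null calibrated by Brown's
scaled-chi-square method on the sampling design (the three components are
strongly dependent, so the raw chi-square(6) reference would be
anticonservative). Benjamini–Hochberg q-values are computed per
tissue × condition × τ batch; features with q < 0.05 under **both**
conditions are *dual-oscillating* and form the universe for phase-shift
analysis.

For each dual-oscillating feature the two conditions are compared by a
joint nonlinear least-squares fit (CircaCompare-style)

    y = (M_A + ΔM·x) + (A_A + ΔA·x)·cos(2π(t − φ_A − Δφ·x)/τ),   x ∈ {0, 1}

with Wald tests on ΔM, ΔA, Δφ. The signed shift Δφ (condition B − A,
wrapped into (−12, 12]) is folded by the circular rule

    fold(Δ) = min(|Δ| mod 24, 24 − |Δ| mod 24)  ∈ [0, 12]

— e.g. a 14-h advance equals a 10-h delay and folds to 10 h — and
classified as **phase-locked** (0–4 h), **intermediate** (4–8 h), or
**phase-inverted** (8–12 h). Tissue-level entrainment is summarized by the
class percentages and the 1-h folded-shift histogram, and datasets are
integrated by the fraction of features shifted by more than 4 h.

Phase set enrichment (PSEA) maps shifts to angles θ = 2π·shift/24 and tests
each gene set against the non-member background with the rotation-invariant
Kuiper statistic (seeded permutation p, BH q). The set's *magnitude* — its
temporal cohesiveness — is the circular mean resultant length R ∈ [0, 1].
Gene-set overrepresentation (e.g. of phase-inverted genes in cistrome
target sets) uses the one-sided Fisher exact test. Period-scan detection
(20–28 h, for constant-light designs) and 12-h ultradian detection with
condition-"licensed" oscillator calls round out the toolkit.

## Worked example

Simulate a visceral-adipose-like dataset (80.46% of rhythmic features
phase-inverted by the second condition, amplitudes attenuated to 60%) and
run the full pipeline:

```r
library(rhythmshift)

spec <- tissue_archetype("VAT", n_features = 2000, seed = 7, noise_sigma = 0.03)
d    <- generate_dataset(spec)
res  <- entrainment_pipeline(d$matrix, d$design, "NRF", "DRF")
res$summary
#> Entrainment summary over 400 dual-oscillating features
#>   phase_locked        73 ( 18.25%)
#>   intermediate         5 (  1.25%)
#>   phase_inverted     322 ( 80.50%)

fold_phase_shift(c(14, -14, 20, 26))
#> [1] 10 10  4  2

head(res$records[, 1:4], 3)
#>   feature_id signed_shift folded_shift entrainment_class
#> 1     f00001     9.149805     9.149805    phase_inverted
#> 2     f00002    -8.640496     8.640496    phase_inverted
#> 3     f00003    10.140485    10.140485    phase_inverted
```

Of the 2000 simulated features, 400 are rhythmic; all are recovered as
dual-oscillating, and the recovered phase-inverted percentage (80.50%)
matches the generative mixture (80.46%) within binomial sampling error.
`res$fits_a`/`res$fits_b` hold the per-condition cosinor fits and ensemble
q-values, `res$comparisons` the per-feature Wald tests.

## The analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the whole
study on synthetic data: `01_simulate.R` (four tissue archetypes — VAT,
liver, kidney, heart — plus a metabolite-like dataset with DRF-licensed
12-h oscillators), `02_detect_rhythms.R`, `03_compare_entrain.R`
(classification, histograms, >4-h cross-dataset integration),
`04_ultradian.R`, and `05_enrichment.R` (PSEA and overrepresentation on a
synthetic gene-set collection). Each writes small summary tables under
`results/` and regenerable bulk data under `scratch/`. Run them in order
from the repository root with `Rscript`.

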