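# flightcallr

Do the nocturnal flight calls of a migrating songbird carry information
about *who* is calling? `flightcallr` is an R package for testing whether
short (tens of milliseconds) stereotyped vocalizations encode individual
identity and sex, built around the analysis design used for American
Redstart (*Setophaga ruticilla*) flight calls: spectrogram-based
energy-distribution measurements, correlation pruning, unsupervised
random-forest call similarity, permutational MANOVA, and ordination.
Because raw field recordings of this kind are rarely shared, the package
also ships a fully seeded synthetic call generator that reproduces the
statistical structure such a study assumes — per-bird acoustic
signatures, sexual dimorphism, five qualitative call-variant shapes, and
no age effect — so every stage of the pipeline is testable end to end
without field data.

## The analysis in brief

For each call clip (mono WAV, 44.1 kHz) a power spectrogram is computed
with a 256-point FFT, 256-sample Hann windows and a 38-sample advance.
From its marginal distributions — the time envelope *e(t)* = Σ_f *P(t,f)*,
the aggregate power spectrum *s(f)* = Σ_t *P(t,f)* and the aggregate
magnitude spectrum *m(f)* = Σ_t √*P(t,f)* — the package measures 95 named
quantities: cumulative-energy percentiles and the derived 90% duration
(t₉₅ − t₅) and 90% bandwidth (f₉₅ − f₅), energy concentrations and
modewidths, Shannon entropies, peak-frequency-contour statistics, and
correlation-envelope statistics. Features with pairwise Pearson |r| ≥ 0.95
are pruned.

Call similarity is the proximity of an unsupervised (synthetic-contrast)
random forest: calls *i*, *j* are similar in proportion to the fraction of
trees in which they share a terminal node. Per bird, the mean of the
C(5,2) = 10 within-individual pairwise similarities is compared with the
mean of the 5·5·35 = 875 between-individual entries by a two-sample
t-test. Group structure is tested by permutational MANOVA
(pseudo-F = [SS_A/(a−1)] / [SS_W/(n−a)] on squared inter-point
distances, permutation p-values), with whole birds permuted as blocks for
bird-level factors (sex, age) so repeated calls from one individual are
never treated as independent. Results are visualised by PCoA and NMDS
with 99% confidence ellipses on group centroids.

## Worked example

```r
library(flightcallr)

report <- run_pipeline(seed = 11)
print(report)
#> Flight-call similarity analysis (180 calls, 36 birds, 48 features)
#>   pMANOVA  sex:     F = 10.71, R2 = 0.057, p = 0.001
#>            age:     F = 3.68, R2 = 0.020, p = 0.052
#>            variant: F = 44.35, R2 = 0.503, p = 0.001
#>   within vs between individual: 0.215 vs 0.149, t = 5.9 (df 40.3), p = 7.4e-07
#>   NMDS stress = 0.131
```

Each per-factor pMANOVA here nests individual identity: sex and age are
tested by permuting whole birds as blocks. The report says: calls
separate strongly by sex (p = 0.001) and by variant class, age shows no
effect beyond its nominal false-positive rate, and calls from the same
bird are distinctly more similar to one another than to other birds'
calls — the signature of individual identity.

Lower-level pieces are available on their own:

```r
cfg  <- population_config(n_birds = 36, calls_per_bird = 5, seed = 1)
gen  <- generate_calls(cfg)                    # 180 synthetic call clips
ft   <- batch_features(gen$clips, gen$manifest)  # 180 x 95 measurements
pr   <- prune_correlated(ft, threshold = 0.95)
D    <- distance_matrix(pr$table)              # Euclidean on z-scores
permanova_terms(D, list(sex = pr$table$sex), nest_in = pr$table$bird_id)
sim  <- unsupervised_proximity(pr$table, n_trees = 4999, seed = 1)
within_between_similarity(sim)
```

Real data enter either as WAV + Raven-style selection tables
(`read_wav`, `read_selection_table`, `extract_clips`) or as a per-call
measurement CSV ingested with `read_feature_table(path, column_map = ...)`
and passed to the pipeline via the `input` config section, which skips
the audio stages.

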