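# BeatRank

Set-based discriminative measurement for ECG beat classification.

Automatic heartbeat classification from the electrocardiogram is
dominated by two difficulties: beats of one type vary strongly across
patients and recording conditions, while beats of different types can
look nearly identical. BeatRank addresses this for researchers working
with annotated ECG collections (such as the MIT-BIH Arrhythmia
Database family) by treating classification as a *ranking-by-
dissimilarity* problem over **sets** of beats rather than a
single-beat decision:

1. **Wavelet features.** Each 235-sample beat segment (90 samples
   before the annotated R peak, the peak, 144 after, at 360 Hz) is
   encoded by an 8-level discrete wavelet decomposition; the default
   encoding keeps `(max, min, mean, var)` of each of the 9 sub-bands —
   a 36-dimensional vector. Six filter families are supported
   (Bior 6.8 default, Db 14, Sym 8, Coif 5, FK 22, RBior 6.8).
2. **Metric learning to rank.** A Mahalanobis metric `w ⪰ 0` is
   learned so that, for each training beat used as a query, sorting
   the remaining beats by the score `g_w(q, x) = −(q−x)ᵀ w (q−x)`
   ranks same-class beats above different-class ones. The structural
   objective penalises each query's most-violated ranking through a
   truncated reciprocal-rank loss Δ(y) = 1 − S, with S = 1/r when the
   first correct match sits at position r ≤ k (default k = 3) and 0
   otherwise, and is optimised by a cutting-plane algorithm with an
   exact separation oracle. The factor `l` with `w = lᵀl` projects
   features so that the learned metric becomes plain Euclidean
   distance.
3. **Minority-Based Dissimilarity (MBD).** A query set `A` (test beats
   of one unknown class) is compared with each per-class corpus set
   `B` through

   D(A,B) = (1/|A_u|) Σ_{a∈A_u} d(a,B) ⊙ (1/|B_v|) Σ_{b∈B_v} d(A,b),

   where `d(a,B)` is the minimum point-to-set distance, `A_u`, `B_v`
   are the α members of each set nearest to the other
   (α = max(1, ⌊β·min(|A|,|B|)⌋), β = 1/10), and ⊙ is `sum` by
   default. MBD generalises the minimum point-wise distance (α = 1,
   `min`) and the mean approach distance (β = 1, `sum`) and resists
   outlier beats that wreck averaging measures. Classes are ranked by
   ascending dissimilarity; Rank-1 is accuracy.

An evaluation harness reproduces the full protocol (repeated
stratified halving, per-class training caps, rare-class query-set
sizes, Rank-1/Rank-5 reporting overall and per class, 16-class or
AAMI 5-class labelling), and a synthetic generator provides beats and
feature clusters with controlled morphology, imbalance, distortion and
contamination so the whole pipeline is testable offline. WFDB-format
records (`.hea`/`.dat`/`.atr`) are read natively.

## Worked example

```r
library(BeatRank)

# 4 synthetic beat classes with distinct morphology, class imbalance,
# jitter, noise and baseline wander
beats <- simulateBeats(defaultBeatSpecs(), c(120, 80, 40, 20), seed = 1)
beats
#> BeatSet: 260 beats x 235 samples, 4 classes
#>   classes: c1(120) c2(80) c3(40) c4(20)

features <- featurizeBeats(beats, family = "bior6.8", levels = 8,
                           encoding = "stats")
features
#> FeatureTable: 260 beats x 36 features, 4 classes

params <- experimentParams(nTrials = 3, setSize = 10,
                           smallClassSizes = NULL, seed = 1)
result <- runEvaluation(features, params)
result
#> RankResult [mbd]: Rank-1 100.00%, Rank-5 100.00% (3 trials)

perClassRates(result)
#>    class rank1 rank5 nSets
#> c1    c1   100   100    18
#> c2    c2   100   100    12
#> c3    c3   100   100     6
#> c4    c4   100   100     3
```

Every query set of 10 held-out beats is matched to the correct class
in all three random halvings — the four synthetic morphologies are
cleanly separable in the wavelet-statistics space, including the
20-beat minority class. On harder data (distorted, contaminated
feature clusters; see the methods vignette) the differences between
measures appear: minimum-style measures (MBD, MPD) stay accurate
while averaging measures (MAD, APD) collapse, and a learned metric
adds a further margin:

```r
clusters <- simulateFeatureClusters(defaultClusterSpec(0.1), rep(40, 4),
                                    seed = 11)
cmp <- compareMeasures(
  clusters,
  experimentParams(nTrials = 10, setSize = 10, metric = "mlr", C = 100,
                   smallClassSizes = NULL, maxIter = 30, seed = 7),
  c("mlr+mbd", "mbd", "mad", "apd", "baseline")
)
sapply(cmp, function(r) overallRates(r)["rank1"])
#> mlr+mbd.rank1     mbd.rank1     mad.rank1     apd.rank1 baseline.rank1
#>         91.25         68.75         55.00         30.00         41.88
```

A thin command-line front end over the same functions is installed at
`inst/scripts/beatrank` (`featurize`, `train`, `measure`, `evaluate`
subcommands).

Real WFDB recordings are an optional input path:
`readWfdbRecord("mitdb/100", channel = 0)` followed by
`segmentBeats()` yields a `BeatSet` ready for `featurizeBeats()`;
`mapToAami()` regroups the 16 beat symbols into the five AAMI
classes.

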