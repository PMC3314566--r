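# stabmark

Stability-aware biomarker discovery for two-class transcriptomics with
biological prior knowledge.

## The problem

Classifiers trained on expression data are accurate but fickle about
*which* features they call important: with far more features than
subjects, many feature subsets explain the data equally well, so ranked
biomarker lists barely overlap between studies or even between
resamples of one study. stabmark addresses this by injecting prior
biological knowledge — functional annotation, interaction-network
topology, or expression dependency — into the learning process, so that
biologically related features are treated as related by the classifier.

## The method

1. **Prior → similarity matrix.** Any prior enters as a symmetric
   feature-by-feature matrix *S* with entries in [0,1] and unit
   diagonal. Builders: GO semantic similarity (information content +
   Lin + best-match average), four interaction-network measures
   (normalized geodesic, Jaccard, FS-Weight-style, hypergeometric
   common-neighborhood significance), and compendium correlation /
   mutual information.
2. **Similarity → embedding.** Samples are mapped through the
   row-stochastic matrix

   *P = D⁻¹(I + α(S − I))*,

   where *D* holds the row sums and α ≥ 0 mixes the prior in (α = 0
   gives *P = I*, the no-prior baseline). Similar features get similar
   codes, which provably ties their learned weights together.
3. **Embedding → ranking.** A bootstrap ensemble of perceptrons
   (random stratified 70/30 splits, unit-norm solutions, Bayes-point
   style averaging *W* = AVE(*w<sub>t</sub>*)) ranks features by
   |*W<sub>i</sub>*|.
4. **Ranking → stability.** List reproducibility is the normalized
   Canberra distance
   Ca(T₁,T₂) = Σᵢ |τ₁(i) − τ₂(i)| / (τ₁(i) + τ₂(i)) divided by its
   random-list expectation (log 4 − 1)p + log 4 − 2: 0 = identical
   lists, ≈1 = random, ≤ ~1.4. α is tuned to minimize it.

## Worked example

Seeded synthetic data with known block structure (10 correlated blocks
of 40 features + 100 noise features, 120 samples, 2 class-informative
blocks):

```r
library(stabmark)

design <- blockDesign(seed = 11)          # the standard study conditions
ex     <- makeExpression(design)          # ExpressionDataset + ground truth
S      <- makeSimilarity(design)          # block-structured prior

tuned <- tuneAlpha(ex$dataset, S, cfg = runConfig(T = 200, seed = 11))
tuned$report
#>   alpha stability  stabilitySE meanAccuracy meanEpochs
#> 1  0.00 0.8631481 0.0004085794    0.6800000      7.180
#> 2  0.25 0.6621152 0.0004838925    0.6586111     32.280
#> 3  0.50 0.6380104 0.0005477234    0.6644444     82.830
#> 4  1.00 0.6352700 0.0012301821    0.6572222    267.285
#> 5  2.00 0.6491317 0.0004751021    0.6630556    500.000
#> 6  4.00 0.7627853 0.0004919949    0.6683333    500.000
tuned$alphaStar
#> [1] 1
```

Reading the table: at the tuned α\* = 1 the mean normalized Canberra
distance between the 200 per-split biomarker lists drops from 0.863
(no prior) to 0.635 — a 26% relative stability gain — while mean test
accuracy changes by only 2.3 percentage points, and the mean number of
perceptron epochs rises as the embedding compresses the margin. With a
scrambled prior (`makeSimilarity(design, fidelity = 0)`) the gain
collapses (≈8%): the *content* of the prior, not the mixing itself,
drives the improvement.

```r
head(featureIds(rankFeatures(tuned$best)))   # the global biomarker list
writeRankedList(rankFeatures(tuned$best), "biomarkers.tsv")
```

Real data enter through `readExpression()` (TSV/CSV, samples × features,
labels in a named column or sidecar), `readOntology()` +
`readAnnotations()`, `readInteractionGraph()` +
`readFeatureProteinMap()`, and `readSimilarity()`; `alignFeatures()`
reconciles feature universes, and `runPipeline()` (or the thin wrapper
in `inst/scripts/run-pipeline.R`) chains all stages from a YAML/JSON
config, echoing every artifact plus a config hash to an output
directory.

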