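# featureforge

Descriptor engineering and feature selection for per-residue protein
secondary structure prediction, in alignment-free settings.

Predicting the eight DSSP states (H, G, I, E, B, T, S, C) — or the
three-state helix/strand/coil collapse — without evolutionary profiles
puts all the weight on the per-residue descriptors. This package builds
and screens those descriptors:

- **Protein-block RMSD statistics.** Local backbone conformation is
  encoded as the RMSD vector of each pentapeptide to the 16 reference
  blocks (a..p) of the published structural alphabet, rebuilt from
  dihedrals with ideal geometry and superposed by least squares (proper
  rotations only). Statistics are pooled per *pattern key* — the
  fragment's equivalence class under a position-dependent reduced
  alphabet — and turned into descriptors via the Welch-style statistic

  t_j(s) = (mu_j − mu_j(s)) / sqrt( sigma_j²(s)/N_occ(s) + sigma_j²/N ),

  mapped through the normal CDF Φ(t), plus Laplace-smoothed
  probabilities of assigned block-letter strings (e.g. `ddfmm`).
- **Physicochemical descriptors.** Periodicity features
  F = |Σ_k H_k e^{2πik/T} f(k)| with Gaussian-like decay
  f(k) = exp(−A(k/n)²) over windows of T·n_T residues (helical signals
  peak near T = 3.6 and 3.0), windowed decayed sums over offset ranges,
  one-hot identities including non-canonical residues (MSE, HYP, MLY,
  ...), terminal-proximity bits, and externally computed disorder
  scores.
- **Two-stage pre-selection.** Wilks' lambda stepwise discriminant
  screening (enter/remove F thresholds 3.84/2.71), then greedy forward
  selection under a pooled-covariance LDA classifier with a marginal-gain
  stopping rule (default 5e-5), with full selection traces and curves.
- **A compact Bi-LSTM head.** Stacked bidirectional LSTM plus ReLU head
  ending in 9 logits (8 states + a mask class for unresolved residues),
  masked cross-entropy, Adam with weight decay, plateau-annealed dropout
  and learning-rate decay, early stopping. Native R with exact BPTT
  gradients (numeric-gradient verified); desk-scale by design.
- **Evaluation.** Q score (class-set agnostic), per-class and macro F1,
  and row-normalized confusion matrices, all excluding masked positions;
  three-state results aggregate the eight-state confusion through
  H,G,I→H; E,B→E; T,S,C→C.
- **Synthetic data.** Deterministic generators for chains with ideal
  segmental geometry (helix φ=−57°, ψ=−47°; strand φ=−120°, ψ=+130°;
  coil) plus angular noise, planted-signal feature matrices, and
  property tables — every module is testable offline.

I/O: PDB/mmCIF structures (via bio3d), DSSP v4 text output, FASTA (via
Biostrings), AAindex flat files and TSV property tables, YAML alphabet
and descriptor catalogs, JSON statistics serialization.

## Worked example

```r
library(featureforge)
set.seed(7)

## 1. synthetic training corpus with known geometry
corpus <- lapply(1:6, function(i)
  genChain(list(c("coil", 6), c("helix", 12), c("coil", 4), c("strand", 8),
                c("coil", 6)), noiseSd = 10, seed = i))
alph  <- loadAlphabets()["physchem5"]
stats <- accumulatePBStats(corpus, alph)
stats
#> PBStats: 192 fragments over 16 blocks; alphabets: physchem5
#>   physchem5: 185 keys, 192 fragments

## 2. descriptor columns for a fresh chain
chain <- genChain(list(c("coil", 6), c("helix", 12), c("coil", 4),
                       c("strand", 8), c("coil", 6)), noiseSd = 10, seed = 99)
pt <- genPropertyTable(seed = 7)
fm <- buildChainFeatures(chain,
  stats = stats, alphabets = alph,
  rmsdSpecs = list(rmsdDescriptorSpec("physchem5", "m"),
                   rmsdDescriptorSpec("physchem5", "d"),
                   rmsdDescriptorSpec("physchem5", "mmmmm")),
  periodicSpecs = list(periodicDescriptorSpec(pt@accession, T = 3.6, nT = 5)),
  windowSpecs = list(windowDescriptorSpec(pt@accession, -5, 6)),
  tables = setNames(list(pt), pt@accession))
fm
#> FeatureMatrix: 36 rows (0 masked) x 5 descriptors

## 3. planted-signal selection (8 classes, 5 informative / 45 noise columns)
planted <- genPlantedFeatures(nRows = 2000, nClasses = 8, nInformative = 5,
                              nNoise = 45, effectSize = 2, seed = 7)
X <- featureValues(planted); y <- featureLabels(planted)
keep  <- sdaSelect(X, y)
trace <- greedyLdaSelect(X, y, candidates = keep, seed = 7)
trace
#> SelectionTrace: 5 descriptors, final accuracy 0.8975 (candidates_exhausted)
trace@chosen
#> [1] 3 5 2 1 4        # exactly the five planted columns, noise never enters
selectionCurve(trace)[c("k95", "k99")]
#> $k95: 4    $k99: 5

## 4. evaluate the selected feature set
model <- fitLda(X[, trace@chosen], y)
pred  <- predictLda(model, X[, trace@chosen])
qScore(as.character(y), pred)
#> [1] 0.897
f1Scores(as.character(y), pred, 8)$macro
#> [1] 0.8951
```

The selection trace reads: the five planted columns are chosen before
any noise column, four of them already carry 95% of the final accuracy,
and the resulting eight-class LDA resolves the planted structure at
Q8 ≈ 0.90 on this design.

A thin command-line wrapper over the same functions ships as
`inst/scripts/featureforge` (subcommands `ingest`, `evaluate`, `synth`).

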