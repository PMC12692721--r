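---
title: "Descriptor engineering for secondary-structure prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor engineering for secondary-structure prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featureforge)
```

## The problem

Per-residue secondary-structure prediction assigns each amino acid of a
protein chain one of the eight DSSP states (H, G, I, E, B, T, S, C), or a
coarser three-state label (helix/strand/coil). Alignment-free predictors
cannot lean on evolutionary profiles, so their accuracy is determined
almost entirely by the quality of the per-residue descriptors fed to the
classifier. `featureforge` implements a descriptor-engineering pipeline
for this setting: structure-statistics descriptors built on a
protein-block structural alphabet, physicochemical periodicity and window
descriptors over AAindex-style property scales (with non-canonical
amino-acid support), and a two-stage statistical pre-selection that
reduces a large descriptor pool to a compact, mutually informative set.

A ninth, technical mask label marks residues without resolved structure.
It is never a biological class: masked positions are excluded from model
fitting, from the loss of the recurrent head, and from every evaluation
metric.

## Protein blocks and RMSD statistics

The local backbone conformation of a pentapeptide is summarized by its
RMSD to each of the 16 protein blocks (letters a..p) of the published
structural alphabet. The blocks ship as a 16 x 8 dihedral table
(`inst/extdata/pb_dihedrals.tsv`, with a provenance note); reference
coordinates (15 backbone atoms: N, CA, C of five residues) are rebuilt
from those dihedrals with ideal bond geometry (N-CA 1.458 A, CA-C
1.525 A, C-N 1.329 A; angles 111.2, 116.2, 121.7 degrees; trans peptide
bonds). Rebuilding a block from its own dihedrals and superposing onto
the stored reference reproduces it to below 1e-6 A, which the test suite
asserts for all 16 blocks.

RMSD uses least-squares superposition over proper rotations (SVD route;
reflections excluded). The suite cross-checks it against an independent
quaternion-eigenvalue implementation to 1e-9 on a thousand random
fragment pairs. RMSD is computed over the 15 backbone atoms only:
the source material is silent on the atom set, and backbone-only is the
minimal convention consistent with describing backbone configuration.

Per-residue statistics are accumulated in a single pass with Welford's
recurrence, per protein block, both globally and conditioned on the
*pattern key* of the surrounding sequence fragment. Variances are
unbiased (divisor n-1); keys seen once have undefined variance and any
descriptor depending on it returns a missing value rather than a guess.

## Reduced alphabets and pattern keys

A pentapeptide has 20^5 = 3,200,000 possible sequences, so conditioning
on the exact fragment is hopelessly sparse. Reduced alphabets pool
letters into equivalence classes, independently at each fragment
position (central residues may keep finer classes than the tails). A
fragment's pattern key is the concatenation of its per-position class
identifiers; RMSD statistics are accumulated per key. The shipped
catalog (`alphabets.yaml`) provides identity alphabets for fragment
lengths 3/5/7/11 and example groupings (aliphatic GAVLI,
sulfur-containing CM, aromatic YWF, charged, polar). Catalog names of
published alphabets whose exact memberships are not available here are
shipped as placeholders and flagged `unverified`; results obtained with
them characterize the mechanism, not the published models.

## RMSD-statistic descriptors

For block $j$ and key $s$, the descriptor is the Welch-style statistic

$$t_j(s) = \frac{\bar\mu_j - \bar\mu_j(s)}{\sqrt{\sigma_j^2(s)/N_{occ}(s) + \sigma_j^2/N}}$$

transformed through the standard normal CDF $\Phi(t)$ — the probability
that fragments carrying this key sit closer to block $j$ than the corpus
average — and finally raised to an integer power. The normal CDF is used
rather than a Student-t CDF: with realistic key counts the difference is
negligible and it avoids per-key degrees-of-freedom bookkeeping. A zero
standard error (constant sample) is clamped to t = +/-38, where the CDF
already saturates in double precision. When the corpus dwarfs the key
count the statistic folds into
$(\bar\mu_j - \bar\mu_j(s))\sqrt{N_{occ}}/\sigma_j(s)$; the tests verify
the fold shrinks monotonically with corpus size.

Multi-letter recipes ("block strings" such as `ddfmm`) are implemented
as Laplace-smoothed probabilities of the assigned block-letter string
over the key window: $(c + 1)/(N + V)$, with $V$ the number of distinct
strings observed for the alphabet. Smoothing matters because keys are
sparse by construction; an unseen key returns the uniform prior $1/V$.
A query shorter than the window matches the centred substring. Each
descriptor may be evaluated at a fixed offset from the residue it
annotates, so a position can be described by the conformational
statistics of its neighbourhood.

## Physicochemical descriptors

Property scales are one value per residue, keyed by three-letter code.
The loader reads AAindex flat files and plain TSV, and z-standardizes
the 20 canonical values by default (AAindex units are heterogeneous; a
raw mode exists). The tables under `inst/extdata` carry *synthetic*
values (labelled so) keyed by the accessions used in the descriptor
catalog, so that catalogs and tests run without external databases;
analyses of real proteins should load genuine scales.

Non-canonical residues keep their three-letter codes end to end. A
scale may carry explicit entries for them (extension TSV); under the
`fallback` policy a missing code inherits its canonical counterpart's
value (hydroxyproline falls back to proline), under `strict` it stays
missing. One-hot identity features give each configured non-canonical
code its own bit — selenomethionine sets the MSE bit, not the MET bit —
because even isosteric substitutions can carry structural signal.

The periodicity descriptor measures how strongly a property oscillates
at period $T$ around a residue:

$$F = \sqrt{\Big(\sum_k H_k \cos\tfrac{2\pi k}{T} f(k)\Big)^2 + \Big(\sum_k H_k \sin\tfrac{2\pi k}{T} f(k)\Big)^2},\qquad k = -n..n$$

with window $2n+1 = T\,n_T$ (rounded) and Gaussian-like decay
$f(k) = \exp(-A (k/n)^2)$. Two renderings were possible for the decay's
normalization; the half-window form is the default because it gives the
window edge the same attenuation $e^{-A}$ for every $(T, n_T)$,
consistent with the small scanned decay strengths (0.5-3); the
$T n_T$-normalized alternative is available via `decayNorm`. The
summation runs symmetrically over $k = -n..n$, matching the stated
window size. Canonical helices surface at periods near 3.6 and 3-10
helices near 3.0; the tests verify that a pure cosine at period 3.6
maximizes $F$ at its own period on the scan grid. Note one numerical
subtlety: exact phase invariance of $F$ for a pure sinusoid holds only
when the window spans whole periods and no decay is applied; with decay
the discrete double-frequency cross-term survives at the few-percent
level. Window (non-periodic) descriptors are decayed sums of a property
over a fixed offset range $[l, r]$ relative to the target (the window
need not contain the target itself); the decay strength defaults to
A = 1, a mid-range choice documented in the catalog since the printed
recipes list no decay column.

Chain ends are handled identically in both families: out-of-chain
offsets contribute zero (no reflection, no renormalization). This is the
simplest contract and is recorded in column metadata.

## Two-stage descriptor pre-selection

Screening thousands of candidate recipes against an 8-class target
proceeds in two stages, as a full best-subset search is intractable.

**Stage 1 — stepwise discriminant analysis.** Classical Wilks' lambda
stepwise selection: enter the candidate with the largest partial F above
`fEnter` (default 3.84), then test entered variables for removal below
`fRemove` (default 2.71). The thresholds are the conventional
chi-square-based defaults; the source procedure cites the classical
method without printing values. Near-collinear candidates are never
entered, so the retained set contains no exactly collinear pair. This
stage is cheap (scatter matrices are computed once) and cuts the pool by
orders of magnitude.

**Stage 2 — greedy forward selection under LDA.** At each step every
remaining candidate is appended in turn to the current set, a pooled-
covariance linear discriminant classifier is refit, and the
accuracy-maximizing candidate is kept (ties to the lowest column index).
Selection stops when the best marginal gain drops below `stopGain`
(default 5e-5, i.e. 0.005 percentage points — the same magnitude at
which adding one more descriptor stops paying for itself) or a cap is
reached. The trace records cumulative accuracy and marginal gains, and
`selectionCurve()` reports the smallest k reaching 95% and 99% of the
final accuracy.

Accuracy during greedy selection is evaluated on a seeded held-out split
(default 20%) by default, mirroring internal-validation practice;
`evalSplit = 0` evaluates on the training rows. The two choices probe
different things: the held-out split guards against overfit in small
candidate pools but quantizes accuracy at 1/n_eval, which can truncate
the trace a step early; training-row evaluation measures pure ranking
fidelity. The planted-signal recovery checks in this package use the
training-row protocol for exactly that reason.

LDA itself is fit with the pooled within-class covariance plus a ridge
of `1e-6 * trace(S)/d` on the diagonal (numerical safeguard; exact
singularity advises a larger ridge). Predictions are the argmax of the
linear discriminant scores with deterministic ties toward the lowest
class index. The test suite cross-checks the boundary against the
closed-form two-class Fisher direction and against an independent
discriminant implementation on random data.

Descriptor matrices are z-standardized per column before selection;
missing values (chain ends, sparse keys, out-of-range offsets) are then
imputed as zero, i.e. at the population mean, keeping them maximally
uninformative rather than inventing signal.

## The recurrent head

The classification head is a stacked bidirectional LSTM over per-residue
feature sequences followed by a ReLU feed-forward head ending in nine
logits (eight states + mask). The reference configuration is two layers
of 512 units per direction with a 2048 -> 1024 -> 512 -> 9 head; since
two directions of 512 produce 1024 features, a linear bridge maps the
LSTM output to the head input whenever the dimensions differ (for a
four-layer/1024 stack the dimensions already match). Training uses
masked cross-entropy (mask targets contribute neither loss nor
gradient), Adam (lr 1e-4, weight decay 1e-4), dropout annealed from 0.7
in steps of 0.1 at each validation plateau (no improvement of at least
1e-4 for 5 epochs — the trigger is a design choice, as only the
qualitative schedule is specified), stepwise learning-rate decay to the
1e-5 floor once dropout reaches zero, and early stopping with patience
13, retaining the best checkpoint.

The implementation is native R with exact backpropagation through time,
validated against numeric differentiation to 1e-6 in the test suite.
Sequences are processed at their natural length — no padding exists, so
batched and unbatched forward passes are exactly equal and batch order
cannot influence per-chain outputs. This implementation is intended for
desk-scale experiments and correctness work: widths in the tests are
tens of units, not the reference 512, and wall-clock scaling to the
reference configuration is outside its design envelope.

## Evaluation

`qScore()` is the fraction of correctly labelled unmasked residues and
is class-set agnostic (Q3, Q8, or a 16-state alphabet alike). Per-class
F1 is `2TP/(2TP + FP + FN)`; a class with no true and no predicted
instances scores 0, and the macro average runs over the full fixed class
set regardless of presence — a conservative convention that penalizes
absent classes rather than silently dropping them. Confusion matrices
are true-by-predicted with row normalization; three-state evaluation
aggregates the eight-state matrix through H,G,I -> H; E,B -> E;
T,S,C -> C. That mapping is fixed by the dominant community convention
(the source's own discussion of turns inside the coil class supports
T -> C). DSSP blank codes map to C; a polyproline-II code, when a DSSP
v4 variant emits one, also folds into C.

## Synthetic data: what it does and does not emulate

`genChain()` builds chains from segmentally ideal dihedrals — helix
(phi, psi) = (-57, -47), strand (-120, +130), coil drawn uniformly from
a broadly plausible region (phi in [-180, -30], psi in [-90, 180]) —
plus optional Gaussian angular noise, with generator-assigned labels.
This gives exact ground truth for geometry-level tests (an ideal helix
must select block m at every interior position) without hydrogen-bond
computation. It does **not** emulate long-range beta-sheet pairing,
irregular loop geometry, or the label noise of real DSSP assignments,
so green geometry tests certify the machinery, not real-data accuracy.
`genPlantedFeatures()` produces class-labelled rows with a known
informative column set (per-class means drawn with spread `effectSize`
in within-class standard deviations; the study condition used throughout
is 8 classes, 5 informative / 45 noise columns, effect 2, n = 2000);
recovery of the planted set is the selection pipeline's litmus test.
All generators are pure functions of (spec, seed).

## Problem sizes

The suite and the acceptance script run at deliberately small scale: a
thousand random 15-atom pairs for the superposition oracle, one hundred
random draws per equation oracle, twenty seeded replicates of the
planted-selection study, and twenty chains of 12-20 residues with a
2-layer/8-unit network for the overfit check. These sizes were chosen so
the whole evidence base recomputes in minutes on one CPU while keeping
every statistical check comfortably powered.

## Known limitations

- The shipped property tables are synthetic stand-ins; real analyses
  must supply genuine AAindex/AAindexNC scales.
- Named published reduced alphabets beyond the identity family are
  placeholders pending their exact memberships.
- The recurrent head is desk-scale; it is not a route to the reference
  configuration's throughput.
- Benchmark-scale accuracy (large non-redundant training corpora,
  language-model embeddings) is out of scope; embeddings and disorder
  scores are consumed as external per-residue files, never computed.
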