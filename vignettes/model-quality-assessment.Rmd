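---
title: "Distance-based model quality assessment, ranking and combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based model quality assessment, ranking and combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distrank)
```

## The problem

Given a pool of candidate tertiary-structure models (decoys) for one protein
target, estimation of model accuracy (EMA/QA) asks: which model should be
submitted as the top prediction, without access to the native structure? The
practical figure of merit is the *ranking loss* — the true GDT-TS of the best
model in the pool minus the true GDT-TS of the model the method ranked first.
distrank implements a distance-prediction-driven QA protocol: candidate
models are scored by how well the distance map computed from their
coordinates matches a predicted inter-residue distance map, these 2D features
are combined with pool-consensus scores in a two-level stacked regressor, and
the resulting ranking drives pool filtering, consensus model combination and
region splicing.

## Similarity metrics

Two structures are compared on their shared residues (matched by residue
index). `gdt_ts()` is the mean over the 1, 2, 4 and 8 Å cutoffs of the
maximal fraction of corresponding Ca pairs superposable within the cutoff;
`tm_score()` is the maximum of `mean(1 / (1 + (d_i/d0)^2))` with
`d0 = 1.24 (L_ref - 15)^{1/3} - 1.8` floored at 0.5 Å, normalised by the
reference length (unmatched residues count in `L_ref` but not in the sum, the
CASP treatment of unresolved residues).

Both scores require a search over superpositions. The exact optimum is found
by enumerating all residue subsets of size ≥ 3 (each fit by least-squares
Kabsch superposition) — affordable only for small chains, so `gdt_ts()` uses
it for `L ≤ 12` (`exact_max`). Above that a documented heuristic is used:
seed superpositions from all contiguous fragments of lengths 4, 8, 16 and L
at stride 4, each iteratively extended (superpose → keep residues within the
cutoff → re-superpose, at most 10 rounds, with the per-cutoff maximum taken
over every superposition visited). The same search yields the TM-score and
the TM-optimal rigid transform used for region splicing. The test suite pins
the small-chain scores to an independently written exhaustive oracle
(quaternion-based superposition), and treats the heuristic as an
approximation: symmetry under argument swap is only asserted to 0.02, and no
claim is made of third-decimal agreement with any particular GDT
implementation (LGA parameters differ between implementations anyway).

## Distance-map matching features

A model's map (`distance_map()`, Cb with Ca fallback by default — the atom
convention of the contact predictors this emulates; which atom a given
upstream predictor used is genuinely open, so both schemes are exposed) is compared with the
predicted map by nine scores (`map_match_scores()`). Image-space scores
operate on `normalize_map()` images, `min(d, 16)/16`: contacts live below
8 Å, and a 16 Å cap keeps near-contact contrast instead of letting large
distances dominate.

* **ssim** — mean structural similarity with a 7×7 uniform window and the
  standard stabilising constants on the [0, 1] image. SSIM can in principle
  be negative; the feature is clamped to [0, 1] so the record's range
  invariant holds.
* **psnr** — peak signal-to-noise on the images; infinite for identical
  inputs, capped at 100 to keep the feature finite.
* **gist** — cosine similarity of a 4×4 spatial grid of 8-bin
  gradient-orientation histograms. This is a descriptor-level stand-in for a
  Gabor-bank GIST (whose exact parameters are not published for this use);
  same grid layout, much lighter.
* **rmse** — root-mean-square difference in Å over off-diagonal cells (raw
  maps, not images).
* **recall / precision** — cell-level contact agreement: cells ≤ 8 Å at
  sequence separation ≥ 6 (the trivial near-diagonal band is ignored),
  predicted vs observed. Binarising at 8 Å is the documented choice; a
  probability-weighted variant would need calibrated map uncertainties.
* **phash** — 64-bit perceptual hash: resample to 32×32, 2D DCT, top-left
  8×8 block, median threshold; similarity is 1 − normalised Hamming
  distance.
* **pearson** — correlation over upper-triangle cells at separation ≥ 6.
* **orb** — keypoint matching on images resized to 256×256: FAST-style
  corners (≥ 12 contiguous circle pixels brighter/darker than the centre) and
  256-bit BRIEF-style binary descriptors with a fixed sampling pattern; the
  score is the matched-keypoint fraction, 0 when either image yields no
  keypoints.

Contact-level features (`contact_match_record()`) take the top L/2 predicted
contacts per sequence-separation class (short 6–11, medium 12–23, long ≥ 24 —
the CASP windows) and report their precision against the model's contacts at
8 Å; classes with no eligible pairs are flagged and score 0.

## Pool protocols

* `filter_redundant()` — within each predictor group, greedily drop the
  lower-ranked model of any pair with pairwise GDT-TS above 0.95; cross-group
  pairs are never filtered. Greedy processing in server-rank order keeps the
  better-ranked representative.
* `consensus_scores()` — mean pairwise similarity of a model to the rest of
  the pool (the clustering-QA principle). Adding near-duplicates of a model
  inflates its consensus score, which is exactly why skewed pools mislead
  clustering QA.
* `rank_average()` — mean rank position, not mean normalised score; rank
  positions are robust to incomparable score scales across source methods.
* Combination: `select_combination_set()` collects neighbours of a reference
  model (presets: "human" = within top 60 and GDT-TS > 0.7 or RMSD < 3 Å;
  "server" = GDT-TS > 0.6; both cap at 20 — both rules appear in the source
  protocols and are exposed as presets because which was applied per target
  is ambiguous), `consensus_combine()` superposes the members onto the
  reference and averages Ca coordinates (a documented stand-in for
  multi-template rebuilding with an external modelling engine — the decision
  surface, in particular the acceptance gate, is unchanged), and
  `accept_candidate()` keeps the candidate only if its GDT-TS to the
  reference is at least 0.9, otherwise the caller falls back to refinement
  (out of scope here). `splice_regions()` replaces a bad region with the
  TM-superposed donor region, keeping everything else bit-for-bit, and
  reports the junction geometry (`geometry_check()`: clashes are non-adjacent
  Ca pairs < 1.9 Å, breaks are adjacent pairs > 4.5 Å). Outputs are Ca
  traces, flagged as such in the PDB header; backbone completion and
  side-chain packing are out of scope.

## The stacked QA regressor

`train_stacked_qa()` follows the two-level architecture: ten level-1
regressors trained by tenfold cross-validation to predict GDT-TS, whose
out-of-fold predictions join the original features as inputs to one level-2
regressor. The published architecture details are not available, so the
learner is pluggable behind this contract; the default is a single
hidden-layer feed-forward network (`nnet`, size 24, weight decay 0.01,
500-iteration cap) — `nnet` is the standard single-hidden-layer
implementation in R, and at these feature dimensions one hidden layer has
ample capacity (a deeper 64/32 design was considered and would need a
hand-rolled optimiser here). The level-2 arbiter is an ensemble of five
independently initialised networks whose predictions are averaged: the
level-2 fit decides between conflicting feature families (map matching vs
consensus) and a single small network is a high-variance arbiter, while
averaging stabilises it at negligible cost. Features are median-imputed and standardised
with training-set statistics; predictions are clipped to [0, 1]; fold
assignment and weight initialisation derive from the training seed, so
refitting with the same seed reproduces predictions bit-for-bit.

## Domain parsing

`filter_hits()` drops template hits with E-value > 1, aligned length ≤ 40
target residues (read as the aligned-region length — consistent with the
40-residue rule operating on target regions), or coverage ≤ 0.5 (the coverage
denominator is left to the upstream aligner; the TSV carries it precomputed).
`parse_domains()` takes the union of retained hit intervals as the
template-based cover; every uncovered region longer than 40 residues becomes
a template-free (FM) domain, shorter gaps are absorbed into the flanking
cover (adjacent template-based segments then merge, so the choice of flank
does not change the tiling), and a target with no retained hits is a single
FM domain. Segments always tile `[1, L]` without overlap. Boundary
adjustment from top-ranked models is deliberately not implemented (a manual,
human-protocol step).

## Evaluation statistics

`ranking_loss()` as defined above; `z_scores()` standardise per-pool scores
with the population (divide-by-n) SD — the CASP convention, switchable to the
sample SD — and report the summed positive part; `skewness()` is the
unadjusted moment estimator `g1 = m3 / m2^{3/2}` (no estimator is prescribed
for this diagnostic, and g1 is the plain moments definition);
`good_fraction()` counts models strictly above a TM-score of 0.5 (the
conventional correct-fold line); `neff()` counts non-redundant sequences at
62% identity by greedy clustering in file order, with identity computed over
the query's non-gap columns and divided by the query's non-gap length (both
choices are covered by a brute-force all-pairs oracle in the tests; no √L or
length normalisation is applied — the raw cluster count is reported);
`coverage_profile()` tallies non-gap rows per query column.

## What the synthetic generator emulates — and what it does not

All tests run on synthetic fixtures, so what they show about real data is
bounded by what the generator reproduces.

* `make_native()` grows self-avoiding Ca traces with exact 3.8 Å virtual
  bonds, alternating ideal-geometry helical segments with loop steps that are
  biased to keep the chain inside a globular radius (`2.5 L^{0.38}` Å), so
  traces carry genuine short-, medium- and long-range contacts. Builds retry
  with derived sub-seeds until clean. There are no side chains, no strand
  pairing, and no physical energetics.
* `make_decoys()` adds chain-correlated Gaussian displacement (iid noise
  smoothed along the chain with a 5-residue kernel whose rows are
  unit-normalised, so the per-atom sd equals σ while the deformation is
  low-frequency). Uncorrelated per-atom noise would make GDT-TS collapse to
  nearly the same value for all decoys; the correlated field spreads it
  realistically. In mixed-level pools the decoys at the largest σ
  additionally share one pool-wide misfold deformation (plus smaller
  individual noise, total marginal sd unchanged). This mirrors how real
  server pools concentrate on a dominant wrong conformation for hard
  targets: it is precisely the regime in which clustering QA confidently
  selects a wrong-cluster model while single-model distance features do not
  — without it, independent noise produces no dense wrong cluster and the
  clustering failure mode cannot occur at all. Noise-sweep pools (a single
  σ) stay purely independent.
* The `skew` parameter reallocates decoys toward the largest σ (weights
  `exp(skew · (level − 1))`, largest-remainder rounding), producing pools
  with few good models and positively skewed quality distributions — the
  hard-target regime.
* `make_predicted_map()` is the native map plus symmetric Gaussian cell
  error, clipped at zero; the pipeline default cell error is 2.5 Å, a
  realistic magnitude for learned distance predictors (an essentially
  error-free map makes every feature rank the pool perfectly and the
  benchmark degenerate). Its `deform_sd` option derives the map from a
  coherently deformed copy of the native before adding cell noise, because
  real predictors err self-consistently on hard targets — they produce the
  map of a somewhat wrong conformation, not white noise around the true one;
  with cell noise alone the map-matching features are near-oracle top-1
  selectors on every pool, which no real benchmark shows. There is no
  distance-dependent error structure and no multi-bin probability
  representation.
* `qa_benchmark()` trains and evaluates on a *mixture* of target
  difficulties (coherent map error cycling through 0.5/1.5/3 Å, pool skew
  through 0/0.75/1.5), the regime in which map-matching features err on
  poorly predicted targets while consensus errs on skewed pools. The "best
  single feature" competitor is selected on the training pools and evaluated
  held out — selecting it on the held-out pools would hand the competitor an
  optimistic selection bias.
* `make_msa()` and `make_hit_table()` produce coverage-structured alignments
  and hit tables that exercise the Neff, coverage-profile and domain-parsing
  rules, including one decoy hit per alignment filter.

Passing tests therefore demonstrate the decision protocols, the metric
implementations, and the qualitative mechanisms (consensus inflation, skew
sensitivity of clustering QA, combination improvement on symmetric pools) —
not absolute performance on CASP pools, which depend on real model error
structure that no Gaussian deformation reproduces.

## Numerical choices and degenerate inputs

* Ties in rankings and top-k contact selection break deterministically by
  model id and (i, j) lexicographic order.
* Zero-variance label vectors train with a warning; zero-variance score
  vectors give all-zero Z-scores and zero skewness with warnings; empty
  predicted contact sets score 0 with a warning; an empty combination member
  set returns the reference unchanged (the hard-target failure mode).
* Kabsch superposition refuses fewer than 3 points or collinear inputs; the
  internal search tolerates degenerate subsets by skipping them.
* Benchmark problem sizes (the package's own choices, stated here for
  reproducibility): ranking recovery uses 12 training + 8 held-out targets of
  60 residues × 30 decoys; the skew contrast uses 20 replicates at skew 0 and
  2.5; combination improvement uses 50 trials of 8-member pools at σ = 2 Å;
  the acceptance script uses the same ranking-recovery sizes, scales the skew
  contrast down to 10 replicates per level, and reports the size it used
  alongside each value.

## Known limitations

Single chains only (first model/chain/altloc of a PDB file, hetero residues
ignored); no mmCIF; no local (per-residue) quality prediction; no refinement,
backbone completion or side-chain packing; the GDT search is a heuristic
above 12 residues; the ORB/GIST features are documented light-weight variants
of their namesakes; synthetic pools cannot certify absolute CASP-scale
performance numbers.
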