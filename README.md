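# distrank

Distance-based quality assessment, ranking and combination of protein
tertiary-structure models.

## What problem this solves

Structure-prediction pipelines produce a *pool* of candidate models (decoys)
per target and must decide, without the native structure, which to submit —
the estimation-of-model-accuracy (EMA/QA) problem. Methods split into
*single-model* QA (score one model from its own features, here: agreement
between the model's inter-residue distance map and a predicted distance map)
and *multi-model* (clustering/consensus) QA (score a model by its mean
structural similarity to the rest of the pool). Consensus is strong when the
pool contains many good, mutually similar models, and fails on hard targets
where the quality distribution is skewed and a dense cluster of wrong models
dominates. distrank implements a protocol that stacks both kinds of signal.

For a pool `{m_1..m_n}` with predicted distance map `D` it computes, per
model:

* nine map-matching scores between `D` and the model map `D(m_i)` — SSIM,
  PSNR, GIST-style descriptor similarity, RMSE, contact recall/precision,
  PHASH, Pearson, ORB-style keypoint matching;
* short/medium/long-range contact-matching scores — precision of the top L/2
  predicted contacts per sequence-separation class against the model's
  contacts (Cb ≤ 8 Å);
* the consensus score `mean_j gdt_ts(m_i, m_j)`;

and feeds them to a two-level stacked regressor (ten networks trained by
tenfold cross-validation to predict GDT-TS; their out-of-fold outputs join
the features as level-2 inputs). Around the ranker sit the pool protocols:
same-group redundancy filtering at pairwise GDT-TS > 0.95, rank averaging
across QA methods, neighbour selection (top 60, GDT-TS > 0.7 or RMSD < 3 Å,
max 20) with superpose-and-average consensus combination gated at GDT-TS ≥
0.9 to the start model, TM-score-based region splicing, alignment-driven
FM/TBM domain parsing (E-value ≤ 1, aligned length > 40, coverage > 0.5;
uncovered regions > 40 residues are template-free domains), and the CASP
evaluation statistics (ranking loss, Z-scores, skewness, Neff at 62%
identity, good-model fraction). A deterministic synthetic-fixture generator
(`make_native()`, `make_decoys()`, `make_predicted_map()`, `make_msa()`,
`make_hit_table()`) makes every stage testable offline.

## Worked example

```r
library(distrank)
fx <- simulate_target(L = 50, n_decoys = 10, seed = 7)   # native + pool + map
ft <- feature_table(fx$pool, fx$predicted_map, fx$contacts)
ft[1:4, c("model_id", "ssim", "rmse", "pearson", "long_score", "consensus")]
#>    model_id  ssim rmse pearson long_score consensus
#> 1 decoy_001 0.750 2.55   0.873       0.56     0.677
#> 2 decoy_002 0.450 6.06   0.507       0.32     0.443
#> 3 decoy_003 0.754 2.45   0.880       0.56     0.684
#> 4 decoy_004 0.350 5.82   0.556       0.16     0.377
```

Each row scores one decoy against the predicted map (`ssim`/`pearson` high
and `rmse` low = the model's distance map matches the prediction;
`long_score` = precision of the top L/2 long-range predicted contacts in the
model; `consensus` = mean pairwise GDT-TS to the rest of the pool). Rank by
consensus and evaluate against the generator's known true scores:

```r
rk <- new_ranking(ft$model_id, ft$consensus)
eval_report(data.frame(model_id = names(fx$pool$true_score),
                       true_score = unname(fx$pool$true_score),
                       predicted_score = rk$score[match(names(fx$pool$true_score),
                                                        rk$model_id)]))
#> <eval_report> loss 0.0000 (top-1 decoy_003), sum +Z 4.248, skewness -0.342, good fraction 0.700
```

Ranking loss 0 means the selected model *is* the pool's best. Combining the
top model with its ranked neighbours and applying the acceptance gate:

```r
combination_plan(rk$model_id[1], fx$pool, rk, preset = "human")
#> <combination_plan> reference decoy_003: 5 member(s), accepted (GDT-TS 0.995)
```

Five pool models passed the neighbour rules; the Ca-averaged consensus
candidate stayed within GDT-TS 0.995 of the start model, above the 0.9 gate,
so it is accepted. For training and applying the stacked ranker see
`?train_stacked_qa` / `?predict_qa`; the same pipeline is scriptable through
the CLI wrapper (`inst/cli/distrank`): `simulate`, `features`, `train`,
`rank`, `combine`, `domains`, `evaluate`.

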