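# sigaudit

Audit tools for gene-expression signature classifiers — for anyone who has
to judge whether a published "validation AUC" means anything.

## The problem

Transcriptomic signature studies often fit a classifier on a validation
cohort *using the candidate signature* and report that classifier's AUC on
the **same cohort**. With thousands of genes and a few dozen patients, this
resubstitution AUC is near 1 for almost any gene set, so it measures the
evaluation scheme, not the biology. `sigaudit` implements the two
diagnostics that expose this:

* **Random-signature resubstitution null** — draw many size-matched gene
  sets uniformly at random from the cohort's own gene list, fit a
  nearest-centroid classifier on the full cohort, score the same cohort.
  If random gene sets score as well as the candidate, the reported AUC is
  training error, full stop.
* **Leave-one-cohort-out audit** — fit once, freeze the model
  (standardization parameters and centroids), score every other cohort.
  Genuine transferable signal keeps a high held-out AUC; overfit
  signatures fall to chance (AUC ≈ 0.5).

The classifier is a nearest-centroid model over the signature genes with a
bounded continuous score `s = (d_neg − d_pos) / (d_neg + d_pos + ε)`;
AUC uses the rank (Mann–Whitney) formulation with ties counted 1/2,

```
AUC = [ Σ ranks(positives) − n₊(n₊+1)/2 ] / (n₊ n₋),
```

which equals the trapezoidal area under the swept ROC curve exactly.
A synthetic multi-cohort generator (Gaussian log-scale expression, cohort
batch shifts, imbalanced labels, partial gene-universe overlap, optional
injected signal) makes every stage runnable without any external dataset.

## Worked example

```r
library(sigaudit)

# a null study: four cohorts, 2,000 genes, no gene carries any signal
cfg     <- sim_config(effect_size = 0, seed = 20260927)
cohorts <- generate_cohorts(cfg)

# a biologically meaningless 103-gene "candidate signature"
sig <- gene_signature(
  withr::with_seed(20260928, sample(sprintf("G%06d", 1:2000), 103)),
  "candidate103")

report <- full_audit(cohorts, sig, n_draws = 50, seed = 20260927)
print(report)
```

```
<audit_report> signature 'candidate103', 4 cohorts, 50 draws per null, seed 20260927
  cohort1      null median 1.000 | resub 0.995 | held-out 0.331 0.514 0.589
  cohort2      null median 0.982 | resub 0.965 | held-out 0.282 0.517 0.457
  cohort3      null median 0.960 | resub 0.972 | held-out 0.605 0.476 0.569
  cohort4      null median 0.992 | resub 1.000 | held-out 0.574 0.476 0.604
```

Read each row as: *random* size-matched gene sets reach a median
resubstitution AUC of 0.96–1.00 on this cohort (`null median`); the
candidate signature's own training AUC (`resub`) sits right in that null;
and the same frozen model scores at chance on the cohorts it never saw
(`held-out`). That is the fingerprint of an overfit validation. With a
genuine injected signal (`effect_size = 1.5`, `batch_sd = 0`) and the true
signature, held-out AUCs are ≈ 1 instead — the audit does not flag
transferable signal (see `analysis/04_signal_recovery.R`).

`write_report(report, "results/audit")` writes a tidy per-draw CSV, the
train×test AUC grid and a JSON summary; `plot_random_null(report)` and
`plot_roc_grid(report)` draw the box-plot and ROC-grid figures.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study end to end and
narrate what they find:

1. `01_simulate_cohorts.R` — generate and write the four null cohorts, the
   YAML config and the 103-gene candidate signature.
2. `02_random_signature_null.R` — the resubstitution null per cohort
   (50 size-matched draws; writes `results/random_null_aucs.csv`).
3. `03_cross_cohort_audit.R` — the full audit grid + figures
   (`results/audit/`).
4. `04_signal_recovery.R` — positive control with a true, batch-free
   signal (`results/signal_audit/`).

Real cohorts can be audited the same way: write the expression matrix as a
genes × samples TSV (gene IDs in the first column), a `sample`/`response`
labels TSV, and the signature as one gene per line; load them with
`read_cohort()` / `read_signature()` and call `full_audit()`.

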