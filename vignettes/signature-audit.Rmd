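---
title: "Auditing expression-signature classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing expression-signature classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigaudit)
```

## The problem

A recurring failure mode in transcriptomic biomarker studies is reporting
*training* error as if it were *test* error. A gene signature is proposed, a
classifier is fit on a validation cohort using that signature, and the AUC of
that classifier **on the same cohort** is reported as the signature's
validation performance. With far more genes than patients, this
resubstitution AUC is close to 1 for almost any gene set — including gene
sets drawn at random — so it carries no evidence about the signature's
biology or its clinical utility.

`sigaudit` packages two complementary diagnostics for this situation:

1. **Random-signature resubstitution null.** Draw many gene sets of the same
   size as the candidate signature, uniformly at random from the cohort's own
   gene list, and record the resubstitution AUC of each. If the candidate's
   reported AUC sits inside this null distribution, the evaluation scheme —
   not the signature — explains the score.
2. **Leave-one-cohort-out audit.** Fit once on one cohort, freeze the model
   entirely, and score every other cohort. A signature with genuine,
   transferable signal keeps a high AUC on cohorts the model never saw; an
   overfit one falls to chance.

A synthetic multi-cohort generator reproduces the structural features these
audits need (log-scale expression, batch shifts, class imbalance, partial
gene-universe overlap), so the whole pipeline is demonstrable and testable
without access to any patient data.

## The classifier

The classifier is a nearest-centroid model over the signature genes, the
family commonly used in expression-signature validation work.

**Fitting.** Given a training cohort with expression matrix
\(x_{gi}\) (gene \(g\), sample \(i\)) and binary response labels
\(y_i \in \{0,1\}\):

* `genes_used` is the intersection of the signature with the cohort's gene
  list, kept in signature order;
* each retained gene is standardized with the mean \(m_g\) and standard
  deviation \(s_g\) computed over **all** training samples (not per class);
  genes with \(s_g = 0\) cannot be standardized and are dropped with a
  warning;
* the class centroids are the per-gene means of the standardized expression
  over responders and over non-responders respectively.

**Scoring.** A sample with standardized profile \(z\) gets

\[ s = \frac{d_- - d_+}{d_- + d_+ + \varepsilon}, \]

where \(d_+\) and \(d_-\) are its distances to the responder and
non-responder centroids and \(\varepsilon = 10^{-12}\) guards the 0/0 case of
a sample equidistant at zero distance from both centroids (possible only in
degenerate one-point geometries). The score is bounded in \([-1, 1]\),
positive when the sample is nearer the responder centroid, and monotone in
relative proximity — so the ROC curve it induces is the same as for any
other monotone function of \(d_- - d_+\). ROC and AUC depend only on the
score *ordering*, which is why the audits are insensitive to the particular
bounded form chosen here. The hard class call is \(\operatorname{sign}(s)\),
with \(s = 0\) assigned to non-responder.

Two distances are offered: Euclidean (default) and correlation
(\(1 - r\)). One caveat worth knowing: correlation distance is invariant to
a uniform per-sample shift across the signature genes, so a signal that
moves *all* signature genes by the same amount is invisible to it. The test
suite exercises the correlation metric with a heterogeneous (half up, half
down) pattern for exactly this reason.

**No leakage, by construction.** Test cohorts are standardized with the
*training* cohort's \(m_g, s_g\) — never their own — and scoring never reads
test labels. A model gene absent from a test cohort is dropped from both the
centroids and the test vectors at scoring time (with a warning giving the
count), because re-fitting or re-standardizing on test data is precisely the
mistake the audit exists to catch. The suite asserts the guard directly:
permuting a test cohort's labels changes its AUC but leaves the score vector
bit-identical.

## ROC and AUC conventions

AUC is computed by the rank (Mann–Whitney) formulation with midranks, i.e.
ties count 1/2:

\[ \mathrm{AUC} = \frac{\sum_{i \in \text{pos}} R_i - n_+(n_++1)/2}{n_+ n_-}. \]

The ROC curve is built by sweeping the unique score values from \(+\infty\)
downward (a sample is called positive when its score is at or above the
threshold); with the midrank convention the trapezoidal area under this
curve equals the rank-formula AUC exactly, and the suite property-tests that
identity on random tied inputs. Single-class label vectors and non-finite
scores are explicit errors, not silent NAs.

Box-plot summaries of AUC collections (`auc_summary()`) use type-7 quantiles
(linear interpolation between order statistics — R's default) and Tukey
whiskers: the most extreme observed values within 1.5 × IQR of the
quartiles. The quantile rule is fixed and documented because different
plotting backends disagree on it.

## The synthetic study

`generate_cohorts()` draws from an additive Gaussian model on the
log-expression scale (the scale of variance-stabilized RNA-seq transforms):

\[ x_{gi}^{(d)} = \mu_g + b_{dg} + \beta_g y_i + \epsilon_{gi}, \qquad
   \mu_g \sim N(0, 1),\;
   b_{dg} \sim N(0, \sigma_b^2),\;
   \epsilon_{gi} \sim N(0, \sigma_e^2), \]

with \(\beta_g\) equal to `effect_size` on the first `n_signal_genes` genes
and 0 elsewhere, and \(y_i \sim \text{Bernoulli}(p_d)\). Each cohort then
drops a uniformly random fraction of the gene universe, independently of the
others, so signatures match slightly different gene counts per cohort — the
situation a real multi-accession study presents.

Defaults, with rationale:

| parameter | default | units / meaning |
|---|---|---|
| `n_cohorts` | 4 | number of cohorts in the study |
| `genes_total` | 2000 | gene universe; large enough for p >> n |
| `samples_per_cohort` | 28, 49, 73, 42 | cohort sizes in the 25–75 range typical of ICT response cohorts |
| `responder_fraction` | 0.4 | responders are usually the minority class; an assumption, not a measured fact |
| `effect_size` | 0 | log-scale responder shift; 0 = null study |
| `n_signal_genes` | min(50, `genes_total`) | block of genes carrying the shift when it is nonzero |
| `batch_sd` | 0.5 | sd of per-cohort per-gene shifts, log units — comparable to half the residual sd |
| `noise_sd` | 1 | residual sd, log units |
| `gene_dropout_fraction` | 0.02 | each cohort misses ~2% of the universe |
| `seed` | 1 | everything reproduces bit-identically from it |

If label sampling leaves a tiny cohort single-class, the minimal number of
labels is flipped deterministically so both classes exist (AUC is undefined
otherwise); the repair is recorded in `metadata$labels_adjusted`.

**What the generator does *not* emulate** — and hence what passing audits do
and do not show about real data:

* genes are independent given class and batch. Real expression has strong
  gene–gene correlation, which lowers the effective dimension; the
  resubstitution inflation seen here (medians near 1.0 at 100 genes vs 26
  samples) is therefore an *upper* bound on, and more extreme than, what
  correlated real cohorts show. The direction of the phenomenon, which is
  what the audits test, is the same.
* no count layer: data are drawn directly on the transformed scale, so
  library-size effects and mean–variance coupling are out of scope.
* batch shifts are gene-wise independent Gaussians, not the structured
  platform/protocol effects of real accessions.

## Audit procedures and randomness

`random_signature_null()` performs `n_draws` (default 50) independent
uniform draws of gene sets **without replacement within a draw**, fits on
the full cohort, scores the same cohort and records the AUC. Repeated random
drawing of gene sets — not resampling of patients — is the resampling scheme
here, since the question is about gene-set identity, not sampling
variability of patients. Draw sizes come from `matched_signature_size()`,
the per-cohort count of signature genes actually present, so the null is
size-matched per cohort.

One master seed drives each audit. Per-draw (and, in `full_audit()`,
per-cohort) sub-seeds are derived from it by a single `sample.int()` call
under the master seed, so any individual draw is reproducible in isolation
and the full report reruns byte-identically. Functions restore the caller's
RNG state (`withr::with_seed`), so audits do not perturb surrounding code.

`cross_cohort_audit()` fits once on the training cohort and freezes
everything. Test cohorts that share *no* model gene are reported as failed
with a reason while the remaining cohorts are still computed. Sub-cohort
questions (e.g. auditing a treatment-scheme subset) are handled by
subsetting cohorts upstream rather than by special-casing: any
`expression_cohort` can be built from a sample subset as long as both
classes remain.

## Numerical and formatting choices

* Standard deviations use the \(n-1\) denominator (`stats::sd`), matching
  the usual convention for standardizing expression.
* \(\varepsilon = 10^{-12}\) in the score denominator; scores are otherwise
  exact arithmetic.
* Text writers format doubles with 17 significant digits, which round-trips
  IEEE doubles exactly: a written cohort or report reloads bit-identically,
  and identical audits produce byte-identical files.
* Gene matching is exact string identity; no alias resolution is attempted.
* Missing values are rejected at the reader, never imputed; expression is
  assumed already transformed and is never re-normalized.

## Problem sizes used in the tests and workflow

The bundled workflow and the end-to-end tests run at the scale the audits
are designed for: four cohorts of 26–73 samples over a 2,000-gene universe,
~100-gene signatures, 50 random draws per cohort null, 20 replicate
simulations for the chance-level check and 5 master seeds for the inflation
and signal-recovery checks. At this scale the whole suite runs in well under
a minute on a single core; all sizes are set in one place in each script and
scale up directly if sharper Monte-Carlo estimates are wanted.

## Known limitations

* The audits assume the candidate signature is a plain gene list and the
  classifier family is nearest-centroid; signatures that ship with trained
  weights or require a different model family need their own scoring hook.
* The generator's independence assumptions (see above) make it a
  demonstration and calibration instrument, not a simulator of any real
  accession.
* `auc_summary()` describes distributions; it deliberately offers no
  significance test against the null — deciding how to compare a candidate's
  AUC with the null distribution (quantile, gap, or formal test) is left to
  the analyst.
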