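#!/usr/bin/env Rscript
# Step 4: the positive control. Inject a genuine, batch-free responder
# signal (mean shift of 1.5 noise-sd on 50 genes) and audit the TRUE
# signature. A sound audit must not flag a transferable signal: held-out
# AUCs should be high, unlike the null candidate of steps 2-3.

suppressPackageStartupMessages(library(sigaudit))

config <- sim_config(
  n_cohorts = 4, genes_total = 2000,
  samples_per_cohort = c(28, 49, 73, 42),
  responder_fraction = 0.4,
  effect_size = 1.5, n_signal_genes = 50,
  batch_sd = 0, noise_sd = 1,
  gene_dropout_fraction = 0.02,
  seed = 20260927)
cohorts <- generate_cohorts(config)
signature <- signal_signature(config)

report <- suppressWarnings(
  full_audit(cohorts, signature, n_draws = 50, seed = 20260927))
print(report)
write_report(report, "results/signal_audit")

grid <- cross_cohort_table(report)
held <- grid$auc[grid$status == "test"]
cat(sprintf("\nheld-out AUC with the true signature: mean %.3f, min %.3f\n",
            mean(held), min(held)))
cat("=> the cross-cohort audit distinguishes genuine transferable signal\n")
cat("   (high held-out AUC) from overfit signatures (chance held-out AUC),\n")
cat("   while resubstitution AUC is inflated in BOTH cases.\n")
cat("Wrote results/signal_audit/\n")
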