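#!/usr/bin/env Rscript
# Step 1: generate the synthetic study -- four cohorts on the log-expression
# scale with cohort batch shifts, imbalanced responder labels and partial
# gene-universe overlap, under the NULL (no gene carries any true response
# signal). Cohorts are written as TSV pairs so the later steps exercise the
# on-disk formats, not just in-memory objects.

suppressPackageStartupMessages(library(sigaudit))

out_dir <- "results/cohorts"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- sim_config(
  n_cohorts = 4, genes_total = 2000,
  samples_per_cohort = c(28, 49, 73, 42),  # cohort sizes in the 25-75 range
  responder_fraction = 0.4,
  effect_size = 0,                          # null: no true signal anywhere
  batch_sd = 0.5, noise_sd = 1,
  gene_dropout_fraction = 0.02,             # cohorts miss ~40 genes each
  seed = 20260927)
write_sim_config(config, file.path(out_dir, "sim_config.yaml"))

cohorts <- generate_cohorts(config)
for (co in cohorts) {
  write_cohort(co, out_dir)
  print(co)
}

# a size-matched "candidate signature": 103 genes drawn once from the
# universe, echoing the size of a published immune-cell signature; under the
# null it is biologically meaningless by construction
signature <- gene_signature(
  withr::with_seed(config$seed + 1L,
                   sample(sprintf("G%06d", 1:2000), 103)),
  name = "candidate103")
write_signature(signature, file.path(out_dir, "candidate103.txt"))

sizes <- vapply(cohorts, function(co) matched_signature_size(signature, co),
                integer(1))
cat("\nSignature genes matched per cohort (103-gene signature):\n")
print(sizes)
cat("\nWrote", length(cohorts), "cohorts, the YAML config and the",
    "candidate signature to", out_dir, "\n")
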