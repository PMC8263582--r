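gene_universe_for_test <- function(n) sprintf("G%06d", seq_len(n))
expect_setdiff_empty <- function(a, b) {
  expect_true(length(setdiff(a, b)) == 0 && length(setdiff(b, a)) == 0)
}

make_cohorts <- function(seed = 1, n_cohorts = 3, genes_total = 120,
                         samples = 24, effect_size = 0, batch_sd = 0.5,
                         dropout = 0) {
  generate_cohorts(sim_config(
    n_cohorts = n_cohorts, genes_total = genes_total,
    samples_per_cohort = samples, effect_size = effect_size,
    n_signal_genes = if (effect_size > 0) 50 else 0,
    batch_sd = batch_sd, gene_dropout_fraction = dropout, seed = seed))
}

test_that("drawing the full gene set makes every null draw identical", {
  co <- make_cohorts(seed = 101, n_cohorts = 1)[[1]]
  audit <- random_signature_null(co, signature_size = length(co$genes),
                                 n_draws = 3, seed = 9)
  expect_length(audit$auc_values, 3)
  expect_equal(audit$auc_values[2], audit$auc_values[1])
  expect_equal(audit$auc_values[3], audit$auc_values[1])
})

test_that("the random-signature null is reproducible from its master seed", {
  co <- make_cohorts(seed = 102, n_cohorts = 1)[[1]]
  a <- random_signature_null(co, 40, n_draws = 8, seed = 13)
  b <- random_signature_null(co, 40, n_draws = 8, seed = 13)
  expect_identical(a, b)
  c_ <- random_signature_null(co, 40, n_draws = 8, seed = 14)
  expect_false(identical(a$auc_values, c_$auc_values))
  expect_true(all(a$auc_values >= 0 & a$auc_values <= 1))
  expect_error(random_signature_null(co, length(co$genes) + 1, 5, 1),
               "exceeds gene count")
})

test_that("matched signature size is plain set arithmetic", {
  co <- make_cohorts(seed = 103, n_cohorts = 1, genes_total = 200)[[1]]
  sig_in <- gene_signature(co$genes[1:50])
  expect_equal(matched_signature_size(sig_in, co), 50L)
  sig_out <- gene_signature(paste0("ABSENT", 1:10))
  expect_equal(matched_signature_size(sig_out, co), 0L)
  # a 103-gene signature of which 5 are missing from the cohort matches 98
  sig_mix <- gene_signature(c(co$genes[1:98], paste0("ABSENT", 1:5)),
                            "sig103")
  expect_length(sig_mix$genes, 103L)
  expect_equal(matched_signature_size(sig_mix, co), 98L)
})

test_that("duplicated cohorts give test AUC equal to resubstitution AUC", {
  co <- make_cohorts(seed = 104, n_cohorts = 1)[[1]]
  twin <- co
  twin$name <- "twin"
  sig <- gene_signature(co$genes[1:30])
  audit <- cross_cohort_audit(list(co, twin), sig, train_name = co$name)
  expect_named(audit$test_results, "twin")
  expect_equal(audit$test_results$twin$auc,
               audit$training_resubstitution$auc)
})

test_that("scoring a test cohort never reads its labels", {
  cohorts <- make_cohorts(seed = 105, n_cohorts = 2)
  sig <- gene_signature(cohorts[[1]]$genes[1:40])
  model <- fit_centroid(cohorts[[1]], sig)
  test_co <- cohorts[[2]]
  s1 <- score_centroid(model, test_co)
  shuffled <- test_co
  perm <- c(seq(2, length(test_co$labels)), 1L)  # cyclic shift, labels only
  shuffled$labels <- setNames(test_co$labels[perm], test_co$samples)
  s2 <- score_centroid(model, shuffled)
  expect_identical(unname(s1), unname(s2))
  expect_false(isTRUE(all.equal(compute_roc(s1, test_co$labels)$auc,
                                compute_roc(s2, shuffled$labels)$auc)))
})

test_that("a test cohort sharing no model genes is reported failed, others computed", {
  cohorts <- make_cohorts(seed = 106, n_cohorts = 3)
  sig <- gene_signature(cohorts[[1]]$genes[1:20])
  broken <- cohorts[[3]]
  keep <- !broken$genes %in% sig$genes
  cohorts[[3]] <- expression_cohort(broken$name,
                                    broken$values[keep, , drop = FALSE],
                                    labels = broken$labels)
  audit <- cross_cohort_audit(cohorts, sig, train_name = "cohort1")
  expect_named(audit$test_results, "cohort2")
  expect_named(audit$failed, "cohort3")
  expect_match(audit$failed[["cohort3"]], "no model gene")
  expect_error(cross_cohort_audit(cohorts, gene_signature("ABSENT1"),
                                  "cohort1"),
               "shares no genes")
  expect_error(cross_cohort_audit(cohorts, sig, "nonexistent"), "not found")
})

test_that("full audit bookkeeping: one null and one cross audit per cohort", {
  cohorts <- make_cohorts(seed = 107, n_cohorts = 4, genes_total = 150,
                          dropout = 0.05)
  sig <- gene_signature(gene_universe_for_test(150)[1:40], "sig40")
  # dropout makes some model genes absent from test cohorts: warnings expected
  report <- suppressWarnings(full_audit(cohorts, sig, n_draws = 6, seed = 17))
  expect_length(report$random_null, 4)
  expect_length(report$cross, 4)
  for (nm in names(cohorts)) {
    expect_equal(report$random_null[[nm]]$signature_size,
                 matched_signature_size(sig, cohorts[[nm]]))
    expect_setdiff_empty(names(report$cross[[nm]]$test_results),
                         setdiff(names(cohorts), nm))
  }
  tab <- cross_cohort_table(report)
  expect_equal(nrow(tab), 4 * 4)  # 1 resubstitution + 3 tests per train
  expect_equal(sum(tab$status == "resubstitution"), 4)
})

test_that("full audit reruns bit-identically and tables recompute from parts", {
  cohorts <- make_cohorts(seed = 108, n_cohorts = 3, genes_total = 100)
  sig <- gene_signature(cohorts[[1]]$genes[1:25])
  r1 <- full_audit(cohorts, sig, n_draws = 5, seed = 23)
  r2 <- full_audit(cohorts, sig, n_draws = 5, seed = 23)
  expect_identical(r1, r2)

  # recomputation oracle: per-cohort results recomputed independently match
  seeds <- withr::with_seed(23L, sample.int(.Machine$integer.max - 1L, 3))
  for (i in seq_along(cohorts)) {
    nm <- names(cohorts)[i]
    rn <- random_signature_null(cohorts[[nm]],
                                matched_signature_size(sig, cohorts[[nm]]),
                                n_draws = 5, seed = seeds[i])
    expect_equal(r1$random_null[[nm]]$auc_values, rn$auc_values)
    cc <- cross_cohort_audit(cohorts, sig, nm)
    expect_equal(r1$cross[[nm]]$training_resubstitution$auc,
                 cc$training_resubstitution$auc)
  }
  tab <- random_null_table(r1)
  expect_equal(nrow(tab), 3 * 5)
  expect_equal(mean(tab$auc),
               mean(unlist(lapply(r1$random_null, `[[`, "auc_values"))))
})
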