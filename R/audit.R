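#' Random-signature resubstitution null
#'
#' The overfitting diagnostic: draw `n_draws` gene sets of `signature_size`
#' genes uniformly without replacement from the cohort's own gene list, fit a
#' nearest-centroid classifier on the FULL cohort with each, and score the
#' same cohort (resubstitution). With many more genes than samples, random,
#' biologically meaningless gene sets reach high training AUCs; the
#' distribution of these AUCs is the null against which a reported training
#' AUC must be judged.
#'
#' One master seed drives the audit; per-draw sub-seeds are derived from it
#' so any individual draw can be reproduced in isolation.
#'
#' @param cohort An [expression_cohort()].
#' @param signature_size Number of genes per random draw; at most the
#'   cohort's gene count. Use [matched_signature_size()] to size-match a
#'   real signature.
#' @param n_draws Number of random gene sets (default 50).
#' @param seed Integer master seed.
#' @param distance_metric Passed to [fit_centroid()].
#'
#' @return An object of class `random_signature_audit`: list with
#'   `cohort_name`, `signature_size`, `n_draws`, `seed`, `auc_values`
#'   (length `n_draws`), `summary` ([auc_summary()] record).
#' @export
random_signature_null <- function(cohort, signature_size, n_draws = 50L,
                                  seed = 1L,
                                  distance_metric = c("euclidean", "correlation")) {
  stopifnot(inherits(cohort, "expression_cohort"))
  distance_metric <- match.arg(distance_metric)
  signature_size <- as.integer(signature_size)
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  if (signature_size < 1L)
    stop("signature_size must be >= 1", call. = FALSE)
  if (signature_size > length(cohort$genes))
    stop(sprintf("signature_size (%d) exceeds gene count of cohort '%s' (%d)",
                 signature_size, cohort$name, length(cohort$genes)),
         call. = FALSE)
  draw_seeds <- derive_seeds(seed, n_draws)
  auc_values <- vapply(seq_len(n_draws), function(i) {
    genes <- withr::with_seed(
      draw_seeds[i],
      cohort$genes[sample.int(length(cohort$genes), signature_size)]
    )
    sig <- gene_signature(genes, name = sprintf("random_draw_%03d", i))
    model <- fit_centroid(cohort, sig, distance_metric)
    s <- score_centroid(model, cohort)
    compute_roc(s, cohort$labels)$auc
  }, numeric(1))
  structure(
    list(cohort_name = cohort$name, signature_size = signature_size,
         n_draws = n_draws, seed = as.integer(seed),
         auc_values = auc_values, summary = auc_summary(auc_values)),
    class = "random_signature_audit"
  )
}

#' @export
print.random_signature_audit <- function(x, ...) {
  cat(sprintf("<random_signature_audit> '%s': %d draws of %d genes; resubstitution AUC median %.3f [%.3f, %.3f]\n",
              x$cohort_name, x$n_draws, x$signature_size,
              x$summary$median, x$summary$min, x$summary$max))
  invisible(x)
}

# Deterministic per-draw sub-seed derivation from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Size-matched signature size for a cohort
#'
#' The number of signature genes actually present in a cohort's gene
#' universe. Random gene sets in the resubstitution null are drawn at this
#' size so the comparison with the real signature is size-matched per
#' cohort.
#'
#' @param signature A [gene_signature()].
#' @param cohort An [expression_cohort()].
#' @return Integer count (possibly 0; callers must reject 0 before
#'   auditing).
#' @export
matched_signature_size <- function(signature, cohort) {
  stopifnot(inherits(signature, "gene_signature"),
            inherits(cohort, "expression_cohort"))
  sum(signature$genes %in% cohort$genes)
}

#' Leave-one-cohort-out generalization audit
#'
#' Fits the signature classifier once on the training cohort, then scores
#' every other cohort with the frozen model: training standardization
#' parameters, training centroids, and the gene-drop rule of
#' [score_centroid()] for model genes missing from a test cohort. The
#' training-resubstitution ROC is recorded alongside so the inflation of the
#' training AUC over the held-out AUCs is visible side by side.
#'
#' @param cohorts Named list of [expression_cohort()] objects (>= 2).
#' @param signature A [gene_signature()] intersecting the training cohort's
#'   genes.
#' @param train_name Name of the training cohort (must be in `cohorts`).
#' @param distance_metric Passed to [fit_centroid()].
#'
#' @return An object of class `cross_cohort_audit`: list with `train_cohort`,
#'   `model`, `training_resubstitution` (`roc_result`), `test_results`
#'   (named list of `roc_result`), `test_genes_dropped` (named integer),
#'   `failed` (named character vector of failure reasons for cohorts that
#'   could not be scored).
#' @export
cross_cohort_audit <- function(cohorts, signature, train_name,
                               distance_metric = c("euclidean", "correlation")) {
  distance_metric <- match.arg(distance_metric)
  cohorts <- as_cohort_list(cohorts)
  if (length(cohorts) < 2L)
    stop("cross-cohort audit needs at least two cohorts", call. = FALSE)
  if (!train_name %in% names(cohorts))
    stop(sprintf("training cohort '%s' not found among: %s", train_name,
                 paste(names(cohorts), collapse = ", ")), call. = FALSE)
  train <- cohorts[[train_name]]
  model <- fit_centroid(train, signature, distance_metric)
  resub <- compute_roc(score_centroid(model, train), train$labels)

  test_names <- setdiff(names(cohorts), train_name)
  test_results <- list()
  test_genes_dropped <- integer(0)
  failed <- character(0)
  for (nm in test_names) {
    res <- tryCatch({
      s <- score_centroid(model, cohorts[[nm]])
      list(roc = compute_roc(s, cohorts[[nm]]$labels),
           dropped = attr(s, "n_genes_dropped"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[nm] <- conditionMessage(res)
    } else {
      test_results[[nm]] <- res$roc
      test_genes_dropped[nm] <- res$dropped
    }
  }
  structure(
    list(train_cohort = train_name, model = model,
         training_resubstitution = resub, test_results = test_results,
         test_genes_dropped = test_genes_dropped, failed = failed),
    class = "cross_cohort_audit"
  )
}

#' @export
print.cross_cohort_audit <- function(x, ...) {
  cat(sprintf("<cross_cohort_audit> trained on '%s' (resubstitution AUC %.3f)\n",
              x$train_cohort, x$training_resubstitution$auc))
  for (nm in names(x$test_results))
    cat(sprintf("  test %-12s AUC %.3f\n", nm, x$test_results[[nm]]$auc))
  for (nm in names(x$failed))
    cat(sprintf("  test %-12s FAILED: %s\n", nm, x$failed[nm]))
  invisible(x)
}

as_cohort_list <- function(cohorts) {
  if (inherits(cohorts, "expression_cohort")) cohorts <- list(cohorts)
  stopifnot(is.list(cohorts),
            all(vapply(cohorts, inherits, logical(1), "expression_cohort")))
  names(cohorts) <- vapply(cohorts, `[[`, character(1), "name")
  if (anyDuplicated(names(cohorts)))
    stop("cohort names must be unique", call. = FALSE)
  cohorts
}

#' Full audit: random-signature null plus cross-cohort grid
#'
#' For every cohort, runs the size-matched random-signature resubstitution
#' null ([random_signature_null()], size from [matched_signature_size()])
#' and the leave-one-cohort-out audit with that cohort as training set
#' ([cross_cohort_audit()]). Per-cohort seeds are derived deterministically
#' from the master seed, so the whole report reruns bit-identically.
#'
#' @param cohorts Named list of [expression_cohort()] objects (>= 2).
#' @param signature A [gene_signature()].
#' @param n_draws Random draws per cohort null (default 50).
#' @param seed Integer master seed.
#' @param distance_metric Passed to the classifier.
#'
#' @return An object of class `audit_report`: list with `signature_name`,
#'   `n_draws`, `seed`, `distance_metric`, `random_null` (named list of
#'   `random_signature_audit`), `cross` (named list of
#'   `cross_cohort_audit`).
#' @export
full_audit <- function(cohorts, signature, n_draws = 50L, seed = 1L,
                       distance_metric = c("euclidean", "correlation")) {
  distance_metric <- match.arg(distance_metric)
  cohorts <- as_cohort_list(cohorts)
  stopifnot(inherits(signature, "gene_signature"))
  if (length(cohorts) < 2L)
    stop("full audit needs at least two cohorts", call. = FALSE)
  cohort_seeds <- derive_seeds(seed, length(cohorts))
  random_null <- list()
  cross <- list()
  for (i in seq_along(cohorts)) {
    nm <- names(cohorts)[i]
    size <- matched_signature_size(signature, cohorts[[nm]])
    if (size == 0L)
      stop(sprintf("signature '%s' shares no genes with cohort '%s'",
                   signature$name, nm), call. = FALSE)
    random_null[[nm]] <- random_signature_null(
      cohorts[[nm]], signature_size = size, n_draws = n_draws,
      seed = cohort_seeds[i], distance_metric = distance_metric)
    cross[[nm]] <- cross_cohort_audit(cohorts, signature, nm,
                                      distance_metric)
  }
  structure(
    list(signature_name = signature$name, n_draws = as.integer(n_draws),
         seed = as.integer(seed), distance_metric = distance_metric,
         random_null = random_null, cross = cross),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> signature '%s', %d cohorts, %d draws per null, seed %d\n",
              x$signature_name, length(x$random_null), x$n_draws, x$seed))
  for (nm in names(x$random_null)) {
    rn <- x$random_null[[nm]]
    cc <- x$cross[[nm]]
    test_auc <- vapply(cc$test_results, `[[`, numeric(1), "auc")
    cat(sprintf("  %-12s null median %.3f | resub %.3f | held-out %s\n",
                nm, rn$summary$median, cc$training_resubstitution$auc,
                paste(sprintf("%.3f", test_auc), collapse = " ")))
  }
  invisible(x)
}
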