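#' Fit a nearest-centroid signature classifier
#'
#' Restricts a cohort to the signature genes present in it, standardizes each
#' gene with the mean and standard deviation computed over ALL training
#' samples, and records the per-class centroids (per-gene mean of the
#' standardized expression over responders and over non-responders). Genes
#' with zero training standard deviation cannot be standardized and are
#' dropped with a warning.
#'
#' Standardization parameters belong to the model: test cohorts are always
#' standardized with the training cohort's mean/sd, never their own. This is
#' the mechanism that keeps the audit free of test-set leakage.
#'
#' @param cohort An [expression_cohort()] with both classes present.
#' @param signature A [gene_signature()]; its intersection with the cohort's
#'   genes must be non-empty.
#' @param distance_metric `"euclidean"` (default) or `"correlation"`
#'   (one minus Pearson correlation).
#'
#' @return An object of class `centroid_model` with elements `genes_used`
#'   (signature order), `center`, `scale` (training standardization),
#'   `centroid_pos`, `centroid_neg`, `distance_metric`,
#'   `training_cohort_name`.
#' @export
fit_centroid <- function(cohort, signature,
                         distance_metric = c("euclidean", "correlation")) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(signature, "gene_signature"))
  distance_metric <- match.arg(distance_metric)
  genes_used <- signature$genes[signature$genes %in% cohort$genes]
  if (length(genes_used) == 0L)
    stop(sprintf("signature '%s' shares no genes with cohort '%s'",
                 signature$name, cohort$name), call. = FALSE)
  n_pos <- sum(cohort$labels == 1L)
  n_neg <- sum(cohort$labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop(sprintf("cohort '%s' lacks one of the two classes", cohort$name),
         call. = FALSE)

  x <- cohort$values[genes_used, , drop = FALSE]
  center <- rowMeans(x)
  scale <- apply(x, 1L, stats::sd)
  zero_var <- scale <= 0
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance gene(s) from model trained on '%s'",
                    sum(zero_var), cohort$name), call. = FALSE)
    if (all(zero_var))
      stop(sprintf("all signature genes have zero variance in cohort '%s'",
                   cohort$name), call. = FALSE)
    genes_used <- genes_used[!zero_var]
    x <- x[!zero_var, , drop = FALSE]
    center <- center[!zero_var]
    scale <- scale[!zero_var]
  }
  z <- (x - center) / scale
  structure(
    list(genes_used = genes_used,
         center = stats::setNames(center, genes_used),
         scale = stats::setNames(scale, genes_used),
         centroid_pos = rowMeans(z[, cohort$labels == 1L, drop = FALSE]),
         centroid_neg = rowMeans(z[, cohort$labels == 0L, drop = FALSE]),
         distance_metric = distance_metric,
         training_cohort_name = cohort$name,
         signature_name = signature$name),
    class = "centroid_model"
  )
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("<centroid_model> %d genes, %s distance, trained on '%s'\n",
              length(x$genes_used), x$distance_metric,
              x$training_cohort_name))
  invisible(x)
}

dist_to_centroid <- function(z, centroid, metric) {
  # z: genes x samples in standardized space; returns one distance per sample
  if (metric == "euclidean") {
    sqrt(colSums((z - centroid)^2))
  } else {
    if (length(centroid) < 2L || stats::sd(centroid) == 0)
      stop("correlation distance needs >= 2 genes with non-constant centroid",
           call. = FALSE)
    1 - suppressWarnings(stats::cor(z, centroid))[, 1L]
  }
}

#' Score a cohort with a frozen nearest-centroid model
#'
#' Standardizes each sample with the TRAINING cohort's per-gene mean and sd,
#' computes its distance to the responder and non-responder centroids, and
#' returns the bounded score `s = (d_neg - d_pos) / (d_neg + d_pos + eps)`,
#' so `s > 0` means the sample is nearer the responder centroid. The hard
#' class call is `sign(s)` with `s = 0` assigned to non-responder. Scoring
#' never reads the test cohort's labels.
#'
#' Model genes absent from the test cohort are dropped from both centroids
#' and the test vectors, with a warning giving the count; if no model gene is
#' present the cohort cannot be scored.
#'
#' @param model A `centroid_model` from [fit_centroid()].
#' @param cohort The [expression_cohort()] to score (may be the training
#'   cohort itself, for resubstitution).
#' @param eps Tiny constant guarding the 0/0 case when a sample sits on both
#'   centroids at once.
#'
#' @return Named numeric vector of scores in [-1, 1], one per sample, with
#'   attribute `"n_genes_dropped"` (model genes absent from the cohort).
#' @export
score_centroid <- function(model, cohort, eps = 1e-12) {
  stopifnot(inherits(model, "centroid_model"),
            inherits(cohort, "expression_cohort"))
  present <- model$genes_used %in% cohort$genes
  if (!any(present))
    stop(sprintf("no model gene is present in cohort '%s'; cannot score",
                 cohort$name), call. = FALSE)
  n_dropped <- sum(!present)
  if (n_dropped > 0L)
    warning(sprintf("%d model gene(s) absent from cohort '%s'; dropped from centroids and test vectors",
                    n_dropped, cohort$name), call. = FALSE)
  g <- model$genes_used[present]
  z <- (cohort$values[g, , drop = FALSE] - model$center[g]) / model$scale[g]
  d_pos <- dist_to_centroid(z, model$centroid_pos[present], model$distance_metric)
  d_neg <- dist_to_centroid(z, model$centroid_neg[present], model$distance_metric)
  s <- (d_neg - d_pos) / (d_neg + d_pos + eps)
  names(s) <- cohort$samples
  attr(s, "n_genes_dropped") <- n_dropped
  s
}

#' Hard class calls from centroid scores
#'
#' @param scores Numeric score vector from [score_centroid()].
#' @return Integer vector: 1 (responder) where the score is strictly
#'   positive, else 0.
#' @export
classify_centroid <- function(scores) {
  as.integer(scores > 0)
}

#' Serialize a centroid model to JSON
#'
#' Writes genes, standardization parameters, centroids, metric and training
#' provenance as a JSON document so a frozen model can be archived and
#' re-applied elsewhere.
#'
#' @param model A `centroid_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centroid_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  doc <- list(
    schema_version = "1.0",
    genes_used = model$genes_used,
    center = unname(model$center),
    scale = unname(model$scale),
    centroid_pos = unname(model$centroid_pos),
    centroid_neg = unname(model$centroid_neg),
    distance_metric = model$distance_metric,
    training_cohort_name = model$training_cohort_name,
    signature_name = model$signature_name
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a centroid model from JSON
#'
#' @param path Path written by [write_centroid_model()].
#' @return A `centroid_model`.
#' @export
read_centroid_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- as.character(doc$genes_used)
  structure(
    list(genes_used = g,
         center = stats::setNames(as.numeric(doc$center), g),
         scale = stats::setNames(as.numeric(doc$scale), g),
         centroid_pos = stats::setNames(as.numeric(doc$centroid_pos), g),
         centroid_neg = stats::setNames(as.numeric(doc$centroid_neg), g),
         distance_metric = doc$distance_metric,
         training_cohort_name = doc$training_cohort_name,
         signature_name = doc$signature_name),
    class = "centroid_model"
  )
}
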