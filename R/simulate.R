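#' Simulation configuration for synthetic multi-cohort expression data
#'
#' Defines the generative model used by [generate_cohorts()]: an additive
#' Gaussian model on the log-expression scale with a shared per-gene baseline,
#' cohort-specific gene-wise batch shifts, an optional responder mean shift on
#' a fixed block of signal genes, and per-cohort random gene dropout so that
#' cohorts cover overlapping but non-identical gene universes.
#'
#' @param n_cohorts Number of cohorts to generate.
#' @param genes_total Size of the shared gene universe.
#' @param samples_per_cohort Integer vector of cohort sizes; recycled to
#'   `n_cohorts` if of length 1.
#' @param responder_fraction Probability that a sample is a responder,
#'   strictly in (0, 1); recycled to `n_cohorts`.
#' @param effect_size Log-scale mean shift added to responders on the signal
#'   genes; 0 gives a pure null simulation.
#' @param n_signal_genes Number of genes carrying the responder shift (the
#'   first `n_signal_genes` genes of the universe).
#' @param batch_sd Standard deviation of the per-cohort, per-gene batch
#'   shifts; 0 removes batch structure.
#' @param noise_sd Residual standard deviation around the gene/cohort/class
#'   mean.
#' @param gene_dropout_fraction Fraction of the gene universe dropped from
#'   each cohort, independently per cohort; in [0, 1).
#' @param seed Integer seed; the whole cohort set is reproducible from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_cohorts = 4L,
                       genes_total = 2000L,
                       samples_per_cohort = c(28L, 49L, 73L, 42L),
                       responder_fraction = 0.4,
                       effect_size = 0,
                       n_signal_genes = min(50L, genes_total),
                       batch_sd = 0.5,
                       noise_sd = 1,
                       gene_dropout_fraction = 0.02,
                       seed = 1L) {
  n_cohorts <- as.integer(n_cohorts)
  genes_total <- as.integer(genes_total)
  samples_per_cohort <- as.integer(samples_per_cohort)
  n_signal_genes <- as.integer(n_signal_genes)
  seed <- as.integer(seed)
  if (length(samples_per_cohort) == 1L)
    samples_per_cohort <- rep(samples_per_cohort, n_cohorts)
  if (length(responder_fraction) == 1L)
    responder_fraction <- rep(responder_fraction, n_cohorts)
  stopifnot(
    n_cohorts >= 1L, genes_total >= 1L,
    length(samples_per_cohort) == n_cohorts,
    all(samples_per_cohort >= 2L),
    length(responder_fraction) == n_cohorts,
    all(responder_fraction > 0 & responder_fraction < 1),
    is.finite(effect_size),
    n_signal_genes >= 0L, n_signal_genes <= genes_total,
    batch_sd >= 0, noise_sd >= 0,
    gene_dropout_fraction >= 0, gene_dropout_fraction < 1,
    !is.na(seed)
  )
  structure(
    list(n_cohorts = n_cohorts, genes_total = genes_total,
         samples_per_cohort = samples_per_cohort,
         responder_fraction = responder_fraction,
         effect_size = effect_size, n_signal_genes = n_signal_genes,
         batch_sd = batch_sd, noise_sd = noise_sd,
         gene_dropout_fraction = gene_dropout_fraction, seed = seed),
    class = "sim_config"
  )
}

gene_universe <- function(genes_total) {
  sprintf("G%06d", seq_len(genes_total))
}

#' Generate synthetic expression cohorts
#'
#' Draws a cohort set under the additive Gaussian model of [sim_config()].
#' For cohort d and sample i, expression of gene g is
#' `mu_g + b_{d,g} + beta_g * y_i + e`, where the baseline `mu_g ~ N(0, 1)`
#' is shared across cohorts, the batch shift `b_{d,g} ~ N(0, batch_sd^2)` is
#' cohort specific, `beta_g = effect_size` on the signal genes and 0
#' elsewhere, `y_i ~ Bernoulli(responder_fraction)` is the response label and
#' `e ~ N(0, noise_sd^2)`. Each cohort then drops a uniformly random
#' `gene_dropout_fraction` of the gene universe, independently of the others.
#'
#' If label sampling leaves a cohort single-class, the minimal number of
#' labels is flipped deterministically (first samples first) so both classes
#' are present — AUC is undefined otherwise — and the repair is recorded in
#' the cohort's `metadata$labels_adjusted`.
#'
#' @param config A [sim_config()] object.
#' @return A named list of [expression_cohort()] objects
#'   (`"cohort1"`, `"cohort2"`, ...).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  universe <- gene_universe(config$genes_total)
  beta <- rep(0, config$genes_total)
  if (config$n_signal_genes > 0L)
    beta[seq_len(config$n_signal_genes)] <- config$effect_size

  withr::with_seed(config$seed, {
    mu <- stats::rnorm(config$genes_total, 0, 1)
    lapply(seq_len(config$n_cohorts), function(d) {
      n <- config$samples_per_cohort[d]
      p_resp <- config$responder_fraction[d]
      y <- stats::rbinom(n, 1L, p_resp)
      adjusted <- FALSE
      if (sum(y) == 0L) { y[1L] <- 1L; adjusted <- TRUE }
      if (sum(y) == n)  { y[1L] <- 0L; adjusted <- TRUE }
      b <- if (config$batch_sd > 0)
        stats::rnorm(config$genes_total, 0, config$batch_sd) else
        numeric(config$genes_total)
      noise <- matrix(stats::rnorm(config$genes_total * n, 0, config$noise_sd),
                      nrow = config$genes_total)
      x <- (mu + b) + outer(beta, y) + noise
      keep <- seq_len(config$genes_total)
      n_drop <- floor(config$gene_dropout_fraction * config$genes_total)
      if (n_drop > 0L) {
        dropped <- sample.int(config$genes_total, n_drop)
        keep <- setdiff(keep, dropped)
      }
      name <- sprintf("cohort%d", d)
      expression_cohort(
        name = name,
        values = x[keep, , drop = FALSE],
        genes = universe[keep],
        samples = sprintf("%s_S%03d", name, seq_len(n)),
        labels = y,
        metadata = list(labels_adjusted = adjusted,
                        responder_fraction = p_resp,
                        effect_size = config$effect_size,
                        batch_sd = config$batch_sd)
      )
    }) -> cohorts
    names(cohorts) <- vapply(cohorts, `[[`, character(1), "name")
    cohorts
  })
}

#' Signature of the injected signal genes
#'
#' Returns the identifiers of the genes that carry the responder mean shift
#' in the simulation, for signal-recovery tests: a genuine, transferable
#' signature that a sound audit must not flag.
#'
#' @param config A [sim_config()] object with `n_signal_genes >= 1`.
#' @return A [gene_signature()] named `"signal"`.
#' @export
signal_signature <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_signal_genes < 1L)
    stop("no signal genes in this configuration (n_signal_genes = 0); ",
         "the signal signature is empty", call. = FALSE)
  gene_signature(gene_universe(config$genes_total)[seq_len(config$n_signal_genes)],
                 name = "signal")
}
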