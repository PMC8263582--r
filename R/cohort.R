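#' Expression cohort container
#'
#' An `expression_cohort` bundles one cohort's log-scale expression matrix
#' (genes in rows, samples in columns) with its gene and sample identifiers
#' and a binary response label per sample (1 = responder, 0 = non-responder).
#' Expression values are assumed to be on a variance-stabilized log scale
#' already; no transformation is applied here.
#'
#' @param name Cohort name (single string).
#' @param values Numeric matrix, genes x samples. Row and column names, if
#'   present, must agree with `genes` and `samples`.
#' @param genes Character vector of unique gene identifiers, one per row.
#' @param samples Character vector of unique sample identifiers, one per
#'   column.
#' @param labels Integer (or coercible) vector of 0/1 response labels, one
#'   per sample. Both classes must be present.
#' @param metadata Optional named list of free-form cohort metadata.
#'
#' @return An object of class `expression_cohort`: a list with elements
#'   `name`, `genes`, `samples`, `values`, `labels`, `metadata`.
#' @export
expression_cohort <- function(name, values, genes = rownames(values),
                              samples = colnames(values), labels,
                              metadata = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric", call. = FALSE)
  if (is.null(genes) || is.null(samples))
    stop("gene and sample identifiers are required", call. = FALSE)
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (nrow(values) != length(genes))
    stop(sprintf("cohort '%s': %d rows but %d gene identifiers",
                 name, nrow(values), length(genes)), call. = FALSE)
  if (ncol(values) != length(samples))
    stop(sprintf("cohort '%s': %d columns but %d sample identifiers",
                 name, ncol(values), length(samples)), call. = FALSE)
  if (anyDuplicated(genes))
    stop(sprintf("cohort '%s': duplicate gene identifiers (e.g. '%s')",
                 name, genes[duplicated(genes)][1L]), call. = FALSE)
  if (anyDuplicated(samples))
    stop(sprintf("cohort '%s': duplicate sample identifiers", name),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop(sprintf("cohort '%s': non-finite expression values", name),
         call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != length(samples))
    stop(sprintf("cohort '%s': %d labels for %d samples",
                 name, length(labels), length(samples)), call. = FALSE)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop(sprintf("cohort '%s': labels must be 0 or 1", name), call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop(sprintf("cohort '%s': both responder and non-responder labels must be present",
                 name), call. = FALSE)
  dimnames(values) <- list(genes, samples)
  names(labels) <- samples
  structure(
    list(name = name, genes = genes, samples = samples, values = values,
         labels = labels, metadata = metadata),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort> '%s': %d genes x %d samples (%d responders, %d non-responders)\n",
              x$name, length(x$genes), length(x$samples),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' Gene signature container
#'
#' A gene signature is a named, ordered list of unique gene identifiers whose
#' expression pattern is claimed to predict a phenotype.
#'
#' @param genes Character vector of gene identifiers; must be non-empty with
#'   no duplicates.
#' @param name Signature name.
#'
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(genes, name = "signature") {
  genes <- as.character(genes)
  if (length(genes) == 0L)
    stop("a gene signature must contain at least one gene", call. = FALSE)
  if (anyNA(genes) || any(!nzchar(genes)))
    stop("gene identifiers must be non-missing, non-empty strings",
         call. = FALSE)
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene identifier in signature: '%s'",
                 genes[duplicated(genes)][1L]), call. = FALSE)
  structure(list(name = as.character(name)[1L], genes = genes),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)
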