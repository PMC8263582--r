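# Deterministic number formatting for all text writers: 17 significant
# digits round-trip an IEEE double exactly, so write -> read is lossless.
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  int_like <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[int_like] <- sprintf("%.0f", x[int_like])
  out[is.na(x)] <- "NA"
  out[is.infinite(x)] <- ifelse(x[is.infinite(x)] > 0, "Inf", "-Inf")
  out
}

#' Write an expression cohort as TSV
#'
#' Writes two files: an expression table (first column `gene`, one column
#' per sample, header row of sample identifiers) and a labels table
#' (columns `sample`, `response` with values 0/1). Numeric formatting is
#' deterministic and lossless, so a written cohort reloads bit-identically.
#'
#' @param cohort An [expression_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector with paths `expression` and `labels`,
#'   invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, paste0(cohort$name, "_expression.tsv"))
  labels_path <- file.path(dir, paste0(cohort$name, "_labels.tsv"))
  fmt <- apply(cohort$values, 2L, format_num)
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(cohort$values))
  df <- data.frame(gene = cohort$genes, fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", cohort$samples)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = cohort$samples, response = unname(cohort$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = expr_path, labels = labels_path))
}

#' Read an expression cohort from TSV/CSV
#'
#' Expects an expression table with gene identifiers in the first column and
#' sample identifiers in the header, plus a labels table with columns
#' `sample` and `response` in {0, 1}. The expression is taken as already
#' log-transformed; only finiteness is checked, nothing is re-normalized and
#' missing values are rejected.
#'
#' @param expression_path Path to the expression table.
#' @param labels_path Path to the labels table.
#' @param name Cohort name to assign.
#' @param sep Field separator (default tab; use "," for CSV).
#' @return An [expression_cohort()].
#' @export
read_cohort <- function(expression_path, labels_path, name, sep = "\t") {
  for (p in c(expression_path, labels_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  expr <- utils::read.table(expression_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  if (ncol(expr) < 2L)
    stop("expression table needs a gene column plus at least one sample",
         call. = FALSE)
  genes <- as.character(expr[[1L]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene identifier in %s: '%s'", expression_path,
                 genes[duplicated(genes)][1L]), call. = FALSE)
  values <- as.matrix(expr[, -1L, drop = FALSE])
  if (!is.numeric(values))
    stop(sprintf("non-numeric expression cells in %s", expression_path),
         call. = FALSE)
  samples <- colnames(expr)[-1L]

  lab <- utils::read.table(labels_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (!all(c("sample", "response") %in% colnames(lab)))
    stop(sprintf("labels file %s must have columns 'sample' and 'response'",
                 labels_path), call. = FALSE)
  missing <- setdiff(samples, lab$sample)
  if (length(missing) > 0L)
    stop(sprintf("samples present in expression but absent from labels: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  resp <- lab$response[match(samples, lab$sample)]
  if (anyNA(resp) || !all(resp %in% c(0, 1)))
    stop(sprintf("label values outside {0, 1} in %s", labels_path),
         call. = FALSE)
  expression_cohort(name = name, values = values, genes = genes,
                    samples = samples, labels = resp)
}

#' Read a gene signature from a plain-text file
#'
#' One gene identifier per line; blank lines and lines starting with `#` are
#' ignored; duplicate identifiers are an error.
#'
#' @param path Signature file path.
#' @param name Signature name (defaults to the file name without extension).
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop(sprintf("empty signature file: %s", path), call. = FALSE)
  if (anyDuplicated(lines))
    stop(sprintf("duplicated gene identifier in %s: '%s'", path,
                 lines[duplicated(lines)][1L]), call. = FALSE)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  gene_signature(lines, name = name)
}

#' Write a gene signature to a plain-text file
#'
#' @param signature A [gene_signature()].
#' @param path Output path; one identifier per line.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  writeLines(signature$genes, path)
  invisible(path)
}

#' Write a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML path written by [write_sim_config()] (or hand-written
#'   with the same field names).
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(sim_config, doc)
}

#' Tidy table of random-null draws
#'
#' @param report An `audit_report` from [full_audit()].
#' @return data.frame with one row per (cohort, draw): columns `cohort`,
#'   `draw`, `signature_size`, `auc`.
#' @export
random_null_table <- function(report) {
  stopifnot(inherits(report, "audit_report"))
  do.call(rbind, lapply(report$random_null, function(rn) {
    data.frame(cohort = rn$cohort_name, draw = seq_len(rn$n_draws),
               signature_size = rn$signature_size, auc = rn$auc_values,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Tidy table of the cross-cohort AUC grid
#'
#' @param report An `audit_report` from [full_audit()].
#' @return data.frame with one row per train-test pair (including the
#'   training-resubstitution row, `test == train`): columns `train`, `test`,
#'   `auc`, `n_genes_used`, `status`.
#' @export
cross_cohort_table <- function(report) {
  stopifnot(inherits(report, "audit_report"))
  rows <- lapply(report$cross, function(cc) {
    out <- data.frame(train = cc$train_cohort, test = cc$train_cohort,
                      auc = cc$training_resubstitution$auc,
                      n_genes_used = length(cc$model$genes_used),
                      status = "resubstitution", stringsAsFactors = FALSE)
    for (nm in names(cc$test_results)) {
      out <- rbind(out, data.frame(
        train = cc$train_cohort, test = nm,
        auc = cc$test_results[[nm]]$auc,
        n_genes_used = length(cc$model$genes_used) - cc$test_genes_dropped[[nm]],
        status = "test", stringsAsFactors = FALSE))
    }
    for (nm in names(cc$failed)) {
      out <- rbind(out, data.frame(
        train = cc$train_cohort, test = nm, auc = NA_real_,
        n_genes_used = 0L, status = paste0("failed: ", cc$failed[[nm]]),
        stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an audit report to disk
#'
#' Writes three files into `out_dir`: `random_null.csv` (one row per draw),
#' `cross_cohort.csv` (one row per train-test pair) and `summary.json`
#' (per-cohort box-plot summaries and the AUC grid, with a schema-version
#' field). All writers are deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report An `audit_report` from [full_audit()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "audit_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rn_path <- file.path(out_dir, "random_null.csv")
  cc_path <- file.path(out_dir, "cross_cohort.csv")
  js_path <- file.path(out_dir, "summary.json")

  rn <- random_null_table(report)
  rn$auc <- format_num(rn$auc)
  utils::write.table(rn, rn_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  cc <- cross_cohort_table(report)
  cc$auc <- ifelse(is.na(cc$auc), "NA", format_num(cc$auc))
  utils::write.table(cc, cc_path, sep = ",", quote = FALSE,
                     row.names = FALSE)

  summary_doc <- list(
    schema_version = "1.0",
    signature = report$signature_name,
    n_draws = report$n_draws,
    seed = report$seed,
    distance_metric = report$distance_metric,
    random_null = lapply(report$random_null, function(rn)
      c(list(signature_size = rn$signature_size), rn$summary)),
    cross_cohort = lapply(report$cross, function(cc) {
      list(resubstitution_auc = cc$training_resubstitution$auc,
           test_auc = lapply(cc$test_results, `[[`, "auc"),
           failed = as.list(cc$failed))
    })
  )
  jsonlite::write_json(summary_doc, js_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(random_null = rn_path, cross_cohort = cc_path,
              summary = js_path))
}
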