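#' ROC curve and AUC with Mann-Whitney tie handling
#'
#' Computes the AUC by the rank (Mann-Whitney) formulation, with tied scores
#' counted 1/2: `AUC = [sum(rank of positives) - n_pos (n_pos + 1) / 2] /
#' (n_pos * n_neg)`, using midranks. The ROC curve is built by sweeping the
#' unique score values from +Inf downward, calling a sample positive when its
#' score is at or above the threshold; with midrank tie handling the
#' trapezoidal area under this curve equals the rank-formula AUC exactly.
#'
#' @param scores Finite numeric vector (larger = more responder-like).
#' @param labels 0/1 vector, same length; both classes must be present.
#'
#' @return An object of class `roc_result`: list with `scores`, `labels`,
#'   `curve` (data.frame `threshold`, `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1)), and `auc`.
#' @export
compute_roc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length", call. = FALSE)
  if (length(scores) == 0L)
    stop("empty score vector", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("non-finite scores; AUC is undefined", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: only one class present in labels", call. = FALSE)

  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds,
                function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds,
                function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thresholds),
                      fpr = c(0, fpr), tpr = c(0, tpr))

  structure(list(scores = scores, labels = labels, curve = curve, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Trapezoidal area under an ROC curve
#'
#' @param roc A `roc_result`.
#' @return The trapezoidal area under `roc$curve`; equal to `roc$auc` up to
#'   floating-point rounding.
#' @export
roc_trapezoid_area <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  with(roc$curve, sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2))
}

#' Box-plot summary of an AUC collection
#'
#' Five-number summary plus mean and Tukey whiskers for a vector of AUC
#' values, matching the usual box-plot convention: whiskers extend to the
#' most extreme observed values within 1.5 x interquartile range of the
#' quartiles. Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param auc_values Non-empty numeric vector of AUC values.
#' @return Named list: `min`, `q1`, `median`, `q3`, `max`, `mean`,
#'   `whisker_low`, `whisker_high`, `n`.
#' @export
auc_summary <- function(auc_values) {
  auc_values <- as.numeric(auc_values)
  if (length(auc_values) == 0L)
    stop("cannot summarize an empty AUC vector", call. = FALSE)
  if (anyNA(auc_values))
    stop("AUC vector contains missing values", call. = FALSE)
  q <- stats::quantile(auc_values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  list(min = min(auc_values),
       q1 = q[1], median = q[2], q3 = q[3],
       max = max(auc_values),
       mean = mean(auc_values),
       whisker_low = min(auc_values[auc_values >= lo_fence]),
       whisker_high = max(auc_values[auc_values <= hi_fence]),
       n = length(auc_values))
}

#' Export an ROC curve as CSV
#'
#' Writes the swept curve (threshold, fpr, tpr) with deterministic
#' formatting.
#'
#' @param roc A `roc_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  df <- roc$curve
  df$threshold <- format_num(df$threshold)
  df$fpr <- format_num(df$fpr)
  df$tpr <- format_num(df$tpr)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
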