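#' Box plot of the random-signature null AUC distributions
#'
#' One box per cohort, whiskers at 1.5 x interquartile range, with a dotted
#' horizontal reference line (default at AUC 0.7) marking the level that
#' even random gene sets exceed under resubstitution.
#'
#' @param report An `audit_report` from [full_audit()].
#' @param reference Horizontal reference AUC (default 0.7); `NA` to omit.
#' @return A ggplot object.
#' @export
plot_random_null <- function(report, reference = 0.7) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  df <- random_null_table(report)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cohort, y = .data$auc)) +
    ggplot2::geom_boxplot(coef = 1.5, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Resubstitution AUC",
                  title = "Random size-matched gene sets, trained and scored on the same cohort") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_bw()
  if (!is.na(reference))
    p <- p + ggplot2::geom_hline(yintercept = reference, linetype = "dotted")
  p
}

#' Grid of ROC curves for the cross-cohort audit
#'
#' One panel per training cohort; each panel shows the held-out ROC curve of
#' every test cohort scored with the frozen model, plus the diagonal chance
#' line.
#'
#' @param report An `audit_report` from [full_audit()].
#' @param include_resubstitution Also draw the training-resubstitution curve
#'   in each panel (default TRUE), making the inflation visible.
#' @return A ggplot object.
#' @export
plot_roc_grid <- function(report, include_resubstitution = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  rows <- list()
  for (cc in report$cross) {
    if (include_resubstitution) {
      cv <- cc$training_resubstitution$curve
      rows[[length(rows) + 1L]] <- data.frame(
        train = cc$train_cohort, test = paste0(cc$train_cohort, " (resub)"),
        fpr = cv$fpr, tpr = cv$tpr, stringsAsFactors = FALSE)
    }
    for (nm in names(cc$test_results)) {
      cv <- cc$test_results[[nm]]$curve
      rows[[length(rows) + 1L]] <- data.frame(
        train = cc$train_cohort, test = nm, fpr = cv$fpr, tpr = cv$tpr,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~train) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Scored cohort",
                  title = "Frozen models applied across cohorts (panel = training cohort)") +
    ggplot2::theme_bw()
}
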