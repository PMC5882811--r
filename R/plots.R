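# ggplot2 autoplot methods for the result objects.

#' @describeIn roc_auc ROC curve plot.
#' @param object A result object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @describeIn gsea_permutation Running-sum (mountain) plot with the leading
#'   edge shaded.
#' @export
autoplot.gsea_result <- function(object, ...) {
  run <- object$running
  ggplot2::ggplot(run, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = run[run$hit, ], sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "Rank", y = "Running enrichment score",
                  title = sprintf("ES = %.3f, p = %.3g", object$es, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @describeIn empirical_enrichment Null-count histograms with the observed
#'   count marked, one facet per cytokine.
#' @param object A result object.
#' @param ... Unused.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  nulls <- attr(object, "null_counts")
  long <- tibble::tibble(
    cytokine = rep(rownames(nulls), ncol(nulls)),
    count = as.vector(nulls)
  )
  obs <- tibble::tibble(cytokine = object$cytokine,
                        observed = object$observed_count)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$observed),
                        color = "red") +
    ggplot2::facet_wrap(~cytokine, scales = "free") +
    ggplot2::labs(x = "TFs in random equal-size set", y = "Null draws") +
    ggplot2::theme_minimal()
}

#' @describeIn subsample_corr_compare Violin plot of the two correlation
#'   distributions.
#' @export
autoplot.subsample_corr <- function(object, ...) {
  ggplot2::ggplot(object$distributions,
                  ggplot2::aes(x = .data$group, y = .data$r)) +
    ggplot2::geom_violin() +
    ggplot2::geom_pointrange(
      data = object$summary,
      ggplot2::aes(x = .data$group, y = .data$median_r,
                   ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::labs(y = "Spearman r (subsampled)", x = NULL,
                  title = sprintf("Wilcoxon p = %.3g", object$wilcoxon_p)) +
    ggplot2::theme_minimal()
}

#' Bar plot of per-cohort CTL correlations
#'
#' Paired bars per cohort: CTL-neoantigen and CTL-ATM Spearman correlations.
#'
#' @param rows Output of [pan_cancer_table()].
#' @return A ggplot object.
#' @export
plot_pan_cancer <- function(rows) {
  long <- tidyr::pivot_longer(
    rows, c("r_neoantigen_ctl", "r_atm_ctl"),
    names_to = "family", values_to = "r")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort, y = .data$r,
                                     fill = .data$family)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(r_neoantigen_ctl = "firebrick", r_atm_ctl = "steelblue"),
      labels = c(r_neoantigen_ctl = "CTL ~ neoantigen", r_atm_ctl = "CTL ~ ATM")) +
    ggplot2::labs(x = NULL, y = "Spearman r", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
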