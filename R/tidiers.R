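# broom-style tidiers for the package's fitted/result objects.

#' @describeIn train_ctl_score Tidy the model coefficients (broom style).
#' @param x A `ctl_score_model`.
#' @param ... Unused.
#' @export
tidy.ctl_score_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$genes),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @describeIn train_ctl_score One-row model summary.
#' @export
glance.ctl_score_model <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda,
                 n_nonzero = sum(x$coefficients != 0),
                 n_train = x$n_train %||% NA_integer_)
}

#' @describeIn roc_auc Tidy the ROC curve points.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @describeIn roc_auc One-row summary with the AUC.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @describeIn grid_search_signature Tidy the selected signature genes.
#' @param x A `ctl_signature`.
#' @param ... Unused.
#' @export
tidy.ctl_signature <- function(x, ...) x$signature

#' @describeIn grid_search_signature One-row summary: thresholds + objective.
#' @export
glance.ctl_signature <- function(x, ...) {
  dplyr::mutate(x$thresholds, n_genes = nrow(x$signature),
                test_auc = x$objective)
}

#' @describeIn gsea_permutation Tidy the running-sum track.
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @export
tidy.gsea_result <- function(x, ...) x$running

#' @describeIn gsea_permutation One-row summary (ES, NES, p, leading edge size).
#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(es = x$es, nes = x$nes, p_value = x$p_value,
                 n_leading_edge = length(x$leading_edge), n_perm = x$n_perm)
}

#' @describeIn subsample_corr_compare Tidy the per-iteration correlation draws.
#' @param x A `subsample_corr`.
#' @param ... Unused.
#' @export
tidy.subsample_corr <- function(x, ...) x$distributions

#' @describeIn subsample_corr_compare Per-group CI summary plus the Wilcoxon p.
#' @export
glance.subsample_corr <- function(x, ...) {
  dplyr::mutate(x$summary, wilcoxon_p = x$wilcoxon_p,
                n_iterations = x$n_iterations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
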