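# RNA-seq CTL score: elastic-net logistic regression of the proteomic
# CTL-high call on log2(counts + 1) for the markers CD8A, GZMB, PRF1, plus
# ROC evaluation by the midrank Mann-Whitney concordance.

#' Train the RNA-seq CTL score
#'
#' Fits an elastic-net-penalized logistic regression of the CTL-high label on
#' `log2(count + 1)` marker expression. Penalty strength is chosen by
#' stratified k-fold cross-validation (`lambda.1se`, favoring the sparser
#' model within one SE of the CV optimum); the mixing parameter is fixed.
#'
#' @param counts Gene-by-sample count matrix containing the marker genes.
#' @param labels [classify_ctl()] tibble or label vector; samples labeled
#'   `unclassified` are dropped.
#' @param penalty_mix Elastic-net mixing parameter alpha in `[0, 1]`
#'   (default 0.5).
#' @param seed Integer seed for the fold assignment.
#' @param genes Marker genes (default CD8A, GZMB, PRF1).
#' @param nfolds Cross-validation folds (default 5, stratified by class).
#' @return A `ctl_score_model`: genes, per-gene coefficients (zeros =
#'   dropped), intercept, alpha, lambda.
#' @export
train_ctl_score <- function(counts, labels, penalty_mix = 0.5, seed = 1L,
                            genes = c("CD8A", "GZMB", "PRF1"), nfolds = 5) {
  check_proportion(penalty_mix, "penalty_mix")
  absent <- setdiff(genes, rownames(counts))
  if (length(absent)) {
    abort(sprintf("marker gene(s) absent from counts: %s",
                  paste(absent, collapse = ", ")))
  }
  lab <- align_labels(labels, colnames(counts))
  keep <- lab %in% c("high", "low")
  y <- as.integer(lab[keep] == "high")
  if (length(unique(y)) < 2) abort("labels contain a single class")
  if (min(table(y)) < 5) abort("need at least 5 samples per class")
  x <- t(log2(counts[genes, keep, drop = FALSE] + 1))

  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = penalty_mix,
                          foldid = foldid, type.measure = "deviance")
  beta <- as.numeric(coef(cv, s = "lambda.1se"))
  structure(
    list(genes = genes, coefficients = setNames(beta[-1], genes),
         intercept = beta[1], transform = "log2(count + 1)",
         alpha = penalty_mix, lambda = cv$lambda.1se, n_train = length(y)),
    class = "ctl_score_model"
  )
}

#' @export
print.ctl_score_model <- function(x, ...) {
  cat("CTL score model: score = intercept + sum(coef * log2(count + 1))\n")
  cat(sprintf("  intercept %.4f, alpha %.2f, lambda %.4g\n",
              x$intercept, x$alpha, x$lambda))
  dropped <- names(x$coefficients)[x$coefficients == 0]
  print(tibble::tibble(gene = x$genes, coefficient = unname(x$coefficients)))
  if (length(dropped)) cat("  dropped (coefficient 0):",
                           paste(dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Score samples with a trained CTL score model
#'
#' @param model A `ctl_score_model`.
#' @param counts Gene-by-sample count matrix covering the model genes;
#'   negative counts are an error.
#' @return Tibble `sample_id`, `score`.
#' @export
score_samples <- function(model, counts) {
  stopifnot(inherits(model, "ctl_score_model"))
  absent <- setdiff(model$genes, rownames(counts))
  if (length(absent)) {
    abort(sprintf("model gene(s) absent from counts: %s",
                  paste(absent, collapse = ", ")))
  }
  x <- counts[model$genes, , drop = FALSE]
  if (any(x < 0)) abort("negative counts are not allowed")
  score <- model$intercept + colSums(log2(x + 1) * model$coefficients)
  tibble::tibble(sample_id = colnames(counts), score = unname(score))
}

#' ROC curve and AUC by midrank concordance
#'
#' The AUC equals the Mann-Whitney probability that a random positive
#' outranks a random negative, with ties counted 1/2 (equivalently the
#' trapezoidal area under the empirical ROC curve).
#'
#' @param scores Numeric vector.
#' @param labels Positive-class indicator: logical, 0/1, or a factor/character
#'   where `"high"`/`"1"`/`"TRUE"` marks positives.
#' @return A `roc_result`: list with `auc`, `curve` (tibble `threshold`,
#'   `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_binary_label(labels)
  if (length(pos) != length(scores)) abort("scores and labels must align")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  curve <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(labels == 1)
  }
  lab <- as.character(labels)
  lab %in% c("high", "1", "TRUE", "pos", "positive")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Serialize a CTL score model to JSON
#'
#' @param model A `ctl_score_model`.
#' @param path Output path.
#' @export
write_score_model <- function(model, path) {
  jsonlite::write_json(
    list(genes = model$genes, coefficients = unname(model$coefficients),
         intercept = model$intercept, transform = model$transform,
         alpha = model$alpha, lambda = model$lambda),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CTL score model from JSON
#'
#' @param path Path written by [write_score_model()].
#' @return A `ctl_score_model`.
#' @export
read_score_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(genes = j$genes, coefficients = setNames(j$coefficients, j$genes),
         intercept = j$intercept, transform = j$transform,
         alpha = j$alpha, lambda = j$lambda),
    class = "ctl_score_model"
  )
}
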