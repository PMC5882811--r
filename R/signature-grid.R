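# Resampling-based gene-signature derivation: a stratified train/test split,
# 1000 class-stratified subsamples of the training group recording per-gene
# Welch p-values and log2 fold changes, and a grid search over (p threshold,
# fold-change threshold, fraction-of-iterations) cells scored by held-out
# test AUC of the weighted-mean signature score.

#' Stratified train/test split of labeled samples
#'
#' @param labels [classify_ctl()] tibble or a named label vector; only
#'   `high`/`low` samples are split (unclassified are dropped).
#' @param test_fraction Proportion assigned to the test side, in (0, 1).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` (sample ids);
#'   disjoint and exhaustive over the classified samples, class proportions
#'   preserved.
#' @export
split_cohort <- function(labels, test_fraction, seed = 1L) {
  check_proportion(test_fraction, "test_fraction", open = TRUE)
  if (is.data.frame(labels)) {
    ids <- labels$sample_id
    lab <- as.character(labels$label)
  } else {
    ids <- names(labels)
    lab <- as.character(labels)
    if (is.null(ids)) abort("label vector must be named by sample id")
  }
  keep <- lab %in% c("high", "low")
  ids <- ids[keep]; lab <- lab[keep]
  if (min(table(lab)) < 4) abort("need at least 4 samples per class")
  set.seed(seed)
  test <- unlist(lapply(unique(lab), function(cl) {
    cl_ids <- ids[lab == cl]
    sample(cl_ids, round(test_fraction * length(cl_ids)))
  }), use.names = FALSE)
  list(train = setdiff(ids, test), test = test)
}

#' Per-gene statistics over repeated stratified subsamples
#'
#' Each iteration draws, without replacement, `subsample_fraction` of each
#' class and records the per-gene Welch p-value and high-minus-low log2 fold
#' change.
#'
#' @param mat Gene-by-sample log2 matrix (training samples).
#' @param labels Labels for the matrix columns ([classify_ctl()] tibble or
#'   vector).
#' @param n_iterations Number of subsample draws (default 1000).
#' @param subsample_fraction Per-class fraction drawn each iteration
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A `subsample_stats` object: `genes`, `p_values` and `fold_changes`
#'   (gene x iteration matrices), plus the drawing parameters.
#' @export
subsample_differential <- function(mat, labels, n_iterations = 1000,
                                   subsample_fraction = 0.8, seed = 1L) {
  check_count(n_iterations, "n_iterations")
  check_proportion(subsample_fraction, "subsample_fraction", open = TRUE)
  lab <- align_labels(labels, colnames(mat))
  idx_high <- which(lab == "high")
  idx_low <- which(lab == "low")
  k_high <- round(subsample_fraction * length(idx_high))
  k_low <- round(subsample_fraction * length(idx_low))
  if (k_high < 3 || k_low < 3) {
    abort("subsample too small: need >= 3 samples per class per iteration")
  }
  set.seed(seed)
  p <- matrix(NA_real_, nrow(mat), n_iterations,
              dimnames = list(rownames(mat), NULL))
  fc <- p
  for (i in seq_len(n_iterations)) {
    s_high <- idx_high[sample.int(length(idx_high), k_high)]
    s_low <- idx_low[sample.int(length(idx_low), k_low)]
    w <- welch_rows(mat, s_high, s_low)
    p[, i] <- w$p_value
    fc[, i] <- w$log2_fc
  }
  structure(
    list(genes = rownames(mat), p_values = p, fold_changes = fc,
         n_iterations = n_iterations, subsample_fraction = subsample_fraction),
    class = "subsample_stats"
  )
}

#' @export
print.subsample_stats <- function(x, ...) {
  cat(sprintf("subsample_stats: %d genes x %d iterations (fraction %.2f)\n",
              length(x$genes), x$n_iterations, x$subsample_fraction))
  invisible(x)
}

# genes meeting a grid cell's joint criteria in >= the required fraction of
# iterations
signature_members <- function(stats, p_threshold, fc_threshold, fraction_required) {
  pass <- stats$p_values <= p_threshold & abs(stats$fold_changes) >= fc_threshold
  freq <- rowMeans(pass)
  stats$genes[freq >= fraction_required]
}

#' Grid search for the CTL-high gene signature
#'
#' For every cell of the threshold grid, forms the set of genes whose
#' subsample statistics satisfy (p <= p_threshold AND |log2 fc| >=
#' fc_threshold) in at least `fraction_required` of iterations, scores the
#' held-out test samples with a weighted mean of the member genes' log2
#' values (per-gene weight = sign of the median fold change times the median
#' absolute fold change, i.e. the signed median fold change across
#' iterations), and evaluates the test AUC against the test labels. Returns
#' the cell maximizing test AUC; ties prefer the smaller signature, then the
#' smaller p threshold.
#'
#' @param stats A [subsample_differential()] result.
#' @param grid List with numeric vectors `p`, `fc`, `fraction`: candidate
#'   thresholds.
#' @param test_matrix Gene-by-sample log2 matrix for the held-out samples.
#' @param test_labels Labels for the test columns.
#' @return A `ctl_signature`: `thresholds` (tibble), `signature` (tibble
#'   `gene`, `coefficient`), `objective` (best test AUC), and `grid_results`
#'   (one row per non-empty cell).
#' @export
grid_search_signature <- function(stats, grid, test_matrix, test_labels) {
  stopifnot(inherits(stats, "subsample_stats"))
  if (!all(c("p", "fc", "fraction") %in% names(grid)) ||
      !all(lengths(grid[c("p", "fc", "fraction")]) > 0)) {
    abort("`grid` needs non-empty numeric vectors `p`, `fc`, `fraction`")
  }
  lab <- align_labels(test_labels, colnames(test_matrix))
  keep <- lab %in% c("high", "low")
  test_matrix <- test_matrix[, keep, drop = FALSE]
  y <- lab[keep] == "high"
  med_fc <- apply(stats$fold_changes, 1, median)
  weights <- setNames(sign(med_fc) * abs(med_fc), stats$genes)

  cells <- tidyr::expand_grid(p_threshold = sort(grid$p),
                              fc_threshold = sort(grid$fc),
                              fraction_required = sort(grid$fraction))
  res <- purrr::pmap(cells, function(p_threshold, fc_threshold, fraction_required) {
    genes <- signature_members(stats, p_threshold, fc_threshold, fraction_required)
    genes <- intersect(genes, rownames(test_matrix))
    if (length(genes) == 0) return(NULL)
    w <- weights[genes]
    if (sum(abs(w)) == 0) return(NULL)
    score <- colSums(test_matrix[genes, , drop = FALSE] * w) / sum(abs(w))
    tibble::tibble(p_threshold = p_threshold, fc_threshold = fc_threshold,
                   fraction_required = fraction_required,
                   n_genes = length(genes),
                   test_auc = roc_auc(score, y)$auc)
  })
  grid_results <- dplyr::bind_rows(purrr::compact(res))
  if (nrow(grid_results) == 0) {
    abort(paste("all grid cells yield empty signatures;",
                "relax the thresholds or check the subsample statistics"))
  }
  best <- grid_results |>
    dplyr::arrange(dplyr::desc(.data$test_auc), .data$n_genes, .data$p_threshold) |>
    dplyr::slice(1)
  genes <- signature_members(stats, best$p_threshold, best$fc_threshold,
                             best$fraction_required)
  genes <- intersect(genes, rownames(test_matrix))
  structure(
    list(thresholds = best[, c("p_threshold", "fc_threshold", "fraction_required")],
         signature = tibble::tibble(gene = genes,
                                    coefficient = unname(weights[genes])),
         objective = best$test_auc,
         grid_results = grid_results),
    class = "ctl_signature"
  )
}

#' @export
print.ctl_signature <- function(x, ...) {
  cat(sprintf("CTL signature: %d genes, held-out AUC %.3f\n",
              nrow(x$signature), x$objective))
  cat(sprintf("  thresholds: p <= %g, |log2 fc| >= %g, in >= %g of iterations\n",
              x$thresholds$p_threshold, x$thresholds$fc_threshold,
              x$thresholds$fraction_required))
  invisible(x)
}
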