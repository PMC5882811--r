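# Proteomic CTL calling and differential statistics. CTL status is called
# from co-detection of the CD8 marker and granzyme B; iTRAQ missingness is
# resolved per 4-plex run; group contrasts use the Welch t statistic with
# Benjamini-Hochberg q-values.

#' Call CTL-high/low status from marker co-detection
#'
#' A sample is CTL `high` when both marker proteins are detected, `low` when
#' neither is detected, and `unclassified` otherwise (one of two detected);
#' unclassified samples are excluded from downstream two-group contrasts.
#'
#' @param detection A protein-by-sample matrix: either logical (TRUE =
#'   detected) or numeric with `NA` meaning undetected.
#' @param markers Length-2 character, the marker rows (default `CD8A`,
#'   `GZMB`).
#' @return Tibble with columns `sample_id`, `label` (factor
#'   high/low/unclassified).
#' @export
classify_ctl <- function(detection, markers = c("CD8A", "GZMB")) {
  if (length(markers) != 2) abort("`markers` must name exactly two proteins")
  absent <- setdiff(markers, rownames(detection))
  if (length(absent)) {
    abort(sprintf("marker row(s) missing from detection table: %s",
                  paste(absent, collapse = ", ")))
  }
  det <- if (is.logical(detection)) detection else !is.na(detection)
  a <- det[markers[1], ]
  b <- det[markers[2], ]
  label <- dplyr::case_when(a & b ~ "high", !a & !b ~ "low",
                            TRUE ~ "unclassified")
  tibble::tibble(
    sample_id = colnames(detection),
    label = factor(label, levels = c("high", "low", "unclassified"))
  )
}

#' Resolve missing values within one iTRAQ 4-plex run
#'
#' Operates on the abundance scale (values must be nonnegative). For each
#' protein: if at least one sample in the run detected it, missing entries
#' are set to 10% of the lowest detected value for that protein within the
#' run; if no sample detected it, the protein is flagged excluded for the
#' run. Observed values are never altered.
#'
#' @param run_values Protein-by-sample abundance matrix for a single run
#'   (missing = `NA`), or a numeric vector for one protein.
#' @return List with `values` (completed matrix) and `excluded` (character,
#'   proteins undetected across the whole run).
#' @export
impute_itraq_run <- function(run_values) {
  vec_in <- is.null(dim(run_values))
  m <- if (vec_in) matrix(run_values, nrow = 1,
                          dimnames = list("protein", NULL)) else run_values
  if (ncol(m) < 1) abort("run must contain at least 1 sample")
  if (any(m < 0, na.rm = TRUE)) {
    abort("negative abundance input: values must be on the abundance scale")
  }
  detected <- rowSums(!is.na(m)) > 0
  excluded <- rownames(m)[!detected]
  for (i in which(detected)) {
    miss <- is.na(m[i, ])
    if (any(miss)) m[i, miss] <- 0.1 * min(m[i, !miss])
  }
  list(values = if (vec_in) m[1, ] else m, excluded = excluded)
}

#' Apply the per-run iTRAQ rule across a whole cohort
#'
#' @param mat Protein-by-sample abundance matrix.
#' @param run_id Integer vector, run assignment per sample (columns).
#' @return List with `values` (matrix; entries of run-excluded proteins stay
#'   `NA`) and `excluded` (tibble `protein`, `run_id`).
#' @export
impute_itraq <- function(mat, run_id) {
  if (length(run_id) != ncol(mat)) abort("`run_id` must match the sample columns")
  excl <- list()
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    res <- impute_itraq_run(mat[, idx, drop = FALSE])
    mat[, idx] <- res$values
    if (length(res$excluded)) {
      excl[[length(excl) + 1]] <- tibble::tibble(protein = res$excluded, run_id = r)
    }
  }
  list(values = mat,
       excluded = if (length(excl)) dplyr::bind_rows(excl) else
         tibble::tibble(protein = character(), run_id = integer()))
}

# vectorized Welch t over matrix rows; shared by differential_stats and the
# subsampling signature machinery
welch_rows <- function(mat, idx1, idx2) {
  x <- mat[, idx1, drop = FALSE]
  y <- mat[, idx2, drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  zero_var <- se2 == 0
  t_stat[zero_var] <- NA_real_
  p[zero_var] <- 1
  list(t_stat = t_stat, log2_fc = m1 - m2, p_value = p, zero_var = zero_var)
}

#' Per-feature differential statistics between CTL-high and CTL-low samples
#'
#' Welch (unequal-variance) two-sample t statistic, two-sided p-value,
#' high-minus-low mean log2 difference, and Benjamini-Hochberg q-value per
#' feature. Unclassified samples are excluded. Features with zero variance in
#' both groups get an undefined t statistic, `p = 1`, and a `zero_var` flag.
#'
#' @param mat Feature-by-sample matrix of log2 values.
#' @param labels Tibble from [classify_ctl()] (`sample_id`, `label`), or a
#'   vector of labels aligned to the matrix columns.
#' @return Tibble: `feature`, `t_stat`, `log2_fc`, `p_value`, `q_value`,
#'   `zero_var`, ordered as the input rows.
#' @export
differential_stats <- function(mat, labels) {
  lab <- align_labels(labels, colnames(mat))
  idx_high <- which(lab == "high")
  idx_low <- which(lab == "low")
  if (length(idx_high) < 2 || length(idx_low) < 2) {
    abort("need at least 2 samples per CTL group")
  }
  w <- welch_rows(mat, idx_high, idx_low)
  tibble::tibble(
    feature = rownames(mat),
    t_stat = unname(w$t_stat), log2_fc = unname(w$log2_fc),
    p_value = unname(w$p_value),
    q_value = unname(p.adjust(w$p_value, method = "BH")),
    zero_var = unname(w$zero_var)
  )
}

align_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "label") %in% names(labels))) {
      abort("label table must have columns `sample_id` and `label`")
    }
    lab <- as.character(labels$label[match(sample_ids, labels$sample_id)])
  } else {
    if (length(labels) != length(sample_ids)) {
      abort("labels must align with the matrix columns")
    }
    lab <- as.character(labels)
  }
  lab
}

#' Filter differential proteins down to candidate secreted cytokines
#'
#' Keeps secreted features that are over-expressed in CTL-high samples at the
#' protein level (BH q <= `q_max`, positive log2 fold change) and show a
#' significantly positive transcript-protein correlation.
#'
#' @param diff Tibble from [differential_stats()].
#' @param secreted Character set of secreted gene names (non-empty).
#' @param rna_protein_corr Tibble with columns `feature`, `r`, `q_value`:
#'   per-gene transcript-protein correlation and its adjusted p.
#' @param q_max Significance threshold for both filters (default 0.05).
#' @return Tibble of candidate factors (subset of `diff` joined with the
#'   correlation columns).
#' @export
secreted_factor_filter <- function(diff, secreted, rna_protein_corr,
                                   q_max = 0.05) {
  if (length(secreted) == 0) abort("`secreted` set must be non-empty")
  corr <- dplyr::rename(rna_protein_corr, corr_r = "r", corr_q = "q_value")
  diff |>
    dplyr::filter(.data$feature %in% secreted,
                  .data$q_value <= q_max, .data$log2_fc > 0) |>
    dplyr::inner_join(corr, by = "feature") |>
    dplyr::filter(.data$corr_q <= q_max, .data$corr_r > 0)
}
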