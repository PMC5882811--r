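# Rank-correlation machinery: Spearman with the t approximation, tie-aware
# Wilcoxon rank-sum (exact by enumeration for small samples), Holm-Sidak
# step-down adjustment, balanced-subsampling correlation comparison, and the
# pan-cancer / class-stratified correlation summaries.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes the Spearman correlation using average (mid) ranks for ties and a
#' two-sided p-value from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 4), finite values.
#' @return A one-row tibble with columns `estimate` (r), `p.value` and `n`.
#'   When either input has zero variance the estimate is `NA` and the row is
#'   flagged via the `degenerate` column.
#' @examples
#' spearman_cor(1:10, (1:10)^2)   # r = 1, monotone transform
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 4) abort("need at least 4 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("inputs must be finite")
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance in `x` or `y`: Spearman correlation undefined")
    return(tibble::tibble(estimate = NA_real_, p.value = NA_real_,
                          n = n, degenerate = TRUE))
  }
  r <- cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(estimate = r, p.value = p, n = n, degenerate = FALSE)
}

# fast scalar path used inside subsampling loops (no tibble, no checks)
spearman_r <- function(x, y) cor(x, y, method = "spearman")

#' Two-sided Wilcoxon rank-sum test with midrank ties
#'
#' Exact by full enumeration of all group assignments when the pooled sample
#' size is at most `exact_limit`; otherwise a normal approximation with the
#' standard tie correction (no continuity correction). The two-sided exact
#' p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))` for the observed
#' rank-sum `w` of the first group.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_limit Pooled size at or below which the exact enumeration is
#'   used (default 12).
#' @return A list with `statistic` (rank sum of `a`), `p.value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 12) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  if (n <= exact_limit) {
    sums <- combn(n, na, FUN = function(i) sum(r[i]))
    eps <- 1e-8
    pl <- mean(sums <= w + eps)
    pg <- mean(sums >= w - eps)
    p <- min(1, 2 * min(pl, pg))
    method <- "exact"
  } else {
    ties <- table(r)
    ew <- na * (n + 1) / 2
    vw <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- if (vw == 0) 1 else 2 * pnorm(-abs(w - ew) / sqrt(vw))
    method <- "normal"
  }
  list(statistic = w, p.value = p, method = method)
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Adjusted p-values are `max over steps j <= i of 1 - (1 - p_(j))^(m - j + 1)`
#' for the ascending-sorted p-values, capped at 1 and returned in the input
#' order. Monotone nondecreasing in raw-p rank by construction.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compare correlation strength between two groups by balanced subsampling
#'
#' Draws `min(nrow(a), nrow(b))` pairs without replacement from each group at
#' every iteration, computes the Spearman correlation per group, and compares
#' the two resulting correlation distributions with a two-sided Wilcoxon
#' rank-sum test. This is the correlation-loss test used to ask whether e.g.
#' the phospho-ATM/CTL coupling present in ATM-wild-type tumors is absent in
#' ATM-altered tumors, with subsampling guaranteeing equal sample size.
#'
#' @param a,b Two-column data frames or matrices (x, y pairs), one per group.
#'   Each group needs at least 8 pairs.
#' @param n_iterations Number of subsample draws (default 1000).
#' @param seed Integer seed.
#' @param group_names Length-2 character, names for the groups.
#' @return A `subsample_corr` object: list with `distributions` (long tibble of
#'   per-iteration r), `summary` (per-group 95% percentile CI), and
#'   `wilcoxon_p`.
#' @export
subsample_corr_compare <- function(a, b, n_iterations = 1000, seed = 1L,
                                   group_names = c("A", "B")) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 2 || ncol(b) != 2) abort("groups must have two columns (x, y)")
  if (nrow(a) < 8 || nrow(b) < 8) abort("each group needs at least 8 pairs")
  check_count(n_iterations, "n_iterations")
  m <- min(nrow(a), nrow(b))
  set.seed(seed)
  ra <- numeric(n_iterations); rb <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    ia <- sample.int(nrow(a), m)
    ib <- sample.int(nrow(b), m)
    ra[i] <- spearman_r(a[ia, 1], a[ia, 2])
    rb[i] <- spearman_r(b[ib, 1], b[ib, 2])
  }
  wp <- wilcoxon_rank_sum(ra, rb)$p.value
  summary <- tibble::tibble(
    group = group_names,
    median_r = c(median(ra), median(rb)),
    ci_lo = c(quantile(ra, 0.025), quantile(rb, 0.025)),
    ci_hi = c(quantile(ra, 0.975), quantile(rb, 0.975))
  )
  structure(
    list(
      distributions = tibble::tibble(
        group = rep(group_names, each = n_iterations),
        iteration = rep(seq_len(n_iterations), 2),
        r = c(ra, rb)
      ),
      summary = summary,
      wilcoxon_p = wp,
      n_iterations = n_iterations,
      subsample_size = m
    ),
    class = "subsample_corr"
  )
}

#' @export
print.subsample_corr <- function(x, ...) {
  cat("Balanced-subsampling correlation comparison\n")
  cat(sprintf("  %d iterations, subsample size %d\n",
              x$n_iterations, x$subsample_size))
  print(x$summary)
  cat(sprintf("  Wilcoxon rank-sum p = %.3g\n", x$wilcoxon_p))
  invisible(x)
}

#' Per-cohort CTL-score correlations with neoantigen load and ATM protein
#'
#' For every cohort, computes the Spearman correlation (and raw p) of the CTL
#' score with the neoantigen count and with the total-ATM RPPA value, then
#' applies the Holm-Sidak step-down adjustment across cohorts separately
#' within each comparison family.
#'
#' @param samples A data frame with columns `cohort`, `ctl_score`,
#'   `neoantigen`, `atm_rppa`, one row per sample; an optional `class` column
#'   (values `"M"`/`"C"`) yields per-cohort class fractions.
#' @return A tibble with one row per cohort: `cohort`, `n`,
#'   `r_neoantigen_ctl`, `p_neoantigen`, `r_atm_ctl`, `p_atm`, and (when class
#'   labels are present) `frac_m`. Cohorts missing a required channel are
#'   skipped with a warning.
#' @export
pan_cancer_table <- function(samples) {
  need <- c("cohort", "ctl_score", "neoantigen", "atm_rppa")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(paste("`samples` lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  rows <- samples |>
    dplyr::group_by(.data$cohort) |>
    dplyr::group_map(function(d, key) {
      if (all(is.na(d$neoantigen)) || all(is.na(d$atm_rppa)) ||
          all(is.na(d$ctl_score)) || nrow(d) < 4) {
        warn(sprintf("cohort '%s' skipped: missing channel or too few samples",
                     key$cohort))
        return(NULL)
      }
      cn <- spearman_cor(d$ctl_score, d$neoantigen)
      ca <- spearman_cor(d$ctl_score, d$atm_rppa)
      out <- tibble::tibble(
        cohort = key$cohort, n = nrow(d),
        r_neoantigen_ctl = cn$estimate, p_neoantigen_raw = cn$p.value,
        r_atm_ctl = ca$estimate, p_atm_raw = ca$p.value
      )
      if ("class" %in% names(d)) out$frac_m <- mean(d$class == "M")
      out
    }) |>
    purrr::compact() |>
    dplyr::bind_rows()
  if (nrow(rows) == 0) abort("no cohort had complete channels")
  rows$p_neoantigen <- holm_sidak(rows$p_neoantigen_raw)
  rows$p_atm <- holm_sidak(rows$p_atm_raw)
  dplyr::relocate(rows, "p_neoantigen", .after = "p_neoantigen_raw") |>
    dplyr::relocate("p_atm", .after = "p_atm_raw")
}

#' Correlations within the bulk population and M-/C-class strata
#'
#' Computes the (CTL, neoantigen) and (CTL, ATM) Spearman correlations for
#' all samples together and for the mutation-class (M) and copy-number-class
#' (C) subsets of a cohort.
#'
#' @param samples Data frame with columns `ctl_score`, `neoantigen`,
#'   `atm_rppa`, `class` (per-sample `"M"`/`"C"`).
#' @param min_n Minimum stratum size (default 8); smaller strata are reported
#'   with `NA` correlations.
#' @return Tibble with rows `All`, `M`, `C` and columns `stratum`, `n`,
#'   `r_neoantigen_ctl`, `r_atm_ctl`.
#' @export
class_stratified_corr <- function(samples, min_n = 8) {
  need <- c("ctl_score", "neoantigen", "atm_rppa", "class")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(paste("`samples` lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  strata <- list(All = samples,
                 M = samples[samples$class == "M", ],
                 C = samples[samples$class == "C", ])
  purrr::imap(strata, function(d, nm) {
    if (nrow(d) < min_n) {
      warn(sprintf("stratum '%s' has fewer than %d samples: unavailable", nm, min_n))
      return(tibble::tibble(stratum = nm, n = nrow(d),
                            r_neoantigen_ctl = NA_real_, r_atm_ctl = NA_real_))
    }
    tibble::tibble(
      stratum = nm, n = nrow(d),
      r_neoantigen_ctl = spearman_r(d$ctl_score, d$neoantigen),
      r_atm_ctl = spearman_r(d$ctl_score, d$atm_rppa)
    )
  }) |>
    dplyr::bind_rows()
}

#' Correlation of per-cohort correlation coefficients
#'
#' The headline cross-cohort contrast: the Spearman correlation between the
#' per-cohort (CTL, ATM) and (CTL, neoantigen) correlation coefficients. A
#' strong negative value indicates that cohorts coupling CTL infiltration to
#' neoantigen load are distinct from those coupling it to ATM.
#'
#' @param rows Output of [pan_cancer_table()] (>= 5 rows).
#' @return One-row tibble `estimate`, `p.value`, `n`, `degenerate`.
#' @export
correlation_of_correlations <- function(rows) {
  if (nrow(rows) < 5) abort("need at least 5 cohorts")
  spearman_cor(rows$r_atm_ctl, rows$r_neoantigen_ctl)
}
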