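test_that("Spearman examples and properties hold", {
  expect_error(spearman_cor(1:3, c(3, 1, 2)), "at least 4")
  # classic small example extended to length 4 keeps the rank formula exact:
  # perfect monotone increase
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$estimate, 1)
  # symmetry and monotone-transform invariance
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_cor(x, y)$estimate, spearman_cor(y, x)$estimate)
  expect_equal(spearman_cor(exp(x), y)$estimate, spearman_cor(x, y)$estimate)
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "zero variance")
  expect_true(out$degenerate)
})

test_that("the three-point Spearman formula value is reproduced via ranks", {
  # r = 1 - 6*6/(3*8) = -0.5 for x = 1:3, y = (3,1,2); check through the
  # rank-then-Pearson identity on a padded version that meets the n >= 4 rule
  rx <- rank(c(1, 2, 3)); ry <- rank(c(3, 1, 2))
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(r, -0.5)
})

test_that("Spearman with heavy ties matches the rank-then-Pearson oracle exactly", {
  for (i in 1:200) {
    set.seed(i)
    n <- sample(5:25, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    rx <- rank(x); ry <- rank(y)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(spearman_cor(x, y)$estimate, oracle, tolerance = 1e-12)
  }
})

test_that("Wilcoxon exact enumeration reproduces hand-computable cases", {
  out <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p.value, 0.1)
  expect_equal(out$method, "exact")
  same <- wilcoxon_rank_sum(c(1, 2, 5), c(1, 2, 5))
  expect_equal(same$p.value, 1)
  # agrees with wilcox.test exact p for tie-free data
  for (i in 1:50) {
    set.seed(i)
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    ours <- wilcoxon_rank_sum(a, b)$p.value
    ref <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon p-values are uniform under the null", {
  set.seed(10)
  ps <- replicate(1000, wilcoxon_rank_sum(rnorm(30), rnorm(30))$p.value)
  # rank sums are discrete, so duplicate p-values are expected; silence the
  # KS tie warning
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Holm-Sidak reproduces the closed form and is monotone and bounded", {
  expect_equal(holm_sidak(c(0.01, 0.04)),
               c(1 - 0.99^2, max(1 - 0.99^2, 1 - 0.96)))
  expect_equal(holm_sidak(0.2), 0.2)  # single test is unadjusted
  for (i in 1:200) {
    set.seed(300 + i)
    p <- runif(sample(2:10, 1))
    adj <- holm_sidak(p)
    ord <- order(p)
    m <- length(p)
    oracle <- pmin(1, cummax(1 - (1 - p[ord])^(m - seq_len(m) + 1)))
    expect_equal(adj[ord], oracle, tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[ord]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("degenerate subsampling returns the plain group Spearman r", {
  set.seed(20)
  a <- cbind(rnorm(12), rnorm(12))
  b <- cbind(rnorm(12), rnorm(12))
  out <- subsample_corr_compare(a, b, n_iterations = 1, seed = 1)
  expect_equal(out$distributions$r[out$distributions$group == "A"],
               cor(a[, 1], a[, 2], method = "spearman"))
  expect_equal(out$distributions$r[out$distributions$group == "B"],
               cor(b[, 1], b[, 2], method = "spearman"))
  expect_error(subsample_corr_compare(a[1:5, ], b), "at least 8")
})

test_that("subsample correlation distributions concentrate with group size", {
  make_pairs <- function(n, rho, seed) {
    set.seed(seed)
    x <- rnorm(n)
    cbind(x, rho * x + sqrt(1 - rho^2) * rnorm(n))
  }
  # the smaller group fixes the subsample size; the larger group is the one
  # actually resampled, so its distribution width must shrink as both scale
  small <- subsample_corr_compare(make_pairs(30, 0.5, 1),
                                  make_pairs(90, 0.5, 2),
                                  n_iterations = 200, seed = 3)
  large <- subsample_corr_compare(make_pairs(300, 0.5, 4),
                                  make_pairs(900, 0.5, 5),
                                  n_iterations = 200, seed = 6)
  width <- function(x) {
    s <- x$summary
    s$ci_hi[s$group == "B"] - s$ci_lo[s$group == "B"]
  }
  expect_lt(width(large), width(small))
})

test_that("pan-cancer table applies Holm-Sidak per family and flags skipped cohorts", {
  set.seed(30)
  mk <- function(nm, n = 40) tibble::tibble(
    cohort = nm, ctl_score = rnorm(n), neoantigen = rpois(n, 30),
    atm_rppa = rnorm(n))
  samples <- dplyr::bind_rows(mk("a"), mk("b"), mk("c"))
  rows <- pan_cancer_table(samples)
  expect_equal(rows$p_neoantigen, holm_sidak(rows$p_neoantigen_raw))
  expect_equal(rows$p_atm, holm_sidak(rows$p_atm_raw))
  expect_true(all(rows$p_neoantigen >= rows$p_neoantigen_raw))
  broken <- mk("d"); broken$atm_rppa <- NA_real_
  expect_warning(rows2 <- pan_cancer_table(dplyr::bind_rows(mk("a"), broken)),
                 "skipped")
  expect_equal(rows2$cohort, "a")
})

test_that("class strata reduce to the bulk when one class is absent", {
  set.seed(40)
  d <- tibble::tibble(ctl_score = rnorm(30), neoantigen = rpois(30, 20),
                      atm_rppa = rnorm(30), class = "M")
  suppressWarnings(strat <- class_stratified_corr(d))
  expect_equal(strat$r_neoantigen_ctl[strat$stratum == "M"],
               strat$r_neoantigen_ctl[strat$stratum == "All"])
  expect_true(is.na(strat$r_neoantigen_ctl[strat$stratum == "C"]))
})

test_that("correlation of correlations handles exact opposition and degeneracy", {
  rows <- tibble::tibble(r_atm_ctl = c(0.5, 0.3, 0.1, -0.2, -0.4),
                         r_neoantigen_ctl = -c(0.5, 0.3, 0.1, -0.2, -0.4))
  expect_equal(correlation_of_correlations(rows)$estimate, -1)
  flat <- tibble::tibble(r_atm_ctl = rep(0.2, 5),
                         r_neoantigen_ctl = rnorm(5))
  expect_warning(out <- correlation_of_correlations(flat), "zero variance")
  expect_true(out$degenerate)
  expect_error(correlation_of_correlations(rows[1:3, ]), "at least 5")
})
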