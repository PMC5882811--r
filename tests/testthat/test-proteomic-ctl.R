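test_that("CTL calls follow the co-detection rule", {
  det <- matrix(c(5, 3,   # s1: both detected
                  NA, NA, # s2: neither
                  6, NA,  # s3: CD8A only
                  NA, 2), # s4: GZMB only
                nrow = 2,
                dimnames = list(c("CD8A", "GZMB"), paste0("s", 1:4)))
  lab <- classify_ctl(det)
  expect_equal(as.character(lab$label),
               c("high", "low", "unclassified", "unclassified"))
  # logical input and permutation equivariance
  perm <- c(3, 1, 4, 2)
  lab2 <- classify_ctl(!is.na(det)[, perm])
  expect_equal(as.character(lab2$label),
               as.character(lab$label[match(lab2$sample_id, lab$sample_id)]))
  expect_error(classify_ctl(det[1, , drop = FALSE]), "GZMB")
})

test_that("iTRAQ rule: 10% of the run minimum fills gaps, all-missing excludes", {
  run <- matrix(c(5, NA, 8, 6), nrow = 1, dimnames = list("p1", paste0("s", 1:4)))
  out <- impute_itraq_run(run)
  expect_equal(unname(out$values[1, ]), c(5, 0.5, 8, 6))
  expect_length(out$excluded, 0)

  all_na <- matrix(NA_real_, 1, 4, dimnames = list("p2", paste0("s", 1:4)))
  expect_equal(impute_itraq_run(all_na)$excluded, "p2")

  complete <- matrix(c(2, 4, 1, 3), nrow = 1, dimnames = list("p3", paste0("s", 1:4)))
  expect_equal(impute_itraq_run(complete)$values, complete)

  expect_error(impute_itraq_run(matrix(c(-1, 2), 1)), "negative abundance")
})

test_that("iTRAQ imputation never alters observed values and imputes below the run minimum", {
  set.seed(4)
  mat <- matrix(rexp(30 * 16, rate = 0.2), nrow = 30,
                dimnames = list(sprintf("p%02d", 1:30), sprintf("s%02d", 1:16)))
  mat[runif(length(mat)) < 0.3] <- NA
  runs <- rep(1:4, each = 4)
  out <- impute_itraq(mat, runs)
  obs <- !is.na(mat)
  expect_equal(out$values[obs], mat[obs])
  for (r in 1:4) {
    idx <- which(runs == r)
    for (p in rownames(mat)) {
      v <- mat[p, idx]
      if (all(is.na(v))) {
        expect_true(any(out$excluded$protein == p & out$excluded$run_id == r))
      } else if (anyNA(v)) {
        expect_true(all(out$values[p, idx][is.na(v)] < min(v, na.rm = TRUE)))
      }
    }
  }
})

test_that("Welch statistics match the closed-form example and the t.test oracle", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                dimnames = list("f1", paste0("s", 1:6)))
  lab <- rep(c("high", "low"), each = 3)
  d <- differential_stats(mat, lab)
  expect_equal(d$log2_fc, -3)
  expect_equal(d$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(d$t_stat, 3), -3.674)

  # identical groups: zero fold change
  mat2 <- rbind(f1 = rep(c(1, 5, 9), 2))
  colnames(mat2) <- paste0("s", 1:6)
  expect_equal(differential_stats(mat2, lab)$log2_fc, 0)

  # brute-force agreement on 100 random small matrices
  for (i in 1:100) {
    set.seed(i)
    ng <- sample(3:8, 1); n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    m <- matrix(rnorm(ng * (n1 + n2)), nrow = ng,
                dimnames = list(sprintf("g%d", 1:ng),
                                sprintf("s%d", 1:(n1 + n2))))
    d <- differential_stats(m, rep(c("high", "low"), c(n1, n2)))
    o <- oracle_welch(m, 1:n1, n1 + 1:n2)
    expect_equal(d$t_stat, unname(o[, "t"]), tolerance = 1e-10)
    expect_equal(d$p_value, unname(o[, "p"]), tolerance = 1e-10)
    expect_equal(d$log2_fc, unname(o[, "fc"]), tolerance = 1e-12)
  }
})

test_that("zero-variance features are flagged with p = 1 and BH q-values are monotone", {
  mat <- rbind(flat = rep(2, 8), sig = c(rnorm(4, 5), rnorm(4, 0)))
  colnames(mat) <- paste0("s", 1:8)
  d <- differential_stats(mat, rep(c("high", "low"), each = 4))
  expect_true(d$zero_var[1])
  expect_true(is.na(d$t_stat[1]))
  expect_equal(d$p_value[1], 1)
  expect_true(all(d$q_value >= d$p_value))
  ord <- order(d$p_value)
  expect_true(all(diff(d$q_value[ord]) >= -1e-15))
  expect_error(differential_stats(mat, rep(c("high", "low"), c(1, 7))),
               "at least 2")
})

test_that("secreted-factor filter applies all three criteria", {
  diff <- tibble::tibble(
    feature = c("CCL5", "CXCL10", "IL16", "CXCL9", "OTHER"),
    t_stat = c(5, 4, 3, 4, 6), log2_fc = c(2, 1.5, 1, -1, 3),
    p_value = c(1e-5, 1e-4, 1e-3, 1e-4, 1e-6),
    q_value = c(1e-4, 1e-3, 0.2, 1e-3, 1e-5), zero_var = FALSE)
  corr <- tibble::tibble(feature = c("CCL5", "CXCL10", "IL16", "CXCL9", "OTHER"),
                         r = c(0.6, -0.5, 0.7, 0.6, 0.8),
                         q_value = c(0.01, 0.01, 0.01, 0.01, 0.01))
  secreted <- c("CCL5", "CXCL10", "IL16", "CXCL9")
  out <- secreted_factor_filter(diff, secreted, corr)
  # CXCL10 has negative transcript-protein correlation -> excluded;
  # IL16 fails the protein q filter; CXCL9 has negative fold change;
  # OTHER is not secreted
  expect_equal(out$feature, "CCL5")
  expect_error(secreted_factor_filter(diff, character(), corr), "non-empty")
})

test_that("planted cytokines with both signals are exactly recovered", {
  set.seed(42)
  n <- 40
  high <- rep(c(TRUE, FALSE), each = n / 2)
  genes <- c("CCL5", "CXCL9", "CXCL10", "IL16", sprintf("g%02d", 1:30))
  prot <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%02d", 1:n)))
  prot[1:4, high] <- prot[1:4, high] + 2.5
  rna <- prot + matrix(rnorm(length(prot), sd = 0.5), nrow = nrow(prot))
  d <- differential_stats(prot, ifelse(high, "high", "low"))
  corr <- purrr::map_dfr(genes, function(g) {
    ct <- spearman_cor(rna[g, ], prot[g, ])
    tibble::tibble(feature = g, r = ct$estimate, p = ct$p.value)
  })
  corr$q_value <- p.adjust(corr$p, "BH")
  out <- secreted_factor_filter(d, genes[1:4], corr)
  expect_setequal(out$feature, genes[1:4])
})
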