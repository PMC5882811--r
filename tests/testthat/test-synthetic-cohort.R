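test_that("identical configs give bit-identical cohorts", {
  cfg <- simulation_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$protein_matrix, b$protein_matrix)
  expect_identical(a$rna_counts, b$rna_counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("matrices share sample ordering and counts are nonnegative integers", {
  co <- simulate_cohort(simulation_config(seed = 2))
  expect_identical(colnames(co$protein_matrix), co$sample_ids)
  expect_identical(colnames(co$rna_counts), co$sample_ids)
  expect_identical(colnames(co$phospho_matrix), co$sample_ids)
  expect_identical(names(co$rppa), co$sample_ids)
  expect_true(all(co$rna_counts >= 0))
  expect_true(all(co$rna_counts == trunc(co$rna_counts)))
  runs <- table(co$metadata$run_id)
  expect_true(all(runs[-length(runs)] == 4))
})

test_that("detection threshold 0 gives a complete protein matrix and missingness is monotone", {
  co0 <- simulate_cohort(simulation_config(detection_threshold = 0, seed = 3))
  expect_false(anyNA(co0$protein_matrix))
  rates <- vapply(c(0.1, 0.3, 0.5), function(q) {
    mean(is.na(simulate_cohort(simulation_config(detection_threshold = q,
                                                 seed = 3))$protein_matrix))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("degenerate configs are rejected", {
  expect_error(simulation_config(n_samples = 6), "at least 8")
  expect_error(simulation_config(frac_ctl_high = 0.01), "at least 2")
  expect_error(simulation_config(frac_ctl_high = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(detection_threshold = -0.1), "\\[0, 1\\]")
})

test_that("phospho-ATM/CTL coupling is present in WT and severed in altered samples", {
  wins <- 0
  for (i in 1:30) {
    co <- simulate_cohort(simulation_config(
      n_samples = 400, atm_ctl_coupling = 0.8, mutant_fraction = 0.5,
      class_label = "C", seed = 5000 + i))
    st <- cohort_sample_table(co)
    patm <- co$truth$phospho_atm[st$sample_id]
    wt <- st$atm_status == "WT"
    r_wt <- cor(patm[wt], st$ctl_score[wt], method = "spearman")
    r_alt <- cor(patm[!wt], st$ctl_score[!wt], method = "spearman")
    wins <- wins + (r_wt > r_alt)
  }
  expect_gte(wins / 30, 0.95)
})

test_that("class label routes the coupling to the right axis", {
  m <- cohort_sample_table(simulate_cohort(simulation_config(
    n_samples = 300, class_label = "M", cohort_name = "m", seed = 11)))
  c_ <- cohort_sample_table(simulate_cohort(simulation_config(
    n_samples = 300, class_label = "C", cohort_name = "c", seed = 12)))
  expect_gt(cor(m$ctl_score, m$neoantigen, method = "spearman"),
            cor(m$ctl_score, m$atm_rppa, method = "spearman"))
  expect_gt(cor(c_$ctl_score, c_$atm_rppa, method = "spearman"),
            cor(c_$ctl_score, c_$neoantigen, method = "spearman"))
})

test_that("pan-cancer simulation keeps cohorts distinct and labeled", {
  cfgs <- lapply(1:13, function(i) {
    simulation_config(class_label = if (i <= 6) "M" else "C",
                      cohort_name = sprintf("coh%02d", i), seed = i)
  })
  cohorts <- simulate_pan_cancer(cfgs)
  expect_length(cohorts, 13)
  classes <- vapply(cohorts, function(co) co$metadata$class[1], character(1))
  expect_identical(unname(classes), c(rep("M", 6), rep("C", 7)))
  schemas <- unique(lapply(cohorts, function(co) names(co$metadata)))
  expect_length(schemas, 1)
  expect_error(simulate_pan_cancer(cfgs[c(1, 1)]), "duplicate cohort name")
  expect_error(simulate_pan_cancer(cfgs[1]), "at least 2")
})

test_that("PPI/TF simulation is seed-deterministic and ATM is present", {
  a <- simulate_ppi_tf(n_nodes = 100, seed = 9)
  b <- simulate_ppi_tf(n_nodes = 100, seed = 9)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$tf_map, b$tf_map)
  expect_true("ATM" %in% a$network$nodes)
  expect_error(simulate_ppi_tf(n_nodes = 5), ">= 10")
})

test_that("planted TF wiring lifts the observed count above the null 97.5th percentile", {
  sim <- simulate_ppi_tf(planted_enrichment = TRUE, seed = 21)
  nbhd <- build_neighborhood(sim$network, "ATM", 2)
  tf_sets <- cytokine_tf_sets(sim$tf_map, c("CCL5"))
  enr <- empirical_enrichment(nbhd, tf_sets, sim$network$nodes,
                              n_iterations = 2000, seed = 22)
  nulls <- attr(enr, "null_counts")
  expect_gt(enr$observed_count[1], quantile(nulls[1, ], 0.975))
})
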