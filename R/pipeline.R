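# End-to-end pipeline glue: a config object, stage ordering with dependency
# checks, TSV/JSON writers for every stage output, and a deterministic run
# manifest (parameters, seeds, output checksums).

#' Pipeline configuration
#'
#' Collects every stage toggle, parameter, iteration count and seed in one
#' list, recorded verbatim in the run manifest.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Base integer seed; per-cohort and per-stage seeds are derived
#'   from it by small offsets.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "classify", "impute", "differential", "score",
#'   "signature", "gsea", "network", "stratify", "pancancer")`.
#' @param n_m_cohorts,n_c_cohorts Number of M-class / C-class cohorts to
#'   simulate (the first C-class cohort is the primary, proteome-bearing
#'   cohort).
#' @param cohort_args Named list of overrides passed to
#'   [simulation_config()].
#' @param markers Marker pair for the proteomic CTL call.
#' @param cytokines Cytokine gene list.
#' @param test_fraction Train/test split fraction for the signature stage.
#' @param subsample_iterations Subsample draws for the signature stage.
#' @param grid Threshold grid for [grid_search_signature()].
#' @param gsea_permutations Permutations for the GSEA stage.
#' @param network_iterations Null draws for the network enrichment stage.
#' @param stratify_iterations Subsample draws for the correlation-loss stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            stages = c("simulate", "classify", "impute",
                                       "differential", "score", "signature",
                                       "gsea", "network", "stratify",
                                       "pancancer"),
                            n_m_cohorts = 2, n_c_cohorts = 2,
                            cohort_args = list(),
                            markers = c("CD8A", "GZMB"),
                            cytokines = DEFAULT_CYTOKINES,
                            test_fraction = 0.5,
                            subsample_iterations = 200,
                            grid = list(p = c(0.01, 0.05), fc = c(0.5, 1),
                                        fraction = c(0.5, 0.8)),
                            gsea_permutations = 199,
                            network_iterations = 2000,
                            stratify_iterations = 200) {
  all_stages <- c("simulate", "classify", "impute", "differential", "score",
                  "signature", "gsea", "network", "stratify", "pancancer")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  structure(
    list(outdir = outdir, seed = as.integer(seed),
         stages = intersect(all_stages, stages),
         n_m_cohorts = n_m_cohorts, n_c_cohorts = n_c_cohorts,
         cohort_args = cohort_args, markers = markers, cytokines = cytokines,
         test_fraction = test_fraction,
         subsample_iterations = subsample_iterations, grid = grid,
         gsea_permutations = gsea_permutations,
         network_iterations = network_iterations,
         stratify_iterations = stratify_iterations),
    class = "pipeline_config"
  )
}

pipeline_cohort_configs <- function(cf) {
  n_total <- cf$n_m_cohorts + cf$n_c_cohorts
  classes <- c(rep("C", cf$n_c_cohorts), rep("M", cf$n_m_cohorts))
  lapply(seq_len(n_total), function(i) {
    args <- utils::modifyList(
      list(class_label = classes[i],
           cohort_name = sprintf("%s%02d", tolower(classes[i]), i),
           cytokine_genes = cf$cytokines,
           seed = cf$seed + i),
      cf$cohort_args)
    args$class_label <- classes[i]
    args$cohort_name <- sprintf("%s%02d", tolower(classes[i]), i)
    args$seed <- cf$seed + i
    do.call(simulation_config, args)
  })
}

#' Run the analysis pipeline
#'
#' Stages run in dependency order on a simulated pan-cancer study: cohort
#' simulation, proteomic CTL calling, per-run iTRAQ resolution, differential
#' statistics, CTL score training/scoring, signature grid search, preranked
#' GSEA of the t-ranked proteins, ATM-neighborhood TF enrichment, the
#' WT-vs-altered correlation-loss test, and the pan-cancer correlation table.
#' Each stage writes its outputs under `config$outdir`; the run manifest
#' (`manifest.json`) records package version, all parameters and seeds, and
#' an md5 checksum per output file, so that identical configs give identical
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  log_stage <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))
  need <- function(stage, dep, what) {
    if (is.null(state[[dep]])) {
      abort(sprintf("stage '%s' requires output of stage '%s' (%s)",
                    stage, dep, what))
    }
  }
  outputs <- character()
  save_tsv <- function(df, name) {
    path <- file.path(cf$outdir, name)
    readr::write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  if ("simulate" %in% cf$stages) {
    cohorts <- simulate_pan_cancer(pipeline_cohort_configs(cf))
    state$simulate <- cohorts
    state$primary <- cohorts[[1]]
    for (nm in names(cohorts)) {
      path <- file.path(cf$outdir, sprintf("rna_%s.tsv", nm))
      write_matrix_tsv(cohorts[[nm]]$rna_counts, path)
      outputs <- c(outputs, path)
    }
    path <- file.path(cf$outdir, "protein_primary.tsv")
    write_matrix_tsv(state$primary$protein_matrix, path)
    outputs <- c(outputs, path)
    save_tsv(dplyr::bind_rows(purrr::map(cohorts, "metadata")), "metadata.tsv")
    log_stage("simulate", sprintf("%d cohorts", length(cohorts)))
  }

  if ("classify" %in% cf$stages) {
    need("classify", "primary", "simulated primary cohort")
    labels <- classify_ctl(state$primary$protein_matrix, markers = cf$markers)
    state$classify <- labels
    save_tsv(labels, "ctl_labels.tsv")
    log_stage("classify", sprintf("%d high / %d low / %d unclassified",
                                  sum(labels$label == "high"),
                                  sum(labels$label == "low"),
                                  sum(labels$label == "unclassified")))
  }

  if ("impute" %in% cf$stages) {
    need("impute", "primary", "simulated primary cohort")
    abundance <- 2^state$primary$protein_matrix
    imp <- impute_itraq(abundance, state$primary$metadata$run_id)
    state$impute <- log2(imp$values)
    save_tsv(imp$excluded, "itraq_excluded.tsv")
    log_stage("impute", sprintf("%d protein/run exclusions", nrow(imp$excluded)))
  }

  if ("differential" %in% cf$stages) {
    need("differential", "impute", "imputed protein matrix")
    need("differential", "classify", "CTL labels")
    diff <- differential_stats(state$impute, state$classify)
    state$differential <- diff
    save_tsv(diff, "differential_stats.tsv")
    log_stage("differential", sprintf("%d features, %d at q<=0.05",
                                      nrow(diff), sum(diff$q_value <= 0.05)))
  }

  if ("score" %in% cf$stages) {
    need("score", "primary", "simulated primary cohort")
    need("score", "classify", "CTL labels")
    model <- train_ctl_score(state$primary$rna_counts, state$classify,
                             seed = cf$seed + 101)
    state$score_model <- model
    path <- file.path(cf$outdir, "ctl_score_model.json")
    write_score_model(model, path)
    outputs <- c(outputs, path)
    scores <- purrr::imap(state$simulate, function(co, nm) {
      dplyr::mutate(score_samples(model, co$rna_counts), cohort = nm)
    }) |> dplyr::bind_rows()
    state$score <- scores
    save_tsv(scores, "ctl_scores.tsv")
    log_stage("score", sprintf("scored %d samples", nrow(scores)))
  }

  if ("signature" %in% cf$stages) {
    need("signature", "primary", "simulated primary cohort")
    need("signature", "classify", "CTL labels")
    log2rna <- log2(state$primary$rna_counts + 1)
    split <- split_cohort(state$classify, cf$test_fraction, seed = cf$seed + 201)
    stats <- subsample_differential(
      log2rna[, split$train, drop = FALSE],
      state$classify[match(split$train, state$classify$sample_id), ],
      n_iterations = cf$subsample_iterations, seed = cf$seed + 202)
    sig <- grid_search_signature(
      stats, cf$grid, log2rna[, split$test, drop = FALSE],
      state$classify[match(split$test, state$classify$sample_id), ])
    state$signature <- sig
    save_tsv(tidy(sig), "signature.tsv")
    save_tsv(sig$grid_results, "signature_grid.tsv")
    log_stage("signature", sprintf("%d genes, test AUC %.3f",
                                   nrow(sig$signature), sig$objective))
  }

  if ("gsea" %in% cf$stages) {
    need("gsea", "differential", "differential statistics")
    diff <- state$differential[!is.na(state$differential$t_stat), ]
    gene_sets <- list(
      cytokine_program = intersect(c(cf$cytokines, cf$markers), diff$feature),
      random_background = diff$feature[seq(1, nrow(diff), by = 7)]
    )
    res <- run_gsea(diff$feature, diff$t_stat, gene_sets,
                    n_perm = cf$gsea_permutations, seed = cf$seed + 301)
    state$gsea <- res
    save_tsv(res, "gsea_results.tsv")
    log_stage("gsea", sprintf("top set %s (p = %.3g)",
                              res$gene_set[1], res$p_value[1]))
  }

  if ("network" %in% cf$stages) {
    need("network", "primary", "simulated primary cohort")
    sim <- simulate_ppi_tf(planted_enrichment = TRUE, seed = cf$seed + 401,
                           cytokine_genes = cf$cytokines)
    nbhd <- build_neighborhood(sim$network, "ATM", order = 2)
    tf_sets <- cytokine_tf_sets(sim$tf_map, cf$cytokines)
    enr <- empirical_enrichment(nbhd, tf_sets, universe = sim$network$nodes,
                                n_iterations = cf$network_iterations,
                                seed = cf$seed + 402)
    state$network <- enr
    save_tsv(tibble::as_tibble(enr), "network_enrichment.tsv")
    write_edge_list(sim$network$edges, file.path(cf$outdir, "ppi_edges.tsv"))
    outputs <- c(outputs, file.path(cf$outdir, "ppi_edges.tsv"))
    log_stage("network", sprintf("min empirical p = %.3g", min(enr$empirical_p)))
  }

  if ("stratify" %in% cf$stages) {
    need("stratify", "primary", "simulated primary cohort")
    need("stratify", "score", "CTL scores")
    co <- state$primary
    sc <- state$score[state$score$cohort == co$config$cohort_name, ]
    tab <- cohort_sample_table(co, setNames(sc$score, sc$sample_id))
    patm <- co$truth$phospho_atm[tab$sample_id]
    wt <- tab$atm_status == "WT"
    res <- subsample_corr_compare(
      cbind(patm[wt], tab$ctl_score[wt]),
      cbind(patm[!wt], tab$ctl_score[!wt]),
      n_iterations = cf$stratify_iterations, seed = cf$seed + 501,
      group_names = c("WT", "altered"))
    state$stratify <- res
    save_tsv(glance(res), "correlation_loss.tsv")
    log_stage("stratify", sprintf("Wilcoxon p = %.3g", res$wilcoxon_p))
  }

  if ("pancancer" %in% cf$stages) {
    need("pancancer", "simulate", "simulated cohorts")
    need("pancancer", "score", "CTL scores")
    samples <- purrr::imap(state$simulate, function(co, nm) {
      sc <- state$score[state$score$cohort == nm, ]
      cohort_sample_table(co, setNames(sc$score, sc$sample_id))
    }) |> dplyr::bind_rows()
    rows <- pan_cancer_table(samples)
    state$pancancer <- rows
    save_tsv(rows, "pan_cancer_table.tsv")
    if (nrow(rows) >= 5) {
      cc <- correlation_of_correlations(rows)
      state$corr_of_corrs <- cc
      save_tsv(cc, "correlation_of_correlations.tsv")
    }
    strat <- class_stratified_corr(samples)
    state$class_strata <- strat
    save_tsv(strat, "class_stratified_corr.tsv")
    log_stage("pancancer", sprintf("%d cohorts", nrow(rows)))
  }

  manifest <- list(
    package = "ctlomics",
    version = as.character(utils::packageVersion("ctlomics")),
    parameters = cf[setdiff(names(cf), "outdir")],
    checksums = as.list(setNames(unname(tools::md5sum(sort(unique(outputs)))),
                                 basename(sort(unique(outputs)))))
  )
  manifest_path <- file.path(cf$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  state$manifest <- manifest
  invisible(state)
}
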