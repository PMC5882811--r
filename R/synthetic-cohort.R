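# Synthetic multi-omic cohort generator. Emulates the statistical structure
# the downstream analyses assume -- CTL-high samples with elevated
# CD8A/GZMB/PRF1 in protein and RNA space, phospho-ATM -> cytokine -> CTL
# coupling present in ATM-wild-type samples and severed in ATM-altered ones,
# neoantigen counts coupled to CTL level in mutation-class (M) cohorts,
# iTRAQ 4-plex detection missingness -- with full ground truth recorded.

CTL_MARKERS <- c("CD8A", "GZMB", "PRF1")
DEFAULT_CYTOKINES <- c("CCL5", "CXCL9", "CXCL10", "IL16")

#' Configuration for a synthetic multi-omic cohort
#'
#' Defaults encode the desk-scale study conditions: cohorts of 80 samples
#' (the size of the breast proteome cohort the framework was built around), a
#' 2 log2-unit CTL-marker shift, and coupling strengths of 0.6 for whichever
#' axis (neoantigen or ATM) the cohort's class makes active.
#'
#' @param n_samples Number of samples (>= 8).
#' @param n_genes Number of genes in the RNA matrix (markers and cytokines
#'   included).
#' @param n_proteins Number of proteins measured (<= `n_genes`; the first
#'   `n_proteins` genes, which always include markers and cytokines).
#' @param frac_ctl_high Fraction of samples in the CTL-high tail of the
#'   latent CTL level.
#' @param ctl_marker_effect Mean shift (log2 units) applied to CD8A/GZMB/PRF1
#'   in CTL-high samples, in both RNA and protein space.
#' @param atm_ctl_coupling Correlation strength in `[0, 1]` tying phospho-ATM
#'   to cytokines and latent CTL in ATM-wild-type samples (active in C-class
#'   cohorts; forced to 0 in M-class).
#' @param neoantigen_ctl_coupling Correlation strength in `[0, 1]` tying
#'   neoantigen counts to latent CTL (active in M-class; 0 in C-class).
#' @param cytokine_genes Cytokine gene names.
#' @param mutant_fraction Fraction of samples flagged ATM-altered.
#' @param detection_threshold Abundance quantile within a 4-plex run below
#'   which a protein value is undetected (0 = no missingness). The default
#'   0.25 leaves the unshifted CTL markers (based near the detection
#'   boundary) frequently undetected in CTL-low samples, as in 4-plex
#'   proteomes where marker dropout carries the signal.
#' @param class_label `"M"` (mutation-driven) or `"C"` (copy-number-driven).
#' @param cohort_name Cohort identifier.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 80, n_genes = 200, n_proteins = 160,
                              frac_ctl_high = 0.35, ctl_marker_effect = 2.0,
                              atm_ctl_coupling = 0.6,
                              neoantigen_ctl_coupling = 0.6,
                              cytokine_genes = DEFAULT_CYTOKINES,
                              mutant_fraction = 0.25,
                              detection_threshold = 0.25,
                              class_label = c("C", "M"),
                              cohort_name = "cohort1", seed = 1L) {
  class_label <- match.arg(class_label)
  n_samples <- check_count(n_samples, "n_samples", min = 1)
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  n_proteins <- check_count(n_proteins, "n_proteins", min = 1)
  check_proportion(frac_ctl_high, "frac_ctl_high")
  check_proportion(atm_ctl_coupling, "atm_ctl_coupling")
  check_proportion(neoantigen_ctl_coupling, "neoantigen_ctl_coupling")
  check_proportion(mutant_fraction, "mutant_fraction")
  check_proportion(detection_threshold, "detection_threshold")
  if (n_samples < 8) abort("`n_samples` must be at least 8 to form runs and groups")
  n_high <- round(frac_ctl_high * n_samples)
  if (n_high < 2 || n_samples - n_high < 2) {
    abort("`frac_ctl_high` must leave at least 2 samples in each CTL class")
  }
  if (n_proteins > n_genes) abort("`n_proteins` cannot exceed `n_genes`")
  n_named <- length(CTL_MARKERS) + length(cytokine_genes) + 1 # + ATM
  if (n_proteins < n_named + 2) {
    abort("`n_proteins` too small to hold markers, cytokines and ATM")
  }
  structure(
    list(n_samples = n_samples, n_genes = n_genes, n_proteins = n_proteins,
         frac_ctl_high = frac_ctl_high, ctl_marker_effect = ctl_marker_effect,
         atm_ctl_coupling = atm_ctl_coupling,
         neoantigen_ctl_coupling = neoantigen_ctl_coupling,
         cytokine_genes = cytokine_genes, mutant_fraction = mutant_fraction,
         detection_threshold = detection_threshold, class_label = class_label,
         cohort_name = cohort_name, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate one multi-omic cohort
#'
#' Draws a latent Gaussian CTL level per sample and builds RNA counts
#' (negative binomial with gene means tied to the log protein abundance, so
#' transcript-protein correlation is positive and tunable), a log2 protein
#' matrix with iTRAQ-style per-run detection missingness, a phospho matrix
#' containing `ATM_pS1981`, a per-sample RPPA total-ATM value, and metadata.
#' The class label decides which coupling is active: M-class cohorts couple
#' neoantigen counts to latent CTL; C-class cohorts couple phospho-ATM (and
#' through it the cytokines) to latent CTL, but only in ATM-wild-type
#' samples -- in ATM-altered samples the phospho-ATM driver is an independent
#' draw.
#'
#' @param config A [simulation_config()].
#' @return A `ctl_cohort` object: list with `sample_ids`, `protein_matrix`,
#'   `phospho_matrix`, `rna_counts`, `rppa` (named vector), `metadata`
#'   (tibble: `sample_id`, `cohort`, `run_id`, `atm_status`, `neoantigen`,
#'   `class`), and `truth` (latent CTL, CTL-high calls, planted genes,
#'   effective couplings).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_samples
  sample_ids <- sprintf("%s_S%03d", cf$cohort_name, seq_len(n))

  genes <- c(CTL_MARKERS, cf$cytokine_genes, "ATM",
             sprintf("G%04d", seq_len(cf$n_genes)))
  genes <- genes[seq_len(cf$n_genes)]
  proteins <- genes[seq_len(cf$n_proteins)]
  cytokines <- intersect(cf$cytokine_genes, genes)

  # latent CTL level and CTL-high tail
  z <- rnorm(n)
  n_high <- round(cf$frac_ctl_high * n)
  ctl_high <- rank(-z, ties.method = "first") <= n_high

  # ATM status and class-dependent effective couplings
  n_mut <- round(cf$mutant_fraction * n)
  altered <- rep(FALSE, n)
  altered[sample.int(n, n_mut)] <- TRUE
  rho_atm <- if (cf$class_label == "C") cf$atm_ctl_coupling else 0
  rho_neo <- if (cf$class_label == "M") cf$neoantigen_ctl_coupling else 0

  # phospho-ATM: coupled to latent CTL in WT, independent in altered samples
  patm <- rho_atm * z + sqrt(1 - rho_atm^2) * rnorm(n)
  patm[altered] <- rnorm(sum(altered))
  # the cytokine driver is phospho-ATM itself in WT, severed (fresh draw)
  # in altered samples
  driver <- patm
  driver[altered] <- rnorm(sum(altered))
  rppa <- setNames(0.85 * patm + sqrt(1 - 0.85^2) * rnorm(n), sample_ids)

  # neoantigen counts: monotone transform of a latent coupled to CTL
  gneo <- rho_neo * z + sqrt(1 - rho_neo^2) * rnorm(n)
  neoantigen <- rnbinom(n, mu = exp(3.9 + 0.8 * gneo), size = 8)

  # protein log2 abundances; markers sit near the detection boundary so
  # per-run missingness tracks the CTL level. Marker expression carries the
  # latent CTL level continuously (gain 0.5) on top of the CTL-high group
  # shift: the markers are the transcripts/proteins of the infiltrating
  # cells themselves, so their abundance scales with infiltration.
  base <- rnorm(length(genes), mean = 6, sd = 1)
  names(base) <- genes
  base[CTL_MARKERS[CTL_MARKERS %in% genes]] <- 4.8
  marker_gain <- 0.5
  lambda <- if (rho_atm > 0) rho_atm / sqrt(1 - rho_atm^2) else 0
  prot_mean <- matrix(base[proteins], nrow = length(proteins), ncol = n,
                      dimnames = list(proteins, sample_ids))
  mk <- intersect(CTL_MARKERS, proteins)
  prot_mean[mk, ] <- prot_mean[mk, ] + rep(marker_gain * z, each = length(mk))
  prot_mean[mk, ctl_high] <- prot_mean[mk, ctl_high] + cf$ctl_marker_effect
  for (cg in intersect(cytokines, proteins)) {
    prot_mean[cg, ] <- prot_mean[cg, ] + lambda * driver
  }
  if ("ATM" %in% proteins) prot_mean["ATM", ] <- prot_mean["ATM", ] + 0.5 * patm
  protein <- prot_mean + matrix(rnorm(length(prot_mean)), nrow = nrow(prot_mean))

  # iTRAQ 4-plex runs in sample order; per-run detection quantile
  run_id <- ceiling(seq_len(n) / 4)
  if (cf$detection_threshold > 0) {
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      thr <- quantile(protein[, idx], cf$detection_threshold)
      block <- protein[, idx, drop = FALSE]
      block[block < thr] <- NA_real_
      protein[, idx] <- block
    }
  }

  # RNA counts: NB with mean tied to the (pre-missingness) protein signal;
  # genes without a protein row get their own baseline plus marker/cytokine
  # effects so RNA carries the same planted structure
  rna_mean_log2 <- matrix(base[genes], nrow = length(genes), ncol = n,
                          dimnames = list(genes, sample_ids))
  mk_all <- intersect(CTL_MARKERS, genes)
  rna_mean_log2[mk_all, ] <- rna_mean_log2[mk_all, ] +
    rep(marker_gain * z, each = length(mk_all))
  rna_mean_log2[mk_all, ctl_high] <- rna_mean_log2[mk_all, ctl_high] + cf$ctl_marker_effect
  for (cg in cytokines) rna_mean_log2[cg, ] <- rna_mean_log2[cg, ] + lambda * driver
  rna_mean_log2 <- rna_mean_log2 + matrix(rnorm(length(rna_mean_log2), sd = 0.5),
                                          nrow = nrow(rna_mean_log2))
  rna <- matrix(rnbinom(length(rna_mean_log2), mu = 2^rna_mean_log2, size = 10),
                nrow = nrow(rna_mean_log2), dimnames = dimnames(rna_mean_log2))

  # phospho matrix: ATM_pS1981 plus noisy sites for cytokine-pathway and
  # filler proteins
  phospho_prot <- c("ATM", intersect(cytokines, proteins),
                    head(setdiff(proteins, c("ATM", cytokines, mk)), 20))
  phospho <- do.call(rbind, lapply(phospho_prot, function(p) {
    sig <- if (p == "ATM") patm else if (p %in% cytokines) {
      lambda * driver + sqrt(1 / (1 + lambda^2)) * rnorm(n)
    } else rnorm(n)
    matrix(sig + rnorm(n, sd = 0.3), nrow = 1)
  }))
  rownames(phospho) <- ifelse(phospho_prot == "ATM", "ATM_pS1981",
                              paste0(phospho_prot, "_pS100"))
  colnames(phospho) <- sample_ids

  metadata <- tibble::tibble(
    sample_id = sample_ids, cohort = cf$cohort_name, run_id = run_id,
    atm_status = ifelse(altered, "altered", "WT"),
    neoantigen = neoantigen, class = cf$class_label
  )
  truth <- list(
    true_ctl = setNames(z, sample_ids),
    ctl_high = setNames(ctl_high, sample_ids),
    de_genes = mk_all,
    coupled_cytokines = cytokines,
    rho_atm_effective = rho_atm,
    rho_neo_effective = rho_neo,
    phospho_atm = setNames(patm, sample_ids)
  )
  structure(
    list(sample_ids = sample_ids, protein_matrix = protein,
         phospho_matrix = phospho, rna_counts = rna, rppa = rppa,
         metadata = metadata, truth = truth, config = cf),
    class = "ctl_cohort"
  )
}

#' @export
print.ctl_cohort <- function(x, ...) {
  cat(sprintf("ctl_cohort '%s' (%s-class): %d samples\n",
              x$config$cohort_name, x$config$class_label, length(x$sample_ids)))
  cat(sprintf("  protein: %d x %d (%.1f%% missing)  rna: %d x %d  phospho: %d sites\n",
              nrow(x$protein_matrix), ncol(x$protein_matrix),
              100 * mean(is.na(x$protein_matrix)),
              nrow(x$rna_counts), ncol(x$rna_counts), nrow(x$phospho_matrix)))
  invisible(x)
}

#' Flatten a cohort to a per-sample analysis table
#'
#' @param cohort A `ctl_cohort`.
#' @param ctl_score Optional named per-sample score to attach; defaults to the
#'   generator's latent CTL truth (useful for oracle checks).
#' @return Tibble with one row per sample: metadata plus `atm_rppa` and
#'   `ctl_score`.
#' @export
cohort_sample_table <- function(cohort, ctl_score = NULL) {
  stopifnot(inherits(cohort, "ctl_cohort"))
  if (is.null(ctl_score)) ctl_score <- cohort$truth$true_ctl
  md <- cohort$metadata
  md$atm_rppa <- unname(cohort$rppa[md$sample_id])
  md$ctl_score <- unname(ctl_score[md$sample_id])
  md
}

#' Simulate a pan-cancer panel of independent cohorts
#'
#' @param configs List of [simulation_config()] objects (>= 2) with distinct
#'   cohort names.
#' @return Named list of `ctl_cohort` objects.
#' @export
simulate_pan_cancer <- function(configs) {
  if (length(configs) < 2) abort("need at least 2 cohort configs")
  nms <- purrr::map_chr(configs, "cohort_name")
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate cohort name '%s'", nms[duplicated(nms)][1]))
  }
  setNames(purrr::map(configs, simulate_cohort), nms)
}

#' Simulate a PPI network and TF-binding map around ATM
#'
#' Generates an Erdos-Renyi graph containing a node named `ATM`, designates a
#' subset of nodes as transcription factors, and assigns each TF a
#' promoter-target gene set. When `planted_enrichment` is TRUE the TFs that
#' bind cytokine promoters are preferentially drawn from ATM's first/second
#' neighborhood; otherwise cytokine binders are placed uniformly among TFs.
#' The graph is sized so that the discrete null distribution of
#' binder-in-network counts has fine support (many attainable values), which
#' keeps the plus-one empirical p near-nominal.
#'
#' @param n_nodes Number of proteins (>= 10; default 600).
#' @param edge_prob Erdos-Renyi edge probability (default 0.025).
#' @param planted_enrichment Plant cytokine-TF wiring into the ATM
#'   neighborhood?
#' @param seed Integer seed.
#' @param cytokine_genes Cytokine gene names used as promoter targets.
#' @param tf_frac Fraction of nodes that are TFs (default 0.5).
#' @param binders_per_cytokine Number of TFs binding each cytokine's promoter
#'   (default 120).
#' @param planted_frac When planting, fraction of each cytokine's binders
#'   drawn from ATM's 2-neighborhood (default 0.85).
#' @return List with `network` (a `ppi_network`) and `tf_map` (named list
#'   TF -> target genes).
#' @export
simulate_ppi_tf <- function(n_nodes = 600, edge_prob = 0.025,
                            planted_enrichment = FALSE, seed = 1L,
                            cytokine_genes = DEFAULT_CYTOKINES,
                            tf_frac = 0.5, binders_per_cytokine = 120,
                            planted_frac = 0.85) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 10)
  check_proportion(edge_prob, "edge_prob")
  set.seed(seed)
  nodes <- c("ATM", sprintf("P%04d", seq_len(n_nodes - 1)))
  g <- igraph::sample_gnp(n_nodes, edge_prob)
  igraph::V(g)$name <- nodes
  net <- ppi_network(igraph::as_data_frame(g, what = "edges"), nodes = nodes)

  tfs <- sort(sample(setdiff(nodes, "ATM"), round(tf_frac * n_nodes)))
  k <- min(binders_per_cytokine, length(tfs))
  nbhd <- tryCatch(build_neighborhood(net, "ATM", order = 2),
                   error = function(e) "ATM")
  tf_in_nbhd <- intersect(tfs, nbhd)

  filler <- sprintf("T%04d", seq_len(50))
  tf_map <- setNames(lapply(tfs, function(tf) {
    sample(filler, 5)
  }), tfs)
  for (cg in cytokine_genes) {
    if (planted_enrichment && length(tf_in_nbhd) > 0) {
      n_in <- min(round(planted_frac * k), length(tf_in_nbhd))
      binders <- c(sample(tf_in_nbhd, n_in),
                   sample(setdiff(tfs, tf_in_nbhd), k - n_in))
    } else {
      binders <- sample(tfs, k)
    }
    for (tf in binders) tf_map[[tf]] <- union(tf_map[[tf]], cg)
  }
  list(network = net, tf_map = tf_map)
}
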