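# Preranked gene set enrichment: weighted Kolmogorov-Smirnov running sum,
# gene-set-label permutation significance with the plus-one rule, and
# leading-edge extraction.

# order features by weight, descending; stable for ties
ranked_order <- function(weights) order(weights, decreasing = TRUE)

check_ranked <- function(features, weights) {
  if (length(features) != length(weights)) {
    abort("`features` and `weights` must align")
  }
  if (anyDuplicated(features)) abort("ranked feature names must be unique")
}

#' Weighted running-sum enrichment score
#'
#' Features are ranked by weight (descending). The running sum increases by
#' `|weight|^exponent / sum(|weight|^exponent over members)` at member
#' positions and decreases by `1 / (N - N_members)` elsewhere; the enrichment
#' score is the signed extremum of largest absolute value. The running sum
#' starts and ends at zero.
#'
#' @param features Character vector of unique feature names.
#' @param weights Ranking metric per feature (t statistic or signature
#'   coefficient).
#' @param gene_set Character set; must overlap the features and be a proper
#'   subset.
#' @param weight_exponent Exponent on `|weight|` (default 1).
#' @return List with `es`, and `running` (tibble `position`, `feature`,
#'   `weight`, `hit`, `running_sum` in ranked order).
#' @export
enrichment_score <- function(features, weights, gene_set, weight_exponent = 1) {
  check_ranked(features, weights)
  ord <- ranked_order(weights)
  f <- features[ord]; w <- weights[ord]
  hit <- f %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) abort("gene set has no overlap with the ranked features")
  if (n_hit == length(f)) abort("gene set covers the whole ranked list")
  wexp <- abs(w)^weight_exponent
  denom <- sum(wexp[hit])
  inc <- if (denom == 0) {
    # all member weights zero: fall back to equal hit increments
    ifelse(hit, 1 / n_hit, 0)
  } else ifelse(hit, wexp / denom, 0)
  dec <- ifelse(hit, 0, 1 / (length(f) - n_hit))
  # accumulate in double precision step by step (not cumsum, which carries
  # extended precision) so the score is reproducible by any direct
  # running-sum reimplementation
  step <- inc - dec
  running <- numeric(length(step))
  acc <- 0
  for (i in seq_along(step)) {
    acc <- acc + step[i]
    running[i] <- acc
  }
  es <- running[which.max(abs(running))]
  list(
    es = es,
    running = tibble::tibble(position = seq_along(f), feature = f,
                             weight = w, hit = hit, running_sum = running)
  )
}

#' Permutation significance of an enrichment score
#'
#' The null draws random feature sets of the same size from the ranked list
#' (gene-set-label permutation, the standard preranked null);
#' `p = (#{|null ES| >= |observed ES|} + 1) / (n_perm + 1)` and
#' `NES = ES / mean(|null ES| of matching sign)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A `gsea_result`: `es`, `nes`, `p_value`, `leading_edge`,
#'   `null_es`, `running`, `gene_set`.
#' @export
gsea_permutation <- function(features, weights, gene_set, n_perm = 999,
                             seed = 1L, weight_exponent = 1) {
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  obs <- enrichment_score(features, weights, gene_set, weight_exponent)
  k <- sum(features %in% gene_set)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    enrichment_score(features, weights, sample(features, k), weight_exponent)$es
  }, numeric(1))
  p <- (sum(abs(null_es) >= abs(obs$es)) + 1) / (n_perm + 1)
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same_sign) == 0 || mean(abs(same_sign)) == 0) {
    warn("degenerate null: NES undefined")
    NA_real_
  } else obs$es / mean(abs(same_sign))
  structure(
    list(es = obs$es, nes = nes, p_value = p,
         leading_edge = leading_edge(features, weights, gene_set,
                                     es_result = obs),
         null_es = null_es, running = obs$running, gene_set = gene_set,
         n_perm = n_perm),
    class = "gsea_result"
  )
}

#' Leading-edge subset of a gene set
#'
#' For a positive enrichment score, the members ranked at or before the
#' running-sum peak; for a negative score, the members at or after the
#' trough.
#'
#' @inheritParams enrichment_score
#' @param es_result Optional precomputed [enrichment_score()] result.
#' @return Character vector of leading-edge features (in rank order).
#' @export
leading_edge <- function(features, weights, gene_set, es_result = NULL) {
  if (is.null(es_result)) {
    es_result <- enrichment_score(features, weights, gene_set)
  }
  run <- es_result$running
  if (es_result$es >= 0) {
    peak <- which.max(run$running_sum)
    run$feature[run$hit & run$position <= peak]
  } else {
    trough <- which.min(run$running_sum)
    run$feature[run$hit & run$position >= trough]
  }
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, NES = %.3f, p = %.4g (%d permutations)\n",
              x$es, x$nes, x$p_value, x$n_perm))
  cat(sprintf("  leading edge (%d): %s\n", length(x$leading_edge),
              paste(head(x$leading_edge, 10), collapse = ", ")))
  invisible(x)
}

#' Run preranked GSEA over a collection of gene sets
#'
#' @inheritParams gsea_permutation
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param min_overlap Sets with fewer overlapping features are skipped
#'   (default 2).
#' @return Tibble: `gene_set`, `size`, `es`, `nes`, `p_value`, `q_value`
#'   (BH over the tested sets), `leading_edge` (semicolon-joined).
#' @export
run_gsea <- function(features, weights, gene_sets, n_perm = 999, seed = 1L,
                     weight_exponent = 1, min_overlap = 2) {
  rows <- purrr::imap(gene_sets, function(members, nm) {
    ov <- sum(features %in% members)
    if (ov < min_overlap || ov == length(features)) return(NULL)
    r <- gsea_permutation(features, weights, members, n_perm = n_perm,
                          seed = seed, weight_exponent = weight_exponent)
    tibble::tibble(gene_set = nm, size = ov, es = r$es, nes = r$nes,
                   p_value = r$p_value,
                   leading_edge = paste(r$leading_edge, collapse = ";"))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) abort("no gene set overlaps the ranked features")
  out$q_value <- p.adjust(out$p_value, method = "BH")
  dplyr::relocate(out, "q_value", .after = "p_value") |>
    dplyr::arrange(.data$p_value)
}
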