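# ATM-neighborhood network analysis: BFS k-neighborhoods on a curated PPI
# graph, edge filtering by phospho-protein Spearman correlation at a given
# FDR, cytokine -> TF promoter-binding sets, and the plus-one empirical
# enrichment test against uniformly sampled equal-size protein sets.

#' Construct an undirected PPI network
#'
#' Self-loops are dropped and duplicated unordered pairs collapsed.
#'
#' @param edges Data frame with columns `from`, `to` (or any two columns of
#'   node names).
#' @param nodes Optional character vector of node names; defaults to the
#'   nodes appearing in `edges`, but may include isolated proteins.
#' @return A `ppi_network`: list with `graph` (igraph), `nodes`, `edges`
#'   (tibble).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (ncol(edges) < 2) abort("`edges` needs two columns of node names")
  names(edges)[1:2] <- c("from", "to")
  edges <- edges[edges$from != edges$to, 1:2]
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges <- edges[!duplicated(key), ]
  vertices <- union(nodes %||% character(), union(edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  structure(list(graph = g, nodes = igraph::V(g)$name, edges = edges),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Nodes within graph distance `order` of a seed node
#'
#' Breadth-first neighborhood including the seed itself; `order = 2` gives
#' the seed's first and second neighbors.
#'
#' @param ppi A `ppi_network`.
#' @param seed_node Seed protein name (default `"ATM"`).
#' @param order Maximum graph distance (default 2; 0 returns just the seed).
#' @return Character vector of node names.
#' @export
build_neighborhood <- function(ppi, seed_node = "ATM", order = 2) {
  stopifnot(inherits(ppi, "ppi_network"))
  if (!seed_node %in% ppi$nodes) {
    abort(sprintf("seed node '%s' absent from the network", seed_node))
  }
  nb <- igraph::ego(ppi$graph, order = order, nodes = seed_node)[[1]]
  sort(igraph::as_ids(nb))
}

# map phospho-site row names ("PROT_pS1981") to their protein
phospho_site_protein <- function(site_names) sub("_.*$", "", site_names)

#' Filter PPI edges by phospho-protein correlation
#'
#' For each edge whose endpoint proteins both have phospho-site rows and at
#' least `min_shared` jointly observed samples, computes the Spearman
#' correlation between the endpoints' phospho signals (when a protein has
#' several sites, the site pair with maximal |r| represents the edge) and a
#' two-sided t-approximation p-value. Benjamini-Hochberg is applied across
#' all tested edges; edges with q above `fdr` are removed, and edges that
#' cannot be tested for lack of phospho coverage are removed and reported
#' separately. Nodes left isolated are dropped.
#'
#' @param ppi A `ppi_network`.
#' @param phospho_matrix Site-by-sample matrix; row names `PROTEIN_pSITE`.
#' @param fdr FDR threshold in (0, 1), default 0.10.
#' @param min_shared Minimum jointly observed samples per edge (default 8).
#' @return A `ppi_network` of the retained edges, with attributes `tested`
#'   (tibble: `from`, `to`, `site_from`, `site_to`, `r`, `p_value`,
#'   `q_value`, `retained`) and `untestable` (tibble of removed-for-coverage
#'   edges).
#' @export
filter_edges_by_phospho <- function(ppi, phospho_matrix, fdr = 0.10,
                                    min_shared = 8) {
  stopifnot(inherits(ppi, "ppi_network"))
  check_proportion(fdr, "fdr", open = TRUE)
  site_prot <- phospho_site_protein(rownames(phospho_matrix))
  tested <- list(); untestable <- list()
  for (i in seq_len(nrow(ppi$edges))) {
    u <- ppi$edges$from[i]; v <- ppi$edges$to[i]
    su <- which(site_prot == u); sv <- which(site_prot == v)
    best <- NULL
    if (length(su) && length(sv)) {
      for (a in su) for (b in sv) {
        x <- phospho_matrix[a, ]; y <- phospho_matrix[b, ]
        ok <- complete.cases(x, y)
        if (sum(ok) < min_shared) next
        ct <- spearman_cor(x[ok], y[ok])
        if (is.na(ct$estimate)) next
        if (is.null(best) || abs(ct$estimate) > abs(best$r)) {
          best <- list(site_from = rownames(phospho_matrix)[a],
                       site_to = rownames(phospho_matrix)[b],
                       r = ct$estimate, p = ct$p.value)
        }
      }
    }
    if (is.null(best)) {
      untestable[[length(untestable) + 1]] <- tibble::tibble(from = u, to = v)
    } else {
      tested[[length(tested) + 1]] <- tibble::tibble(
        from = u, to = v, site_from = best$site_from, site_to = best$site_to,
        r = best$r, p_value = best$p)
    }
  }
  tested <- dplyr::bind_rows(tested)
  untestable <- if (length(untestable)) dplyr::bind_rows(untestable) else
    tibble::tibble(from = character(), to = character())
  if (nrow(tested) == 0) {
    out <- ppi_network(tibble::tibble(from = character(), to = character()))
    attr(out, "tested") <- tested
    attr(out, "untestable") <- untestable
    return(out)
  }
  tested$q_value <- p.adjust(tested$p_value, method = "BH")
  tested$retained <- tested$q_value <= fdr
  out <- ppi_network(tested[tested$retained, c("from", "to")])
  attr(out, "tested") <- tested
  attr(out, "untestable") <- untestable
  out
}

#' Transcription factors binding each cytokine's promoter
#'
#' @param tf_map Named list TF -> target gene set (e.g. from [read_gmt()]).
#' @param cytokines Character vector of cytokine gene names (non-empty).
#' @return Named list cytokine -> character vector of TFs, preserving the
#'   input cytokine order; a cytokine bound by no TF yields an empty set with
#'   a warning.
#' @export
cytokine_tf_sets <- function(tf_map, cytokines) {
  if (length(cytokines) == 0) abort("`cytokines` must be non-empty")
  sets <- lapply(cytokines, function(cg) {
    tfs <- names(tf_map)[purrr::map_lgl(tf_map, function(t) cg %in% t)]
    if (length(tfs) == 0) warn(sprintf("cytokine '%s' bound by no TF", cg))
    tfs
  })
  setNames(sets, cytokines)
}

#' Empirical enrichment of cytokine TFs in a node set
#'
#' For each cytokine, counts its promoter-binding TFs present in the network
#' node set, then compares that count to an empirical null built by drawing
#' uniform random subsets of the universe of the same size as the node set
#' (without replacement within each draw) and counting analogously. The
#' plus-one empirical p-value is
#' `(#{null >= observed} + 1) / (n_iterations + 1)`.
#'
#' @param network_nodes Character, the node set (e.g. the filtered ATM
#'   neighborhood); must be a subset of `universe` and strictly smaller.
#' @param tf_sets Named list cytokine -> TF set from [cytokine_tf_sets()].
#' @param universe Character, all candidate proteins.
#' @param n_iterations Null draws (default 1e5).
#' @param seed Integer seed.
#' @param pooled Additionally test the union of all cytokine TF sets as a
#'   `"pooled"` row (default FALSE).
#' @return An `enrichment_result`: tibble with `cytokine`, `observed_count`,
#'   `empirical_p`, `n_iterations`; the integer matrix of null counts is in
#'   `attr(, "null_counts")` (one row per tested set).
#' @export
empirical_enrichment <- function(network_nodes, tf_sets, universe,
                                 n_iterations = 1e5, seed = 1L,
                                 pooled = FALSE) {
  n_iterations <- check_count(n_iterations, "n_iterations")
  if (!all(network_nodes %in% universe)) {
    abort("`network_nodes` must be a subset of `universe`")
  }
  m <- length(network_nodes)
  if (length(universe) <= m) abort("`universe` must be larger than the network")
  sets <- tf_sets
  if (pooled) sets <- c(sets, list(pooled = unique(unlist(tf_sets))))
  # indicator vectors over the universe for fast subset counting
  ind <- vapply(sets, function(s) as.numeric(universe %in% s),
                numeric(length(universe)))
  observed <- vapply(sets, function(s) length(intersect(s, network_nodes)),
                     integer(1))
  set.seed(seed)
  nulls <- matrix(0L, nrow = length(sets), ncol = n_iterations,
                  dimnames = list(names(sets), NULL))
  nuniv <- length(universe)
  for (i in seq_len(n_iterations)) {
    draw <- sample.int(nuniv, m)
    nulls[, i] <- as.integer(colSums(ind[draw, , drop = FALSE]))
  }
  p <- (rowSums(nulls >= observed) + 1) / (n_iterations + 1)
  out <- tibble::tibble(
    cytokine = names(sets),
    observed_count = unname(observed),
    empirical_p = unname(p),
    n_iterations = n_iterations
  )
  structure(out, null_counts = nulls, network_size = m,
            class = c("enrichment_result", class(out)))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Empirical TF enrichment (network size %d, %d iterations)\n",
              attr(x, "network_size"), x$n_iterations[1]))
  NextMethod()
}
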