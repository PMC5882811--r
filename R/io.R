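# Readers and writers for the pipeline's plain-text interchange formats:
# feature x sample TSV matrices (empty cell or "NA" = missing), GMT gene
# sets, and two-column TSV / SIF edge lists. Readers reject malformed input
# with a line number rather than coerce.

#' Read a feature-by-sample matrix from TSV
#'
#' The first column holds feature names, the header row holds sample ids.
#' Empty cells and `NA` are treated as missing. Ragged rows, non-numeric
#' cells, and duplicated feature names are errors.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (features in rows) with `NA` for missing entries.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("matrix file needs a header and at least one row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expect <- length(header)
  samples <- header[-1]
  rows <- fields[-1]
  feat <- character(length(rows))
  vals <- matrix(NA_real_, nrow = length(rows), ncol = ncol_expect - 1)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    # a trailing empty field is dropped by strsplit; restore it
    if (length(f) == ncol_expect - 1 && grepl("\t$", lines[[i + 1]])) {
      f <- c(f, "")
    }
    if (length(f) != ncol_expect) {
      abort(sprintf("line %d: expected %d fields, found %d",
                    i + 1, ncol_expect, length(f)))
    }
    feat[i] <- f[1]
    cells <- f[-1]
    miss <- cells == "" | cells == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      abort(sprintf("line %d: non-numeric value '%s'", i + 1,
                    cells[which(bad)[1]]))
    }
    num[miss] <- NA_real_
    vals[i, ] <- num
  }
  if (anyDuplicated(feat)) {
    abort(sprintf("duplicated feature name '%s'", feat[duplicated(feat)][1]))
  }
  dimnames(vals) <- list(feat, samples)
  vals
}

#' Write a feature-by-sample matrix to TSV
#'
#' Missing entries are written as empty cells. Numbers are formatted with
#' full precision (15 significant digits) so that write/read round-trips are
#' the identity to within 1e-9.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("matrix must have row and column names")
  }
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  body <- apply(mat, 1, function(r) paste(fmt(r), collapse = "\t"))
  lines <- c(paste(c("feature", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are collapsed; duplicate set names, lines
#' with fewer than three fields, and empty member lists are errors reported
#' with their line number.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> unique members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty GMT file")
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("line %d: GMT lines need at least 3 tab-separated fields", i))
    }
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members)) abort(sprintf("line %d: empty member list", i))
    nms[i] <- f[1]
    out[[i]] <- members
  }
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate set name '%s'", nms[duplicated(nms)][1]))
  }
  names(out) <- nms
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for each set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a fully named list")
  }
  lines <- purrr::imap_chr(sets, function(members, nm) {
    paste(c(nm, description, members), collapse = "\t")
  })
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read an undirected edge list (two-column TSV or SIF)
#'
#' TSV lines are `nodeA<TAB>nodeB`; SIF lines are
#' `nodeA<TAB>interaction<TAB>nodeB` (detected by a 3+-field first line).
#' Self-loops are dropped and duplicated unordered pairs are collapsed.
#'
#' @param path Path to the edge-list file.
#' @return Tibble with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty edge-list file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  sif <- nf[1] >= 3
  bad <- which(if (sif) nf < 3 else nf != 2)
  if (length(bad)) {
    abort(sprintf("line %d: expected %s fields", bad[1], if (sif) ">= 3" else "2"))
  }
  from <- purrr::map_chr(fields, 1)
  to <- purrr::map_chr(fields, if (sif) 3 else 2)
  edges <- tibble::tibble(from = from, to = to)
  edges <- edges[edges$from != edges$to, ]
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges[!duplicated(key), ]
}

#' Write an undirected edge list as two-column TSV
#'
#' @param edges Data frame with columns `from`, `to`.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  writeLines(paste(edges$from, edges$to, sep = "\t"), path)
  invisible(path)
}
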