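#' Common ancestors and the most informative common ancestor
#'
#' `common_ancestors()` intersects the reflexive ancestor closures of two
#' terms, so an ancestor of the pair — including either term itself when one
#' subsumes the other — is always a candidate. `max_ic_ancestor()` picks the
#' common ancestor with maximal information content (the MICA); ties are
#' broken lexicographically by id for determinism.
#'
#' @param dag An `onto_dag`.
#' @param t,u Term ids present in `dag`.
#' @return `common_ancestors()`: character vector of ids.
#'   `max_ic_ancestor()`: one-row tibble with `mica` (id, or `NA` when the
#'   terms share no ancestor, possible only in multi-root DAGs) and `ic_ma`
#'   (0 in that case).
#' @export
common_ancestors <- function(dag, t, u) {
  intersect(ancestors(dag, t), ancestors(dag, u))
}

#' @rdname common_ancestors
#' @export
max_ic_ancestor <- function(dag, t, u) {
  ca <- common_ancestors(dag, t, u)
  if (length(ca) == 0) {
    warning("terms ", t, " and ", u, " share no ancestor; IC_ma set to 0")
    return(tibble::tibble(mica = NA_character_, ic_ma = 0))
  }
  ics <- vapply(ca, function(a) information_content(dag, a), numeric(1))
  ord <- order(-ics, ca)
  tibble::tibble(mica = ca[ord[1]], ic_ma = unname(ics[ord[1]]))
}

#' Lin semantic similarity between two ontology terms
#'
#' Lin's measure: `2 * IC(MICA) / (IC(t) + IC(u))`, where IC is the negative
#' log of the fraction of ontology terms in a term's inclusive descendant
#' closure. Scores lie in \[0, 1\]. Self-similarity is defined as 1 for every
#' term, which also covers the root where the raw ratio is 0/0; a pair whose
#' only shared ancestor has zero IC (e.g. the root) scores 0.
#'
#' @inheritParams common_ancestors
#' @param detail If `TRUE` return a one-row tibble with the ICs, the MICA and
#'   the score instead of a bare number.
#' @return A similarity in \[0, 1\], or a tibble when `detail = TRUE` with
#'   columns `term_a`, `term_b`, `ic_a`, `ic_b`, `mica`, `ic_ma`, `score`.
#' @examples
#' dag <- generate_dag(n_terms = 20, seed = 7)$dag
#' ids <- dag$terms$id
#' lin_similarity(dag, ids[5], ids[6])
#' @export
lin_similarity <- function(dag, t, u, detail = FALSE) {
  check_term(dag, t)
  check_term(dag, u)
  ic_a <- information_content(dag, t)
  ic_b <- information_content(dag, u)
  if (t == u) {
    mica <- t
    ic_ma <- ic_a
    score <- 1
  } else {
    ma <- max_ic_ancestor(dag, t, u)
    mica <- ma$mica
    ic_ma <- ma$ic_ma
    score <- if (ic_ma == 0) 0 else 2 * ic_ma / (ic_a + ic_b)
  }
  if (!detail) {
    return(score)
  }
  tibble::tibble(
    term_a = t, term_b = u, ic_a = ic_a, ic_b = ic_b,
    mica = mica, ic_ma = ic_ma, score = score
  )
}

#' All-vs-all Lin similarity matrix
#'
#' Computes the full symmetric matrix of Lin similarities over a set of
#' terms. Closures and ICs are computed once per term, so this scales to
#' ontology-sized inputs (thousands of terms) without repeating BFS work
#' per pair.
#'
#' @param dag An `onto_dag`.
#' @param terms Ordered character vector of term ids; defaults to every term
#'   in the DAG.
#' @return A `sim_matrix` object: a numeric matrix with `labels` row/column
#'   names, unit diagonal, values in \[0, 1\].
#' @export
similarity_matrix <- function(dag, terms = dag$terms$id) {
  if (length(terms) == 0) stop("empty term list", call. = FALSE)
  for (t in terms) check_term(dag, t)
  anc <- all_ancestor_sets(dag)
  n_desc <- all_descendant_counts(dag)
  ic <- -log(n_desc / dag$total_terms)
  n <- length(terms)
  m <- matrix(1, n, n, dimnames = list(terms, terms))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ca <- intersect(anc[[terms[i]]], anc[[terms[j]]])
        ic_ma <- if (length(ca)) max(ic[ca]) else 0
        denom <- ic[[terms[i]]] + ic[[terms[j]]]
        m[i, j] <- m[j, i] <- if (ic_ma == 0 || denom == 0) 0 else 2 * ic_ma / denom
      }
    }
  }
  structure(m, class = c("sim_matrix", "matrix", "array"))
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat("<sim_matrix> ", nrow(x), " x ", ncol(x), " cell types\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Tidy a similarity matrix into unordered pairs
#'
#' @param x A `sim_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered distinct pair: `term_a`,
#'   `term_b`, `score`, `band`.
#' @exportS3Method generics::tidy
tidy.sim_matrix <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    term_a = labs[idx[, 1]],
    term_b = labs[idx[, 2]],
    score = x[idx],
    band = similarity_band(x[idx])
  )
}

#' @exportS3Method generics::glance
glance.sim_matrix <- function(x, ...) {
  up <- x[upper.tri(x)]
  tibble::tibble(
    n_terms = nrow(x),
    n_pairs = length(up),
    mean_score = if (length(up)) mean(up) else NA_real_,
    max_score = if (length(up)) max(up) else NA_real_,
    prop_weak = if (length(up)) mean(up < 0.1) else NA_real_
  )
}

#' Qualitative similarity bands
#'
#' Maps a Lin score to the qualitative relationship bands used to read the
#' score distribution: below 0.1 the relationship between cells is weak,
#' 0.1–0.4 moderate, 0.4–0.7 significant, and 0.7 and above a strong
#' correlation suggesting shared location, function or identity.
#'
#' @param score Numeric vector of scores in \[0, 1\].
#' @return Factor with levels `weak`, `moderate`, `significant`, `strong`.
#' @examples
#' similarity_band(c(0.05, 0.5, 0.87))
#' @export
similarity_band <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    stop("similarity scores must lie in [0, 1]", call. = FALSE)
  }
  # right = FALSE gives half-open [a, b) bins; include.lowest closes the
  # final bin at 1 so a perfect score is "strong"
  cut(score,
    breaks = c(0, 0.1, 0.4, 0.7, 1),
    labels = c("weak", "moderate", "significant", "strong"),
    right = FALSE, include.lowest = TRUE
  )
}

#' Rank the cell types most similar to a query term
#'
#' @param dag An `onto_dag`.
#' @param term Query term id.
#' @param k Number of neighbours to return (`k >= 1`); if `k` exceeds the
#'   number of other terms the full ranking is returned.
#' @return A tibble with columns `rank`, `id`, `name`, `score`, `band`,
#'   sorted by score descending with lexicographic id tie-break; the query
#'   term itself is excluded.
#' @export
rank_similar <- function(dag, term, k = 10) {
  check_term(dag, term)
  stopifnot(k >= 1)
  others <- setdiff(dag$terms$id, term)
  scores <- unname(vapply(others, function(u) lin_similarity(dag, term, u), numeric(1)))
  ord <- order(-scores, others)
  top <- utils::head(ord, k)
  tibble::tibble(
    rank = seq_along(top),
    id = others[top],
    name = dag$terms$name[match(others[top], dag$terms$id)],
    score = scores[top],
    band = similarity_band(scores[top])
  )
}

#' Histogram of pairwise similarity scores
#'
#' Bins the strict upper triangle of a similarity matrix (each unordered
#' pair once, diagonal excluded), so the counts sum to n(n-1)/2.
#'
#' @param matrix A `sim_matrix`.
#' @param bin_width Positive bin width on the \[0, 1\] score axis
#'   (default 0.01).
#' @return A tibble with columns `bin_left`, `bin_right`, `count`.
#' @export
score_distribution <- function(matrix, bin_width = 0.01) {
  stopifnot(bin_width > 0)
  if (is.null(dim(matrix)) || nrow(matrix) == 0) {
    stop("empty similarity matrix", call. = FALSE)
  }
  up <- matrix[upper.tri(matrix)]
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(up, breaks = breaks, plot = FALSE, right = FALSE, include.lowest = TRUE)
  tibble::tibble(
    bin_left = h$breaks[-length(h$breaks)],
    bin_right = h$breaks[-1],
    count = h$counts
  )
}

#' Hierarchically cluster cell types by their similarity profiles
#'
#' Rows of the similarity matrix are treated as feature vectors; pairwise
#' Euclidean distances between them feed agglomerative clustering. The
#' default linkage is average; the dendrogram leaves are ordered
#' deterministically by the usual tight-cluster-first layout, suitable for
#' heatmap row ordering.
#'
#' @param matrix A `sim_matrix` with at least two rows.
#' @param linkage One of `"average"`, `"complete"`, `"single"`, `"ward"`
#'   (mapped to Ward's D2 criterion).
#' @return A `cell_clustering` object: list with `hclust` (the merge tree),
#'   `order` (leaf labels in display order) and `newick` (the dendrogram as
#'   a Newick string with branch lengths from merge heights).
#' @export
cluster_cells <- function(matrix, linkage = c("average", "complete", "single", "ward")) {
  linkage <- match.arg(linkage)
  if (is.null(dim(matrix)) || nrow(matrix) < 2) {
    stop("need at least two cell types to cluster", call. = FALSE)
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  d <- stats::dist(unclass(matrix), method = "euclidean")
  hc <- stats::hclust(d, method = method)
  phy <- ape::as.phylo(hc)
  structure(
    list(
      hclust = hc,
      order = hc$labels[hc$order],
      newick = ape::write.tree(phy)
    ),
    class = "cell_clustering"
  )
}

#' @export
print.cell_clustering <- function(x, ...) {
  cat("<cell_clustering> ", length(x$order), " leaves, linkage: ",
    x$hclust$method, "\n",
    sep = ""
  )
  cat("leaf order:", paste(utils::head(x$order, 8), collapse = ", "),
    if (length(x$order) > 8) "...", "\n"
  )
  invisible(x)
}

#' Export a similarity matrix as TSV
#'
#' Wide format writes the labelled square matrix; long format writes one row
#' per unordered pair (`term_a`, `term_b`, `score`). Scores are written at
#' 4 decimal places.
#'
#' @param matrix A `sim_matrix`.
#' @param path Output file path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(matrix, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- tibble::as_tibble(as.data.frame(unclass(matrix)), rownames = "id")
    write_result_table(df, path)
  } else {
    write_result_table(tidy(matrix)[, c("term_a", "term_b", "score")], path)
  }
  invisible(path)
}
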