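#' Build a gene query
#'
#' Normalizes, deduplicates and wraps a set of query gene symbols — typically
#' the genes highly expressed in the cell whose type is to be identified.
#'
#' @param genes Character vector of gene symbols.
#' @param category `"normal"` or `"cancer"`; selects which compendium
#'   partition the query is scored against, since tumour cells carry their
#'   own regulatory programmes.
#' @return A `gene_query`: list with `genes` (normalized, deduplicated,
#'   sorted), `raw_count` (number of symbols submitted) and `category`.
#' @export
gene_query <- function(genes, category = c("normal", "cancer")) {
  category <- match.arg(category)
  raw_count <- length(genes)
  genes <- sort(unique(normalize_symbols(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("empty gene query", call. = FALSE)
  structure(
    list(genes = genes, raw_count = raw_count, category = category),
    class = "gene_query"
  )
}

#' Read a gene list from a plain-text file
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @inheritParams gene_query
#' @return A `gene_query`.
#' @export
read_gene_list <- function(path, category = c("normal", "cancer")) {
  if (!file.exists(path)) stop("cannot read gene list: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  gene_query(lines[nzchar(lines)], category = category)
}

#' @export
print.gene_query <- function(x, ...) {
  cat("<gene_query> ", length(x$genes), " genes (", x$raw_count,
    " submitted), category: ", x$category, "\n",
    sep = ""
  )
  invisible(x)
}

#' Overlap scores between a query and one cell-specific network
#'
#' Two raw overlap ratios against the cell's gene universe M (all TFs and
#' targets of its cell-specific network):
#' `r_net = |Q intersect M| / |M|` (how much of the cell's signature the
#' query covers) and `r_query = |Q intersect M| / |Q|` (how much of the
#' query the signature explains). No enrichment statistic is applied; the
#' ratios are reported as-is.
#'
#' @param query A `gene_query`.
#' @param comp A `network_compendium` with provenance `"cell_specific"`.
#' @param cell_id The cell to score against.
#' @return One-row tibble: `cell_id`, `overlap`, `universe_size`, `r_net`,
#'   `r_query`. When the universe is empty `r_net` is 0 and the row carries
#'   `empty_universe = TRUE`.
#' @export
overlap_scores <- function(query, comp, cell_id) {
  stopifnot(inherits(query, "gene_query"), inherits(comp, "network_compendium"))
  if (comp$provenance != "cell_specific") {
    stop("overlap_scores expects a cell-specific compendium (got ",
      comp$provenance, ")",
      call. = FALSE
    )
  }
  m <- gene_universe(comp, cell_id)
  ov <- length(intersect(query$genes, m))
  tibble::tibble(
    cell_id = cell_id,
    overlap = ov,
    universe_size = length(m),
    r_net = if (length(m) == 0) 0 else ov / length(m),
    r_query = ov / length(query$genes),
    empty_universe = length(m) == 0
  )
}

#' Predict cell types from a query gene list
#'
#' Scores the query against every cell-specific network in its category
#' partition and ranks candidates by the network-side ratio `r_net`
#' descending (ties by `r_query` descending, then cell id). Queries shorter
#' than 10 genes trigger a warning, as short lists give unstable ratios.
#'
#' @param query A `gene_query`; its `category` selects the partition.
#' @param comp A `network_compendium` with provenance `"cell_specific"`.
#' @return A `cell_prediction` object: tibble with columns `rank`,
#'   `cell_id`, `overlap`, `universe_size`, `r_net`, `r_query`, one row per
#'   cell in the partition.
#' @examples
#' comp <- generate_compendium(n_cells = 4, seed = 1)
#' cs <- cell_specific_networks(filter_edges(comp))
#' q <- generate_query(cs, cs$cells$cell_id[1],
#'   n_genes = 12,
#'   planted_overlap = 0.75, seed = 2
#' )
#' predict_cell_types(q, cs)
#' @export
predict_cell_types <- function(query, comp) {
  stopifnot(inherits(query, "gene_query"), inherits(comp, "network_compendium"))
  if (comp$provenance != "cell_specific") {
    stop("predict_cell_types expects a cell-specific compendium (got ",
      comp$provenance, ")",
      call. = FALSE
    )
  }
  cells <- comp$cells$cell_id[comp$cells$category == query$category]
  if (length(cells) == 0) {
    stop("no cells in partition: ", query$category, call. = FALSE)
  }
  if (length(query$genes) < 10) {
    warning("query has fewer than 10 genes; predictions may be unstable")
  }
  rows <- purrr::map_dfr(cells, function(cl) overlap_scores(query, comp, cl))
  rows <- rows |>
    dplyr::arrange(
      dplyr::desc(.data$r_net), dplyr::desc(.data$r_query),
      .data$cell_id
    ) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"empty_universe")
  structure(rows,
    class = c("cell_prediction", class(rows)),
    query = query
  )
}

#' @exportS3Method generics::glance
glance.cell_prediction <- function(x, ...) {
  q <- attr(x, "query")
  tibble::tibble(
    n_cells = nrow(x),
    n_query_genes = length(q$genes),
    category = q$category,
    top_cell = x$cell_id[1],
    top_r_net = x$r_net[1],
    top_r_query = x$r_query[1]
  )
}

#' @exportS3Method generics::tidy
tidy.cell_prediction <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Radar-chart series for the top predicted cell types
#'
#' Extracts the two plot-ready series drawn on the prediction radar charts:
#' the network-side ratios (`r_net`, "net map") and the query-side ratios
#' (`r_query`, "gene list map") over the `top_n` highest-ranked cells, in
#' rank order.
#'
#' @param rows A `cell_prediction` (or compatible tibble sorted by rank).
#' @param top_n Number of vertices (`>= 3`); if fewer rows are available all
#'   are used with a warning.
#' @return A tibble in long format: `cell_id`, `series` (`"net"` or
#'   `"query"`), `value`, with cells ordered as ranked.
#' @export
radar_series <- function(rows, top_n = 10) {
  stopifnot(top_n >= 3)
  if (nrow(rows) < top_n) {
    warning("only ", nrow(rows), " rows available; using all")
    top_n <- nrow(rows)
  }
  top <- utils::head(rows, top_n)
  tidyr::pivot_longer(
    tibble::as_tibble(top)[, c("cell_id", "r_net", "r_query")],
    cols = c("r_net", "r_query"),
    names_to = "series", values_to = "value"
  ) |>
    dplyr::mutate(
      series = dplyr::recode(.data$series, r_net = "net", r_query = "query"),
      cell_id = factor(.data$cell_id, levels = top$cell_id)
    ) |>
    dplyr::arrange(.data$series, .data$cell_id)
}

#' Write a prediction table as TSV
#'
#' Columns `rank`, `cell_type`, `percent_of_cell_type`
#' (`r_net`), `percent_of_query_gene_list` (`r_query`), `overlap_count`,
#' floats at 4 decimals.
#'
#' @param rows A `cell_prediction`.
#' @param path Output path.
#' @param top_n Keep only the first `top_n` rows (default all).
#' @return `path`, invisibly.
#' @export
write_prediction <- function(rows, path, top_n = nrow(rows)) {
  out <- utils::head(tibble::as_tibble(rows), top_n) |>
    dplyr::transmute(
      rank = .data$rank,
      cell_type = .data$cell_id,
      percent_of_cell_type = .data$r_net,
      percent_of_query_gene_list = .data$r_query,
      overlap_count = .data$overlap
    )
  write_result_table(out, path)
  invisible(path)
}
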