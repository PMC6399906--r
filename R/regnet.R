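#' Load a TF-gene regulatory network compendium
#'
#' Reads confidence-scored transcription-factor-to-gene edge lists for a set
#' of cell types, either from a single long-format TSV with columns
#' `cell_id`, `category`, `tf`, `target`, `score`, or from a manifest TSV
#' with columns `cell_id`, `path`, `category` where each `path` is a per-cell
#' TSV with columns `tf`, `target`, `score` (header optional). Gene symbols
#' are normalized (uppercased, trimmed); duplicate `(tf, target)` pairs
#' within one cell are collapsed keeping the maximum score.
#'
#' @param path A long-format TSV, or a manifest TSV when
#'   `manifest = TRUE`.
#' @param manifest Set `TRUE` to treat `path` as a manifest of per-cell
#'   files.
#' @return A `network_compendium`: a list with `edges` (tibble `cell_id`,
#'   `category`, `tf`, `target`, `score`), `cells` (tibble `cell_id`,
#'   `category`, `n_edges`) and `provenance` (`"raw"`).
#' @export
load_compendium <- function(path, manifest = FALSE) {
  if (!file.exists(path)) stop("cannot read compendium file: ", path, call. = FALSE)
  if (manifest) {
    man <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("cell_id", "path", "category")
    if (!all(need %in% names(man))) {
      stop("manifest must have columns cell_id, path, category", call. = FALSE)
    }
    base <- dirname(path)
    edges <- purrr::pmap_dfr(man, function(cell_id, path, category, ...) {
      f <- if (file.exists(path)) path else file.path(base, path)
      if (!file.exists(f)) stop("cannot read cell network file: ", path, call. = FALSE)
      e <- read_edge_file(f)
      if (nrow(e) == 0) warning("empty network for cell ", cell_id)
      dplyr::mutate(e, cell_id = cell_id, category = category, .before = 1)
    })
    cells <- man[, c("cell_id", "category")]
  } else {
    edges <- readr::read_tsv(path,
      show_col_types = FALSE,
      col_types = readr::cols(
        cell_id = readr::col_character(), category = readr::col_character(),
        tf = readr::col_character(), target = readr::col_character(),
        score = readr::col_double()
      )
    )
    need <- c("cell_id", "category", "tf", "target", "score")
    if (!all(need %in% names(edges))) {
      stop("long-format compendium must have columns ",
        paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    cells <- dplyr::distinct(edges, .data$cell_id, .data$category)
  }
  new_compendium(edges, cells, provenance = "raw")
}

read_edge_file <- function(f) {
  first <- readr::read_lines(f, n_max = 1)
  has_header <- length(first) == 1 && grepl("score", first, ignore.case = TRUE)
  e <- readr::read_tsv(f,
    col_names = if (has_header) TRUE else c("tf", "target", "score"),
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE
  )
  if (has_header) names(e) <- tolower(names(e))
  if (!all(c("tf", "target", "score") %in% names(e))) {
    stop("cell network file ", f, " must have columns tf, target, score",
      call. = FALSE
    )
  }
  score <- suppressWarnings(as.numeric(e$score))
  bad <- which(is.na(score) | is.na(e$tf) | is.na(e$target))
  if (length(bad)) {
    stop("malformed row in ", f, " (line ", bad[1] + has_header, ")",
      call. = FALSE
    )
  }
  e$score <- score
  e[, c("tf", "target", "score")]
}

new_compendium <- function(edges, cells, provenance) {
  stopifnot(provenance %in% c("raw", "filtered", "cell_specific"))
  bad_cat <- setdiff(unique(cells$category), c("normal", "cancer"))
  if (length(bad_cat)) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "),
      " (must be normal or cancer)",
      call. = FALSE
    )
  }
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell_id in compendium", call. = FALSE)
  }
  if (nrow(edges)) {
    if (any(!nzchar(trimws(edges$tf))) || any(!nzchar(trimws(edges$target)))) {
      stop("empty tf or target symbol in compendium", call. = FALSE)
    }
    if (any(edges$score < 0)) stop("negative confidence score", call. = FALSE)
    edges <- edges |>
      dplyr::mutate(
        tf = normalize_symbols(.data$tf),
        target = normalize_symbols(.data$target)
      ) |>
      dplyr::group_by(.data$cell_id, .data$category, .data$tf, .data$target) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  }
  cells <- cells |>
    dplyr::left_join(
      dplyr::count(edges, .data$cell_id, name = "n_edges"),
      by = "cell_id"
    ) |>
    dplyr::mutate(n_edges = dplyr::coalesce(.data$n_edges, 0L))
  structure(
    list(edges = tibble::as_tibble(edges), cells = tibble::as_tibble(cells),
         provenance = provenance),
    class = "network_compendium"
  )
}

#' Normalize gene symbols
#'
#' Uppercases and trims whitespace. No alias resolution is attempted.
#'
#' @param x Character vector of symbols.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(x))
}

#' @export
print.network_compendium <- function(x, ...) {
  cat("<network_compendium> ", nrow(x$cells), " cells (",
    sum(x$cells$category == "normal"), " normal, ",
    sum(x$cells$category == "cancer"), " cancer), ",
    nrow(x$edges), " edges, provenance: ", x$provenance, "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::glance
glance.network_compendium <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_normal = sum(x$cells$category == "normal"),
    n_cancer = sum(x$cells$category == "cancer"),
    n_edges = nrow(x$edges),
    provenance = x$provenance
  )
}

#' @exportS3Method generics::tidy
tidy.network_compendium <- function(x, ...) {
  x$edges
}

#' Drop low-confidence regulatory edges
#'
#' Removes every edge whose confidence score is strictly below `threshold`;
#' an edge scoring exactly the threshold is kept. The default 0.01 sits at
#' the evident fault in FANTOM-style confidence-score distributions, below
#' which regulations are taken to be weak or noise. Per-cell removal counts
#' are attached as the `"removed"` attribute.
#'
#' @param comp A `network_compendium` with provenance `"raw"`.
#' @param threshold Non-negative score cutoff (default 0.01).
#' @return A `network_compendium` with provenance `"filtered"`. Cells whose
#'   edges are all removed are retained (empty) with a warning.
#' @export
filter_edges <- function(comp, threshold = 0.01) {
  stopifnot(inherits(comp, "network_compendium"))
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (comp$provenance != "raw") {
    stop("filter_edges expects a raw compendium (got ", comp$provenance, ")",
      call. = FALSE
    )
  }
  kept <- dplyr::filter(comp$edges, .data$score >= threshold)
  removed <- comp$edges |>
    dplyr::filter(.data$score < threshold) |>
    dplyr::count(.data$cell_id, name = "n_removed")
  out <- new_compendium(kept, comp$cells[, c("cell_id", "category")], "filtered")
  emptied <- setdiff(comp$cells$cell_id[comp$cells$n_edges > 0],
                     unique(kept$cell_id))
  if (length(emptied)) {
    warning("all edges removed for cell(s): ", paste(emptied, collapse = ", "))
  }
  attr(out, "removed") <- removed
  attr(out, "threshold") <- threshold
  out
}

#' Extract cell-specific (unique-edge) networks
#'
#' Within each category partition (normal and cancer processed
#' independently), a `(tf, target)` edge is retained in a cell only if no
#' other cell of the same category contains that pair; shared edges are
#' dropped from every cell. The result is each cell's unique regulatory
#' signature, the background used for cell-type prediction.
#'
#' @param comp A `network_compendium` with provenance `"filtered"`.
#' @return A `network_compendium` with provenance `"cell_specific"`.
#' @export
cell_specific_networks <- function(comp) {
  stopifnot(inherits(comp, "network_compendium"))
  if (comp$provenance != "filtered") {
    stop("cell_specific_networks expects a filtered compendium (got ",
      comp$provenance, ")",
      call. = FALSE
    )
  }
  uniq <- comp$edges |>
    dplyr::group_by(.data$category, .data$tf, .data$target) |>
    dplyr::filter(dplyr::n_distinct(.data$cell_id) == 1L) |>
    dplyr::ungroup()
  new_compendium(uniq, comp$cells[, c("cell_id", "category")], "cell_specific")
}

#' Gene universe of one cell's network
#'
#' All gene symbols (TFs and targets) appearing in the cell's edges — the
#' denominator set M of the network-side overlap ratio.
#'
#' @param comp A `network_compendium`.
#' @param cell_id A cell present in the compendium.
#' @return Character vector of normalized symbols (possibly empty).
#' @export
gene_universe <- function(comp, cell_id) {
  check_cell(comp, cell_id)
  e <- comp$edges[comp$edges$cell_id == cell_id, ]
  sort(unique(c(e$tf, e$target)))
}

check_cell <- function(comp, cell_id) {
  if (!cell_id %in% comp$cells$cell_id) {
    stop("unknown cell: ", cell_id, call. = FALSE)
  }
  invisible(cell_id)
}

#' Shared regulatory network of two cell types
#'
#' The `(tf, target)` pairs present in both cells' filtered networks. The
#' reported score is the smaller of the two per-cell confidence scores
#' (conservative), and rows are sorted by score descending with
#' lexicographic `(tf, target)` tie-break. Sharing is computed on filtered
#' networks — after unique-edge extraction no edge could be shared by
#' construction.
#'
#' @param comp A `network_compendium` with provenance `"filtered"`.
#' @param cell_a,cell_b Cells present in the compendium.
#' @return A tibble with columns `tf`, `target`, `score`; zero rows when the
#'   edge sets are disjoint.
#' @export
shared_network <- function(comp, cell_a, cell_b) {
  stopifnot(inherits(comp, "network_compendium"))
  if (comp$provenance != "filtered") {
    stop("shared_network expects a filtered compendium (got ",
      comp$provenance, ")",
      call. = FALSE
    )
  }
  check_cell(comp, cell_a)
  check_cell(comp, cell_b)
  ea <- comp$edges[comp$edges$cell_id == cell_a, c("tf", "target", "score")]
  eb <- comp$edges[comp$edges$cell_id == cell_b, c("tf", "target", "score")]
  dplyr::inner_join(ea, eb, by = c("tf", "target"), suffix = c("_a", "_b")) |>
    dplyr::mutate(score = pmin(.data$score_a, .data$score_b)) |>
    dplyr::select("tf", "target", "score") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$tf, .data$target)
}

#' Annotate a cell pair with its network availability
#'
#' Returns `"Common Network"` when both cells have non-empty filtered
#' networks that share at least one edge, `"<cell> Network"` when exactly
#' one of the pair has a network, and `"No Network"` when neither does (or
#' when both do but share nothing).
#'
#' @param comp A `network_compendium` with provenance `"filtered"`, or
#'   `NULL` (treated as no networks at all).
#' @param cell_a,cell_b Cell labels; cells absent from the compendium are
#'   treated as having no network.
#' @return A single label string.
#' @export
common_network_label <- function(comp, cell_a, cell_b) {
  has_net <- function(cell) {
    !is.null(comp) && cell %in% comp$cells$cell_id &&
      comp$cells$n_edges[comp$cells$cell_id == cell] > 0
  }
  a <- has_net(cell_a)
  b <- has_net(cell_b)
  if (a && b) {
    if (nrow(shared_network(comp, cell_a, cell_b)) > 0) {
      return("Common Network")
    }
    return("No Network")
  }
  if (a) {
    return(paste(cell_a, "Network"))
  }
  if (b) {
    return(paste(cell_b, "Network"))
  }
  "No Network"
}
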