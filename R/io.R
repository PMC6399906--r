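#' Write a result table as UTF-8 TSV
#'
#' All result tables share one writer: header row, tab separation, numeric
#' columns formatted at a fixed number of decimals (default 4, the precision
#' used in the exported similarity and shared-network tables), deterministic
#' row order (rows are written as given). Full precision is retained in the
#' in-memory objects; only the file is rounded.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param digits Decimal places for numeric (non-integer) columns.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, digits = 4) {
  out <- dplyr::mutate(df, dplyr::across(
    dplyr::where(function(x) is.double(x)),
    function(x) sprintf(paste0("%.", digits, "f"), x)
  ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Pairwise similarity table with network annotation
#'
#' The list-vs-list similarity report: one row per requested pair with the
#' Lin score and, when a filtered compendium is supplied, the shared-network
#' availability label for the pair. Cell labels are matched to compendium
#' cells by name.
#'
#' @param dag An `onto_dag`.
#' @param pairs Two-column data frame (or tibble) of term ids
#'   (`celltype_a`, `celltype_b` or first two columns).
#' @param comp Optional `network_compendium` with provenance `"filtered"`;
#'   pass cell labels equal to term names or ids as appropriate.
#' @return Tibble with columns `celltype_a`, `celltype_b`, `similarity` and,
#'   if `comp` is given, `common_network`.
#' @export
similarity_report <- function(dag, pairs, comp = NULL) {
  a <- pairs[[1]]
  b <- pairs[[2]]
  out <- tibble::tibble(
    celltype_a = a,
    celltype_b = b,
    similarity = purrr::map2_dbl(a, b, function(x, y) lin_similarity(dag, x, y))
  )
  if (!is.null(comp)) {
    nm <- stats::setNames(dag$terms$name, dag$terms$id)
    label_of <- function(x) if (x %in% names(nm)) nm[[x]] else x
    out$common_network <- purrr::map2_chr(a, b, function(x, y) {
      common_network_label(comp, label_of(x), label_of(y))
    })
  }
  out
}
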