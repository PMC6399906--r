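#' Generate a random single-root ontology DAG
#'
#' Builds a synthetic cell-type ontology for testing and simulation: term 0
#' is the root and each later term draws between 1 and `max_parents` parents
#' uniformly from the terms generated before it, which guarantees a single
#' root and acyclicity by construction. With `max_parents = 1` the result is
#' a tree. Output is deterministic under `seed`.
#'
#' @param n_terms Number of terms (`>= 1`).
#' @param max_parents Maximum parents per non-root term (`>= 1`).
#' @param seed Integer seed.
#' @param prefix Accession prefix for generated ids.
#' @return A list with `dag` (an `onto_dag`) and `obo` (the same ontology as
#'   OBO flat-file text, round-trippable through [parse_obo()]).
#' @examples
#' fx <- generate_dag(n_terms = 12, max_parents = 2, seed = 42)
#' fx$dag$total_terms
#' @export
generate_dag <- function(n_terms, max_parents = 2, seed = 1, prefix = "SYN") {
  if (n_terms < 1 || max_parents < 1) {
    stop("n_terms and max_parents must be >= 1", call. = FALSE)
  }
  ids <- sprintf("%s:%07d", prefix, seq_len(n_terms) - 1L)
  edges <- withr::with_seed(seed, {
    if (n_terms == 1) {
      tibble::tibble(child = character(), parent = character(), relation = character())
    } else {
      purrr::map_dfr(2:n_terms, function(i) {
        k <- sample.int(min(max_parents, i - 1L), 1)
        tibble::tibble(
          child = ids[i],
          parent = sample(ids[seq_len(i - 1L)], k),
          relation = "is_a"
        )
      })
    }
  })
  terms <- tibble::tibble(
    id = ids,
    name = paste0("synthetic cell type ", seq_len(n_terms) - 1L),
    obsolete = FALSE
  )
  dag <- new_onto_dag(terms, edges, relation_types = "is_a")
  list(dag = dag, obo = write_obo_text(dag))
}

#' Serialize an ontology DAG to OBO flat-file text
#'
#' @param dag An `onto_dag`.
#' @return A character scalar of OBO 1.2 text.
#' @export
write_obo_text <- function(dag) {
  stanzas <- purrr::map_chr(seq_len(nrow(dag$terms)), function(i) {
    id <- dag$terms$id[i]
    isa <- dag$edges$parent[dag$edges$child == id & dag$edges$relation == "is_a"]
    other <- dag$edges[dag$edges$child == id & dag$edges$relation != "is_a", ]
    paste(
      c(
        "[Term]",
        paste0("id: ", id),
        paste0("name: ", dag$terms$name[i]),
        if (length(isa)) paste0("is_a: ", sort(isa)),
        if (nrow(other)) paste0("relationship: ", other$relation, " ", other$parent)
      ),
      collapse = "\n"
    )
  })
  paste0("format-version: 1.2\n\n", paste(stanzas, collapse = "\n\n"), "\n")
}

#' Generate a synthetic scored network compendium
#'
#' Emulates a FANTOM-style compendium: per cell, `edges_per_cell` TF-gene
#' pairs are sampled without replacement from the `n_tfs` x `n_genes` grid
#' and given confidence scores from `score_law`. The default score law is a
#' mixture of 85% Uniform(0.01, 0.4) and 15% Uniform(0, 0.01), reproducing
#' the characteristic fault at 0.01 that motivates the confidence filter.
#' Deterministic under `seed`.
#'
#' @param n_cells Number of cells.
#' @param n_tfs,n_genes Sizes of the TF and target-gene pools.
#' @param edges_per_cell Edges sampled per cell (must not exceed the grid).
#' @param categories Character vector recycled over cells (`"normal"` /
#'   `"cancer"`).
#' @param score_law Function `n -> numeric(n)` drawing confidence scores.
#' @param seed Integer seed.
#' @return A `network_compendium` with provenance `"raw"`.
#' @export
generate_compendium <- function(n_cells, n_tfs = 15, n_genes = 40,
                                edges_per_cell = 30,
                                categories = "normal",
                                score_law = default_score_law,
                                seed = 1) {
  if (n_cells < 1 || n_tfs < 1 || n_genes < 1 || edges_per_cell < 1) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (edges_per_cell > n_tfs * n_genes) {
    stop("edges_per_cell exceeds the TF x gene grid", call. = FALSE)
  }
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  genes <- sprintf("G%04d", seq_len(n_genes))
  cats <- rep_len(categories, n_cells)
  edges <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(c) {
      idx <- sample.int(n_tfs * n_genes, edges_per_cell)
      tibble::tibble(
        cell_id = sprintf("cell_%02d", c),
        category = cats[c],
        tf = tfs[(idx - 1L) %% n_tfs + 1L],
        target = genes[(idx - 1L) %/% n_tfs + 1L],
        score = score_law(edges_per_cell)
      )
    })
  })
  cells <- tibble::tibble(
    cell_id = sprintf("cell_%02d", seq_len(n_cells)),
    category = cats
  )
  new_compendium(edges, cells, "raw")
}

#' @rdname generate_compendium
#' @param n Number of scores to draw.
#' @export
default_score_law <- function(n) {
  low <- stats::runif(n) < 0.15
  ifelse(low, stats::runif(n, 0, 0.01), stats::runif(n, 0.01, 0.4))
}

#' Write a compendium to disk as TSV
#'
#' Long format (`cell_id`, `category`, `tf`, `target`, `score`), readable by
#' [load_compendium()]. Scores are written at full precision so the
#' round-trip is exact.
#'
#' @param comp A `network_compendium`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_compendium <- function(comp, path) {
  readr::write_tsv(comp$edges, path)
  invisible(path)
}

#' Generate a query gene list planted in one cell's universe
#'
#' Draws `ceiling(planted_overlap * n_genes)` genes from the cell's gene
#' universe and fills the remainder with decoy symbols (reserved `DECOY_`
#' prefix) guaranteed absent from every universe. Used to test that
#' prediction recovers the planted cell.
#'
#' @param comp A `network_compendium` (any provenance; typically
#'   cell-specific).
#' @param cell_id The cell to plant the query in.
#' @param n_genes Query size (`>= 1`).
#' @param planted_overlap Fraction in \[0, 1\] of the query drawn from the
#'   cell's universe.
#' @param seed Integer seed.
#' @return A `gene_query` with the cell's category.
#' @export
generate_query <- function(comp, cell_id, n_genes, planted_overlap, seed = 1) {
  check_cell(comp, cell_id)
  stopifnot(n_genes >= 1, planted_overlap >= 0, planted_overlap <= 1)
  m <- gene_universe(comp, cell_id)
  n_plant <- ceiling(planted_overlap * n_genes)
  if (n_plant > length(m)) {
    stop("cell universe (", length(m), ") smaller than requested overlap (",
      n_plant, ")",
      call. = FALSE
    )
  }
  genes <- withr::with_seed(seed, {
    planted <- if (n_plant > 0) sample(m, n_plant) else character()
    decoys <- sprintf("DECOY_%04d", seq_len(n_genes - n_plant))
    c(planted, decoys)
  })
  cat <- comp$cells$category[comp$cells$cell_id == cell_id]
  gene_query(genes, category = cat)
}
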