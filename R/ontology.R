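#' Parse an OBO flat file into an ontology DAG
#'
#' Reads an OBO 1.2/1.4 flat file (`[Term]` stanzas with `id:`, `name:`,
#' `is_a:`, `relationship:` and `is_obsolete:` lines) and builds a directed
#' acyclic graph of cell-type terms. Only edges whose relation label is in
#' `relation_types` are admitted; obsolete terms are dropped before anything
#' is counted, so they contribute neither to the term total nor to any
#' closure. Edges pointing at terms that are obsolete or absent from the file
#' are dropped with a warning.
#'
#' @param path Path to an OBO file.
#' @param relation_types Character vector of admitted edge labels. The
#'   default `"is_a"` is the conservative reading of an ontology backbone;
#'   add `"part_of"` or `"develops_from"` to admit those `relationship:`
#'   edges as well.
#' @return An `onto_dag` object: a list with
#'   \describe{
#'     \item{terms}{tibble with columns `id`, `name`, `obsolete` (always
#'       `FALSE` after parsing) for every admitted term,}
#'     \item{edges}{tibble with columns `child`, `parent`, `relation`,}
#'     \item{parents, children}{adjacency lists keyed by term id,}
#'     \item{total_terms}{number of admitted non-obsolete terms,}
#'     \item{roots}{ids with no admitted parent,}
#'     \item{relation_types}{the labels that were admitted.}
#'   }
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: T:0", "name: root", "",
#'   "[Term]", "id: T:1", "name: a", "is_a: T:0 ! root"
#' ), obo)
#' dag <- parse_obo(obo)
#' dag$total_terms
#' @export
parse_obo <- function(path, relation_types = "is_a") {
  if (!file.exists(path)) {
    stop("cannot read OBO file: ", path, call. = FALSE)
  }
  stopifnot(length(relation_types) >= 1)
  lines <- readLines(path, warn = FALSE)

  # split into stanzas; only [Term] stanzas matter
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0) {
    stop("no stanzas found in OBO file: ", path, call. = FALSE)
  }
  bounds <- c(stanza_starts, length(lines) + 1L)

  ids <- character()
  names_ <- character()
  obsolete <- logical()
  edge_child <- character()
  edge_parent <- character()
  edge_rel <- character()

  strip_val <- function(x) {
    # drop trailing "! comment" then trim
    stringr::str_trim(sub("\\s*!.*$", "", x))
  }

  for (k in seq_along(stanza_starts)) {
    if (lines[stanza_starts[k]] != "[Term]") next
    body <- lines[seq(stanza_starts[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(body)]
    get_field <- function(tag) {
      hits <- grep(paste0("^", tag, ":"), body, value = TRUE)
      strip_val(sub(paste0("^", tag, ":"), "", hits))
    }
    id <- get_field("id")
    if (length(id) != 1 || !nzchar(id)) {
      stop("[Term] stanza without a single non-empty id in ", path, call. = FALSE)
    }
    nm <- get_field("name")
    obs <- any(tolower(get_field("is_obsolete")) == "true")
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm)) nm[1] else id)
    obsolete <- c(obsolete, obs)
    if (obs) next
    isa <- get_field("is_a")
    if ("is_a" %in% relation_types && length(isa)) {
      edge_child <- c(edge_child, rep(id, length(isa)))
      edge_parent <- c(edge_parent, isa)
      edge_rel <- c(edge_rel, rep("is_a", length(isa)))
    }
    rel <- get_field("relationship")
    if (length(rel)) {
      parts <- stringr::str_split_fixed(rel, "\\s+", 2)
      keep <- parts[, 1] %in% setdiff(relation_types, "is_a")
      if (any(keep)) {
        edge_child <- c(edge_child, rep(id, sum(keep)))
        edge_parent <- c(edge_parent, parts[keep, 2])
        edge_rel <- c(edge_rel, parts[keep, 1])
      }
    }
  }

  if (anyDuplicated(ids)) {
    stop("duplicate term id in OBO file: ", ids[duplicated(ids)][1], call. = FALSE)
  }

  admitted <- ids[!obsolete]
  terms <- tibble::tibble(id = admitted, name = names_[!obsolete], obsolete = FALSE)
  edges <- tibble::tibble(child = edge_child, parent = edge_parent, relation = edge_rel)
  bad <- !(edges$parent %in% admitted)
  if (any(bad)) {
    warning(sum(bad), " edge(s) referencing obsolete or unknown terms dropped")
    edges <- edges[!bad, , drop = FALSE]
  }
  edges <- dplyr::distinct(edges)

  new_onto_dag(terms, edges, relation_types)
}

# Assemble and validate an onto_dag from term/edge tibbles.
new_onto_dag <- function(terms, edges, relation_types) {
  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  children <- split(edges$child, factor(edges$parent, levels = terms$id))
  dag <- structure(
    list(
      terms = terms,
      edges = edges,
      parents = parents,
      children = children,
      total_terms = nrow(terms),
      roots = terms$id[vapply(parents[terms$id], length, 1L) == 0L],
      relation_types = relation_types
    ),
    class = "onto_dag"
  )
  cyc <- find_cycle_member(dag)
  if (!is.null(cyc)) {
    stop("cycle detected in ontology involving term: ", cyc, call. = FALSE)
  }
  dag
}

# Kahn's algorithm; returns NULL if acyclic, else the id of one term on a cycle.
find_cycle_member <- function(dag) {
  indeg <- vapply(dag$children[dag$terms$id], length, 1L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (p in dag$parents[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < dag$total_terms) names(indeg)[indeg > 0L][1] else NULL
}

#' @export
print.onto_dag <- function(x, ...) {
  cat("<onto_dag> ", x$total_terms, " terms, ", nrow(x$edges), " edges (",
    paste(x$relation_types, collapse = ", "), "), ",
    length(x$roots), " root(s)\n",
    sep = ""
  )
  invisible(x)
}

check_term <- function(dag, term) {
  if (!term %in% dag$terms$id) {
    stop("unknown ontology term: ", term, call. = FALSE)
  }
  invisible(term)
}

# BFS over an adjacency list; reflexive (start included).
reachable <- function(adj, start) {
  out <- character()
  queue <- start
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    if (v %in% out) next
    out <- c(out, v)
    queue <- c(queue, adj[[v]])
  }
  out
}

#' Ancestor and descendant closures
#'
#' Reflexive-transitive closures over the admitted edges: a term is a member
#' of its own ancestor and descendant sets. With this convention every leaf
#' has a non-empty descendant set, so term probabilities are strictly
#' positive and information content is always finite.
#'
#' @param dag An `onto_dag`.
#' @param term A term id present in `dag`.
#' @return Character vector of term ids (unordered).
#' @export
ancestors <- function(dag, term) {
  check_term(dag, term)
  reachable(dag$parents, term)
}

#' @rdname ancestors
#' @export
descendants <- function(dag, term) {
  check_term(dag, term)
  reachable(dag$children, term)
}

#' Term probability and information content
#'
#' `term_probability()` is the fraction of the ontology covered by a term:
#' the number of terms in its inclusive descendant closure divided by the
#' total number of admitted non-obsolete terms. On a single-root DAG the root
#' has probability 1. `information_content()` is the negative natural log of
#' that probability (nats): 0 at the root, maximal at the rarest leaves.
#'
#' @inheritParams ancestors
#' @return A probability in (0, 1], or a non-negative IC in nats.
#' @examples
#' dag <- generate_dag(n_terms = 10, seed = 1)$dag
#' information_content(dag, dag$roots[1]) # 0 at the root
#' @export
term_probability <- function(dag, term) {
  stopifnot(dag$total_terms > 0)
  length(descendants(dag, term)) / dag$total_terms
}

#' @rdname term_probability
#' @export
information_content <- function(dag, term) {
  -log(term_probability(dag, term))
}

# Descendant counts for every term in one pass (reverse topological order);
# used by the all-pairs similarity code where per-term BFS would be wasteful.
all_descendant_counts <- function(dag) {
  ids <- dag$terms$id
  counts <- vapply(ids, function(t) length(reachable(dag$children, t)), 1L)
  names(counts) <- ids
  counts
}

# Ancestor closure for every term, as a named list of character vectors.
all_ancestor_sets <- function(dag) {
  ids <- dag$terms$id
  out <- lapply(ids, function(t) reachable(dag$parents, t))
  names(out) <- ids
  out
}

#' Turn an ontology DAG into a tidy term table
#'
#' @param x An `onto_dag`.
#' @param ... Unused.
#' @return A tibble with one row per admitted term: `id`, `name`,
#'   `n_ancestors`, `n_descendants`, `probability`, `ic`.
#' @exportS3Method generics::tidy
tidy.onto_dag <- function(x, ...) {
  tibble::tibble(
    id = x$terms$id,
    name = x$terms$name,
    n_ancestors = unname(vapply(x$terms$id, function(t) length(ancestors(x, t)), 1L)),
    n_descendants = unname(vapply(x$terms$id, function(t) length(descendants(x, t)), 1L)),
    probability = .data$n_descendants / x$total_terms,
    ic = -log(.data$probability)
  )
}

#' @exportS3Method generics::glance
glance.onto_dag <- function(x, ...) {
  tibble::tibble(
    n_terms = x$total_terms,
    n_edges = nrow(x$edges),
    n_roots = length(x$roots),
    relation_types = paste(x$relation_types, collapse = ",")
  )
}
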