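# Shared fixtures and independent oracles.

# Toy five-term DAG: root; A is_a root; B is_a root; C is_a {A, B}; D is_a A.
t1_obo_lines <- function(extra = character()) {
  c(
    "format-version: 1.2", "",
    "[Term]", "id: T:root", "name: root", "",
    "[Term]", "id: T:A", "name: a", "is_a: T:root ! root", "",
    "[Term]", "id: T:B", "name: b", "is_a: T:root", "",
    "[Term]", "id: T:C", "name: c", "is_a: T:A", "is_a: T:B", "",
    "[Term]", "id: T:D", "name: d", "is_a: T:A",
    extra
  )
}

t1_dag <- function(extra = character()) {
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(t1_obo_lines(extra), f)
  parse_obo(f)
}

# Reachability oracle via igraph, independent of the package's BFS.
ig_of <- function(dag) {
  igraph::graph_from_data_frame(
    dag$edges[, c("child", "parent")],
    directed = TRUE,
    vertices = dag$terms$id
  )
}

oracle_ancestors <- function(dag, term) {
  g <- ig_of(dag)
  names(igraph::subcomponent(g, term, mode = "out"))
}

oracle_descendants <- function(dag, term) {
  g <- ig_of(dag)
  names(igraph::subcomponent(g, term, mode = "in"))
}

# Brute-force Lin similarity: enumerate all common ancestors explicitly and
# recompute every IC from raw descendant counts, no shared code with the
# implementation.
oracle_lin <- function(dag, t, u) {
  g <- ig_of(dag)
  ic <- function(x) {
    -log(length(igraph::subcomponent(g, x, mode = "in")) / nrow(dag$terms))
  }
  if (t == u) {
    return(1)
  }
  ca <- intersect(
    names(igraph::subcomponent(g, t, mode = "out")),
    names(igraph::subcomponent(g, u, mode = "out"))
  )
  if (length(ca) == 0) {
    return(0)
  }
  ic_ma <- max(vapply(ca, ic, numeric(1)))
  denom <- ic(t) + ic(u)
  if (ic_ma == 0 || denom == 0) 0 else 2 * ic_ma / denom
}

# Small compendium with known structure for regnet tests: two normal cells
# sharing one edge, one cancer cell.
toy_compendium <- function() {
  edges <- tibble::tibble(
    cell_id = c("c1", "c1", "c1", "c2", "c2", "c3"),
    category = c("normal", "normal", "normal", "normal", "normal", "cancer"),
    tf = c("F1", "F1", "F2", "F1", "F3", "F1"),
    target = c("G1", "G2", "G3", "G1", "G4", "G1"),
    score = c(0.3, 0.2, 0.009, 0.25, 0.05, 0.4)
  )
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(edges, f)
  load_compendium(f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
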