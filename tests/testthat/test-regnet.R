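test_that("compendium loads from long TSV with normalization and max-score collapse", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    cell_id = c("c1", "c1", "c1", "c2"),
    category = "normal",
    tf = c(" f1 ", "F1", "f2", "F1"),
    target = c("g1", "G1", "g2", "G9"),
    score = c(0.2, 0.5, 0.1, 0.3)
  ), f)
  comp <- load_compendium(f)
  expect_equal(comp$provenance, "raw")
  expect_equal(nrow(comp$cells), 2)
  e1 <- comp$edges[comp$edges$cell_id == "c1", ]
  expect_equal(nrow(e1), 2) # duplicate (F1,G1) collapsed
  expect_equal(e1$score[e1$tf == "F1" & e1$target == "G1"], 0.5)
  expect_true(all(e1$tf == toupper(e1$tf)))
  expect_setequal(gene_universe(comp, "c1"), c("F1", "F2", "G1", "G2"))
})

test_that("compendium loads from a manifest of per-cell files", {
  dir <- withr::local_tempdir()
  readr::write_tsv(
    tibble::tibble(tf = c("F1", "F2"), target = c("G1", "G2"), score = c(0.3, 0.2)),
    file.path(dir, "c1.tsv")
  )
  writeLines(c("F1\tG1\t0.25"), file.path(dir, "c2.tsv")) # headerless
  readr::write_tsv(
    tibble::tibble(
      cell_id = c("c1", "c2"), path = c("c1.tsv", "c2.tsv"),
      category = c("normal", "cancer")
    ),
    file.path(dir, "manifest.tsv")
  )
  comp <- load_compendium(file.path(dir, "manifest.tsv"), manifest = TRUE)
  expect_equal(nrow(comp$cells), 2)
  expect_equal(comp$cells$category, c("normal", "cancer"))
  expect_equal(comp$edges$score[comp$edges$cell_id == "c2"], 0.25)

  writeLines(c("F1\tG1\tnot_a_number"), file.path(dir, "bad.tsv"))
  readr::write_tsv(
    tibble::tibble(cell_id = "cx", path = "bad.tsv", category = "normal"),
    file.path(dir, "manifest_bad.tsv")
  )
  expect_error(
    load_compendium(file.path(dir, "manifest_bad.tsv"), manifest = TRUE),
    "malformed row.*bad\\.tsv.*line 1"
  )
})

test_that("unknown categories and duplicate cells are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    cell_id = "c1", category = "weird", tf = "F1", target = "G1", score = 0.5
  ), f)
  expect_error(load_compendium(f), "unknown category")
})

test_that("edge filtering is strict at the threshold and keeps emptied cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    cell_id = "c1", category = "normal",
    tf = c("F1", "F2", "F3"), target = c("G1", "G2", "G3"),
    score = c(0.009, 0.01, 0.5)
  ), f)
  comp <- load_compendium(f)
  filt <- filter_edges(comp)
  expect_equal(filt$provenance, "filtered")
  expect_setequal(filt$edges$score, c(0.01, 0.5)) # 0.009 removed, boundary kept
  expect_equal(attr(filt, "removed")$n_removed, 1)
  # threshold 0 is the identity
  expect_equal(nrow(filter_edges(comp, 0)$edges), 3)
  expect_error(filter_edges(comp, -1), ">= 0")
  # all edges below threshold: cell retained empty, with a warning
  expect_warning(all_gone <- filter_edges(comp, 0.9), "all edges removed")
  expect_equal(nrow(all_gone$edges), 0)
  expect_equal(all_gone$cells$cell_id, "c1")
  expect_equal(all_gone$cells$n_edges, 0L)
})

test_that("filtering is idempotent in effect and monotone in the threshold", {
  for (seed in 1:5) {
    comp <- generate_compendium(n_cells = 5, seed = seed)
    f1 <- filter_edges(comp, 0.01)
    # idempotence: re-filtering the kept edge set removes nothing
    expect_true(all(f1$edges$score >= 0.01))
    f_hi <- filter_edges(comp, 0.05)
    expect_lte(nrow(f_hi$edges), nrow(f1$edges))
    expect_true(all(
      paste(f_hi$edges$cell_id, f_hi$edges$tf, f_hi$edges$target) %in%
        paste(f1$edges$cell_id, f1$edges$tf, f1$edges$target)
    ))
  }
})

test_that("cell-specific extraction keeps only edges unique within a category", {
  comp <- toy_compendium()
  filt <- filter_edges(comp)
  cs <- cell_specific_networks(filt)
  expect_equal(cs$provenance, "cell_specific")
  # (F1,G1) is in both normal cells -> dropped from both; kept in cancer c3
  e <- cs$edges
  expect_false(any(e$cell_id %in% c("c1", "c2") & e$tf == "F1" & e$target == "G1"))
  expect_true(any(e$cell_id == "c3" & e$tf == "F1" & e$target == "G1"))
  # unique edges survive
  expect_true(any(e$cell_id == "c1" & e$tf == "F1" & e$target == "G2"))
  expect_true(any(e$cell_id == "c2" & e$tf == "F3" & e$target == "G4"))
  # wrong provenance rejected
  expect_error(cell_specific_networks(comp), "filtered")
  expect_error(cell_specific_networks(cs), "filtered")
})

test_that("uniqueness partition invariant: kept + dropped pairs equal the filtered input", {
  for (seed in 1:5) {
    comp <- generate_compendium(
      n_cells = 6, n_tfs = 5, n_genes = 10,
      edges_per_cell = 20, seed = seed
    )
    filt <- filter_edges(comp)
    cs <- cell_specific_networks(filt)
    # every kept pair occurs in exactly one cell per category
    per_pair <- dplyr::count(cs$edges, .data$category, .data$tf, .data$target,
      name = "n_cells"
    )
    expect_true(all(per_pair$n_cells == 1))
    # kept pairs are a subset of filtered pairs, and dropped pairs are exactly
    # those occurring in > 1 cell of the partition
    key <- function(e) paste(e$category, e$tf, e$target)
    multi <- dplyr::count(
      dplyr::distinct(filt$edges, .data$category, .data$cell_id, .data$tf, .data$target),
      .data$category, .data$tf, .data$target
    )
    expect_setequal(
      unique(key(cs$edges)),
      paste(multi$category, multi$tf, multi$target)[multi$n == 1]
    )
  }
})

test_that("shared networks intersect filtered edges with min score, sorted", {
  comp <- toy_compendium()
  filt <- filter_edges(comp)
  sn <- shared_network(filt, "c1", "c2")
  expect_equal(nrow(sn), 1)
  expect_equal(sn$tf, "F1")
  expect_equal(sn$target, "G1")
  expect_equal(sn$score, 0.25) # min(0.3, 0.25)
  # symmetry as sets
  sn_rev <- shared_network(filt, "c2", "c1")
  expect_equal(sn, sn_rev)
  # sharing crosses categories freely (it is the uniqueness rule that is
  # per-category): F1-G1 is also in the cancer cell c3
  expect_equal(nrow(shared_network(filt, "c1", "c3")), 1)
  expect_error(shared_network(filt, "c1", "nope"), "unknown cell")
  expect_error(shared_network(comp, "c1", "c2"), "filtered")
  # score-descending order with lexicographic tie-break on a larger fixture
  for (seed in 1:3) {
    g <- generate_compendium(n_cells = 2, n_tfs = 4, n_genes = 8,
                             edges_per_cell = 25, seed = seed)
    gf <- filter_edges(g)
    s <- shared_network(gf, "cell_01", "cell_02")
    if (nrow(s) > 1) {
      expect_true(all(diff(s$score) <= 0))
    }
  }
})

test_that("common-network labels cover all availability cases", {
  comp <- toy_compendium()
  filt <- filter_edges(comp)
  expect_equal(common_network_label(filt, "c1", "c2"), "Common Network")
  expect_equal(common_network_label(filt, "c1", "unknown_cell"), "c1 Network")
  expect_equal(common_network_label(filt, "ghost", "c2"), "c2 Network")
  expect_equal(common_network_label(filt, "ghost_a", "ghost_b"), "No Network")
  expect_equal(common_network_label(NULL, "a", "b"), "No Network")
})
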