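test_that("loading collapses duplicates, drops self-loops, keeps isolated genes", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_a\tgene_b\tinteraction_type",
               "A\tB\t0417", "B\tA\t0417", "C\tC\t0417"),
             file.path(dir, "edges.tsv"))
  writeLines(c("symbol\tentrez\tuniprot",
               "A\t1\tP00001", "B\t2\tP00002", "C\t3\tP00003"),
             file.path(dir, "genes.tsv"))
  store <- load_interactome(file.path(dir, "edges.tsv"), file.path(dir, "genes.tsv"))

  expect_equal(nrow(store$edges), 1L)
  expect_setequal(gene_universe(store), c("A", "B", "C"))
  rep <- load_report(store)
  counts <- stats::setNames(rep$count, rep$stage)
  expect_equal(unname(counts["duplicates_collapsed"]), 1)
  expect_equal(unname(counts["self_loops_dropped"]), 1)
  expect_equal(unname(counts["edges_kept"]), 1)
})

test_that("interaction-type filter keeps only rows carrying a requested code", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_a\tgene_b\tinteraction_type",
               "A\tB\t0417", "A\tC\t0915"),
             file.path(dir, "edges.tsv"))
  writeLines(c("symbol\tentrez\tuniprot", "A\t\t", "B\t\t", "C\t\t"),
             file.path(dir, "genes.tsv"))
  unfiltered <- load_interactome(file.path(dir, "edges.tsv"), file.path(dir, "genes.tsv"))
  filtered <- load_interactome(file.path(dir, "edges.tsv"), file.path(dir, "genes.tsv"),
                               interaction_type_filter = "0417")
  expect_equal(nrow(unfiltered$edges), 2L)
  expect_equal(nrow(filtered$edges), 1L)
  expect_equal(filtered$edges$from, "A")
  expect_equal(filtered$edges$to, "B")
})

test_that("loader counts agree with a brute-force dedupe over the raw fixture rows", {
  dir <- withr::local_tempdir()
  fx <- make_interactome_fixture(dir, n_genes = 40, model = "erdos_renyi",
                                 params = list(p = 0.12), seed = 11,
                                 n_duplicates = 10, n_self_loops = 5)
  raw <- utils::read.delim(fx$files$edges, stringsAsFactors = FALSE)
  # independent set-based dedupe of the raw rows
  not_self <- raw$gene_a != raw$gene_b
  pair <- paste(pmin(raw$gene_a[not_self], raw$gene_b[not_self]),
                pmax(raw$gene_a[not_self], raw$gene_b[not_self]))
  expected_edges <- length(unique(pair))
  expected_selfloops <- sum(!not_self)

  store <- load_interactome(fx$files$edges, fx$files$genes)
  expect_equal(nrow(store$edges), expected_edges)
  expect_equal(length(gene_universe(store)), fx$n_genes)
  counts <- stats::setNames(load_report(store)$count, load_report(store)$stage)
  expect_equal(unname(counts["self_loops_dropped"]), expected_selfloops)
  expect_equal(unname(counts["duplicates_collapsed"]),
               sum(not_self) - expected_edges)
})

test_that("hprd-flat and biogrid-tab dialects pick the documented columns", {
  dir <- withr::local_tempdir()
  writeLines(c("A\th1\trs1\tB\th2\trs2\ty2h\t123",
               "B\th2\trs2\tC\th3\trs3\ty2h\t456"),
             file.path(dir, "hprd.tsv"))
  pad <- function(a, b, type) paste(c("x", "x", "x", "x", "x", "x", "x",
                                      a, b, "x", "x", type), collapse = "\t")
  writeLines(c(paste(rep("h", 12), collapse = "\t"),
               pad("A", "B", "psi-mi:MI:0417(footprinting)"),
               pad("B", "C", "psi-mi:MI:0915(physical association)")),
             file.path(dir, "biogrid.tsv"))
  writeLines(c("symbol\tentrez\tuniprot", "A\t\t", "B\t\t", "C\t\t"),
             file.path(dir, "genes.tsv"))

  hprd <- load_interactome(file.path(dir, "hprd.tsv"), file.path(dir, "genes.tsv"),
                           dialect = "hprd-flat")
  expect_setequal(paste(hprd$edges$from, hprd$edges$to), c("A B", "B C"))

  bg <- load_interactome(file.path(dir, "biogrid.tsv"), file.path(dir, "genes.tsv"),
                         dialect = "biogrid-tab", interaction_type_filter = "0417")
  expect_equal(nrow(bg$edges), 1L)
  expect_equal(paste(bg$edges$from, bg$edges$to), "A B")
})

test_that("resolution is case-insensitive, namespace-ordered, and deduplicating", {
  store <- interactome_from_tables(
    genes = data.frame(symbol = c("MSX1", "PAX3"), entrez = c("4487", "5077"),
                       uniprot = c("P28360", "P23760")))
  r <- resolve_genes(c("msx1"), store)
  expect_equal(r$resolved, "MSX1")
  expect_equal(nrow(r$rejected), 0L)

  r2 <- resolve_genes(c("MSX1", "MSX1", "NOPE"), store)
  expect_equal(r2$resolved, "MSX1")
  expect_equal(r2$rejected$token, "NOPE")
  expect_equal(r2$rejected$reason, "unknown")

  # all three namespaces reach the same record; entrez numerically, uniprot
  # isoform-insensitively
  expect_equal(resolve_genes("0004487", store)$resolved, "MSX1")
  expect_equal(resolve_genes("p28360-2", store)$resolved, "MSX1")

  expect_error(resolve_genes(c("NOPE", "ALSO_NOPE"), store),
               class = "seednet_resolution_error")
  expect_error(resolve_genes(character(), store),
               class = "seednet_resolution_error")
})

test_that("namespace precedence is symbol-first and configurable", {
  # contrived clash: token 7088 is gene X's entrez and gene Y's symbol
  store <- interactome_from_tables(
    genes = data.frame(symbol = c("X", "7088"), entrez = c("7088", NA)))
  expect_equal(resolve_genes("7088", store)$resolved, "7088")
  expect_equal(resolve_genes("7088", store,
                             precedence = c("entrez", "symbol", "uniprot"))$resolved,
               "X")
})

test_that("resolved keys re-resolve to themselves (fixed point)", {
  fx <- make_interactome_fixture(withr::local_tempdir(), n_genes = 25,
                                 model = "erdos_renyi", params = list(p = 0.2),
                                 seed = 3)
  store <- load_interactome(fx$files$edges, fx$files$genes)
  first <- resolve_genes(fx$keys[1:10], store)$resolved
  again <- resolve_genes(first, store)$resolved
  expect_identical(first, again)
})

test_that("edge-list round trip and reload idempotence preserve node and edge sets", {
  dir <- withr::local_tempdir()
  fx <- make_interactome_fixture(dir, n_genes = 30, model = "erdos_renyi",
                                 params = list(p = 0.15), seed = 5,
                                 n_duplicates = 3, n_self_loops = 2)
  s1 <- load_interactome(fx$files$edges, fx$files$genes)
  s2 <- load_interactome(fx$files$edges, fx$files$genes)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$genes, s2$genes)

  write_edge_list(s1, file.path(dir, "out_edges.tsv"), file.path(dir, "out_genes.tsv"))
  s3 <- load_interactome(file.path(dir, "out_edges.tsv"), file.path(dir, "out_genes.tsv"))
  expect_setequal(gene_universe(s3), gene_universe(s1))
  expect_setequal(edge_key(s3$edges$from, s3$edges$to),
                  edge_key(s1$edges$from, s1$edges$to))
})

test_that("id-table ambiguities are rejected at load, not at query time", {
  # second record reuses the first record's entrez -> rejected
  store <- interactome_from_tables(
    genes = data.frame(symbol = c("A", "B"), entrez = c("10", "10")))
  expect_equal(nrow(store$genes), 1L)
  expect_equal(store$genes$key, "A")
})

test_that("GMT catalogs resolve genes, drop unknowns, and prune emptied terms", {
  store <- toy_store(list(c("A", "B"), c("B", "C")))
  dir <- withr::local_tempdir()
  writeLines(c("T1\tdesc\tA\tB",
               "T2\tdesc\tA\tZZZ",
               "T3\tdesc\tZZZ\tQQQ"),
             file.path(dir, "cat.gmt"))
  cat <- load_catalog(file.path(dir, "cat.gmt"), "pathway", store)
  expect_setequal(names(cat$terms), c("T1", "T2"))
  expect_setequal(cat$terms$T1, c("A", "B"))
  expect_equal(cat$terms$T2, "A")
  counts <- stats::setNames(load_report(cat)$count, load_report(cat)$stage)
  expect_equal(unname(counts["gene_tokens_dropped"]), 3)
  expect_equal(unname(counts["terms_removed"]), 1)

  writeLines("T1\tdesc\tZZZ", file.path(dir, "empty.gmt"))
  expect_error(load_catalog(file.path(dir, "empty.gmt"), "pathway", store),
               class = "seednet_parse_error")
})

test_that("catalog term survival matches an independent intersection pass", {
  dir <- withr::local_tempdir()
  fx <- make_interactome_fixture(dir, n_genes = 60, model = "erdos_renyi",
                                 params = list(p = 0.1), seed = 9)
  store <- load_interactome(fx$files$edges, fx$files$genes)
  universe <- gene_universe(store)
  # 50 terms mixing known keys and planted unknown tokens
  set.seed(42)
  lines <- vapply(1:50, function(i) {
    known <- sample(universe, sample(2:6, 1))
    unknown <- if (i %% 3 == 0) sprintf("FAKE%02d", i) else character()
    paste(c(sprintf("T%02d", i), "d", known, unknown), collapse = "\t")
  }, character(1))
  writeLines(lines, file.path(dir, "big.gmt"))
  cat <- load_catalog(file.path(dir, "big.gmt"), "disease", store)

  # oracle: line-by-line set intersection with the id table's symbols
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    surv <- intersect(parts[-(1:2)], universe)
    if (length(surv)) {
      expect_setequal(cat$terms[[parts[1]]], surv)
    } else {
      expect_false(parts[1] %in% names(cat$terms))
    }
  }
})

test_that("unreadable inputs raise I/O errors", {
  expect_error(load_interactome("/nonexistent/e.tsv", "/nonexistent/g.tsv"),
               class = "seednet_io_error")
  store <- toy_store(list(c("A", "B")))
  expect_error(load_catalog("/nonexistent/c.gmt", "pathway", store),
               class = "seednet_io_error")
})
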