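test_that("a unique shortest path between two candidates recruits the whole chain", {
  store <- toy_store(list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E")))
  sn <- build_subnetwork(store, candidates = c("A", "E"))
  expect_setequal(sn$nodes$key, c("A", "B", "C", "D", "E"))
  expect_equal(nrow(sn$edges), 4L)
  roles <- stats::setNames(sn$nodes$role, sn$nodes$key)
  expect_equal(unname(roles[c("A", "E")]), c("candidate", "candidate"))
  # B and D are both interactors and path members; intermediate wins
  expect_equal(unname(roles[c("B", "C", "D")]), rep("intermediate", 3))
})

test_that("all co-minimal shortest paths are included (diamond)", {
  store <- toy_store(list(c("A", "B"), c("B", "D"), c("A", "C"), c("C", "D")))
  sn <- build_subnetwork(store, candidates = c("A", "D"))
  expect_setequal(sn$nodes$key, c("A", "B", "C", "D"))
  expect_equal(nrow(sn$edges), 4L)
  expect_true(all(sn$edges$on_path))
  # two logged paths per direction
  expect_equal(nrow(sn$path_log), 4L)
  expect_setequal(vapply(sn$path_log$path, paste, character(1), collapse = ">")[
    sn$path_log$source == "A"], c("A>B>D", "A>C>D"))
})

test_that("candidate adjacency to targets terminates the path search", {
  store <- toy_store(list(c("A", "T1"), c("A", "T2"), c("A", "L")))
  sn <- build_subnetwork(store, candidates = "A", targets = c("T1", "T2"))
  expect_setequal(sn$nodes$key, c("A", "T1", "T2", "L"))
  expect_equal(sum(sn$nodes$role == "intermediate"), 0L)
  roles <- stats::setNames(sn$nodes$role, sn$nodes$key)
  expect_equal(unname(roles["L"]), "interactor")
  expect_equal(unname(roles[c("T1", "T2")]), c("target", "target"))
})

test_that("only minimally distant targets are linked; farther targets stay isolated", {
  store <- toy_store(list(c("A", "X"), c("X", "T1"),
                          c("A", "P"), c("P", "Q"), c("Q", "T2")))
  sn <- build_subnetwork(store, candidates = "A", targets = c("T1", "T2"))
  expect_true(all(c("X", "T1", "T2") %in% sn$nodes$key))
  # T2 is distance 3: no path recruited, Q not present
  expect_false("Q" %in% sn$nodes$key)
  expect_equal(sn$path_log$dest, "T1")
  roles <- stats::setNames(sn$nodes$role, sn$nodes$key)
  expect_equal(unname(roles["T2"]), "target")
})

test_that("target interactors are not recruited; unreachable targets persist", {
  store <- toy_store(list(c("A", "B"), c("T1", "Z")), extra_nodes = "T2")
  sn <- build_subnetwork(store, candidates = "A", targets = c("T1", "T2"))
  # Z interacts with target T1 only: excluded
  expect_false("Z" %in% sn$nodes$key)
  expect_true(all(c("T1", "T2") %in% sn$nodes$key))
})

test_that("a gene in both sets has role 'both' and never matches itself", {
  store <- toy_store(list(c("A", "B"), c("B", "T1")))
  sn <- build_subnetwork(store, candidates = c("A", "T1"), targets = "T1")
  roles <- stats::setNames(sn$nodes$role, sn$nodes$key)
  expect_equal(unname(roles["T1"]), "both")
  # T1 (as candidate) must not log a zero-length self path
  expect_false(any(sn$path_log$length == 0L))
})

test_that("isolated candidates are retained with their role", {
  store <- toy_store(list(c("A", "B")), extra_nodes = "LONER")
  sn <- build_subnetwork(store, candidates = c("A", "LONER"))
  expect_true("LONER" %in% sn$nodes$key)
  roles <- stats::setNames(sn$nodes$role, sn$nodes$key)
  expect_equal(unname(roles["LONER"]), "candidate")
})

test_that("induced-subgraph mode adds edges among recruited nodes", {
  # B and C are both interactors of candidates and adjacent to each other:
  # the B-C edge is drawn only in induced mode
  store <- toy_store(list(c("A", "B"), c("D", "C"), c("B", "C"), c("A", "D")))
  sn_paths <- build_subnetwork(store, candidates = c("A", "D"))
  sn_ind <- build_subnetwork(store, candidates = c("A", "D"), edges = "induced")
  expect_false("B|C" %in% edge_key(sn_paths$edges$from, sn_paths$edges$to))
  expect_true("B|C" %in% edge_key(sn_ind$edges$from, sn_ind$edges$to))
})

test_that("builder equals the brute-force enumeration on atlas graphs (<= 7 nodes)", {
  checked <- 0L
  for (idx in seq(2, 1252, by = 3)) {
    g <- igraph::graph_from_atlas(idx)
    n <- igraph::vcount(g)
    if (n < 3 || !igraph::is_connected(g)) next
    nodes <- sprintf("N%d", seq_len(n))
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]])
    store <- interactome_from_tables(genes = data.frame(symbol = nodes),
                                     edges = edges)
    set.seed(idx)
    cand <- sample(nodes, min(3L, n - 1L))
    sn <- build_subnetwork(store, cand)
    or <- oracle_subnetwork(nodes, edges, cand)
    got <- sn_keys(sn)
    expect_identical(got$nodes, or$nodes)
    expect_identical(got$edges, or$edges)
    expect_identical(got$path_edges, or$path_edges)
    # two-set mode on the remaining nodes
    rest <- setdiff(nodes, cand)
    if (length(rest) >= 1) {
      targ <- rest[seq_len(min(2L, length(rest)))]
      sn2 <- build_subnetwork(store, cand, targets = targ)
      or2 <- oracle_subnetwork(nodes, edges, cand, targets = targ)
      expect_identical(sn_keys(sn2)$nodes, or2$nodes)
      expect_identical(sn_keys(sn2)$edges, or2$edges)
    }
    checked <- checked + 1L
  }
  expect_gt(checked, 250L)
})

test_that("builder equals the brute-force enumeration on random fixtures (<= 50 nodes)", {
  for (seed in 1:25) {
    gt <- random_graph_tbl(n = 10 + (seed * 7) %% 41, p = 0.09, seed = 1000 + seed)
    store <- store_from_tbl(gt)
    set.seed(seed)
    cand <- sample(gt$nodes, 5)
    targ <- sample(setdiff(gt$nodes, cand), 4)
    sn <- build_subnetwork(store, cand)
    or <- oracle_subnetwork(gt$nodes, gt$edges, cand)
    expect_identical(sn_keys(sn)$nodes, or$nodes)
    expect_identical(sn_keys(sn)$edges, or$edges)
    sn2 <- build_subnetwork(store, cand, targets = targ)
    or2 <- oracle_subnetwork(gt$nodes, gt$edges, cand, targets = targ)
    expect_identical(sn_keys(sn2)$nodes, or2$nodes)
    expect_identical(sn_keys(sn2)$edges, or2$edges)
  }
})

test_that("builder is deterministic and monotone in candidates/interactors", {
  gt <- random_graph_tbl(30, 0.12, seed = 77)
  store <- store_from_tbl(gt)
  set.seed(7)
  cand <- sample(gt$nodes, 4)
  sn_a <- build_subnetwork(store, cand)
  sn_b <- build_subnetwork(store, cand)
  expect_identical(sn_a$nodes, sn_b$nodes)
  expect_identical(sn_a$edges, sn_b$edges)
  adj <- oracle_adj(gt$nodes, gt$edges)
  must_have <- unique(c(cand, unlist(adj[cand])))
  expect_true(all(must_have %in% sn_a$nodes$key))
  targ <- setdiff(gt$nodes, must_have)[1:3]
  sn_t <- build_subnetwork(store, cand, targets = targ)
  expect_true(all(must_have %in% sn_t$nodes$key))
})

test_that("removing a candidate's unique closest target reroutes to the next-closest", {
  # A adjacent to T1; T2 two hops away via m
  store <- toy_store(list(c("A", "T1"), c("A", "M"), c("M", "T2")))
  sn_before <- build_subnetwork(store, "A", targets = c("T1", "T2"))
  expect_identical(unique(sn_before$path_log$dest), "T1")
  sn_after <- build_subnetwork(store, "A", targets = "T2")
  expect_identical(unique(sn_after$path_log$dest), "T2")
  expect_true("M" %in% sn_after$nodes$key)
  # T1 persists as a direct interactor of A even though no longer a target
  expect_true("T1" %in% sn_after$nodes$key)
  expect_equal(sn_after$nodes$role[sn_after$nodes$key == "T1"], "interactor")
})

test_that("every intermediate lies on a logged shortest path", {
  gt <- random_graph_tbl(35, 0.1, seed = 12)
  store <- store_from_tbl(gt)
  set.seed(12)
  cand <- sample(gt$nodes, 5)
  sn <- build_subnetwork(store, cand)
  inter <- sn$nodes$key[sn$nodes$role == "intermediate"]
  on_paths <- unique(unlist(sn$path_log$path))
  expect_true(all(inter %in% on_paths))
  # and every subnetwork edge exists in the source interactome
  expect_true(all(edge_key(sn$edges$from, sn$edges$to) %in%
                  edge_key(store$edges$from, store$edges$to)))
})
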