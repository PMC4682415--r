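#' Generate a synthetic interactome fixture with known ground truth
#'
#' Fabricates an edge list and three-namespace identifier table in exactly
#' the dialects [load_interactome()] reads, so every pipeline stage can be
#' exercised without downloading a real interactome.  Identifiers follow
#' recognizable per-namespace patterns (`SYM0001` / `9000001` / `Q900001`)
#' so namespace-confusion bugs surface immediately.  The returned manifest
#' records every planted fact (edge counts, injected duplicates and
#' self-loops, planted distances) for independent verification.
#'
#' Models:
#' * `erdos_renyi`: `params$p` edge probability.
#' * `preferential_attachment`: `params$m` edges added per new node.
#' * `path_union`: `params$pairs`, a list of `list(a =, b =, distance =)`
#'   gene indices and exact hop distances; each pair is joined by a fresh
#'   chain of intermediate genes so the planted distance is exact by
#'   construction (endpoints and intermediates are otherwise untouched).
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Number of genes (>= 2).
#' @param model Generative model.
#' @param params Model parameters (see above).
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @param n_duplicates,n_self_loops Raw rows injected to exercise the
#'   loader's de-duplication accounting.
#' @param type_codes Interaction-type codes cycled over edge rows (column 3).
#' @return A manifest list: `seed`, `model`, `params`, `n_genes`, `files`
#'   (paths `edges`, `genes`), `edge_count` (unique undirected edges),
#'   `injected`, `planted` (for `path_union`: tibble of pair keys and
#'   distances), `keys` (canonical keys = symbols, in index order).
#' @export
make_interactome_fixture <- function(dir, n_genes,
                                     model = c("erdos_renyi", "preferential_attachment", "path_union"),
                                     params = list(), seed = 1L,
                                     n_duplicates = 0L, n_self_loops = 0L,
                                     type_codes = "0417") {
  model <- match.arg(model)
  if (n_genes < 2L) stop_domain("Fixture needs at least 2 genes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  ids <- function(i) sprintf("SYM%04d", i)
  planted <- NULL
  total <- n_genes

  pairs_mat <- with_seed(seed, {
    if (model == "erdos_renyi") {
      p <- params$p %||% 0.1
      g <- igraph::sample_gnp(n_genes, p)
      igraph::as_edgelist(g)
    } else if (model == "preferential_attachment") {
      m <- params$m %||% 2L
      g <- igraph::sample_pa(n_genes, m = m, directed = FALSE)
      igraph::as_edgelist(g)
    } else {
      pairs <- params$pairs %||% list()
      if (length(pairs) == 0L) stop_domain("path_union model needs params$pairs")
      need <- sum(vapply(pairs, function(pr) max(0, pr$distance - 1), numeric(1)))
      el <- matrix(numeric(), ncol = 2)
      nxt <- n_genes + 1L
      for (pr in pairs) {
        if (pr$distance < 1L) stop_domain("Planted distance must be >= 1")
        if (pr$a > n_genes || pr$b > n_genes || pr$a == pr$b) {
          stop_domain("Planted pair endpoints must be distinct gene indices <= n_genes")
        }
        chain <- c(pr$a, if (pr$distance > 1L) seq.int(nxt, nxt + pr$distance - 2L), pr$b)
        nxt <- nxt + max(0L, pr$distance - 1L)
        el <- rbind(el, cbind(chain[-length(chain)], chain[-1L]))
      }
      total <- n_genes + need
      el
    }
  })
  if (model == "path_union") {
    planted <- tibble(
      a = ids(vapply(params$pairs, `[[`, numeric(1), "a")),
      b = ids(vapply(params$pairs, `[[`, numeric(1), "b")),
      distance = vapply(params$pairs, `[[`, numeric(1), "distance"))
  }

  idx <- seq_len(total)
  genes <- tibble(symbol = ids(idx),
                  entrez = as.character(9000000L + idx),
                  uniprot = sprintf("Q9%05d", idx))

  a <- ids(pmin(pairs_mat[, 1], pairs_mat[, 2]))
  b <- ids(pmax(pairs_mat[, 1], pairs_mat[, 2]))
  keep <- !duplicated(paste(a, b)) & a != b
  a <- a[keep]; b <- b[keep]
  edge_count <- length(a)

  inj <- with_seed(seed + 1L, {
    dup_a <- character(); dup_b <- character()
    if (n_duplicates > 0L) {
      if (edge_count == 0L) stop_domain("Cannot inject duplicates into an edgeless fixture")
      i <- sample.int(edge_count, n_duplicates, replace = TRUE)
      flip <- sample(c(TRUE, FALSE), n_duplicates, replace = TRUE)
      dup_a <- ifelse(flip, b[i], a[i])
      dup_b <- ifelse(flip, a[i], b[i])
    }
    self <- if (n_self_loops > 0L) ids(sample.int(total, n_self_loops, replace = TRUE)) else character()
    list(dup_a = dup_a, dup_b = dup_b, self = self)
  })

  all_a <- c(a, inj$dup_a, inj$self)
  all_b <- c(b, inj$dup_b, inj$self)
  types <- rep_len(as.character(type_codes), length(all_a))

  edges_path <- file.path(dir, "edges.tsv")
  genes_path <- file.path(dir, "genes.tsv")
  readr::write_tsv(tibble(gene_a = all_a, gene_b = all_b, interaction_type = types),
                   edges_path, progress = FALSE)
  readr::write_tsv(genes, genes_path, progress = FALSE)

  list(seed = as.integer(seed), model = model, params = params,
       n_genes = as.integer(total),
       files = list(edges = edges_path, genes = genes_path),
       edge_count = edge_count,
       injected = list(duplicates = as.integer(n_duplicates),
                       self_loops = as.integer(n_self_loops)),
       planted = planted,
       keys = ids(idx))
}

#' Generate a GMT catalog fixture with planted overlaps
#'
#' Plants annotation terms with exact, specified overlaps against a named
#' gene set, enabling closed-form enrichment checks: term `i` contains
#' `overlap[i]` genes drawn from `network_set` and `size[i] - overlap[i]`
#' genes drawn from the rest of the universe.
#'
#' @param path Output GMT path.
#' @param universe Character vector of canonical keys to draw from.
#' @param network_set Character vector (subset of `universe`) that overlaps
#'   are planted against.
#' @param sizes,overlaps Integer vectors (equal length): term sizes and
#'   planted overlaps with `network_set`.
#' @param seed Integer seed.
#' @param category Category recorded in the manifest.
#' @return Manifest list: `path`, `category`, `terms` (tibble `term`, `size`,
#'   `overlap`), `seed`.
#' @export
make_catalog_fixture <- function(path, universe, network_set, sizes, overlaps,
                                 seed = 1L, category = "pathway") {
  stopifnot(length(sizes) == length(overlaps), all(network_set %in% universe))
  outside <- setdiff(universe, network_set)
  if (any(overlaps > sizes) || any(overlaps > length(network_set)) ||
      any(sizes - overlaps > length(outside))) {
    stop_domain("Infeasible overlap specification for the given universe")
  }
  lines <- with_seed(seed, {
    vapply(seq_along(sizes), function(i) {
      inside <- if (overlaps[i] > 0L) sample(network_set, overlaps[i]) else character()
      rest <- if (sizes[i] - overlaps[i] > 0L) sample(outside, sizes[i] - overlaps[i]) else character()
      paste(c(sprintf("TERM%03d", i), sprintf("planted term %d", i), inside, rest),
            collapse = "\t")
    }, character(1))
  })
  readr::write_lines(lines, path)
  list(path = path, category = category, seed = as.integer(seed),
       terms = tibble(term = sprintf("TERM%03d", seq_along(sizes)),
                      size = as.integer(sizes), overlap = as.integer(overlaps)))
}

#' Generate candidate / target query-list files for a fixture
#'
#' Writes plain-text gene lists (one identifier per line) drawn from a
#' fixture's keys, optionally switching namespace per line to exercise the
#' resolver.
#'
#' @param path Output path.
#' @param keys Canonical keys (fixture symbols) to write.
#' @return Invisibly, `path`.
#' @export
write_query_list <- function(path, keys) {
  readr::write_lines(keys, path)
  invisible(path)
}
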