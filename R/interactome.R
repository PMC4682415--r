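#' Edge-list dialects
#'
#' An interactome edge list is a tab-separated file with one interaction per
#' row.  Different providers place the interactor identifier columns (and an
#' optional interaction-type column) in different positions; a dialect records
#' that column mapping.  Lines starting with `#` are always ignored.
#'
#' Presets:
#' * `"generic"`: header row; interactors in columns 1 and 2, interaction
#'   type (if any) in column 3.  This is the dialect the fixture generator
#'   emits.
#' * `"hprd-flat"`: no header; interactor gene symbols in columns 1 and 4
#'   (the layout of HPRD's binary-interaction flat files).
#' * `"biogrid-tab"`: header row; official symbols in columns 8 and 9,
#'   interaction type (PSI-MI code string) in column 12 (BioGRID tab2
#'   layout).
#'
#' @param col_a,col_b Column positions of the two interactor identifiers.
#' @param col_type Column position of the interaction-type code, or `NULL`
#'   when the dialect carries none.
#' @param header Does the file carry a header row (skipped on read)?
#' @return An `edge_dialect` object.
#' @export
edge_dialect <- function(col_a = 1L, col_b = 2L, col_type = NULL, header = TRUE) {
  stopifnot(col_a >= 1L, col_b >= 1L, col_a != col_b)
  structure(
    list(col_a = as.integer(col_a), col_b = as.integer(col_b),
         col_type = if (!is.null(col_type)) as.integer(col_type),
         header = isTRUE(header)),
    class = "edge_dialect"
  )
}

dialect_preset <- function(dialect) {
  if (inherits(dialect, "edge_dialect")) return(dialect)
  switch(match.arg(dialect, c("generic", "hprd-flat", "biogrid-tab")),
    "generic" = edge_dialect(1L, 2L, 3L, header = TRUE),
    "hprd-flat" = edge_dialect(1L, 4L, NULL, header = FALSE),
    "biogrid-tab" = edge_dialect(8L, 9L, 12L, header = TRUE)
  )
}

normalise_symbol <- function(x) toupper(trimws(x))

normalise_entrez <- function(x) {
  n <- suppressWarnings(as.numeric(trimws(x)))
  ifelse(!is.na(n) & n == round(n), format(n, scientific = FALSE, trim = TRUE), NA_character_)
}

# UniProt accessions compared case-insensitively with isoform suffix removed.
normalise_uniprot <- function(x) toupper(sub("-[0-9]+$", "", trimws(x)))

#' Read a three-namespace gene identifier table
#'
#' Tab-separated with header columns `symbol`, `entrez`, `uniprot`; an empty
#' cell means the record lacks that identifier.  A record must carry at least
#' one identifier.
#'
#' @param path Path to the TSV file.
#' @return A tibble with character columns `symbol`, `entrez`, `uniprot`.
#' @export
read_id_table <- function(path) {
  check_readable(path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("symbol", "entrez", "uniprot")
  if (!all(need %in% names(tab))) {
    stop_parse(sprintf("ID table %s lacks required header columns symbol/entrez/uniprot", path))
  }
  tab <- tab[need]
  tab[] <- lapply(tab, function(col) {
    col <- trimws(col)
    col[!nzchar(col) | is.na(col)] <- NA_character_
    col
  })
  as_tibble(tab)
}

# Build the gene store: canonical keys, per-namespace lookups, ambiguity
# rejection.  Canonical key = symbol if present, else ENTREZ:<id>, else the
# normalised UniProt accession.
build_gene_store <- function(id_table) {
  sym <- ifelse(is.na(id_table$symbol), NA, normalise_symbol(id_table$symbol))
  ent <- if (is.null(id_table$entrez)) rep(NA_character_, nrow(id_table)) else normalise_entrez(id_table$entrez)
  uni <- ifelse(is.na(id_table$uniprot), NA, normalise_uniprot(id_table$uniprot))
  key <- ifelse(!is.na(sym), sym, ifelse(!is.na(ent), paste0("ENTREZ:", ent), uni))

  keep <- !is.na(key)
  n_no_id <- sum(!keep)
  genes <- tibble(key = key[keep], symbol = sym[keep], entrez = ent[keep], uniprot = uni[keep])

  # Reject (drop + report) any later record whose canonical key or any
  # namespace value collides with an earlier record's.
  seen_key <- new.env(parent = emptyenv())
  seen <- list(symbol = new.env(parent = emptyenv()),
               entrez = new.env(parent = emptyenv()),
               uniprot = new.env(parent = emptyenv()))
  ok <- logical(nrow(genes))
  n_ambiguous <- 0L
  for (i in seq_len(nrow(genes))) {
    k <- genes$key[i]
    vals <- list(symbol = genes$symbol[i], entrez = genes$entrez[i], uniprot = genes$uniprot[i])
    clash <- !is.null(seen_key[[k]])
    for (ns in names(vals)) {
      v <- vals[[ns]]
      if (!is.na(v) && !is.null(seen[[ns]][[v]]) && !identical(seen[[ns]][[v]], k)) clash <- TRUE
    }
    if (clash) {
      n_ambiguous <- n_ambiguous + 1L
      next
    }
    ok[i] <- TRUE
    seen_key[[k]] <- TRUE
    for (ns in names(vals)) {
      v <- vals[[ns]]
      if (!is.na(v)) seen[[ns]][[v]] <- k
    }
  }
  genes <- genes[ok, ]

  lookup <- function(values) {
    idx <- !is.na(values)
    stats::setNames(genes$key[idx], values[idx])
  }
  list(
    genes = genes,
    lookups = list(symbol = lookup(genes$symbol),
                   entrez = lookup(genes$entrez),
                   uniprot = lookup(genes$uniprot)),
    dropped = c(no_identifier = n_no_id, ambiguous = n_ambiguous)
  )
}

resolve_token <- function(token, lookups, precedence) {
  token <- trimws(token)
  if (!nzchar(token)) return(NA_character_)
  for (ns in precedence) {
    v <- switch(ns,
      symbol = normalise_symbol(token),
      entrez = normalise_entrez(token),
      uniprot = normalise_uniprot(token))
    if (is.na(v)) next
    hit <- lookups[[ns]][v]
    if (!is.na(hit)) return(unname(hit))
  }
  NA_character_
}

#' Load an interactome from an edge list and identifier table
#'
#' Reads a tab-separated edge list (see [edge_dialect()] for supported
#' layouts) and a gene identifier table, canonicalizes identifiers, and
#' returns an undirected simple graph over canonical gene keys.  Self-loops
#' are dropped, duplicate (including reversed) edges are collapsed, rows
#' whose identifiers do not resolve against the table are dropped, and — when
#' `interaction_type_filter` is given and the dialect carries a type column —
#' rows whose type cell does not contain one of the requested codes are
#' dropped.  Genes present in the identifier table but with no surviving edge
#' remain in the store as isolated nodes.
#'
#' Every drop is counted in a load report retrievable with [load_report()].
#'
#' @param edge_list_path Path to the edge list TSV.
#' @param id_table_path Path to the identifier table TSV (see
#'   [read_id_table()]).
#' @param interaction_type_filter Optional character vector of interaction
#'   type codes (e.g. `"0417"` for binary biophysical interactions); a row is
#'   kept when its type cell contains any of the codes as a substring.
#' @param dialect Dialect preset name or an [edge_dialect()] object.
#' @param precedence Namespace order used to resolve edge tokens.
#' @return An `interactome` object.
#' @examples
#' fx <- make_interactome_fixture(tempfile(), n_genes = 12,
#'                                model = "erdos_renyi",
#'                                params = list(p = 0.3), seed = 1)
#' net <- load_interactome(fx$files$edges, fx$files$genes)
#' net
#' @export
load_interactome <- function(edge_list_path, id_table_path,
                             interaction_type_filter = NULL,
                             dialect = "generic",
                             precedence = c("symbol", "entrez", "uniprot")) {
  dialect <- dialect_preset(dialect)
  id_table <- read_id_table(id_table_path)
  store <- build_gene_store(id_table)
  check_readable(edge_list_path)

  lines <- readr::read_lines(edge_list_path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (dialect$header) {
    if (length(lines) == 0L) stop_parse("Edge list is empty where a header row was declared")
    lines <- lines[-1L]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need_cols <- max(dialect$col_a, dialect$col_b, dialect$col_type %||% 0L)
  bad_shape <- vapply(fields, length, integer(1)) < need_cols
  if (length(fields) > 0L && all(bad_shape)) {
    stop_parse(sprintf("No edge-list row carries the %d columns the dialect requires; malformed header or wrong dialect?", need_cols))
  }
  n_malformed <- sum(bad_shape)
  fields <- fields[!bad_shape]

  rows_read <- length(fields) + n_malformed
  tok_a <- vapply(fields, `[[`, character(1), dialect$col_a)
  tok_b <- vapply(fields, `[[`, character(1), dialect$col_b)

  n_type_dropped <- 0L
  if (!is.null(interaction_type_filter) && !is.null(dialect$col_type)) {
    type_cell <- vapply(fields, `[[`, character(1), dialect$col_type)
    keep <- Reduce(`|`, lapply(as.character(interaction_type_filter),
                               function(code) grepl(code, type_cell, fixed = TRUE)),
                   logical(length(type_cell)))
    n_type_dropped <- sum(!keep)
    tok_a <- tok_a[keep]
    tok_b <- tok_b[keep]
  }

  key_a <- vapply(tok_a, resolve_token, character(1), store$lookups, precedence, USE.NAMES = FALSE)
  key_b <- vapply(tok_b, resolve_token, character(1), store$lookups, precedence, USE.NAMES = FALSE)
  resolved <- !is.na(key_a) & !is.na(key_b)
  n_unresolved <- sum(!resolved)
  key_a <- key_a[resolved]
  key_b <- key_b[resolved]

  self <- key_a == key_b
  n_self <- sum(self)
  key_a <- key_a[!self]
  key_b <- key_b[!self]

  lo <- pmin(key_a, key_b)
  hi <- pmax(key_a, key_b)
  pair <- paste(lo, hi, sep = "\r")
  dup <- duplicated(pair)
  n_dup <- sum(dup)
  edges <- tibble(from = lo[!dup], to = hi[!dup])

  if (nrow(edges) == 0L && rows_read > 0L && n_type_dropped < rows_read) {
    # all rows failed to resolve (or were self loops): surface loudly
    if (n_unresolved == rows_read - n_malformed - n_type_dropped && n_unresolved > 0L) {
      stop_parse("No edge-list row resolved against the identifier table")
    }
  }

  report <- tibble(
    stage = c("rows_read", "malformed", "type_filtered", "unresolved",
              "self_loops_dropped", "duplicates_collapsed", "edges_kept"),
    count = c(rows_read, n_malformed, n_type_dropped, n_unresolved,
              n_self, n_dup, nrow(edges))
  )
  new_interactome(store, edges, report)
}

new_interactome <- function(store, edges, report = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = store$genes$key))
  obj <- structure(
    list(genes = store$genes, lookups = store$lookups, graph = g, edges = edges),
    class = "interactome"
  )
  attr(obj, "load_report") <- report %||%
    tibble(stage = "edges_kept", count = nrow(edges))
  obj
}

#' Construct an interactome directly from data frames
#'
#' Programmatic constructor used by tests and simulations: no file round
#' trip.  Identifier semantics match [load_interactome()] (self-loops
#' dropped, duplicate edges collapsed, unresolvable endpoints rejected).
#'
#' @param genes Data frame with any of the columns `symbol`, `entrez`,
#'   `uniprot` (missing columns are treated as all-absent).
#' @param edges Data frame (or two-column matrix) of identifier token pairs;
#'   may be empty.
#' @param precedence Namespace order used to resolve edge tokens.
#' @return An `interactome` object.
#' @export
interactome_from_tables <- function(genes, edges = NULL,
                                    precedence = c("symbol", "entrez", "uniprot")) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  for (col in c("symbol", "entrez", "uniprot")) {
    if (is.null(genes[[col]])) genes[[col]] <- NA_character_
    genes[[col]] <- as.character(genes[[col]])
  }
  store <- build_gene_store(genes)
  if (is.null(edges) || NROW(edges) == 0L) {
    return(new_interactome(store, tibble(from = character(), to = character())))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  key_a <- vapply(as.character(edges[[1]]), resolve_token, character(1),
                  store$lookups, precedence, USE.NAMES = FALSE)
  key_b <- vapply(as.character(edges[[2]]), resolve_token, character(1),
                  store$lookups, precedence, USE.NAMES = FALSE)
  ok <- !is.na(key_a) & !is.na(key_b) & key_a != key_b
  lo <- pmin(key_a[ok], key_b[ok])
  hi <- pmax(key_a[ok], key_b[ok])
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  new_interactome(store, tibble(from = lo[!dup], to = hi[!dup]))
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d genes, %d interactions\n",
              nrow(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Gene universe of an interactome store
#'
#' @param store An `interactome`.
#' @return Character vector of canonical gene keys (including isolated genes).
#' @export
gene_universe <- function(store) {
  stopifnot(inherits(store, "interactome"))
  store$genes$key
}

#' Resolve free-form gene identifiers against a store
#'
#' Each token is trimmed and matched case-insensitively against the store's
#' namespaces in `precedence` order (default: symbol, then Entrez, then
#' UniProt; Entrez values are compared numerically, UniProt accessions
#' case-insensitively with isoform suffixes ignored).  Duplicate hits are
#' collapsed preserving first occurrence.
#'
#' @param tokens Character vector of identifiers (any namespace).
#' @param store An `interactome`.
#' @param precedence Namespace trial order.
#' @return A list with `resolved` (canonical keys, first-occurrence order)
#'   and `rejected` (tibble of `token`, `reason`; reason is `"unknown"` or
#'   `"ambiguous"`).  If every token is rejected an error of class
#'   `seednet_resolution_error` is thrown (distinct from partial rejection,
#'   which is reported in `rejected`).
#' @export
resolve_genes <- function(tokens, store,
                          precedence = c("symbol", "entrez", "uniprot")) {
  stopifnot(inherits(store, "interactome"))
  tokens <- trimws(as.character(tokens))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop_resolution("Empty query: no identifiers supplied")
  }
  keys <- vapply(tokens, resolve_token, character(1), store$lookups, precedence,
                 USE.NAMES = FALSE)
  rejected <- tibble(token = tokens[is.na(keys)],
                     reason = rep("unknown", sum(is.na(keys))))
  resolved <- keys[!is.na(keys)]
  resolved <- resolved[!duplicated(resolved)]
  if (length(resolved) == 0L) {
    stop_resolution("Empty query: every identifier was rejected",
                    rejected = rejected)
  }
  list(resolved = resolved, rejected = rejected)
}

#' Load a GMT annotation catalog against a store
#'
#' GMT format: one term per line, `term TAB description TAB gene TAB gene
#' ...`.  Gene tokens are resolved as in [resolve_genes()]; tokens not in the
#' store are dropped (counted in the load report) and terms left empty by
#' dropping are removed.
#'
#' @param path Path to the GMT file.
#' @param category One of `"pathway"`, `"disease"`, `"drug"`, `"gwas"`.
#' @param store The `interactome` the catalog annotates.
#' @param provenance Free-text source label stored with the catalog.
#' @return An `annotation_catalog`: list with `category`, `terms` (named list
#'   of canonical-key vectors), `provenance`.  Load accounting via
#'   [load_report()].
#' @export
load_catalog <- function(path, category = c("pathway", "disease", "drug", "gwas"),
                         store, provenance = basename(path)) {
  category <- match.arg(category)
  check_readable(path)
  stopifnot(inherits(store, "interactome"))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  terms <- list()
  n_tok <- 0L
  n_dropped <- 0L
  n_empty <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      n_empty <- n_empty + 1L
      next
    }
    term <- parts[[1]]
    toks <- parts[-(1:2)]
    toks <- toks[nzchar(trimws(toks))]
    n_tok <- n_tok + length(toks)
    keys <- vapply(toks, resolve_token, character(1), store$lookups,
                   c("symbol", "entrez", "uniprot"), USE.NAMES = FALSE)
    n_dropped <- n_dropped + sum(is.na(keys))
    keys <- unique(keys[!is.na(keys)])
    if (length(keys) == 0L) {
      n_empty <- n_empty + 1L
      next
    }
    terms[[term]] <- keys
  }
  if (length(terms) == 0L) {
    stop_parse(sprintf("Catalog %s has zero surviving terms", path))
  }
  obj <- annotation_catalog(terms, category, provenance)
  attr(obj, "load_report") <- tibble(
    stage = c("terms_read", "gene_tokens_read", "gene_tokens_dropped", "terms_removed"),
    count = c(length(lines), n_tok, n_dropped, n_empty)
  )
  obj
}

#' Construct an annotation catalog from a named list
#'
#' @param terms Named list: term name -> character vector of canonical keys
#'   (each term must have at least one gene; names must be unique).
#' @param category Catalog category label.
#' @param provenance Free-text source label.
#' @return An `annotation_catalog`.
#' @export
annotation_catalog <- function(terms, category = c("pathway", "disease", "drug", "gwas"),
                               provenance = "constructed") {
  category <- match.arg(category)
  stopifnot(is.list(terms), length(terms) > 0L,
            !is.null(names(terms)), !anyDuplicated(names(terms)),
            all(lengths(terms) >= 1L))
  structure(list(category = category,
                 terms = lapply(terms, function(g) unique(as.character(g))),
                 provenance = provenance),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("<annotation_catalog> category=%s, %d terms (source: %s)\n",
              x$category, length(x$terms), x$provenance))
  invisible(x)
}

#' Write an interactome back out as an edge list and identifier table
#'
#' Canonical keys are written in the `"generic"` dialect so that reloading
#' with [load_interactome()] round-trips the node and edge sets exactly.
#'
#' @param store An `interactome`.
#' @param edge_list_path,id_table_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_edge_list <- function(store, edge_list_path, id_table_path) {
  stopifnot(inherits(store, "interactome"))
  edges <- arrange(store$edges, .data$from, .data$to)
  readr::write_tsv(tibble(gene_a = edges$from, gene_b = edges$to,
                          interaction_type = "0417"),
                   edge_list_path, progress = FALSE)
  genes <- store$genes
  readr::write_tsv(tibble(symbol = ifelse(is.na(genes$symbol), "", genes$symbol),
                          entrez = ifelse(is.na(genes$entrez), "", genes$entrez),
                          uniprot = ifelse(is.na(genes$uniprot), "", genes$uniprot)),
                   id_table_path, progress = FALSE)
  invisible(c(edge_list_path, id_table_path))
}

#' @importFrom rlang .data
#' @exportS3Method generics::tidy
tidy.interactome <- function(x, ...) {
  deg <- igraph::degree(x$graph)
  mutate(x$genes, degree = as.integer(deg[.data$key]))
}

#' @exportS3Method generics::glance
glance.interactome <- function(x, ...) {
  tibble(n_genes = nrow(x$genes),
         n_edges = nrow(x$edges),
         n_isolated = sum(igraph::degree(x$graph) == 0L))
}
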