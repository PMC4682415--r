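#' Export a subnetwork in SIF (Cytoscape simple interaction format)
#'
#' One line per edge, `geneA TAB pp TAB geneB`, lexicographically ordered.
#' Isolated nodes are emitted as single-token lines so the node set survives
#' a round trip.  `scope = "shortest_paths_only"` restricts the edge set to
#' edges lying on logged shortest paths (isolated-node emission then applies
#' to nodes untouched by those edges).
#'
#' @param network A `subnetwork`.
#' @param path Output file path.
#' @param scope `"entire"` or `"shortest_paths_only"`.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(network, path, scope = c("entire", "shortest_paths_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(network, "subnetwork"))
  if (nrow(network$nodes) == 0L) stop_domain("Refusing to export an empty subnetwork")
  edges <- network$edges
  if (scope == "shortest_paths_only") edges <- edges[edges$on_path, , drop = FALSE]
  edges <- arrange(edges, .data$from, .data$to)
  covered <- unique(c(edges$from, edges$to))
  isolated <- sort(setdiff(network$nodes$key, covered))
  out <- c(sprintf("%s\tpp\t%s", edges$from, edges$to), isolated)
  tryCatch(readr::write_lines(out, path),
           error = function(e) stop_io(sprintf("Cannot write SIF file %s: %s", path, conditionMessage(e))))
  invisible(path)
}

#' Read a SIF file back as an edge/node table
#'
#' @param path SIF file path.
#' @return List with `edges` (tibble `from`, `to`) and `nodes` (all keys seen,
#'   including isolated single-token lines).
#' @export
read_sif <- function(path) {
  check_readable(path)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- vapply(parts, length, integer(1)) >= 3L
  edges <- tibble(from = vapply(parts[is_edge], `[[`, character(1), 1L),
                  to = vapply(parts[is_edge], `[[`, character(1), 3L))
  nodes <- unique(c(edges$from, edges$to,
                    vapply(parts[!is_edge], `[[`, character(1), 1L)))
  list(edges = edges, nodes = sort(nodes))
}

#' Export the genes of a subnetwork as a plain-text list
#'
#' One identifier per line, deduplicated and sorted.  A gene lacking the
#' requested namespace falls back to its canonical key; the number of such
#' fallbacks is returned (and a warning raised) so run logs can record it.
#'
#' @param network A `subnetwork`.
#' @param store The `interactome` providing identifier records.
#' @param path Output file path.
#' @param namespace `"symbol"`, `"entrez"` or `"uniprot"`.
#' @return Invisibly, a list with `path` and `n_fallback`.
#' @export
write_gene_list <- function(network, store, path,
                            namespace = c("symbol", "entrez", "uniprot")) {
  namespace <- match.arg(namespace)
  stopifnot(inherits(network, "subnetwork"), inherits(store, "interactome"))
  genes <- store$genes
  idx <- match(network$nodes$key, genes$key)
  ids <- genes[[namespace]][idx]
  n_fallback <- sum(is.na(ids))
  if (n_fallback > 0L) {
    warning(sprintf("%d gene(s) lack a %s identifier; canonical keys emitted instead",
                    n_fallback, namespace), call. = FALSE)
    ids[is.na(ids)] <- network$nodes$key[is.na(ids)]
  }
  out <- sort(unique(ids))
  tryCatch(readr::write_lines(out, path),
           error = function(e) stop_io(sprintf("Cannot write gene list %s: %s", path, conditionMessage(e))))
  invisible(list(path = path, n_fallback = n_fallback))
}

RESULTS_SCHEMA_VERSION <- "1.0"

#' Assemble a self-contained results document
#'
#' Bundles the query echo, subnetwork, connectivity report with its baseline
#' table, and per-category enrichment results into one document that can be
#' written to JSON with [write_results()] and reloaded without recomputation.
#' The creation timestamp lives only in `metadata` so content fields stay
#' deterministic.
#'
#' @param query List echoing the input: `candidates`, `targets` (or NULL),
#'   `rejected` tibble.
#' @param subnetwork A `subnetwork`.
#' @param connectivity Output of [connectivity_table()].
#' @param enrichment An `enrichment_result` (possibly empty).
#' @param title,notes Free text.
#' @param seed Seed used for the baselines.
#' @param log Optional named list of per-stage counts.
#' @param timestamp Creation time string; pass `""` for fully deterministic
#'   output.
#' @return A `results_document`.
#' @export
results_document <- function(query, subnetwork, connectivity, enrichment,
                             title = "", notes = "", seed = NA_integer_,
                             log = list(), timestamp = "") {
  structure(list(
    schema_version = RESULTS_SCHEMA_VERSION,
    metadata = list(tool = "seednet",
                    version = as.character(utils::packageVersion("seednet")),
                    seed = as.integer(seed),
                    timestamp = timestamp),
    title = title,
    notes = notes,
    query = query,
    subnetwork = subnetwork,
    connectivity = connectivity,
    enrichment = enrichment,
    log = log
  ), class = "results_document")
}

doc_to_json_list <- function(doc) {
  sn <- doc$subnetwork
  enr <- as_tibble(doc$enrichment)
  list(
    schema_version = doc$schema_version,
    metadata = doc$metadata,
    title = doc$title,
    notes = doc$notes,
    query = list(
      candidates = as.list(doc$query$candidates),
      targets = if (is.null(doc$query$targets)) NULL else as.list(doc$query$targets),
      rejected = lapply(seq_len(nrow(doc$query$rejected)), function(i)
        list(token = doc$query$rejected$token[i], reason = doc$query$rejected$reason[i]))
    ),
    subnetwork = list(
      mode = sn$mode,
      candidates = as.list(sn$candidates),
      targets = if (is.null(sn$targets)) NULL else as.list(sn$targets),
      nodes = lapply(seq_len(nrow(sn$nodes)), function(i)
        list(key = sn$nodes$key[i], role = sn$nodes$role[i])),
      edges = lapply(seq_len(nrow(sn$edges)), function(i)
        list(from = sn$edges$from[i], to = sn$edges$to[i], on_path = sn$edges$on_path[i])),
      path_log = lapply(seq_len(nrow(sn$path_log)), function(i)
        list(source = sn$path_log$source[i], dest = sn$path_log$dest[i],
             length = sn$path_log$length[i], path = as.list(sn$path_log$path[[i]])))
    ),
    connectivity = list(
      sentinel = attr(doc$connectivity, "sentinel") %||% 17,
      replicates = attr(doc$connectivity, "replicates") %||% NA_integer_,
      seed = attr(doc$connectivity, "seed") %||% NA_integer_,
      rows = lapply(seq_len(nrow(doc$connectivity)), function(i)
        list(scheme = doc$connectivity$scheme[i],
             min_spl = doc$connectivity$min_spl[i],
             avg_spl = doc$connectivity$avg_spl[i],
             disconnected_candidates = doc$connectivity$disconnected_candidates[i],
             pair_count = doc$connectivity$pair_count[i]))
    ),
    enrichment = lapply(seq_len(nrow(enr)), function(i)
      list(term = enr$term[i], category = enr$category[i],
           p_value = enr$p_value[i], overlap = enr$overlap[i],
           network_only = enr$network_only[i], term_only = enr$term_only[i],
           neither = enr$neither[i], universe_size = enr$universe_size[i],
           overlap_genes = as.list(enr$overlap_genes[[i]]))),
    log = doc$log
  )
}

#' Write / read a results document as JSON
#'
#' The on-disk layout is a versioned schema with stable field ordering, so a
#' write–read–write cycle is byte-identical.  `read_results()` validates the
#' document and raises a `seednet_schema_error` on violations.
#'
#' @param doc A `results_document`.
#' @param path JSON file path.
#' @return `write_results()`: invisibly, `path`.  `read_results()`: a
#'   `results_document`.
#' @export
write_results <- function(doc, path) {
  stopifnot(inherits(doc, "results_document"))
  tryCatch(
    jsonlite::write_json(doc_to_json_list(doc), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE),
    error = function(e) stop_io(sprintf("Cannot write results %s: %s", path, conditionMessage(e))))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  check_readable(path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_schema(sprintf("Not valid JSON: %s", conditionMessage(e))))
  need <- c("schema_version", "metadata", "title", "notes", "query",
            "subnetwork", "connectivity", "enrichment", "log")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop_schema(sprintf("Results document lacks field(s): %s", paste(missing, collapse = ", ")))
  }
  if (!identical(raw$schema_version, RESULTS_SCHEMA_VERSION)) {
    stop_schema(sprintf("Unsupported results schema version: %s", raw$schema_version %||% "<none>"))
  }
  sn_raw <- raw$subnetwork
  for (f in c("mode", "candidates", "nodes", "edges", "path_log")) {
    if (is.null(sn_raw[[f]])) stop_schema(sprintf("Subnetwork field missing: %s", f))
  }
  chr <- function(x) vapply(x, function(el) as.character(el), character(1))
  sn <- structure(list(
    nodes = tibble(key = vapply(sn_raw$nodes, function(n) n$key, character(1)),
                   role = vapply(sn_raw$nodes, function(n) n$role, character(1))),
    edges = tibble(from = vapply(sn_raw$edges, function(e) e$from, character(1)),
                   to = vapply(sn_raw$edges, function(e) e$to, character(1)),
                   on_path = vapply(sn_raw$edges, function(e) isTRUE(e$on_path), logical(1))),
    path_log = tibble(
      source = vapply(sn_raw$path_log, function(p) p$source, character(1)),
      dest = vapply(sn_raw$path_log, function(p) p$dest, character(1)),
      length = vapply(sn_raw$path_log, function(p) as.integer(p$length), integer(1)),
      path = lapply(sn_raw$path_log, function(p) chr(p$path))),
    candidates = chr(sn_raw$candidates),
    targets = if (is.null(sn_raw$targets)) NULL else chr(sn_raw$targets),
    mode = sn_raw$mode
  ), class = "subnetwork")

  conn_rows <- raw$connectivity$rows
  conn <- tibble(
    scheme = vapply(conn_rows, function(r) r$scheme, character(1)),
    min_spl = vapply(conn_rows, function(r) as.numeric(r$min_spl), numeric(1)),
    avg_spl = vapply(conn_rows, function(r) as.numeric(r$avg_spl), numeric(1)),
    disconnected_candidates = vapply(conn_rows, function(r) as.numeric(r$disconnected_candidates), numeric(1)),
    pair_count = vapply(conn_rows, function(r) as.numeric(r$pair_count), numeric(1)))
  attr(conn, "sentinel") <- as.numeric(raw$connectivity$sentinel)
  attr(conn, "replicates") <- if (is.null(raw$connectivity$replicates)) NA_integer_ else as.integer(raw$connectivity$replicates)
  attr(conn, "seed") <- if (is.null(raw$connectivity$seed)) NA_integer_ else as.integer(raw$connectivity$seed)
  class(conn) <- c("baseline_table", class(conn))

  enr <- if (length(raw$enrichment) == 0L) {
    tibble(term = character(), category = character(), p_value = numeric(),
           overlap = integer(), network_only = integer(), term_only = integer(),
           neither = integer(), universe_size = integer(), overlap_genes = list())
  } else {
    tibble(
      term = vapply(raw$enrichment, function(r) r$term, character(1)),
      category = vapply(raw$enrichment, function(r) r$category, character(1)),
      p_value = vapply(raw$enrichment, function(r) as.numeric(r$p_value), numeric(1)),
      overlap = vapply(raw$enrichment, function(r) as.integer(r$overlap), integer(1)),
      network_only = vapply(raw$enrichment, function(r) as.integer(r$network_only), integer(1)),
      term_only = vapply(raw$enrichment, function(r) as.integer(r$term_only), integer(1)),
      neither = vapply(raw$enrichment, function(r) as.integer(r$neither), integer(1)),
      universe_size = vapply(raw$enrichment, function(r) as.integer(r$universe_size), integer(1)),
      overlap_genes = lapply(raw$enrichment, function(r) chr(r$overlap_genes)))
  }
  class(enr) <- c("enrichment_result", class(enr))

  results_document(
    query = list(candidates = chr(raw$query$candidates),
                 targets = if (is.null(raw$query$targets)) NULL else chr(raw$query$targets),
                 rejected = tibble(
                   token = vapply(raw$query$rejected, function(r) r$token, character(1)),
                   reason = vapply(raw$query$rejected, function(r) r$reason, character(1)))),
    subnetwork = sn,
    connectivity = conn,
    enrichment = enr,
    title = raw$title,
    notes = raw$notes,
    seed = raw$metadata$seed %||% NA_integer_,
    log = raw$log,
    timestamp = raw$metadata$timestamp %||% ""
  )
}

#' @export
print.results_document <- function(x, ...) {
  cat(sprintf("<results_document> '%s' (schema %s, seed %s)\n",
              x$title, x$schema_version, format(x$metadata$seed)))
  print(x$subnetwork)
  invisible(x)
}
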