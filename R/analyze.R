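#' Run the full analysis pipeline on files
#'
#' The single-call front end the command-line script wraps: load the
#' interactome and catalogs, resolve the query lists, build the subnetwork,
#' compute connectivity statistics with random baselines, run enrichment, and
#' write every export (JSON results document, entire and shortest-paths-only
#' SIF, gene lists in all three namespaces) into `out_dir`.  Two-set mode is
#' triggered solely by supplying `targets`.
#'
#' Partial identifier rejection is tolerated and echoed in the document's
#' query section and run log; if every candidate (or every target) is
#' rejected, a `seednet_resolution_error` is raised.
#'
#' @param interactome,id_table Paths to the edge list and identifier table.
#' @param candidates Path to a plain-text candidate gene list (one identifier
#'   per line, any namespace).
#' @param targets Optional path to a target gene list.
#' @param catalogs Named character vector of GMT paths; names are categories
#'   (`pathway`, `disease`, `drug`, `gwas`).
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param sentinel Sentinel hop count for disconnected pairs.
#' @param replicates Random-baseline replicates per scheme.
#' @param seed Integer RNG seed for the baselines.
#' @param dialect Edge-list dialect (see [edge_dialect()]).
#' @param interaction_type_filter Optional interaction-type code filter.
#' @param title Title recorded in the results document.
#' @param timestamp Metadata timestamp; defaults to empty (deterministic
#'   output).
#' @return The `results_document`, invisibly when `out_dir` is given.
#' @export
analyze <- function(interactome, id_table, candidates, targets = NULL,
                    catalogs = character(), out_dir = NULL,
                    sentinel = 17, replicates = 5L, seed = 1L,
                    dialect = "generic", interaction_type_filter = NULL,
                    title = "", timestamp = "") {
  store <- load_interactome(interactome, id_table,
                            interaction_type_filter = interaction_type_filter,
                            dialect = dialect)
  read_list <- function(path) {
    check_readable(path)
    toks <- readr::read_lines(path, progress = FALSE)
    toks[nzchar(trimws(toks))]
  }
  cand_res <- resolve_genes(read_list(candidates), store)
  targ_res <- if (!is.null(targets)) resolve_genes(read_list(targets), store)

  cats <- purrr::imap(as.list(catalogs), function(path, category) {
    load_catalog(path, category = category, store = store)
  })

  sn <- build_subnetwork(store, cand_res$resolved, targ_res$resolved %||% NULL)
  conn <- connectivity_table(store, cand_res$resolved, targ_res$resolved %||% NULL,
                             replicates = replicates, seed = seed, sentinel = sentinel)
  enr <- if (length(cats)) enrich(sn, unname(cats), store) else {
    structure(tibble(term = character(), category = character(), p_value = numeric(),
                     overlap = integer(), network_only = integer(), term_only = integer(),
                     neither = integer(), universe_size = integer(), overlap_genes = list()),
              class = c("enrichment_result", class(tibble())))
  }

  rejected <- bind_rows(
    cand_res$rejected,
    if (!is.null(targ_res)) targ_res$rejected else NULL
  )
  log <- c(
    stats::setNames(as.list(load_report(store)$count), load_report(store)$stage),
    list(candidates_resolved = length(cand_res$resolved),
         targets_resolved = length(targ_res$resolved %||% character()),
         tokens_rejected = nrow(rejected),
         subnetwork_nodes = nrow(sn$nodes),
         subnetwork_edges = nrow(sn$edges),
         paths_logged = nrow(sn$path_log),
         enriched_terms = nrow(enr))
  )

  doc <- results_document(
    query = list(candidates = cand_res$resolved,
                 targets = targ_res$resolved %||% NULL,
                 rejected = rejected),
    subnetwork = sn, connectivity = conn, enrichment = enr,
    title = title, seed = seed, log = log, timestamp = timestamp
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(doc, file.path(out_dir, "results.json"))
    write_sif(sn, file.path(out_dir, "network_entire.sif"), scope = "entire")
    write_sif(sn, file.path(out_dir, "network_paths.sif"), scope = "shortest_paths_only")
    for (ns in c("symbol", "entrez", "uniprot")) {
      suppressWarnings(
        write_gene_list(sn, store, file.path(out_dir, sprintf("genes_%s.txt", ns)),
                        namespace = ns))
    }
    return(invisible(doc))
  }
  doc
}

#' @exportS3Method generics::tidy
tidy.results_document <- function(x, ...) x$connectivity

#' @exportS3Method generics::glance
glance.results_document <- function(x, ...) {
  tibble(mode = x$subnetwork$mode,
         n_nodes = nrow(x$subnetwork$nodes),
         n_edges = nrow(x$subnetwork$edges),
         n_rejected = nrow(x$query$rejected),
         n_enriched_terms = nrow(as_tibble(x$enrichment)),
         min_spl = x$connectivity$min_spl[1],
         avg_spl = x$connectivity$avg_spl[1])
}
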