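#' Build the analysis subnetwork seeded by one or two gene sets
#'
#' With candidates only, every candidate gene recruits all of its immediate
#' interacting partners, and, for each candidate, all shortest paths (in the
#' full interactome) to its nearest other candidate gene(s) are added: when
#' several candidates are co-minimal, or several equally short paths exist,
#' all of them are included.  With a target set, candidate-to-candidate paths
#' are not sought; instead each candidate is connected by all shortest paths
#' to its closest target gene(s).  Immediate interactors of target genes are
#' not recruited, and targets that end up unconnected are still shown as
#' isolated nodes.
#'
#' Node roles follow the precedence both > candidate > target > intermediate
#' > interactor.  By default the edge set consists of candidate–interactor
#' edges plus the edges lying on recruited shortest paths; `edges =
#' "induced"` instead includes every interactome edge among recruited nodes.
#'
#' Shortest paths are always measured on the full interactome, not on the
#' growing subnetwork.  A gene present in both sets is treated as a candidate
#' for recruitment and never matched to itself (no zero-length paths).  A
#' candidate with no route to any counterpart recruits only its direct
#' interactors and persists as a (possibly isolated) node.
#'
#' @param store An `interactome`.
#' @param candidates Character vector of canonical candidate keys (must exist
#'   in the store; resolve free-form identifiers first with
#'   [resolve_genes()]).
#' @param targets Optional character vector of canonical target keys; its
#'   presence switches the builder to candidate-to-target mode.
#' @param edges `"paths"` (default) or `"induced"`; see Details.
#' @return A `subnetwork`: list with `nodes` (tibble `key`, `role`), `edges`
#'   (tibble `from`, `to`, `on_path`), `path_log` (tibble `source`, `dest`,
#'   `length`, `path` list-column of ordered key sequences), `candidates`,
#'   `targets`, `mode`.
#' @examples
#' net <- interactome_from_tables(
#'   genes = data.frame(symbol = c("A", "B", "C", "D", "E")),
#'   edges = data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "D", "E"))
#' )
#' sn <- build_subnetwork(net, candidates = c("A", "E"))
#' sn$nodes
#' @export
build_subnetwork <- function(store, candidates, targets = NULL,
                             edges = c("paths", "induced")) {
  edges <- match.arg(edges)
  stopifnot(inherits(store, "interactome"))
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0L) stop_domain("Candidate set is empty")
  known <- candidates %in% store$genes$key
  if (!all(known)) {
    stop_domain(sprintf("Unknown candidate key(s): %s",
                        paste(candidates[!known], collapse = ", ")))
  }
  if (!is.null(targets)) {
    targets <- unique(as.character(targets))
    if (length(targets) == 0L) stop_domain("Target set supplied but empty")
    if (!all(targets %in% store$genes$key)) {
      stop_domain(sprintf("Unknown target key(s): %s",
                          paste(setdiff(targets, store$genes$key), collapse = ", ")))
    }
  }
  g <- store$graph
  mode <- if (is.null(targets)) "candidate_only" else "candidate_target"

  # direct interactors of candidates
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, candidates), names)))
  interactors <- setdiff(nb %||% character(), candidates)

  # shortest-path recruitment: per candidate, all shortest paths to every
  # co-minimal counterpart (other candidates, or closest targets)
  counterparts_of <- function(ci) {
    pool <- if (mode == "candidate_only") setdiff(candidates, ci) else setdiff(targets, ci)
    if (length(pool) == 0L) return(character())
    dm <- igraph::distances(g, v = ci, to = pool)
    d <- stats::setNames(dm[1L, ], colnames(dm))
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0L) return(character())
    names(d)[d == min(d)]
  }

  src <- character(); dst <- character(); len <- integer(); paths <- list()
  for (ci in candidates) {
    for (cj in counterparts_of(ci)) {
      ps <- igraph::all_shortest_paths(g, from = ci, to = cj)$res
      for (p in ps) {
        seqp <- names(p)
        src <- c(src, ci); dst <- c(dst, cj)
        len <- c(len, length(seqp) - 1L)
        paths <- c(paths, list(seqp))
      }
    }
  }
  path_log <- tibble(source = src, dest = dst, length = len, path = paths)

  path_nodes <- unique(unlist(paths)) %||% character()
  nodes <- unique(c(candidates, interactors, path_nodes,
                    if (mode == "candidate_target") targets))

  role <- rep("interactor", length(nodes))
  names(role) <- nodes
  role[nodes %in% path_nodes] <- "intermediate"
  if (mode == "candidate_target") role[nodes %in% targets] <- "target"
  role[nodes %in% candidates] <- "candidate"
  if (mode == "candidate_target") {
    role[nodes %in% intersect(candidates, targets)] <- "both"
  }

  # edge assembly
  path_edges <- unique(do.call(rbind, c(list(matrix(character(), ncol = 2)),
    lapply(paths, function(seqp) {
      if (length(seqp) < 2L) return(matrix(character(), ncol = 2))
      cbind(pmin(seqp[-length(seqp)], seqp[-1L]), pmax(seqp[-length(seqp)], seqp[-1L]))
    }))))
  path_pair <- if (nrow(path_edges)) paste(path_edges[, 1], path_edges[, 2], sep = "\r") else character()

  cand_edges <- store$edges[store$edges$from %in% candidates | store$edges$to %in% candidates, , drop = FALSE]
  if (edges == "induced") {
    base_edges <- store$edges[store$edges$from %in% nodes & store$edges$to %in% nodes, , drop = FALSE]
  } else {
    base_edges <- unique(bind_rows(
      cand_edges,
      tibble(from = path_edges[, 1], to = path_edges[, 2])
    ))
  }
  base_edges <- arrange(base_edges, .data$from, .data$to)
  edge_tbl <- mutate(base_edges,
                     on_path = paste(.data$from, .data$to, sep = "\r") %in% path_pair)

  node_tbl <- tibble(key = nodes, role = unname(role[nodes]))
  node_tbl <- arrange(node_tbl, .data$key)

  structure(list(nodes = node_tbl, edges = edge_tbl, path_log = path_log,
                 candidates = candidates, targets = targets, mode = mode),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  counts <- table(factor(x$nodes$role,
                         levels = c("candidate", "target", "both", "interactor", "intermediate")))
  cat(sprintf("<subnetwork> mode=%s: %d nodes (%s), %d edges, %d shortest paths logged\n",
              x$mode, nrow(x$nodes),
              paste(sprintf("%d %s", as.integer(counts), names(counts))[counts > 0],
                    collapse = ", "),
              nrow(x$edges), nrow(x$path_log)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.subnetwork <- function(x, ...) x$nodes

#' @exportS3Method generics::glance
glance.subnetwork <- function(x, ...) {
  tibble(mode = x$mode,
         n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges),
         n_candidates = length(x$candidates),
         n_targets = length(x$targets %||% character()),
         n_intermediates = sum(x$nodes$role == "intermediate"),
         n_paths = nrow(x$path_log))
}

#' Plot a subnetwork with role colouring
#'
#' Fruchterman–Reingold layout (seeded for reproducibility) with nodes
#' coloured by role, mirroring the conventional red/blue/yellow scheme for
#' candidate/target/both.
#'
#' @param object A `subnetwork`.
#' @param seed Layout seed.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.subnetwork <- function(object, seed = 42L, ...) {
  g <- igraph::graph_from_data_frame(object$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = object$nodes$key))
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$key)
  segs <- mutate(object$edges,
                 x = nodes$x[idx[.data$from]], y = nodes$y[idx[.data$from]],
                 xend = nodes$x[idx[.data$to]], yend = nodes$y[idx[.data$to]])
  pal <- c(candidate = "#d62728", target = "#1f77b4", both = "#e6c300",
           intermediate = "#2ca02c", interactor = "#aaaaaa")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$role),
                        size = 3) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::theme_void()
}
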