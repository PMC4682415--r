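# Independent brute-force oracles, written without igraph so the production
# path (igraph-backed) and the checks share no graph code.  All take a plain
# edge data frame (columns from/to) plus the full node vector.

oracle_adj <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

oracle_bfs <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (!is.finite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# every shortest path src -> dst, as a list of ordered node vectors
oracle_all_shortest_paths <- function(adj, src, dst) {
  d_src <- oracle_bfs(adj, src)
  if (!is.finite(d_src[dst])) return(list())
  d_dst <- oracle_bfs(adj, dst)
  total <- d_src[dst]
  paths <- list()
  walk <- function(cur, acc) {
    if (cur == dst) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (nb in adj[[cur]]) {
      if (d_src[nb] == d_src[cur] + 1 && d_src[nb] + d_dst[nb] == total) {
        walk(nb, c(acc, nb))
      }
    }
  }
  walk(src, src)
  paths
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

path_edge_keys <- function(path) {
  if (length(path) < 2L) return(character())
  edge_key(path[-length(path)], path[-1L])
}

# brute-force subnetwork definition: candidates + their direct interactors +
# all nodes/edges on all shortest paths candidate -> nearest counterpart(s)
oracle_subnetwork <- function(nodes, edges, candidates, targets = NULL) {
  adj <- oracle_adj(nodes, edges)
  interactors <- unique(unlist(adj[candidates]))
  path_nodes <- character()
  path_edges <- character()
  for (ci in candidates) {
    pool <- if (is.null(targets)) setdiff(candidates, ci) else setdiff(targets, ci)
    if (length(pool) == 0L) next
    d <- oracle_bfs(adj, ci)[pool]
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0L) next
    for (cj in names(d)[d == min(d)]) {
      for (p in oracle_all_shortest_paths(adj, ci, cj)) {
        path_nodes <- c(path_nodes, p)
        path_edges <- c(path_edges, path_edge_keys(p))
      }
    }
  }
  cand_edges <- edges[edges$from %in% candidates | edges$to %in% candidates, ]
  all_nodes <- unique(c(candidates, interactors, path_nodes,
                        if (!is.null(targets)) targets))
  all_edges <- unique(c(edge_key(cand_edges$from, cand_edges$to), path_edges))
  list(nodes = sort(all_nodes), edges = sort(all_edges),
       path_edges = sort(unique(path_edges)))
}

# brute-force connectivity statistics per the stated counting rules
oracle_connectivity <- function(nodes, edges, candidates, targets = NULL,
                                sentinel = 17) {
  adj <- oracle_adj(nodes, edges)
  if (is.null(targets)) {
    contrib <- numeric()
    reach <- stats::setNames(logical(length(candidates)), candidates)
    dists <- lapply(candidates, function(ci) oracle_bfs(adj, ci))
    names(dists) <- candidates
    for (i in seq_along(candidates)) {
      others <- candidates[-i]
      di <- dists[[candidates[i]]][others]
      reach[candidates[i]] <- any(is.finite(di))
      if (i < length(candidates)) {
        later <- candidates[(i + 1):length(candidates)]
        dl <- dists[[candidates[i]]][later]
        contrib <- c(contrib, ifelse(is.finite(dl), dl, sentinel))
      }
    }
    list(min_spl = min(contrib), avg_spl = mean(contrib),
         disconnected = sum(!reach), pair_count = length(contrib))
  } else {
    dists <- lapply(candidates, function(ci) oracle_bfs(adj, ci))
    names(dists) <- candidates
    # targets unreachable from every candidate drop out
    t_ok <- vapply(targets, function(t) {
      any(vapply(candidates, function(ci) ci != t && is.finite(dists[[ci]][t]),
                 logical(1)))
    }, logical(1))
    kept <- targets[t_ok]
    contrib <- numeric()
    disconnected <- 0L
    for (ci in candidates) {
      pool <- setdiff(targets, ci)
      if (length(pool) == 0L || !any(is.finite(dists[[ci]][pool]))) {
        disconnected <- disconnected + 1L
      }
      for (t in setdiff(kept, ci)) {
        dv <- dists[[ci]][t]
        contrib <- c(contrib, if (is.finite(dv)) dv else sentinel)
      }
    }
    if (length(contrib) == 0L) {
      list(min_spl = sentinel, avg_spl = sentinel,
           disconnected = disconnected, pair_count = 0L)
    } else {
      list(min_spl = min(contrib), avg_spl = mean(contrib),
           disconnected = disconnected, pair_count = length(contrib))
    }
  }
}

# exact upper hypergeometric tail by direct point-mass summation (stats::dhyper
# uses saddle-point evaluation, an algorithm independent of lchoose sums)
oracle_fisher_tail <- function(overlap, set_a, set_b, universe) {
  if (overlap == 0) return(1.0)
  k <- seq.int(overlap, min(set_a, set_b))
  min(sum(stats::dhyper(k, set_b, universe - set_b, set_a)), 1.0)
}

# --- tiny graph builders used across test files ---

# interactome from a plain letters edge list; nodes may include isolated ones
toy_store <- function(edge_pairs, extra_nodes = character()) {
  nodes <- unique(c(unlist(edge_pairs), extra_nodes))
  edges <- if (length(edge_pairs)) {
    data.frame(a = vapply(edge_pairs, `[[`, character(1), 1L),
               b = vapply(edge_pairs, `[[`, character(1), 2L))
  } else NULL
  interactome_from_tables(genes = data.frame(symbol = nodes), edges = edges)
}

# seeded random graph built with base R only (independent of igraph samplers)
random_graph_tbl <- function(n, p, seed) {
  nodes <- sprintf("G%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  set.seed(seed)
  keep <- stats::runif(nrow(pairs)) < p
  list(nodes = nodes,
       edges = data.frame(from = nodes[pairs[keep, 1]],
                          to = nodes[pairs[keep, 2]],
                          stringsAsFactors = FALSE))
}

store_from_tbl <- function(gt) {
  interactome_from_tables(genes = data.frame(symbol = gt$nodes),
                          edges = gt$edges)
}

# normalise a subnetwork object to comparable node/edge key sets
sn_keys <- function(sn) {
  list(nodes = sort(sn$nodes$key),
       edges = sort(edge_key(sn$edges$from, sn$edges$to)),
       path_edges = sort(unique(edge_key(sn$edges$from[sn$edges$on_path],
                                         sn$edges$to[sn$edges$on_path]))))
}
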