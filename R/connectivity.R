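#' Connectivity statistics of a query gene set on the interactome
#'
#' Reports the three connectivity statistics for a candidate set (all
#' unordered candidate pairs) or a candidate/target pair of sets (all
#' candidate x target cross-pairs, self-pairs excluded).  Each pair
#' contributes its unweighted shortest-path hop count on the full interactome
#' exactly once — multiple equally short paths are not counted multiple
#' times — or the sentinel distance when no path exists.  In two-set mode a
#' target unreachable from every candidate is excluded from the pair set
#' entirely before any averaging (disconnected targets are not counted),
#' whereas disconnected candidates do contribute sentinel-valued pairs.
#'
#' The sentinel (default 17) is a hop count chosen to exceed the longest
#' shortest path observed in the human interactome snapshot it was
#' calibrated on by a comfortable margin; other interactomes may warrant
#' other values.
#'
#' If, in two-set mode, every target is unreachable, no pairs remain; the
#' report then carries the sentinel for both path statistics and
#' `pair_count = 0`.
#'
#' @param store An `interactome`.
#' @param candidates Character vector of canonical candidate keys (at least
#'   two in candidate-only mode).
#' @param targets Optional character vector of canonical target keys.
#' @param sentinel Hop count substituted for pairs with no connecting path.
#' @return A `connectivity_report` tibble (one row): `min_spl`, `avg_spl`,
#'   `disconnected_candidates`, `pair_count`.
#' @examples
#' net <- interactome_from_tables(
#'   genes = data.frame(symbol = c("A", "B", "C")),
#'   edges = data.frame(a = "A", b = "B")
#' )
#' compute_connectivity(net, candidates = c("A", "B"))
#' @export
compute_connectivity <- function(store, candidates, targets = NULL, sentinel = 17) {
  stopifnot(inherits(store, "interactome"), sentinel >= 1)
  candidates <- unique(as.character(candidates))
  bad <- setdiff(c(candidates, targets %||% character()), store$genes$key)
  if (length(bad)) stop_domain(sprintf("Unknown key(s): %s", paste(bad, collapse = ", ")))
  g <- store$graph

  if (is.null(targets)) {
    if (length(candidates) < 2L) {
      stop_domain("Connectivity statistics are undefined for fewer than 2 candidate genes")
    }
    d <- igraph::distances(g, v = candidates, to = candidates)
    dv <- d[upper.tri(d)]
    contrib <- ifelse(is.finite(dv), dv, sentinel)
    # a candidate is disconnected when it reaches no other candidate
    diag(d) <- Inf
    disconnected <- sum(apply(d, 1L, function(row) all(!is.finite(row))))
    report <- tibble(min_spl = min(contrib), avg_spl = mean(contrib),
                     disconnected_candidates = as.numeric(disconnected),
                     pair_count = length(contrib))
  } else {
    targets <- unique(as.character(targets))
    d <- igraph::distances(g, v = candidates, to = targets)
    rownames(d) <- candidates
    colnames(d) <- targets
    # self-pairs (gene in both sets) never contribute
    for (k in intersect(candidates, targets)) d[k, k] <- NA
    # targets unreachable from every candidate drop out of the pair set
    reachable_t <- apply(d, 2L, function(col) any(is.finite(col) & !is.na(col)))
    d_kept <- d[, reachable_t, drop = FALSE]
    contrib <- as.vector(d_kept)
    contrib <- contrib[!is.na(contrib)]
    contrib <- ifelse(is.finite(contrib), contrib, sentinel)
    disconnected <- sum(apply(d, 1L, function(row) {
      row <- row[!is.na(row)]
      length(row) == 0L || all(!is.finite(row))
    }))
    if (length(contrib) == 0L) {
      report <- tibble(min_spl = as.numeric(sentinel), avg_spl = as.numeric(sentinel),
                       disconnected_candidates = as.numeric(disconnected),
                       pair_count = 0L)
    } else {
      report <- tibble(min_spl = min(contrib), avg_spl = mean(contrib),
                       disconnected_candidates = as.numeric(disconnected),
                       pair_count = length(contrib))
    }
  }
  class(report) <- c("connectivity_report", class(report))
  attr(report, "sentinel") <- sentinel
  report
}

baseline_scheme_names <- function(two_set) {
  if (two_set) c("candidate_to_random", "random_to_target", "random_to_random")
  else "random"
}

#' Random-gene-set connectivity baselines
#'
#' Contextualizes an observed connectivity report with randomized gene sets.
#' Per replicate, random sets are drawn uniformly without replacement from
#' the store's full gene universe (isolated genes included; coincidental
#' overlap with the true sets is allowed), matching the cardinality of the
#' set they replace; [compute_connectivity()] is applied; and each scheme's
#' row is the arithmetic mean over replicates of every statistic, so
#' fractional disconnected counts are expected.
#'
#' Candidate-only mode has the single scheme `random` (candidates replaced).
#' Two-set mode has three schemes: `candidate_to_random` (targets replaced),
#' `random_to_target` (candidates replaced), `random_to_random` (both
#' replaced).
#'
#' Randomness comes from R's Mersenne–Twister generator seeded once from
#' `seed`; results are reproducible given `(seed, replicates)` and the
#' caller's RNG state is left untouched.
#'
#' @inheritParams compute_connectivity
#' @param replicates Number of random networks per scheme (default 5).
#' @param seed Integer RNG seed.
#' @return A `baseline_table` tibble: one row per scheme with the averaged
#'   statistics, plus attributes `replicates` and `seed`.
#' @export
random_baseline <- function(store, candidates, targets = NULL,
                            replicates = 5L, seed = 1L, sentinel = 17) {
  stopifnot(inherits(store, "interactome"), replicates >= 1L)
  universe <- gene_universe(store)
  candidates <- unique(as.character(candidates))
  targets <- if (!is.null(targets)) unique(as.character(targets))
  sizes <- c(length(candidates), length(targets %||% character()))
  if (max(sizes) > length(universe)) {
    stop_domain("Gene universe smaller than the set to randomize")
  }
  two_set <- !is.null(targets)
  schemes <- baseline_scheme_names(two_set)

  rows <- with_seed(seed, {
    lapply(schemes, function(scheme) {
      reps <- lapply(seq_len(replicates), function(r) {
        cand <- if (scheme %in% c("random", "random_to_target", "random_to_random")) {
          sample(universe, length(candidates))
        } else candidates
        targ <- if (!two_set) NULL
          else if (scheme %in% c("candidate_to_random", "random_to_random")) {
            sample(universe, length(targets))
          } else targets
        compute_connectivity(store, cand, targ, sentinel = sentinel)
      })
      reps <- bind_rows(reps)
      tibble(scheme = scheme,
             min_spl = mean(reps$min_spl),
             avg_spl = mean(reps$avg_spl),
             disconnected_candidates = mean(reps$disconnected_candidates),
             pair_count = mean(reps$pair_count))
    })
  })
  out <- bind_rows(rows)
  class(out) <- c("baseline_table", class(out))
  attr(out, "replicates") <- as.integer(replicates)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "sentinel") <- sentinel
  out
}

#' Combined observed + baseline connectivity table
#'
#' Convenience wrapper producing the familiar network-statistics table: the
#' observed row first, then the randomized scheme rows.
#'
#' @inheritParams random_baseline
#' @return A tibble with a `scheme` column (`observed` first).
#' @export
connectivity_table <- function(store, candidates, targets = NULL,
                               replicates = 5L, seed = 1L, sentinel = 17) {
  obs <- compute_connectivity(store, candidates, targets, sentinel = sentinel)
  base <- random_baseline(store, candidates, targets,
                          replicates = replicates, seed = seed, sentinel = sentinel)
  out <- bind_rows(
    mutate(as_tibble(obs), scheme = if (is.null(targets)) "observed" else "candidate_to_target",
           .before = 1L),
    as_tibble(base)
  )
  attr(out, "replicates") <- attr(base, "replicates")
  attr(out, "seed") <- attr(base, "seed")
  attr(out, "sentinel") <- sentinel
  class(out) <- c("baseline_table", class(out))
  out
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat(sprintf(
    "<connectivity_report> min SPL %s, avg SPL %.2f, disconnected candidates %g (%d pairs, sentinel %g)\n",
    format(x$min_spl), x$avg_spl, x$disconnected_candidates, x$pair_count,
    attr(x, "sentinel") %||% NA))
  invisible(x)
}

#' Baseline comparison plot
#'
#' Bar chart of average shortest path length per scheme; the observed row (if
#' present) is highlighted.
#'
#' @param object A `baseline_table` or the output of [connectivity_table()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.baseline_table <- function(object, ...) {
  df <- as_tibble(object)
  if (!"scheme" %in% names(df)) df$scheme <- "baseline"
  df$scheme <- factor(df$scheme, levels = unique(df$scheme))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme, y = .data$avg_spl)) +
    ggplot2::geom_col(fill = "#1f77b4") +
    ggplot2::labs(x = NULL, y = "average shortest path length") +
    ggplot2::theme_minimal()
}
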