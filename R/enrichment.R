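#' Upper-tail Fisher exact (hypergeometric) p-value
#'
#' One-sided over-representation p-value: the probability of observing
#' `overlap` or more shared genes between a set of size `set_a` and a set of
#' size `set_b` drawn from a universe of `universe` genes,
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(universe, set_b,
#' set_a)}.  The tail is accumulated in log space from binomial-coefficient
#' logarithms, which keeps the sum numerically stable for universes up to
#' \eqn{10^5} and beyond.
#'
#' @param overlap Observed overlap count.
#' @param set_a,set_b Sizes of the two sets.
#' @param universe Universe size.
#' @return The p-value in (0, 1].
#' @examples
#' fisher_upper_tail(4, 4, 5, 10)   # 1/42
#' @export
fisher_upper_tail <- function(overlap, set_a, set_b, universe) {
  stopifnot(length(overlap) == 1L, length(set_a) == 1L,
            length(set_b) == 1L, length(universe) == 1L)
  if (is.na(overlap) || is.na(set_a) || is.na(set_b) || is.na(universe) ||
      overlap < 0 || set_a < 0 || set_b < 0 || universe < 1 ||
      overlap > min(set_a, set_b) || set_a > universe || set_b > universe) {
    stop_domain("Impossible contingency counts for fisher_upper_tail")
  }
  if (overlap == 0) return(1.0)
  k <- seq.int(overlap, min(set_a, set_b))
  logs <- lchoose(set_b, k) + lchoose(universe - set_b, set_a - k) -
    lchoose(universe, set_a)
  m <- max(logs)
  p <- exp(m) * sum(exp(logs - m))
  min(p, 1.0)
}

#' Over-representation of annotation terms among subnetwork genes
#'
#' For every catalog term sharing at least `min_overlap` genes with the
#' tested gene set, reports the Fisher exact upper-tail p-value together with
#' the four contingency counts and the overlapping genes (the quantities
#' that parameterize a Venn diagram).  Results are sorted by ascending
#' p-value within category.
#'
#' The tested set defaults to all subnetwork nodes (candidates, targets,
#' interactors and intermediates alike); `gene_set = "candidates"` restricts
#' it to the candidate genes.  The universe defaults to every gene in the
#' interactome store; `universe = "catalogs"` uses the union of all catalog
#' genes instead.  Raw p-values are reported; `adjust = TRUE` appends
#' Benjamini–Hochberg values in `p_adjusted` (computed within category)
#' without altering `p_value`.
#'
#' @param network A `subnetwork`.
#' @param catalogs A single `annotation_catalog` or a list of them.
#' @param store The `interactome` the network and catalogs were resolved
#'   against.
#' @param universe `"store"` (default) or `"catalogs"`.
#' @param gene_set `"network"` (default) or `"candidates"`.
#' @param min_overlap Minimum overlap for a term to be reported.
#' @param adjust Append BH-adjusted p-values?
#' @return An `enrichment_result` tibble: `term`, `category`, `p_value`,
#'   `overlap`, `network_only`, `term_only`, `neither`, `universe_size`,
#'   `overlap_genes` (list-column).
#' @export
enrich <- function(network, catalogs, store,
                   universe = c("store", "catalogs"),
                   gene_set = c("network", "candidates"),
                   min_overlap = 1L, adjust = FALSE) {
  universe <- match.arg(universe)
  gene_set <- match.arg(gene_set)
  stopifnot(inherits(network, "subnetwork"), inherits(store, "interactome"))
  if (inherits(catalogs, "annotation_catalog")) catalogs <- list(catalogs)
  stopifnot(all(vapply(catalogs, inherits, logical(1), "annotation_catalog")))

  uni <- if (universe == "store") gene_universe(store)
    else unique(unlist(lapply(catalogs, function(cat) unlist(cat$terms, use.names = FALSE))))
  if (length(uni) == 0L) stop_domain("Empty enrichment universe")
  net_genes <- if (gene_set == "network") network$nodes$key else network$candidates
  extraneous <- setdiff(net_genes, gene_universe(store))
  if (length(extraneous)) {
    stop_domain("Subnetwork carries genes unknown to the store; catalog/store mismatch?")
  }
  net_genes <- intersect(net_genes, uni)

  rows <- purrr::map(catalogs, function(cat) {
    purrr::imap(cat$terms, function(genes, term) {
      genes <- intersect(genes, uni)
      ov <- intersect(net_genes, genes)
      if (length(ov) < min_overlap || length(genes) == 0L) return(NULL)
      p <- fisher_upper_tail(length(ov), length(net_genes), length(genes), length(uni))
      tibble(term = term, category = cat$category, p_value = p,
             overlap = length(ov),
             network_only = length(net_genes) - length(ov),
             term_only = length(genes) - length(ov),
             neither = length(uni) - length(net_genes) - length(genes) + length(ov),
             universe_size = length(uni),
             overlap_genes = list(sort(ov)))
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0L) {
    out <- tibble(term = character(), category = character(),
                  p_value = numeric(), overlap = integer(),
                  network_only = integer(), term_only = integer(),
                  neither = integer(), universe_size = integer(),
                  overlap_genes = list())
  } else {
    out <- arrange(out, .data$category, .data$p_value, .data$term)
    if (adjust) {
      out <- mutate(dplyr::group_by(out, .data$category),
                    p_adjusted = stats::p.adjust(.data$p_value, method = "BH"))
      out <- dplyr::ungroup(out)
    }
  }
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Enrichment overview plot
#'
#' Horizontal bars of -log10 p-value for the strongest terms per category.
#'
#' @param object An `enrichment_result`.
#' @param top Number of terms shown per category.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, top = 10L, ...) {
  df <- dplyr::slice_head(dplyr::group_by(as_tibble(object), .data$category), n = top)
  df <- dplyr::ungroup(df)
  df <- mutate(df, term = stats::reorder(.data$term, -.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$term)) +
    ggplot2::geom_col(fill = "#2ca02c") +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL) +
    ggplot2::theme_minimal()
}
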