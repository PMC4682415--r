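---
title: "Seed-gene subnetworks, connectivity nulls, and enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene subnetworks, connectivity nulls, and enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

## The problem

A common end point of a GWAS or expression study is a list of genes with no
obvious functional story. A standard way to characterize such a list is to
place it in the protein–protein interaction (PPI) network: extract the
sub-interactome the genes span, judge whether they are more tightly connected
than chance, and ask which pathways, diseases, drugs and GWAS traits are
over-represented among the genes of that subnetwork. seednet implements this
workflow as a scriptable library: deterministic graph construction rules, a
node-resampling null model for connectivity, and Fisher exact
over-representation tests, with file formats (TSV edge lists, GMT catalogs,
SIF, JSON) chosen so everything interoperates with Cytoscape and ordinary
spreadsheet tooling.

## Subnetwork construction

Queries come as one or two gene sets. The first set, the *candidate genes*,
always recruits all of its immediate interaction partners. What happens next
depends on whether a second set is present:

* **Candidates only.** For each candidate, the builder finds its nearest
  other candidate(s) in the *full* interactome — not in the partially built
  subnetwork — and adds every shortest path to every co-minimal neighbor.
  Ties are never broken: if three candidates are equally near, or a pair is
  joined by five equally short paths, all are included.
* **Candidates and targets.** Candidate-to-candidate paths are not sought.
  Instead each candidate is joined by all shortest paths to its closest
  target(s). Immediate interactors of targets are *not* recruited, and a
  target no candidate can reach stays in the picture as an isolated node, so
  the display never silently loses part of the query.

Nodes carry roles with the precedence `both > candidate > target >
intermediate > interactor`; an *intermediate* is a gene recruited only
because it lies on a recorded shortest path, and the builder logs every such
path (source, destination, ordered node sequence) so that any intermediate
can be justified after the fact.

Two design points were genuinely open and are worth stating:

* **Edge set.** The default edge set is candidate–interactor edges plus the
  edges of logged shortest paths, not the full induced subgraph on recruited
  nodes. Networks of recruited paths read as trees of evidence; the induced
  subgraph would add edges between two interactors that no rule asked for.
  The induced reading is available with `edges = "induced"`.
* **Genes in both sets.** A gene listed as both candidate and target is
  treated as a candidate for recruitment and excluded from its own
  closest-target search: a zero-length self-path is degenerate and would
  otherwise always win.

A candidate with no route to any counterpart still recruits its direct
interactors and persists, possibly isolated; downstream statistics count it
rather than dropping it.

## Connectivity statistics and the sentinel

Three statistics summarize how tightly the query is knit: the minimum and the
arithmetic mean of shortest-path lengths over all query pairs, and the number
of disconnected candidates. Pairs are unordered candidate pairs
(candidate-only mode) or candidate × target cross-pairs with self-pairs
excluded (two-set mode). Each pair contributes its hop count exactly once,
however many co-minimal paths realize it.

A pair with no connecting path contributes a fixed **sentinel distance**,
default 17 hops — a value chosen, for the human interactome snapshot the
convention comes from, to sit five hops above the longest observed shortest
path. The sentinel keeps disconnected pairs inside the averages while making
them visually unmistakable. It is exposed as a parameter because a different
interactome (or a fixture) has a different diameter; nothing in the code
depends on the specific value.

Asymmetric treatment of disconnection is deliberate and follows the tool
convention this package reimplements: a *target* unreachable from every
candidate is removed from the pair set before averaging (it contributes
nothing), whereas a disconnected *candidate* stays and contributes
sentinel-valued pairs, and only disconnected candidates are counted in the
report. If every target is unreachable the pair set empties; the report then
carries the sentinel with `pair_count = 0` rather than an undefined mean.

## The null model

Observed statistics are contextualized by node resampling: random gene sets
drawn uniformly *without replacement* from the store's full gene universe —
isolated genes included, coincidental overlap with the real sets allowed —
matched in size to the set they replace. With candidates only there is one
scheme (candidates replaced); with two sets there are three
(`candidate_to_random`, `random_to_target`, `random_to_random`). Each scheme
runs 5 replicates by default and reports the arithmetic mean of every
statistic, so fractional disconnected counts such as 2.6 are expected, and
the baseline "minimum" row is the mean of per-replicate minima. This is a
node-resampling null only; degree-preserving rewiring nulls are a different
instrument and are out of scope.

Randomness uses R's Mersenne–Twister generator, seeded once per baseline
call; the caller's RNG state is saved and restored, and results are
reproducible from `(seed, replicates)` alone.

## Enrichment

For each annotation term the contingency table is: the tested gene set
(default: *all* subnetwork nodes, since interactors and intermediates are
exactly the genes the network brought into view; `gene_set = "candidates"`
restricts to the seeds), the term's genes, their overlap, and the rest of the
universe (default: all genes in the interactome store, the same population
the input validation step works against; `universe = "catalogs"` is
available). The p-value is the one-sided hypergeometric upper tail
\(P(X \ge k)\), i.e. Fisher's exact test in the enrichment direction,
accumulated in log space from `lchoose` terms so the sum stays stable for
universes of 10^5 genes and beyond. Raw p-values are reported by default —
the workflow this mirrors reported unadjusted values, and borderline results
(a p of 0.0496, say) are interpretable as such; Benjamini–Hochberg adjusted
values can be appended with `adjust = TRUE` but never replace the raw
column. Each result row carries the four counts and the overlapping gene
list, which is exactly the parameterization of a two-set Venn diagram.

## Identifier handling

Genes may arrive as HUGO-style symbols, Entrez IDs or UniProt accessions.
The store assigns each record a canonical key and resolves free-form tokens
by trying namespaces in the order symbol → Entrez → UniProt (configurable).
Symbols compare case-insensitively; Entrez numerically (`007088` = `7088`);
UniProt case-insensitively with isoform suffixes (`-2`) ignored. Ambiguities
— a namespace value claimed by two records — are rejected at load time with
a report, so queries can only ever be `unknown`, never silently ambiguous.
Rejected query tokens are echoed, not fatal; only a fully rejected list
aborts a run.

Edge lists are parsed through a declared column mapping with presets for the
HPRD flat-file layout (symbols in columns 1 and 4) and the BioGRID tab
layout (symbols in columns 8/9, PSI-MI interaction-type string in column
12). The interaction-type filter is a substring predicate over that column —
e.g. keep `0417` to restrict BioGRID rows to binary biophysical
interactions. Merging multiple sources is by union after canonicalization;
self-loops are dropped, duplicate and reversed duplicate edges collapsed,
and every drop is counted in a retrievable load report.

## Synthetic fixtures

`make_interactome_fixture()` fabricates edge lists and identifier tables in
the exact dialects the loaders read, under three models: Erdős–Rényi
G(n, p) for unstructured graphs, preferential attachment for hub-dominated
degree distributions (the feature of real interactomes that most affects
path statistics), and `path_union`, which plants specified exact distances
between chosen gene pairs using fresh chain intermediates. Identifiers
follow per-namespace patterns (`SYM0001` / `9000001` / `Q900001`) so a
namespace mix-up cannot pass silently. `make_catalog_fixture()` plants GMT
terms with exact overlaps against a named gene set, giving closed-form
expected contingency tables. Same seed, byte-identical files.

What the fixtures do *not* emulate: literature-curation bias (real
interactomes over-sample well-studied genes), correlated annotation terms,
and the scale of the human interactome (~20k nodes). Tests passing on
fixtures therefore validate the *rules* — recruitment, counting, null
schemes, tail probabilities — not any biological claim about real data.

## Numerical and testing choices

* Shortest paths are unweighted hop counts; all-shortest-paths enumeration
  is exact, not sampled.
* The Fisher tail uses a log-sum-exp over `lchoose` terms; the test suite
  checks it against reverse-cumulated `dhyper` point masses (an independent
  algorithm) to relative error below 1e-9 over every contingency table with
  universe ≤ 60, and against exact rational-arithmetic references for a
  spot-check set including universes of 10^5.
* Builder and statistics are verified against brute-force BFS/path-
  enumeration oracles written without igraph: exhaustively over the
  non-isomorphic connected graphs of ≤ 7 nodes (graph atlas), over seeded
  random 8-node connected graphs, and over 100 seeded random fixtures of up
  to 50 nodes. Fixture sizes were chosen so the whole suite runs in a few
  minutes on one CPU.
* The 500-replicate null-calibration test compares the baseline mean against
  the exact expectation from enumerating all C(12,3) candidate subsets of a
  12-node fixture, within 3 standard errors.
* Exports are deterministic: lexicographic SIF ordering, stable JSON field
  order, timestamps confined to a metadata field that defaults to empty.

## Known limitations

* Distances are topological only; no edge confidence weights.
* The null model resamples nodes, not topology; hubs in the query make many
  random sets look close too, which is visible in the baselines but not
  corrected for.
* Enrichment treats terms independently; correlated catalogs (nested
  pathways) inflate the count of significant terms, which is why raw
  p-values plus explicit counts, rather than a single adjusted verdict, are
  returned.
* GO-term enrichment and degree-preserving nulls are deliberately not
  implemented.
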