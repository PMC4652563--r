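---
title: "Building significance-tested gene set networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building significance-tested gene set networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsnet)
library(dplyr)
```

## The model

A gene set network (GSN) is a graph whose nodes are gene sets — pathways,
GO terms, any named gene family — and whose edges assert a set-level
relationship that is stronger than chance. gsnet builds two kinds.

**Co-membership networks (M-GSNs).** Two sets GS1 and GS2 are connected
when they share more genes than expected. With a universe of $N$ genes,
$n = |GS1|$, $K = |GS2|$ and $k = |GS1 \cap GS2|$, the shared-gene count is
referred to the hypergeometric distribution,

$$ p = \sum_{i \ge k} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}, $$

the one-sided enrichment (upper-tail) probability. Edges are undirected:
the formula is symmetric in $n$ and $K$.

**Regulatory networks (R-GSNs).** Direction comes from a gene-regulation
edge list (transcription-factor/target and pathway-derived regulations).
Shared genes are removed first — with $U_1 = GS1 \setminus GS2$ and
$U_2 = GS2 \setminus GS1$ — and the same hypergeometric model is applied to
regulation counts instead of gene counts: $N$ = all regulations loaded,
$n$ = regulations leaving $U_1$ for targets outside GS1, $K$ = regulations
entering $U_2$ from sources outside GS2, and $k$ = regulations from $U_1$
into $U_2$. A significant $k$ draws the directed edge GS1 → GS2; both
directions of a pair can be significant and both are kept (a set-level
"loop").

In both constructions every pair of the run — all $\binom{s}{2}$ unordered
pairs for an M-GSN, all $s(s-1)$ ordered pairs for an R-GSN — forms a
single Benjamini–Hochberg family, and an edge is drawn exactly when it is
rejected at FDR $\alpha$ (default 0.05). Pairs with $k = 0$ stay in the
family with $p = 1$; they can never be rejected, but they count toward the
family size, which is the conservative reading of adjusting "over all
hypotheses". Pairs with identical membership, or an empty regulation
network, are untestable and excluded.

**Disease subnetworks.** A disease gene list is treated as one extra gene
set: every set of a merged multi-collection is scored against it with the
co-membership model ($K$ = list size, $N$ = merged universe size), one BH
family over all sets, and the selected sets are re-built into a directed
disease-specific R-GSN.

## Worked example

```{r example}
gmt <- c(
  "cycle\tcell division\tCDK1\tCDK2\tCCNB1\tPLK1\tBUB1",
  "damage\tDNA damage response\tTP53\tATM\tCHEK2\tCDK2\tCCNB1",
  "lipid\tlipid transport\tAPOE\tAPOA1\tLPL\tABCA1"
)
sets <- read_gmt(gmt, name = "demo")
sets

regs <- regulation_network(tibble::tibble(
  source = c("CDK1", "PLK1", "BUB1", "CDK1",
             sprintf("X%d", 1:8)),      # unrelated background
  target = c("TP53", "ATM", "CHEK2", "ATM",
             sprintf("Y%d", 1:8))
))
rgsn <- build_rgsn(sets, regs, alpha = 0.05)
tidy(rgsn)
glance(rgsn)
```

All four regulations that touch the gene sets run from the unique genes of
`cycle` into the unique genes of `damage`: the ordered pair
(`cycle`, `damage`) gets $k = n = K = 4$ out of $N = 12$ regulations,
$p = 1/\binom{12}{4} \approx 0.002$, and is the only pair to survive BH.

## Parameters that matter

* `alpha` (default 0.05) — the FDR level of the BH step-up; every network
  construction forms one family per run.
* `mode` (default `"upper-tail"`) — the p-value is the one-sided
  enrichment tail $P(X \ge k)$. The point mass $P(X = k)$ is available as
  `"point"`; at typical parameter magnitudes the two differ by a few
  percent, and the tail is the statistically defensible choice for an
  enrichment question as well as the closer match to published
  disease-enrichment values, so it is the pinned default.
* `count_variant` (default `"canonical"`) — the R-GSN counts above, under
  which $k \le \min(n, K)$ holds by construction. The `"literal"` variant
  counts $n$ as regulations from all of GS1 to targets outside GS2, a
  wording-level alternative kept for sensitivity analysis; it can push $k$
  outside the hypergeometric support, in which case $k$ is clipped with a
  warning.
* `restrict_universe` (default `FALSE`) — $N$ for R-GSNs counts all loaded
  regulations after filtering; the flag restricts $N$ to regulations whose
  endpoints lie inside the collection's universe.
* `intersect_disease_list` (default `FALSE`) — $K$ is the full disease
  list size by default; the flag intersects the list with the universe
  first, the stricter reading when a list contains symbols outside the
  collections.
* For M-GSNs, $N$ defaults to the collection's own universe (its member
  union) because each collection's network is built separately; when
  collections are merged with `gsc_combine()`, the merged member union is
  the universe, which is the configuration the disease workflow uses.

## Numerical choices

All hypergeometric arithmetic is evaluated in log space (log-gamma based
tail routines), so edge p-values around $10^{-130}$ — routine for deeply
overlapping pathway pairs — remain representable; `log.p = TRUE` exposes
the log scale directly where even that underflows. BH q-values are the
standard step-up minima capped at 1, so `rejected` is exactly `q <= alpha`
and rejection sets are nested across `alpha`. Output edge tables are
sorted by (p, gs1, gs2) with stable ties, making repeated writes
byte-identical. Degenerate inputs are explicit: a one-set collection
yields a valid empty network, an empty regulation network yields no
testable pairs, zero-variance degree vectors make the degree correlation
an error rather than NaN, and closeness of a node that reaches nothing is
0 with an `unreachable` flag (reachable-only averaging, the igraph
convention, applied in the out-direction for directed networks).

Degree centrality is normalized by $s - 1$; for directed networks in- and
out-degree centralities are each at most 1 and their sum (the total DC) can
approach 2, which is why hub sets in a directed network can report values
near 2 while undirected values stay in $[0, 1]$. Betweenness is reported
unnormalized, with fractional credit across tied shortest paths.

The edge-overlap null model draws exactly $m$ distinct unordered pairs
uniformly (Erdős–Rényi $G(n, m)$) per replicate; the expected overlap of
two independent draws is $e_1 e_2 / \binom{n}{2}$, which the generator is
tested against. The Fisher table for an observed overlap uses all
$\binom{n}{2}$ possible pairs as the universe:
$[s, |A|-s; |B|-s, \binom{n}{2}-|A|-|B|+s]$. A seed is mandatory wherever
randomness enters, and the driver restores the caller's RNG state.

## What the synthetic generator emulates

`fixture_spec()` + `generate_collection()` + `generate_regulations()`
produce a study with known ground truth: a universe of anonymous genes,
sets whose sizes are skewed toward small sets (probability ∝ 1/size over
the size range, mirroring the empirical excess of 2–20-gene sets in
curated collections), a controlled pairwise overlap, a sparse Bernoulli
background of directed regulations, and planted ordered set pairs whose
$U_1 \times U_2$ region is regulated at `background_rate * multiplier`.

Overlap is implemented with a shared core pool: each set draws
`round(overlap * size)` genes from a core of `core_size` genes (5% of the
universe by default, floor 20) and the rest from a private, never-reused
block. Overlap can therefore only arise inside the core, giving the
closed-form expected pairwise overlap $c_1 c_2 / \text{core}$ used by the
generator's own tests, and `overlap = 0` yields exactly disjoint sets.

What it does **not** emulate: scale-free regulator topology, hub
transcription factors, autoregulation statistics, per-database error
profiles, or correlated set membership beyond the single core pool.
Passing the planted-recovery tests therefore shows that the statistical
machinery detects genuine cross-set regulation and controls the FDR under
a clean null — not that real regulation databases satisfy the model's
independence assumptions.

The recovery study used in the tests runs 200 seeded replicates of 30
sets with 3 planted pairs at multiplier 50 over a 0.001 background. The
planted sets are given 30–50 disjoint genes over a 2,000-gene universe so
that each planted region spans ≥ 900 ordered gene pairs; the realized
cross-count then concentrates far above the BH rejection boundary
(binomial mean ≈ 45, while ≈ 9 would already reject), making full recovery
the analytic expectation rather than a tuned outcome. Problem sizes
throughout the suite (12–30 sets, universes of a few hundred to a few
thousand genes, 200–1,000 replicates) were chosen as the smallest scales at
which the asserted expectations are sharp.

## Design decisions that were genuinely open

* **Tail versus point probability.** The construction recipe's formula is
  typeset as the single hypergeometric term, but published enrichment
  values behave like one-sided tails. The package computes both; the tail
  is the default (see above) and the two stay within ~10% of each other at
  the relevant parameter ranges.
* **The R-GSN count wording.** Step-level descriptions of $n$ disagree
  ("outside GS1" versus "outside GS2"). The canonical variant keeps
  $(n, K, k)$ mutually consistent ($k \le n$, $k \le K$ structurally) and
  is the default; the literal variant is a config switch.
* **$k = 0$ pairs in the BH family** (kept, as argued above) — exposed
  rather than configurable, since removing them can only shrink the family
  and make rejection easier.
* **Name collisions when merging collections** are disambiguated by
  prefixing the collection name (`KEGG::Cell cycle`); merging is otherwise
  lossless.
* **Self-regulations are retained**: they contribute to the global $N$ but
  can never enter a cross-set $k$, because a gene cannot sit in two
  disjoint unique parts.

## Known limitations

Published full-scale edge counts depend on licensed database snapshots and
are not reproducible from this package alone; the suite validates the
machinery by oracle equivalence (exhaustive enumeration for small
hypergeometric and Fisher problems, a literal-definition BH
implementation, brute-force path counting for betweenness) and by planted
ground truth instead. Disease-enrichment p-values recomputed at the
published $(N, K, n, k)$ land 2–6% below the published figures under the
tail mode — consistent with the published analysis having used a slightly
smaller effective universe/list than the rounded counts it prints — and
the package reports its own computed values rather than adjusting toward
printed ones. Gene identity is a single flat symbol namespace; organism
handling, ID-mapping services and weighted centralities are out of scope.
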