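# gsnet — significance-tested gene set networks

Pathway databases and GO annotations describe biology one gene set at a
time. Much of what a cell does, however, happens *between* those sets:
pathways cross-talk through shared members, and regulators in one pathway
drive targets in another. `gsnet` builds networks over gene sets for
systems biologists who want those relationships with statistical control
rather than as raw overlap counts:

* **M-GSNs** (co-membership): undirected edges between gene sets that
  share significantly many genes — pathway crosstalk for pathway
  collections, gene sharing/moonlighting for GO terms.
* **R-GSNs** (regulatory): directed edges GS1 → GS2 when significantly
  many regulations run from GS1's unique genes (members not shared with
  GS2) to GS2's unique genes, built from a filtered gene-regulation edge
  list.
* **Disease-specific subnetworks**: gene sets enriched for a disease gene
  list, rewired into their own directed regulatory network.
* **Analytics**: degree/closeness/betweenness centrality reports, exclusive
  (R-minus-M) networks, shared-edge comparison between networks, and an
  Erdős–Rényi G(n, m) overlap null with Fisher's exact test.

## The statistic

Every edge is a hypergeometric enrichment test. For co-membership, with a
universe of N genes, n = |GS1|, K = |GS2| and k shared genes,

    p = Σ_{i ≥ k}  C(K, i) · C(N−K, n−i) / C(N, n)

(the one-sided upper tail). For regulation, shared genes are removed first
(U1 = GS1∖GS2, U2 = GS2∖GS1) and the same model is applied to regulation
counts: N = all regulations, n = regulations leaving U1, K = regulations
entering U2, k = regulations from U1 into U2. All pairs of a run form one
Benjamini–Hochberg family at FDR α (default 0.05); an edge exists exactly
when its pair is rejected. Computation is in log space, so p ≈ 1e-130
edges are handled exactly.

## Worked example

```r
library(gsnet)

sets <- read_gmt(c(
  "cycle\tcell division\tCDK1\tCDK2\tCCNB1\tPLK1\tBUB1",
  "damage\tDNA damage response\tTP53\tATM\tCHEK2\tCDK2\tCCNB1",
  "lipid\tlipid transport\tAPOE\tAPOA1\tLPL\tABCA1"
), name = "demo")

regs <- regulation_network(tibble::tibble(
  source = c("CDK1", "PLK1", "BUB1", "CDK1", sprintf("X%d", 1:8)),
  target = c("TP53", "ATM", "CHEK2", "ATM", sprintf("Y%d", 1:8))
))

rgsn <- build_rgsn(sets, regs, alpha = 0.05)
tidy(rgsn)
#> # A tibble: 1 × 8
#>   gs1   gs2        n     K     k     N       p      q
#>   <chr> <chr>  <int> <int> <int> <int>   <dbl>  <dbl>
#> 1 cycle damage     4     4     4    12 0.00202 0.0121
```

Four of the twelve regulations run from `cycle`'s unique genes (CDK1,
PLK1, BUB1) into `damage`'s unique genes (TP53, ATM, CHEK2); that is all
of n, K and k for the ordered pair, p = 1/C(12,4) ≈ 0.002, and after BH
over the six ordered pairs (q = 0.012) it is the single significant
directed edge. `tidy(rgsn, tests = TRUE)` returns every tested pair,
`glance(rgsn)` the one-row network summary, `autoplot(rgsn)` a network
plot, and `centrality_report(rgsn)` per-node centralities — here `cycle`
is the source (out-degree centrality 0.5) and `damage` the sink.

A command-line wrapper with the same workflows
(`build-mgsn`, `build-rgsn`, `disease`, `analyze`, `compare`, `simulate`)
is installed at `inst/cli/gsnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gsnet.R", package="gsnet"))')" \
  build-mgsn --gmt sets.gmt --alpha 0.05 --out mgsn.tsv
```

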