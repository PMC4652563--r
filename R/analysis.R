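#' Convert a gene set network to an igraph graph
#'
#' Isolated nodes are retained; edge attributes carry the test statistics.
#'
#' @param net A `gsn`.
#' @return An igraph graph.
#' @export
as_igraph_gsn <- function(net) {
  stopifnot(inherits(net, "gsn"))
  ed <- net$edges
  igraph::graph_from_data_frame(
    d = data.frame(from = ed$gs1, to = ed$gs2, p = ed$p, q = ed$q),
    directed = net$directed,
    vertices = data.frame(name = sort(net$nodes$set))
  )
}

#' Node centrality report
#'
#' Per-node degree, closeness and betweenness centralities. Degree
#' centrality is normalized by (s - 1): for directed networks the in- and
#' out-degree centralities are each at most 1 and the total degree
#' centrality (their sum) can reach 2, which is why hub gene sets in a
#' directed network can show values like 1.96. Closeness is the inverse of
#' the mean shortest-path length to the reachable nodes (out-direction for
#' directed networks); a node that reaches nothing gets closeness 0 and
#' `unreachable = TRUE`. Betweenness is the standard unnormalized
#' shortest-path count with fractional credit for ties, over ordered pairs
#' when directed.
#'
#' @param net A `gsn` with at least 2 nodes.
#' @return Tibble with columns `set`, `degree`, `in_degree`, `out_degree`,
#'   `dc`, `in_dc`, `out_dc`, `closeness`, `unreachable`, `betweenness`.
#' @export
centrality_report <- function(net) {
  g <- as_igraph_gsn(net)
  s <- igraph::vcount(g)
  if (s < 2L) abort("centrality needs at least 2 nodes")
  nm <- igraph::V(g)$name
  if (net$directed) {
    din <- igraph::degree(g, mode = "in")
    dout <- igraph::degree(g, mode = "out")
    deg <- din + dout
  } else {
    deg <- igraph::degree(g, mode = "all")
    din <- dout <- rep(NA_integer_, s)
  }
  mode <- if (net$directed) "out" else "all"
  cl <- suppressWarnings(
    igraph::closeness(g, mode = mode, normalized = TRUE)
  )
  unreachable <- !is.finite(cl) | is.nan(cl)
  cl[unreachable] <- 0
  btw <- igraph::betweenness(g, directed = net$directed, normalized = FALSE)
  tibble(
    set = nm,
    degree = unname(as.integer(deg)),
    in_degree = unname(as.integer(din)),
    out_degree = unname(as.integer(dout)),
    dc = unname(deg / (s - 1)),
    in_dc = unname(din / (s - 1)),
    out_dc = unname(dout / (s - 1)),
    closeness = unname(as.numeric(cl)),
    unreachable = unname(unreachable),
    betweenness = unname(as.numeric(btw))
  )
}

#' Normalized proportion of regulatory edges to nodes
#'
#' For a collection with `r` regulatory edges, `s` gene sets and `g_i`
#' unique genes inside a combined universe of `g` genes, the normalized
#' edge/node proportion is (r / s) * (g / g_i): the raw edges-per-set
#' ratio rescaled by the collection's share of the gene universe, making
#' collections of different gene coverage comparable.
#'
#' @param r Regulatory edge count of the collection.
#' @param s Gene set count.
#' @param g_i Unique gene count of the collection.
#' @param g Total unique genes across collections.
#' @param digits Rounding applied to the reported value (2 decimals, as in
#'   summary tables); use `NULL` for the raw ratio.
#' @return The normalized proportion.
#' @examples
#' normalized_edge_proportion(4452, 186, 5267, 11111) # 50.49
#' @export
normalized_edge_proportion <- function(r, s, g_i, g, digits = 2) {
  if (any(c(r, s, g_i, g) <= 0)) abort("all counts must be positive")
  if (g_i > g) abort("g_i cannot exceed g")
  x <- (r / s) * (g / g_i)
  if (is.null(digits)) x else round(x, digits)
}

#' Degree-centrality correlation between two networks
#'
#' Pearson correlation of the per-node degree centralities of two networks
#' on the same node set, e.g. an M-GSN against the matching R-GSN; a high
#' correlation means hubs in one network tend to be hubs in the other.
#'
#' @param net_a,net_b `gsn` objects with identical node sets (>= 3 nodes).
#' @return List with `r` (Pearson correlation) and `r_squared`.
#' @export
degree_correlation <- function(net_a, net_b) {
  ca <- centrality_report(net_a); cb <- centrality_report(net_b)
  if (!identical(ca$set, cb$set)) abort("node sets differ")
  if (nrow(ca) < 3L) abort("need at least 3 nodes")
  if (stats::sd(ca$dc) == 0 || stats::sd(cb$dc) == 0) {
    abort("degree centrality has zero variance; correlation undefined")
  }
  r <- cor(ca$dc, cb$dc, method = "pearson")
  list(r = r, r_squared = r^2)
}

edge_keys <- function(net) {
  e <- net$edges
  unique(paste(pmin(e$gs1, e$gs2), pmax(e$gs1, e$gs2), sep = "\r"))
}

#' Compare the edge sets of two undirected networks
#'
#' Reports the shared (unordered) edge count, the percentage of the edge
#' union that is shared — e.g. 1461 / (2230 + 3274 - 1461) = 36.14% for a
#' co-membership versus regulatory network — and the percentage of the
#' reference network `net_b` that is shared.
#'
#' @param net_a,net_b Undirected `gsn` objects on a shared node namespace.
#' @return Tibble with one row: `n_a`, `n_b`, `shared`, `pct_union`,
#'   `pct_reference`.
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "gsn"), inherits(net_b, "gsn"))
  if (net_a$directed || net_b$directed) {
    abort("compare_networks needs undirected networks; see to_undirected()")
  }
  ka <- edge_keys(net_a); kb <- edge_keys(net_b)
  shared <- length(intersect(ka, kb))
  union_n <- length(ka) + length(kb) - shared
  tibble(
    n_a = length(ka), n_b = length(kb), shared = shared,
    pct_union = if (union_n == 0L) 0 else 100 * shared / union_n,
    pct_reference = if (length(kb) == 0L) 0 else 100 * shared / length(kb)
  )
}

#' Random-network overlap null for an observed edge overlap
#'
#' Generates `reps` Erdos-Renyi G(n, m) graphs (exactly `n_edges` distinct
#' unordered pairs drawn uniformly over the `nodes`), records each one's
#' edge overlap with the reference network, and computes a two-sided
#' Fisher's exact p-value for the observed overlap of a real network pair
#' against the universe of all C(n, 2) possible edges.
#'
#' @param nodes Character vector of node names (or a node count).
#' @param n_edges Edges per random replicate; at most C(n, 2).
#' @param reference Undirected `gsn` whose edges the replicates are
#'   intersected with.
#' @param observed Optional undirected `gsn`; when supplied, the Fisher
#'   test uses its observed edge overlap with `reference`. When absent
#'   `fisher_p` is `NA`.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed; the overlap sequence is reproducible.
#' @return List with `overlaps` (integer vector, length `reps`), `mean`,
#'   `min`, `max`, `reps`, `seed`, and `fisher_p`.
#' @export
random_overlap_null <- function(nodes, n_edges, reference, observed = NULL,
                                reps = 1000, seed = 1L) {
  if (length(nodes) == 1L && is.numeric(nodes)) {
    nodes <- paste0("V", seq_len(nodes))
  }
  n <- length(nodes)
  total <- choose(n, 2)
  if (reps < 1L) abort("reps must be >= 1")
  if (n_edges > total) abort("n_edges exceeds the number of possible pairs")
  stopifnot(inherits(reference, "gsn"), !reference$directed)
  ref_keys <- edge_keys(reference)

  # map an index in 1..C(n,2) to an unordered pair key
  pair_key <- function(idx) {
    i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * (idx - 1))) / 2) + 1
    base <- (i - 1) * n - i * (i - 1) / 2
    j <- idx - base + i
    a <- nodes[i]; b <- nodes[j]
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  }
  old <- get_rng_state()
  set.seed(seed)
  on.exit(restore_rng_state(old), add = TRUE)
  overlaps <- integer(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(total, n_edges)
    overlaps[r] <- sum(pair_key(idx) %in% ref_keys)
  }
  fisher_p <- NA_real_
  if (!is.null(observed)) {
    cmp <- compare_networks(observed, reference)
    a <- cmp$shared
    b <- cmp$n_a - cmp$shared
    cc <- cmp$n_b - cmp$shared
    d <- total - cmp$n_a - cmp$n_b + cmp$shared
    fisher_p <- fisher_exact(a, b, cc, round(d))
  }
  list(overlaps = overlaps, mean = mean(overlaps), min = min(overlaps),
       max = max(overlaps), reps = reps, seed = seed, fisher_p = fisher_p)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
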