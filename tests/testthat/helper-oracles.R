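# Independent brute-force oracles used across the suite. These deliberately
# avoid phyper/p.adjust/fisher.test/igraph so that each check compares two
# genuinely different routes to the same number.

# P(X >= k) (or P(X = k)) by exhaustive enumeration of all C(N, n) draws,
# with the K marked items being 1..K.
enum_hyper <- function(N, n, K, k, point = FALSE) {
  if (n == 0L || N == 0L) return(if (point) as.numeric(k == 0) else 1)
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  if (point) mean(marked == k) else mean(marked >= k)
}

# Literal-definition Benjamini-Hochberg, O(m^2): q_i = min over all j with
# p_j >= p_i of m * p_j / rank(p_j), rejection by the step-up cutoff.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  r <- integer(m); r[o] <- seq_len(m)
  q <- vapply(seq_len(m), function(i) {
    js <- which(r >= r[i])
    min(1, min(m * p[js] / r[js]))
  }, numeric(1))
  cut <- 0L
  for (i in seq_len(m)) if (sort(p)[i] <= i * alpha / m) cut <- i
  rejected <- r <= cut
  list(q = q, rejected = rejected)
}

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, using choose() only.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Unnormalized shortest-path betweenness by explicit path enumeration
# (all simple paths between every ordered/unordered node pair).
betweenness_oracle <- function(edges, nodes, directed) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    out <- edges$gs2[edges$gs1 == v]
    if (!directed) out <- c(out, edges$gs1[edges$gs2 == v])
    unique(out)
  })
  all_paths <- function(from, to) {
    found <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        found[[length(found) + 1L]] <<- path
        return()
      }
      for (nb in setdiff(adj[[last]], path)) walk(c(path, nb))
    }
    walk(from)
    found
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  if (!directed) pairs <- pairs[pairs$s < pairs$t, ]
  for (i in seq_len(nrow(pairs))) {
    ps <- all_paths(pairs$s[i], pairs$t[i])
    if (length(ps) == 0L) next
    lens <- lengths(ps)
    sp <- ps[lens == min(lens)]
    for (path in sp) {
      inner <- path[-c(1, length(path))]
      if (length(inner) > 0L) {
        btw[inner] <- btw[inner] + 1 / length(sp)
      }
    }
  }
  btw
}

# Tiny constructors -----------------------------------------------------

gsc_from_list <- function(sets, universe = NULL, name = "test") {
  gene_set_collection(
    tibble::tibble(
      set = rep(names(sets), lengths(sets)),
      gene = unlist(sets, use.names = FALSE)
    ),
    name = name, universe = universe
  )
}

regnet_from_pairs <- function(src, tgt) {
  regulation_network(tibble::tibble(source = src, target = tgt))
}

undirected_net <- function(...) read_network_edges(c(...))

directed_net <- function(...) read_network_edges(c(...), directed = TRUE)
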