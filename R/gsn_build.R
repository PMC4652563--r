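empty_edges <- function() {
  tibble(gs1 = character(), gs2 = character(), n = integer(), K = integer(),
         k = integer(), N = integer(), p = double(), q = double())
}

new_gsn <- function(nodes, edges, tests, directed, kind, alpha,
                    mode = "upper-tail", universe_size = NA_integer_,
                    regulation_count = NA_integer_) {
  edges <- arrange(as_tibble(edges), .data$p, .data$gs1, .data$gs2)
  structure(
    list(
      nodes = as_tibble(nodes),
      edges = edges,
      tests = as_tibble(tests),
      directed = directed,
      kind = kind,
      alpha = alpha,
      mode = mode,
      universe_size = universe_size,
      regulation_count = regulation_count,
      finalized = TRUE
    ),
    class = "gsn"
  )
}

#' @export
print.gsn <- function(x, ...) {
  cat(sprintf("<gsn: %s> %s, %d nodes, %d significant edges (alpha = %g)\n",
              x$kind, if (x$directed) "directed" else "undirected",
              nrow(x$nodes), nrow(x$edges), x$alpha))
  invisible(x)
}

node_table <- function(collection) {
  sets <- collection$sets
  if (!"collection" %in% names(sets)) sets$collection <- collection$name
  select(arrange(sets, .data$set), "set", "collection")
}

vec_upper_tail <- function(k, N, n, K, mode) {
  if (mode == "point") {
    dhyper(k, m = K, n = N - K, k = n)
  } else {
    ifelse(k == 0, 1,
           phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
  }
}

#' Co-membership test parameters for a pair of gene sets
#'
#' For gene sets GS1 and GS2 in a universe of `universe_size` genes, the
#' shared-gene count is tested against the hypergeometric model with
#' N = universe size, n = |GS1|, K = |GS2|, k = |GS1 intersect GS2|.
#'
#' @param gs1,gs2 Character vectors of gene symbols (already canonical).
#' @param universe_size Number of genes in the universe.
#' @return A [hypergeom_params()].
#' @export
comembership_params <- function(gs1, gs2, universe_size) {
  gs1 <- unique(canonical_symbols(gs1)); gs2 <- unique(canonical_symbols(gs2))
  if (length(gs1) > universe_size || length(gs2) > universe_size) {
    abort("gene set larger than the universe")
  }
  hypergeom_params(N = universe_size, n = length(gs1), K = length(gs2),
                   k = length(intersect(gs1, gs2)))
}

#' Build a co-membership gene set network (M-GSN)
#'
#' Tests every unordered pair of gene sets in the collection for a
#' significantly large number of shared genes (hypergeometric upper tail),
#' adjusts all pairs as one Benjamini-Hochberg family, and connects a pair
#' with an undirected edge when it is rejected at FDR `alpha`. Isolated
#' nodes are retained.
#'
#' @param collection A [gene_set_collection()].
#' @param alpha False discovery rate, default 0.05.
#' @param mode P-value mode passed to the hypergeometric test:
#'   `"upper-tail"` (default) or `"point"`.
#' @param universe_size Population size N; defaults to the collection's own
#'   universe size.
#' @return A `gsn` object. `$edges` holds the significant edges with their
#'   (n, K, k, N, p, q); `$tests` holds every tested pair.
#' @export
build_mgsn <- function(collection, alpha = 0.05,
                       mode = c("upper-tail", "point"),
                       universe_size = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  mode <- match.arg(mode)
  N <- universe_size %||% length(collection$universe)
  sets <- gsc_genes(collection)
  nm <- sort(names(sets))
  s <- length(nm)
  nodes <- node_table(collection)
  if (s < 2L) {
    return(new_gsn(nodes, empty_edges(), empty_edges(), FALSE, "M",
                   alpha, mode, universe_size = N))
  }
  genes <- collection$universe
  X <- matrix(FALSE, nrow = s, ncol = length(genes),
              dimnames = list(nm, genes))
  for (i in seq_len(s)) X[i, sets[[nm[i]]]] <- TRUE
  sizes <- rowSums(X)
  if (any(sizes > N)) abort("gene set larger than the universe")
  O <- tcrossprod(X * 1)
  ij <- which(upper.tri(O), arr.ind = TRUE)
  tests <- tibble(
    gs1 = nm[ij[, 1]], gs2 = nm[ij[, 2]],
    n = as.integer(sizes[ij[, 1]]), K = as.integer(sizes[ij[, 2]]),
    k = as.integer(O[ij]), N = as.integer(N)
  )
  tests$p <- vec_upper_tail(tests$k, tests$N, tests$n, tests$K, mode)
  adj <- bh_fdr(tests$p, alpha)
  tests$q <- adj$q
  tests <- arrange(tests, .data$p, .data$gs1, .data$gs2)
  edges <- filter(tests, .data$q <= alpha)
  new_gsn(nodes, edges, tests, FALSE, "M", alpha, mode, universe_size = N)
}

#' Regulatory test parameters for an ordered pair of gene sets
#'
#' Shared genes are removed first: with U1 = GS1 minus GS2 and
#' U2 = GS2 minus GS1, the counts over the regulation edge list are
#' N = total regulations, n = regulations leaving U1 for targets outside
#' GS1, K = regulations entering U2 from sources outside GS2, and
#' k = regulations from U1 into U2. Under this (default, `"canonical"`)
#' reading k <= min(n, K) holds by construction. The `"literal"` variant
#' instead counts n as regulations from GS1 to targets outside GS2 and K as
#' regulations into GS2 from sources outside GS2; there k can exceed the
#' support and is clipped with a warning.
#'
#' @param gs1,gs2 Character vectors of gene symbols.
#' @param regnet A [regulation_network()].
#' @param count_variant `"canonical"` (default) or `"literal"`.
#' @return A [hypergeom_params()], or `NULL` when the pair is untestable
#'   (no regulations, or identical membership).
#' @export
regulatory_params <- function(gs1, gs2, regnet,
                              count_variant = c("canonical", "literal")) {
  count_variant <- match.arg(count_variant)
  stopifnot(inherits(regnet, "regulation_network"))
  gs1 <- unique(canonical_symbols(gs1)); gs2 <- unique(canonical_symbols(gs2))
  N <- nrow(regnet$edges)
  u1 <- setdiff(gs1, gs2); u2 <- setdiff(gs2, gs1)
  if (N == 0L || (length(u1) == 0L && length(u2) == 0L)) return(NULL)
  src <- regnet$edges$source; tgt <- regnet$edges$target
  s_u1 <- src %in% u1; t_u2 <- tgt %in% u2
  if (count_variant == "canonical") {
    n <- sum(s_u1 & !(tgt %in% gs1))
    K <- sum(t_u2 & !(src %in% gs2))
  } else {
    n <- sum((src %in% gs1) & !(tgt %in% gs2))
    K <- sum(t_u2 & !(src %in% gs2))
  }
  k <- sum(s_u1 & t_u2)
  lo <- max(0L, n + K - N); hi <- min(n, K)
  if (k < lo || k > hi) {
    warn(sprintf("regulatory k = %d clipped into [%d, %d]", k, lo, hi))
    k <- min(max(k, lo), hi)
  }
  hypergeom_params(N = N, n = n, K = K, k = k)
}

# ordered-pair regulation counts for all set pairs at once; returns a tibble
# of testable pairs (gs1, gs2, n, K, k, N)
rgsn_count_table <- function(collection, regnet, count_variant,
                             restrict_universe = FALSE) {
  sets <- gsc_genes(collection)
  nm <- sort(names(sets))
  s <- length(nm)
  ed <- regnet$edges
  if (restrict_universe) {
    ed <- filter(ed, .data$source %in% collection$universe,
                 .data$target %in% collection$universe)
  }
  N <- nrow(ed)
  if (s < 2L || N == 0L) return(empty_edges()[0, c(1:6)])
  E <- nrow(ed)
  srcIn <- matrix(FALSE, s, E); tgtIn <- matrix(FALSE, s, E)
  for (i in seq_len(s)) {
    srcIn[i, ] <- ed$source %in% sets[[nm[i]]]
    tgtIn[i, ] <- ed$target %in% sets[[nm[i]]]
  }
  sig <- vapply(nm, function(x) paste(sort(sets[[x]]), collapse = "\r"),
                character(1))
  res <- vector("list", s * (s - 1L))
  pos <- 0L
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      if (i == j) next
      if (sig[i] == sig[j]) next   # identical membership: untestable
      u1src <- srcIn[i, ] & !srcIn[j, ]   # source in U1 = Si \ Sj
      u2tgt <- tgtIn[j, ] & !tgtIn[i, ]   # target in U2 = Sj \ Si
      if (count_variant == "canonical") {
        n <- sum(u1src & !tgtIn[i, ])
        K <- sum(u2tgt & !srcIn[j, ])
      } else {
        n <- sum(srcIn[i, ] & !tgtIn[j, ])
        K <- sum(u2tgt & !srcIn[j, ])
      }
      k <- sum(u1src & u2tgt)
      pos <- pos + 1L
      res[[pos]] <- c(i, j, n, K, k)
    }
  }
  if (pos == 0L) return(empty_edges()[0, c(1:6)])
  m <- do.call(rbind, res[seq_len(pos)])
  out <- tibble(gs1 = nm[m[, 1]], gs2 = nm[m[, 2]],
                n = as.integer(m[, 3]), K = as.integer(m[, 4]),
                k = as.integer(m[, 5]), N = as.integer(N))
  lo <- pmax(0L, out$n + out$K - out$N); hi <- pmin(out$n, out$K)
  bad <- out$k < lo | out$k > hi
  if (any(bad)) {
    warn(sprintf("%d pair(s) had k clipped into the hypergeometric support",
                 sum(bad)))
    out$k <- pmin(pmax(out$k, lo), hi)
  }
  out
}

#' Build a regulatory gene set network (R-GSN)
#'
#' Tests every ordered pair (GS1, GS2) of gene sets for a significantly
#' large number of regulations running from GS1's unique genes to GS2's
#' unique genes (see [regulatory_params()]), adjusts all ordered pairs as
#' one Benjamini-Hochberg family, and connects significant pairs with a
#' directed edge GS1 -> GS2. Both directions of a pair may be significant
#' ("loops" at the set level); both are retained.
#'
#' @inheritParams build_mgsn
#' @param regnet A [regulation_network()] sharing the collection's symbol
#'   namespace.
#' @param count_variant See [regulatory_params()].
#' @param restrict_universe If `TRUE`, the regulation total N counts only
#'   regulations whose source and target both lie in the collection's
#'   universe; default uses all loaded regulations.
#' @return A directed `gsn`.
#' @export
build_rgsn <- function(collection, regnet, alpha = 0.05,
                       mode = c("upper-tail", "point"),
                       count_variant = c("canonical", "literal"),
                       restrict_universe = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  mode <- match.arg(mode)
  count_variant <- match.arg(count_variant)
  nodes <- node_table(collection)
  tests <- rgsn_count_table(collection, regnet, count_variant,
                            restrict_universe)
  if (nrow(tests) == 0L) {
    return(new_gsn(nodes, empty_edges(), empty_edges(), TRUE, "R", alpha,
                   mode, regulation_count = nrow(regnet$edges)))
  }
  tests$p <- vec_upper_tail(tests$k, tests$N, tests$n, tests$K, mode)
  adj <- bh_fdr(tests$p, alpha)
  tests$q <- adj$q
  tests <- arrange(tests, .data$p, .data$gs1, .data$gs2)
  edges <- filter(tests, .data$q <= alpha)
  new_gsn(nodes, edges, tests, TRUE, "R", alpha, mode,
          universe_size = length(collection$universe),
          regulation_count = tests$N[1])
}

#' Discard edge directions of a directed gene set network
#'
#' Each reciprocal significant pair A -> B, B -> A (a set-level "loop")
#' collapses to a single undirected edge that keeps the smaller p-value;
#' the original directed records are retained in the attribute
#' `directed_edges`.
#'
#' @param net A directed `gsn`.
#' @return An undirected `gsn` of kind `"R-undirected"` (or
#'   `"<kind>-undirected"`).
#' @export
to_undirected <- function(net) {
  stopifnot(inherits(net, "gsn"))
  if (!net$directed) abort("network is already undirected")
  ed <- net$edges
  if (nrow(ed) > 0L) {
    ed <- ed |>
      mutate(a = pmin(.data$gs1, .data$gs2), b = pmax(.data$gs1, .data$gs2)) |>
      group_by(.data$a, .data$b) |>
      arrange(.data$p, .by_group = TRUE) |>
      summarise(n = .data$n[1], K = .data$K[1], k = .data$k[1],
                N = .data$N[1], p = .data$p[1], q = .data$q[1],
                .groups = "drop") |>
      rename(gs1 = "a", gs2 = "b")
  } else {
    ed <- empty_edges()
  }
  out <- new_gsn(net$nodes, ed, net$tests, FALSE,
                 paste0(net$kind, "-undirected"), net$alpha, net$mode,
                 universe_size = net$universe_size,
                 regulation_count = net$regulation_count)
  attr(out, "directed_edges") <- net$edges
  out
}

#' Exclusive network (edge-set difference)
#'
#' Keeps the edges of `base` whose unordered pair does not occur in
#' `subtract` — e.g. the exclusive R-GSN ("R-GSN minus M-GSN") containing
#' regulatory relationships not explained by gene sharing. Nodes are
#' preserved.
#'
#' @param base,subtract Undirected `gsn` objects over the same node
#'   namespace.
#' @return An undirected `gsn` of kind `"exclusive"`.
#' @export
exclusive_network <- function(base, subtract) {
  stopifnot(inherits(base, "gsn"), inherits(subtract, "gsn"))
  if (base$directed || subtract$directed) {
    abort("exclusive_network needs undirected networks; see to_undirected()")
  }
  keys <- function(e) paste(pmin(e$gs1, e$gs2), pmax(e$gs1, e$gs2), sep = "\r")
  ed <- base$edges[!keys(base$edges) %in% keys(subtract$edges), , drop = FALSE]
  new_gsn(base$nodes, ed, base$tests, FALSE, "exclusive", base$alpha,
          base$mode, universe_size = base$universe_size,
          regulation_count = base$regulation_count)
}
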