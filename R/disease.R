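#' Select disease-related gene sets by overlap with a disease gene list
#'
#' The disease gene list is treated as one extra gene set: for every set in
#' the combined collection, the overlap with the list is tested with the
#' co-membership hypergeometric model (N = combined universe size, n = set
#' size, K = list size, k = overlap), and all sets are adjusted as a single
#' Benjamini-Hochberg family.
#'
#' @param combined A [gene_set_collection()], normally the output of
#'   [gsc_combine()] over several collections.
#' @param disease A disease gene list from [read_gene_list()], or a
#'   character vector of symbols.
#' @param alpha False discovery rate for selection, default 0.05.
#' @param mode Hypergeometric mode, see [hypergeom_pvalue()].
#' @param intersect_disease_list If `TRUE`, K counts only the listed genes
#'   present in the universe; the default uses the full list size.
#' @return Tibble sorted by ascending p with columns `set`, `collection`,
#'   `n` (set size), `k` (overlap), `N`, `K`, `p`, `q`, `selected`.
#' @export
select_related_sets <- function(combined, disease, alpha = 0.05,
                                mode = c("upper-tail", "point"),
                                intersect_disease_list = FALSE) {
  stopifnot(inherits(combined, "gene_set_collection"))
  mode <- match.arg(mode)
  genes <- if (is.data.frame(disease)) disease$gene else disease
  genes <- unique(canonical_symbols(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) abort("disease gene list is empty")
  N <- length(combined$universe)
  K <- if (intersect_disease_list) {
    length(intersect(genes, combined$universe))
  } else {
    length(genes)
  }
  sets <- gsc_genes(combined)
  origin <- node_table(combined)
  rows <- tibble(
    set = names(sets),
    n = unname(lengths(sets)),
    k = unname(vapply(sets, function(g) length(intersect(g, genes)),
                      integer(1))),
    N = N, K = K
  )
  rows$k <- pmin(rows$k, pmin(rows$n, rows$K))
  rows$p <- vec_upper_tail(rows$k, rows$N, rows$n, rows$K, mode)
  adj <- bh_fdr(rows$p, alpha)
  rows$q <- adj$q
  rows$selected <- adj$rejected
  rows |>
    left_join(origin, by = "set") |>
    select("set", "collection", "n", "k", "N", "K", "p", "q", "selected") |>
    arrange(.data$p, .data$set)
}

#' Build a disease-specific regulatory gene set network
#'
#' Restricts the combined collection to the disease-related sets (the
#' `selected` rows of [select_related_sets()]) and builds the directed
#' R-GSN among them with [build_rgsn()]. Node rows record each set's
#' collection of origin.
#'
#' @param selection Output of [select_related_sets()], or a character
#'   vector of set names.
#' @param combined The combined [gene_set_collection()] the selection came
#'   from.
#' @param regnet A [regulation_network()].
#' @inheritParams build_rgsn
#' @return A directed `gsn` of kind `"disease-R"`.
#' @export
build_disease_rgsn <- function(selection, combined, regnet, alpha = 0.05,
                               mode = c("upper-tail", "point"),
                               count_variant = c("canonical", "literal"),
                               restrict_universe = FALSE) {
  keep <- if (is.data.frame(selection)) {
    selection$set[selection$selected %||% rep(TRUE, nrow(selection))]
  } else {
    selection
  }
  if (length(keep) == 0L) abort("no gene sets selected for the disease network")
  sub <- gsc_subset(combined, keep)
  if ("collection" %in% names(combined$sets)) {
    sub$sets <- left_join(sub$sets,
                          select(combined$sets, "set", "collection"),
                          by = "set")
  }
  net <- build_rgsn(sub, regnet, alpha = alpha, mode = mode,
                    count_variant = count_variant,
                    restrict_universe = restrict_universe)
  net$kind <- "disease-R"
  net
}
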