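#' Specification for a synthetic gene-set / regulation fixture
#'
#' Describes a seeded synthetic study: a gene universe, a family of gene
#' sets with small-set-skewed sizes and a controlled pairwise overlap, a
#' sparse background of random gene regulations, and a handful of planted
#' ordered set pairs whose unique genes regulate each other at an elevated
#' rate. Generation is a pure function of the spec (seed included).
#'
#' Overlap scheme: a shared core pool of `core_size` genes is set aside;
#' each set draws `round(overlap * size)` genes from the core (without
#' replacement within the set) and the rest from a private, never-reused
#' block of the universe. Overlap between two sets can therefore occur only
#' inside the core, giving the closed-form expected pairwise overlap
#' `c1 * c2 / core_size` for core draws c1, c2; `overlap = 0` yields
#' exactly disjoint sets.
#'
#' @param universe_size Number of genes in the universe.
#' @param n_sets Number of gene sets.
#' @param size_range Integer range of set sizes; sizes are drawn with a
#'   small-set skew (probability proportional to 1/size), mirroring the
#'   empirical excess of 2-20 gene sets over larger ones in curated
#'   collections.
#' @param overlap Pairwise overlap fraction in \[0, 1).
#' @param planted Tibble (or data frame) of planted ordered pairs with
#'   columns `gs1`, `gs2`, or `NULL`.
#' @param multiplier Regulation-rate multiplier for planted pairs (>= 1).
#' @param background_rate Per ordered gene pair Bernoulli regulation rate.
#' @param core_size Size of the shared core pool; defaults to
#'   `max(20, ceiling(0.05 * universe_size))`.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(universe_size = 800, n_sets = 30,
                         size_range = c(2L, 20L), overlap = 0.2,
                         planted = NULL, multiplier = 50,
                         background_rate = 0.001,
                         core_size = NULL, seed = 1L) {
  if (overlap < 0 || overlap >= 1) abort("overlap fraction must be in [0, 1)")
  if (multiplier < 1) abort("multiplier must be >= 1")
  if (background_rate < 0 || background_rate > 1) {
    abort("background_rate must be in [0, 1]")
  }
  if (background_rate * multiplier > 1) {
    abort("multiplier x background_rate exceeds 1")
  }
  structure(
    list(
      universe_size = as.integer(universe_size),
      n_sets = as.integer(n_sets),
      size_range = as.integer(size_range),
      overlap = overlap,
      planted = if (is.null(planted)) NULL else as_tibble(planted),
      multiplier = multiplier,
      background_rate = background_rate,
      core_size = core_size %||% max(20L, ceiling(0.05 * universe_size)),
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# independent RNG substream per component, so adding a fixture component
# never perturbs the draws of another
with_substream <- function(spec, offset, code) {
  old <- get_rng_state()
  set.seed(spec$seed * 97L + offset)
  on.exit(restore_rng_state(old), add = TRUE)
  force(code)
}

#' Generate a synthetic gene set collection
#'
#' @param spec A [fixture_spec()].
#' @return A [gene_set_collection()] named `"synthetic"`; its universe is
#'   the full fixture universe (including genes not drawn into any set is
#'   not possible here: the universe is the union of members, so the
#'   fixture universe is attached as the explicit universe).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  genes <- sprintf("G%05d", seq_len(spec$universe_size))
  core <- genes[seq_len(spec$core_size)]
  private_pool <- genes[-seq_len(spec$core_size)]
  with_substream(spec, 1L, {
    sizes_avail <- seq(spec$size_range[1], spec$size_range[2])
    sizes <- sample(sizes_avail, spec$n_sets, replace = TRUE,
                    prob = 1 / sizes_avail)
    n_core <- round(spec$overlap * sizes)
    n_priv <- sizes - n_core
    if (sum(n_priv) > length(private_pool)) {
      abort("universe too small for the requested sets")
    }
    if (any(n_core > length(core))) {
      abort("core pool too small for the requested overlap")
    }
    priv_idx <- c(0L, cumsum(n_priv))
    memb <- purrr::map(seq_len(spec$n_sets), function(i) {
      g <- c(
        if (n_core[i] > 0L) sample(core, n_core[i]) else character(),
        private_pool[seq.int(priv_idx[i] + 1L, length.out = n_priv[i])]
      )
      tibble(set = sprintf("SET%03d", i), gene = g)
    })
    gene_set_collection(bind_rows(memb), name = "synthetic",
                        universe = genes)
  })
}

#' Generate a synthetic regulation network with planted enrichment
#'
#' Background: every ordered pair of distinct universe genes carries a
#' regulation independently with probability `background_rate`. For each
#' planted ordered set pair (GS1, GS2), the pairs from U1 = GS1 minus GS2
#' into U2 = GS2 minus GS1 are instead drawn at
#' `background_rate * multiplier`. The returned truth table records the
#' realized (n, K, k, N) of every planted pair under
#' [regulatory_params()].
#'
#' @param collection The [gene_set_collection()] from
#'   [generate_collection()].
#' @param spec The same [fixture_spec()].
#' @return List with `regnet` (a [regulation_network()]) and `truth`
#'   (tibble `gs1`, `gs2`, `n`, `K`, `k`, `N`).
#' @export
generate_regulations <- function(collection, spec) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(spec, "fixture_spec"))
  sets <- gsc_genes(collection)
  planted <- spec$planted
  if (!is.null(planted)) {
    missing <- setdiff(c(planted$gs1, planted$gs2), names(sets))
    if (length(missing) > 0L) {
      abort(sprintf("planted pair names unknown set(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  genes <- collection$universe
  G <- length(genes)
  with_substream(spec, 2L, {
    # planted regions first (ordered gene pairs U1 x U2 per planted pair)
    planted_edges <- NULL
    planted_keys <- character()
    if (!is.null(planted) && nrow(planted) > 0L) {
      planted_edges <- purrr::pmap(planted, function(gs1, gs2, ...) {
        u1 <- setdiff(sets[[gs1]], sets[[gs2]])
        u2 <- setdiff(sets[[gs2]], sets[[gs1]])
        grid <- expand.grid(source = u1, target = u2,
                            stringsAsFactors = FALSE)
        grid <- grid[grid$source != grid$target, , drop = FALSE]
        keep <- stats::runif(nrow(grid)) <
          spec$background_rate * spec$multiplier
        list(edges = grid[keep, , drop = FALSE],
             region = paste(grid$source, grid$target, sep = "\r"))
      })
      planted_keys <- unique(unlist(lapply(planted_edges, `[[`, "region")))
      planted_edges <- bind_rows(lapply(planted_edges, `[[`, "edges"))
    }
    # background over all remaining ordered pairs (self-pairs excluded)
    total_pairs <- as.double(G) * (G - 1)
    n_bg <- rbinom(1L, size = G * (G - 1L), prob = spec$background_rate)
    bg <- NULL
    if (n_bg > 0L) {
      idx <- sample(total_pairs, n_bg)
      si <- ceiling(idx / (G - 1))
      off <- idx - (si - 1) * (G - 1)
      ti <- ifelse(off >= si, off + 1, off)
      bg <- tibble(source = genes[si], target = genes[ti])
      bg <- bg[!paste(bg$source, bg$target, sep = "\r") %in% planted_keys, ,
               drop = FALSE]
    }
    ed <- bind_rows(
      if (is.null(bg)) NULL else bg,
      if (is.null(planted_edges)) NULL else as_tibble(planted_edges)
    )
    if (is.null(ed) || nrow(ed) == 0L) {
      ed <- tibble(source = character(), target = character())
    }
    ed$provenance <- "synthetic"
    regnet <- if (nrow(ed) == 0L) {
      structure(list(edges = tibble(source = character(), target = character()),
                     provenance = tibble(source = character(),
                                         target = character(),
                                         provenance = character()),
                     n_records = 0L),
                class = "regulation_network")
    } else {
      regulation_network(ed)
    }
    truth <- if (is.null(planted) || nrow(planted) == 0L) {
      tibble(gs1 = character(), gs2 = character(), n = integer(),
             K = integer(), k = integer(), N = integer())
    } else {
      purrr::pmap_dfr(planted, function(gs1, gs2, ...) {
        prm <- regulatory_params(sets[[gs1]], sets[[gs2]], regnet)
        tibble(gs1 = gs1, gs2 = gs2,
               n = prm$n %||% 0L, K = prm$K %||% 0L,
               k = prm$k %||% 0L, N = prm$N %||% 0L)
      })
    }
    list(regnet = regnet, truth = truth)
  })
}
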