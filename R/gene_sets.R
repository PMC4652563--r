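#' Canonicalize gene symbols
#'
#' Gene symbols are stored in a single canonical form: leading/trailing
#' whitespace stripped and letters uppercased. This is a safety net for
#' mixed-case input, not a substitute for a proper identifier mapping
#' (see [map_gene_ids()]).
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of canonical symbols.
#' @export
canonical_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a gene set collection
#'
#' A gene set collection is a named family of gene sets over a common gene
#' universe. Internally it is a long membership table (one row per
#' set-gene pair); the universe defaults to the union of all member genes.
#'
#' @param membership Data frame with columns `set` and `gene`, optionally
#'   `description`. Symbols are canonicalized and duplicates within a set
#'   collapsed.
#' @param name Collection name.
#' @param universe Optional character vector overriding the gene universe;
#'   must contain every member gene.
#' @return A `gene_set_collection` object.
#' @examples
#' gsc <- gene_set_collection(
#'   tibble::tibble(set = c("S1", "S1", "S2"), gene = c("A", "B", "B"))
#' )
#' gsc_sizes(gsc)
#' @export
gene_set_collection <- function(membership, name = "collection", universe = NULL) {
  membership <- as_tibble(membership)
  if (!all(c("set", "gene") %in% names(membership))) {
    abort("`membership` needs columns `set` and `gene`.")
  }
  if (!"description" %in% names(membership)) membership$description <- ""
  membership <- membership |>
    mutate(
      set = as.character(.data$set),
      gene = canonical_symbols(.data$gene)
    ) |>
    filter(nzchar(.data$set), nzchar(.data$gene)) |>
    distinct(.data$set, .data$gene, .keep_all = TRUE)
  if (nrow(membership) == 0L) abort("collection has no set memberships")
  genes <- sort(unique(membership$gene))
  if (is.null(universe)) {
    universe <- genes
  } else {
    universe <- sort(unique(canonical_symbols(universe)))
    missing <- setdiff(genes, universe)
    if (length(missing) > 0L) {
      abort(sprintf(
        "universe is missing %d member gene(s), e.g. %s",
        length(missing), paste(head(missing, 3), collapse = ", ")
      ))
    }
  }
  sets <- membership |>
    group_by(.data$set) |>
    summarise(description = .data$description[1], size = n(), .groups = "drop")
  structure(
    list(
      name = name,
      sets = sets,
      membership = select(membership, "set", "gene"),
      universe = universe
    ),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %s: %d sets, %d universe genes\n",
    x$name, nrow(x$sets), length(x$universe)
  ))
  invisible(x)
}

#' Gene set sizes
#'
#' @param collection A [gene_set_collection()].
#' @return Tibble with columns `set`, `description`, `size`.
#' @export
gsc_sizes <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  collection$sets
}

#' Gene sets as a named list
#'
#' @param collection A [gene_set_collection()].
#' @return Named list of character vectors (one per set).
#' @export
gsc_genes <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  split(collection$membership$gene, collection$membership$set)
}

#' Restrict a collection to a subset of its sets
#'
#' The universe is kept unchanged, matching the construction of
#' disease-specific networks where selected sets are still tested against
#' the full combined universe.
#'
#' @param collection A [gene_set_collection()].
#' @param sets Character vector of set names to keep.
#' @return A `gene_set_collection`.
#' @export
gsc_subset <- function(collection, sets) {
  stopifnot(inherits(collection, "gene_set_collection"))
  unknown <- setdiff(sets, collection$sets$set)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown set name(s): %s", paste(head(unknown, 3), collapse = ", ")))
  }
  gene_set_collection(
    filter(collection$membership, .data$set %in% sets),
    name = collection$name,
    universe = collection$universe
  )
}

#' Merge collections into one global collection
#'
#' Gene sets are kept as-is; when the same set name occurs in more than one
#' collection, names are disambiguated by prefixing the collection name
#' (`"KEGG::Cell cycle"`). The merged universe is the union of the member
#' genes of all collections. The source collection of every set is recorded
#' and carried into downstream networks.
#'
#' @param ... [gene_set_collection()] objects, optionally named.
#' @param name Name for the merged collection.
#' @return A `gene_set_collection` with an extra `collection` column in
#'   `$sets`.
#' @export
gsc_combine <- function(..., name = "combined") {
  colls <- list(...)
  if (length(colls) == 1L && is.list(colls[[1]]) &&
      !inherits(colls[[1]], "gene_set_collection")) {
    colls <- colls[[1]]
  }
  stopifnot(length(colls) >= 1L)
  labels <- names(colls) %||% rep("", length(colls))
  labels <- ifelse(nzchar(labels), labels,
                   vapply(colls, function(x) x$name, character(1)))
  tabs <- purrr::map2(colls, labels, function(cl, lab) {
    cl$membership |>
      left_join(select(cl$sets, "set", "description"), by = "set") |>
      mutate(collection = lab)
  })
  long <- bind_rows(tabs)
  dup <- long |> distinct(.data$set, .data$collection) |> count(.data$set) |>
    filter(.data$n > 1L) |> pull("set")
  if (length(dup) > 0L) {
    long <- mutate(long, set = ifelse(.data$set %in% dup,
                                      paste0(.data$collection, "::", .data$set),
                                      .data$set))
  }
  out <- gene_set_collection(select(long, "set", "gene", "description"),
                             name = name)
  origin <- long |> distinct(.data$set, .data$collection)
  out$sets <- left_join(out$sets, origin, by = "set")
  out
}

#' Read a GMT gene set file
#'
#' One gene set per line: set name, description, then member genes, all
#' tab-separated (the MSigDB exchange format). Duplicate symbols within a
#' line are collapsed after canonicalization.
#'
#' @param path File path, or a character vector of lines.
#' @param name Collection name (defaults to the file name).
#' @param universe Optional universe override, passed to
#'   [gene_set_collection()].
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, name = NULL, universe = NULL) {
  if (length(path) == 1L && file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    if (is.null(name)) name <- basename(path)
  } else {
    lines <- path
    if (is.null(name)) name <- "collection"
  }
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("GMT parse error: line %d has %d field(s), need >= 3",
                  idx[bad[1]], lengths(fields)[bad[1]]))
  }
  set_names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(set_names)) {
    abort(sprintf("duplicate set name in GMT: %s",
                  set_names[duplicated(set_names)][1]))
  }
  long <- tibble(
    set = rep(set_names, lengths(fields) - 2L),
    description = rep(vapply(fields, `[[`, character(1), 2L),
                      lengths(fields) - 2L),
    gene = unlist(lapply(fields, function(f) f[-(1:2)]), use.names = FALSE)
  )
  gene_set_collection(long, name = name, universe = universe)
}

#' Write a collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- gsc_genes(collection)
  desc <- setNames(collection$sets$description, collection$sets$set)
  nm <- sort(names(sets))
  lines <- vapply(nm, function(s) {
    paste(c(s, desc[[s]], sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a disease gene list (one symbol per line)
#'
#' @param path File path or character vector of lines.
#' @param name List name.
#' @return A tibble with one column `gene` (canonical, deduplicated), with
#'   attribute `name`.
#' @export
read_gene_list <- function(path, name = "disease") {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  genes <- unique(canonical_symbols(lines[nzchar(trimws(lines))]))
  if (length(genes) == 0L) abort("gene list is empty")
  out <- tibble(gene = genes)
  attr(out, "name") <- name
  out
}

#' Remap gene identifiers
#'
#' Applies a symbol-to-symbol mapping to a collection or regulation network
#' (e.g. onto NCBI official gene symbols). Membership is re-deduplicated
#' after mapping, so a mapping that sends two members of a set to the same
#' symbol collapses them (counted in the returned log attribute, not an
#' error).
#'
#' @param x A [gene_set_collection()] or [regulation_network()].
#' @param mapping Named character vector, `old -> new` (names are old
#'   symbols). Compared after canonicalization.
#' @param unmapped Policy for symbols absent from `mapping`: `"keep"`
#'   (default) or `"drop"`.
#' @return An object of the same class; attribute `map_log` carries counts
#'   of mapped, unmapped and collapsed entries.
#' @export
map_gene_ids <- function(x, mapping, unmapped = c("keep", "drop")) {
  UseMethod("map_gene_ids")
}

map_symbols <- function(genes, mapping, unmapped) {
  from <- canonical_symbols(names(mapping))
  to <- canonical_symbols(unname(mapping))
  hit <- match(genes, from)
  out <- ifelse(is.na(hit), genes, to[hit])
  if (unmapped == "drop") out[is.na(hit)] <- NA_character_
  list(genes = out, n_mapped = sum(!is.na(hit)), n_unmapped = sum(is.na(hit)))
}

#' @export
map_gene_ids.gene_set_collection <- function(x, mapping,
                                             unmapped = c("keep", "drop")) {
  unmapped <- match.arg(unmapped)
  m <- map_symbols(x$membership$gene, mapping, unmapped)
  memb <- mutate(x$membership, gene = m$genes) |> filter(!is.na(.data$gene))
  before <- nrow(memb)
  memb <- distinct(memb, .data$set, .data$gene)
  out <- gene_set_collection(memb, name = x$name)
  attr(out, "map_log") <- list(mapped = m$n_mapped, unmapped = m$n_unmapped,
                               collapsed = before - nrow(memb))
  out
}

#' @export
map_gene_ids.regulation_network <- function(x, mapping,
                                            unmapped = c("keep", "drop")) {
  unmapped <- match.arg(unmapped)
  ms <- map_symbols(x$provenance$source, mapping, unmapped)
  mt <- map_symbols(x$provenance$target, mapping, unmapped)
  ed <- tibble(source = ms$genes, target = mt$genes,
               provenance = x$provenance$provenance) |>
    filter(!is.na(.data$source), !is.na(.data$target))
  out <- regulation_network(ed)
  attr(out, "map_log") <- list(
    mapped = ms$n_mapped + mt$n_mapped,
    unmapped = ms$n_unmapped + mt$n_unmapped,
    collapsed = nrow(x$edges) - nrow(out$edges)
  )
  out
}
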