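#' Write a gene set network to disk
#'
#' Edge-list TSV carries one row per significant edge with the columns
#' `gs1, gs2, directed, n, K, k, N, p, q`, sorted by ascending p then
#' lexicographic set names, so repeated writes of the same network are
#' byte-identical. GraphML output goes through igraph.
#'
#' @param net A finalized `gsn`.
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "gsn"))
  format <- match.arg(format)
  if (!isTRUE(net$finalized)) abort("network is not finalized")
  if (format == "graphml") {
    igraph::write_graph(as_igraph_gsn(net), path, format = "graphml")
    return(invisible(path))
  }
  ed <- net$edges |>
    mutate(directed = net$directed) |>
    select("gs1", "gs2", "directed", "n", "K", "k", "N", "p", "q") |>
    arrange(.data$p, .data$gs1, .data$gs2)
  lines <- c(
    paste(names(ed), collapse = "\t"),
    if (nrow(ed) > 0L) {
      do.call(paste, c(lapply(ed, function(col) {
        if (is.double(col)) format(col, digits = 15, trim = TRUE) else as.character(col)
      }), sep = "\t"))
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an external network edge list
#'
#' Accepts a plain two-column (or more) TSV of set-name pairs — for
#' instance a co-enrichment network produced elsewhere — and wraps it as an
#' undirected `gsn` of kind `"external"` so it can be compared against
#' built networks.
#'
#' @param path File path or character vector of lines; first two columns
#'   are the endpoints. A header row named `gs1`/`gs2` (or
#'   `source`/`target`) is detected and skipped.
#' @param nodes Optional node namespace; defaults to the endpoint union.
#' @param directed Treat rows as ordered pairs (default unordered).
#' @return A `gsn` of kind `"external"` with NA statistics on its edges.
#' @export
read_network_edges <- function(path, nodes = NULL, directed = FALSE) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L) {
    first <- tolower(strsplit(lines[1], "\t", fixed = TRUE)[[1]][1:2])
    if (all(first %in% c("gs1", "gs2", "source", "target"))) {
      lines <- lines[-1]
    }
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    abort(sprintf("edge list line %d has fewer than 2 fields",
                  which(lengths(parts) < 2L)[1]))
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  ed <- if (directed) {
    tibble(gs1 = a, gs2 = b)
  } else {
    tibble(gs1 = pmin(a, b), gs2 = pmax(a, b))
  }
  ed <- ed |>
    distinct() |>
    mutate(n = NA_integer_, K = NA_integer_, k = NA_integer_,
           N = NA_integer_, p = NA_real_, q = NA_real_)
  nodes <- nodes %||% sort(unique(c(a, b)))
  new_gsn(tibble(set = sort(nodes), collection = "external"),
          ed, ed, directed, "external", alpha = NA_real_)
}
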