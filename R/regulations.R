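#' Construct a regulation network
#'
#' A deduplicated set of directed gene-to-gene regulation edges. Each
#' ordered (source, target) pair appears once; the provenance tags of all
#' contributing records are kept in a per-edge index. Self-regulations are
#' retained: they count toward the global regulation total but can never
#' contribute to a cross-set regulation count, because a gene cannot sit in
#' the unique parts of two different sets at once.
#'
#' @param records Data frame with columns `source` and `target`, optionally
#'   `provenance`.
#' @return A `regulation_network`: `$edges` (tibble `source`, `target`),
#'   `$provenance` (tibble `source`, `target`, `provenance`, one row per
#'   contributing tag), `$n_records` (input record count).
#' @export
regulation_network <- function(records) {
  records <- as_tibble(records)
  if (!all(c("source", "target") %in% names(records))) {
    abort("`records` needs columns `source` and `target`.")
  }
  if (!"provenance" %in% names(records)) records$provenance <- "unknown"
  records <- records |>
    mutate(source = canonical_symbols(.data$source),
           target = canonical_symbols(.data$target))
  if (any(!nzchar(records$source) | !nzchar(records$target))) {
    abort("empty source or target symbol in regulation records")
  }
  edges <- records |>
    distinct(.data$source, .data$target) |>
    arrange(.data$source, .data$target)
  structure(
    list(
      edges = edges,
      provenance = distinct(records, .data$source, .data$target,
                            .data$provenance),
      n_records = nrow(records)
    ),
    class = "regulation_network"
  )
}

#' @export
print.regulation_network <- function(x, ...) {
  cat(sprintf("<regulation_network> %d unique directed edges (%d records)\n",
              nrow(x$edges), x$n_records))
  invisible(x)
}

#' Declare a per-source filter for regulation records
#'
#' Regulation databases are filtered with source-specific quality criteria:
#' a minimum interaction score (e.g. String score >= 800), a maximum
#' binding-site quality rank (e.g. TRANSFAC quality <= 5), exclusion of
#' computationally predicted records (e.g. TRED), or no filtering at all
#' (e.g. SPIKE, curated pathway regulations).
#'
#' @param provenance Provenance tag the filter applies to.
#' @param kind One of `"accept-all"`, `"min-score"`, `"max-quality"`,
#'   `"exclude-flag"`.
#' @param threshold Numeric threshold; required for `min-score` and
#'   `max-quality`, forbidden otherwise.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(provenance,
                        kind = c("accept-all", "min-score", "max-quality",
                                 "exclude-flag"),
                        threshold = NULL) {
  kind <- match.arg(kind)
  needs <- kind %in% c("min-score", "max-quality")
  if (needs && is.null(threshold)) {
    abort(sprintf("filter kind '%s' requires a threshold", kind))
  }
  if (!needs && !is.null(threshold)) {
    abort(sprintf("filter kind '%s' takes no threshold", kind))
  }
  structure(list(provenance = provenance, kind = kind, threshold = threshold),
            class = "filter_spec")
}

apply_filter <- function(records, spec) {
  switch(spec$kind,
    "accept-all" = rep(TRUE, nrow(records)),
    "min-score" = !is.na(records$score) & records$score >= spec$threshold,
    "max-quality" = !is.na(records$quality) & records$quality <= spec$threshold,
    "exclude-flag" = is.na(records$predicted) | !records$predicted
  )
}

#' Read and filter a gene regulation table
#'
#' Reads a single-dialect TSV with header columns
#' `source  target  provenance  score  quality  predicted` (the last three
#' optional) and applies one [filter_spec()] per provenance tag before
#' deduplicating into unique directed edges.
#'
#' @param path File path or character vector of lines.
#' @param filters List of [filter_spec()]s. A record whose provenance has
#'   no filter is an error unless a filter with `provenance = "*"`
#'   (accept-all default) is supplied, or `filters` is `NULL` (keep all).
#' @return A [regulation_network()]; attribute `filter_log` is a tibble of
#'   kept/dropped counts per provenance.
#' @export
read_regulations <- function(path, filters = NULL) {
  if (length(path) == 1L && file.exists(path)) {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  } else {
    df <- readr::read_tsv(I(paste(path, collapse = "\n")),
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf("malformed regulation row at line %d: %s",
                  probs$row[1] + 1L, probs$expected[1]))
  }
  if (!all(c("source", "target") %in% names(df))) {
    abort("regulation table needs `source` and `target` columns")
  }
  if (any(is.na(df$source) | is.na(df$target) |
          !nzchar(trimws(df$source)) | !nzchar(trimws(df$target)))) {
    bad <- which(is.na(df$source) | is.na(df$target) |
                 !nzchar(trimws(df$source)) | !nzchar(trimws(df$target)))[1]
    abort(sprintf("malformed regulation row at line %d: missing source/target",
                  bad + 1L))
  }
  if (!"provenance" %in% names(df)) df$provenance <- "unknown"
  for (col in c("score", "quality")) {
    df[[col]] <- if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else NA_real_
  }
  df$predicted <- if ("predicted" %in% names(df)) {
    tolower(trimws(df$predicted)) %in% c("true", "t", "1", "yes", "y")
  } else {
    NA
  }

  keep <- rep(TRUE, nrow(df))
  if (!is.null(filters)) {
    by_tag <- setNames(filters,
                       vapply(filters, `[[`, character(1), "provenance"))
    default <- by_tag[["*"]]
    for (tag in unique(df$provenance)) {
      spec <- by_tag[[tag]] %||% default
      if (is.null(spec)) {
        abort(sprintf("no filter declared for provenance '%s' and no '*' default",
                      tag))
      }
      rows <- df$provenance == tag
      keep[rows] <- apply_filter(df[rows, , drop = FALSE], spec)
    }
  }
  log <- df |>
    mutate(kept = keep) |>
    group_by(.data$provenance) |>
    summarise(records = n(), dropped = sum(!.data$kept),
              kept = sum(.data$kept), .groups = "drop")
  inform(sprintf("read_regulations: kept %d of %d records (%d unique edges)",
                 sum(keep), nrow(df),
                 nrow(distinct(df[keep, c("source", "target")]))))
  out <- regulation_network(df[keep, , drop = FALSE])
  attr(out, "filter_log") <- log
  out
}
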