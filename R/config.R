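default_config <- function() {
  list(
    alpha = 0.05,
    mode = "upper-tail",
    count_variant = "canonical",
    restrict_universe = FALSE,
    intersect_disease_list = FALSE,
    seed = 1L,
    reps = 1000L
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON; JSON is a YAML subset) document of run options
#' and merges it over the defaults. Unknown keys are an error rather than
#' being silently ignored, so typos cannot change a run unnoticed. Also
#' accepts a `filters` block keyed by provenance tag, each entry with
#' `kind` and optional `threshold`, turned into [filter_spec()]s.
#'
#' @param path Config file path, or `NULL`/nonexistent empty document for
#'   pure defaults.
#' @return A named list: the effective configuration, with class
#'   `gsn_config` and (possibly empty) element `filters`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  cfg$filters <- NULL
  user <- if (is.null(path)) {
    list()
  } else {
    doc <- yaml::read_yaml(path)
    if (is.null(doc)) list() else doc
  }
  known <- c(names(default_config()), "filters")
  unknown <- setdiff(names(user), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(user)] <- user
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort("config: alpha must lie in (0, 1)")
  }
  if (!cfg$mode %in% c("upper-tail", "point")) {
    abort("config: mode must be 'upper-tail' or 'point'")
  }
  if (!cfg$count_variant %in% c("canonical", "literal")) {
    abort("config: count_variant must be 'canonical' or 'literal'")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$reps <- as.integer(cfg$reps)
  if (!is.null(cfg$filters)) {
    cfg$filters <- purrr::imap(cfg$filters, function(f, tag) {
      filter_spec(tag, kind = f$kind, threshold = f$threshold)
    })
    names(cfg$filters) <- NULL
  }
  structure(cfg, class = "gsn_config")
}

atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

arg_value <- function(argv, flag, default = NULL) {
  i <- which(argv == flag)
  if (length(i) == 0L) return(default)
  if (i[1] == length(argv)) abort(sprintf("flag %s needs a value", flag))
  argv[i[1] + 1L]
}

require_arg <- function(argv, flag) {
  v <- arg_value(argv, flag)
  if (is.null(v)) abort(sprintf("missing required flag %s", flag))
  v
}

require_file <- function(argv, flag) {
  v <- require_arg(argv, flag)
  if (!file.exists(v)) abort(sprintf("input file not found: %s", v))
  v
}

log_msg <- function(...) message(sprintf(...))

#' Command-line style driver
#'
#' Dispatches the workflows behind the `gsnet` command-line script:
#' `build-mgsn`, `build-rgsn`, `disease`, `analyze`, `compare`,
#' `simulate`. Each command reads its inputs, runs the corresponding
#' package functions, logs stage counts to stderr and writes its outputs
#' atomically (temp file then rename), so a failed run leaves no partial
#' files.
#'
#' @param argv Character vector of command-line tokens, e.g.
#'   `c("build-mgsn", "--gmt", "sets.gmt", "--out", "mgsn.tsv")`.
#' @return Exit status, invisibly (0 on success). Errors propagate as R
#'   conditions; the CLI wrapper converts them to a nonzero exit.
#' @export
run_gsn <- function(argv) {
  if (length(argv) == 0L) abort("no command given")
  cmd <- argv[1]
  argv <- argv[-1]
  cfg <- load_config(arg_value(argv, "--config"))
  alpha <- as.numeric(arg_value(argv, "--alpha", cfg$alpha))
  mode <- arg_value(argv, "--mode", cfg$mode)
  seed <- as.integer(arg_value(argv, "--seed", cfg$seed))

  switch(cmd,
    "build-mgsn" = {
      gsc <- read_gmt(require_file(argv, "--gmt"))
      log_msg("read %d gene sets over %d genes", nrow(gsc$sets),
              length(gsc$universe))
      net <- build_mgsn(gsc, alpha = alpha, mode = mode)
      log_msg("tested %d pairs, %d significant edges", nrow(net$tests),
              nrow(net$edges))
      atomic_write(function(p) write_network(net, p),
                   require_arg(argv, "--out"))
    },
    "build-rgsn" = {
      gsc <- read_gmt(require_file(argv, "--gmt"))
      reg <- read_regulations(require_file(argv, "--regulations"),
                              filters = cfg$filters)
      log_msg("read %d gene sets; %d unique regulations", nrow(gsc$sets),
              nrow(reg$edges))
      net <- build_rgsn(gsc, reg, alpha = alpha, mode = mode,
                        count_variant = cfg$count_variant,
                        restrict_universe = isTRUE(cfg$restrict_universe))
      log_msg("tested %d ordered pairs, %d significant edges",
              nrow(net$tests), nrow(net$edges))
      atomic_write(function(p) write_network(net, p),
                   require_arg(argv, "--out"))
    },
    "disease" = {
      gsc <- read_gmt(require_file(argv, "--gmt"))
      reg <- read_regulations(require_file(argv, "--regulations"),
                              filters = cfg$filters)
      dis <- read_gene_list(require_file(argv, "--disease-list"))
      sel <- select_related_sets(gsc, dis, alpha = alpha, mode = mode,
                                 intersect_disease_list =
                                   isTRUE(cfg$intersect_disease_list))
      log_msg("%d of %d gene sets disease-related", sum(sel$selected),
              nrow(sel))
      net <- build_disease_rgsn(sel, gsc, reg, alpha = alpha, mode = mode,
                                count_variant = cfg$count_variant)
      log_msg("disease network: %d nodes, %d edges", nrow(net$nodes),
              nrow(net$edges))
      out <- require_arg(argv, "--out")
      atomic_write(function(p) write_network(net, p), out)
      tab <- arg_value(argv, "--enrichment-out")
      if (!is.null(tab)) {
        atomic_write(function(p) {
          readr::write_tsv(sel, p, progress = FALSE)
        }, tab)
      }
    },
    "analyze" = {
      net <- read_network_edges(require_file(argv, "--network"))
      rep <- centrality_report(net)
      atomic_write(function(p) readr::write_tsv(rep, p, progress = FALSE),
                   require_arg(argv, "--out"))
    },
    "compare" = {
      neta <- read_network_edges(require_file(argv, "--network"))
      netb <- read_network_edges(require_file(argv, "--network-b"))
      nodes <- sort(union(neta$nodes$set, netb$nodes$set))
      neta$nodes <- tibble(set = nodes, collection = "external")
      netb$nodes <- tibble(set = nodes, collection = "external")
      cmp <- compare_networks(neta, netb)
      null <- random_overlap_null(nodes, n_edges = cmp$n_a,
                                  reference = netb, observed = neta,
                                  reps = cfg$reps, seed = seed)
      out <- c(as.list(cmp),
               list(null_mean = null$mean, null_min = null$min,
                    null_max = null$max, reps = null$reps, seed = seed,
                    fisher_p = null$fisher_p))
      atomic_write(function(p) {
        jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA)
      }, require_arg(argv, "--out"))
    },
    "simulate" = {
      spec <- fixture_spec(seed = seed)
      gsc <- generate_collection(spec)
      sim <- generate_regulations(gsc, spec)
      dir <- require_arg(argv, "--out")
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      atomic_write(function(p) write_gmt(gsc, p),
                   file.path(dir, "collection.gmt"))
      atomic_write(function(p) {
        readr::write_tsv(mutate(sim$regnet$edges, provenance = "synthetic"),
                         p, progress = FALSE)
      }, file.path(dir, "regulations.tsv"))
      atomic_write(function(p) readr::write_tsv(sim$truth, p, progress = FALSE),
                   file.path(dir, "truth.tsv"))
    },
    abort(sprintf("unknown command '%s'", cmd))
  )
  invisible(0L)
}
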