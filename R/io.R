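#' Parse a simulation configuration from a file and/or flag overrides
#'
#' Reads a flat key-value configuration file (one `key: value` or `key=value`
#' pair per line, `#` comments allowed) and merges command-line style
#' overrides on top (flags win; each override is reported via `message()`).
#' Keys mirror the [sim_config()] arguments plus the optional sweep controls
#' `replicates` and `master_seed`.  A value given as a comma-separated list
#' (e.g. `r: 0, 0.5, 1`) turns the parameter into a sweep axis; with at least
#' one axis the result is a [sweep_grid()], otherwise a [sim_config()].
#'
#' @param file Path to a config file, or `NULL`.
#' @param flags Named list of overrides (values may be strings, numbers, or
#'   comma-separated strings).
#' @return A `sim_config` or `sweep_grid`.
#' @export
parse_config <- function(file = NULL, flags = list()) {
  kv <- list()
  if (!is.null(file)) {
    lines <- readLines(file)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) stop("cannot parse config line: ", ln)
      kv[[m[2]]] <- m[3]
    }
  }
  for (nm in names(flags)) {
    if (!is.null(kv[[nm]])) {
      message(sprintf("config file value '%s = %s' overridden by flag '%s'",
                      nm, kv[[nm]], as.character(flags[[nm]])))
    }
    kv[[nm]] <- flags[[nm]]
  }
  if (length(kv) == 0L) stop("empty configuration")
  parsed <- lapply(kv, parse_config_value)
  sweep_keys <- c("replicates", "master_seed", "burn_in", "n_samples",
                  "interval")
  axes <- parsed[lengths(parsed) > 1 & !(names(parsed) %in% sweep_keys)]
  scalars <- parsed[lengths(parsed) == 1 | names(parsed) %in% sweep_keys]
  if (length(axes) == 0L) {
    do.call(sim_config, scalars[setdiff(names(scalars), sweep_keys)])
  } else {
    base <- scalars[setdiff(names(scalars), sweep_keys)]
    do.call(sim_config, utils::modifyList(base,
                                          lapply(axes, `[[`, 1L)))  # validate
    args <- list(axes = axes, base = base)
    for (k in sweep_keys) if (!is.null(scalars[[k]])) args[[k]] <- scalars[[k]]
    do.call(sweep_grid, args)
  }
}

parse_config_value <- function(x) {
  if (!is.character(x)) return(x)
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) num else parts
}

#' Export the genotype cloud as a GraphML graph
#'
#' Each distinct genotype present in a finite-sites population becomes a node
#' with attributes `frequency` (count / N), `viable`, and `robustness`;
#' undirected edges connect genotypes in the population that differ by a
#' single point mutation.  No layout coordinates are written.
#'
#' @param pop A finite-sites `wf_population`.
#' @param landscape Its `percolation_landscape`.
#' @param path Output GraphML file path.
#' @return The igraph object, invisibly.
#' @export
export_genotype_graph <- function(pop, landscape, path) {
  stopifnot(pop$representation == "finite")
  tab <- rank_frequency_table(pop)
  idx <- tab$genotype
  nodes <- data.frame(
    name = as.character(idx),
    frequency = tab$frequency,
    viable = landscape$viability[idx + 1L],
    robustness = robustness_indices(landscape, idx))
  present <- logical(length(landscape$viability))
  present[idx + 1L] <- TRUE
  nb <- neighbor_indices(idx, landscape$L)     # length(idx) x L
  from <- rep(idx, landscape$L)
  to <- as.vector(nb)
  keep <- present[to + 1L] & from < to         # each undirected edge once
  edges <- data.frame(from = as.character(from[keep]),
                      to = as.character(to[keep]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Genotype frequencies sorted by rank
#'
#' @param pop A finite-sites `wf_population`.
#' @return A data frame with columns `rank`, `genotype` (index), `count`, and
#'   `frequency`, sorted by descending count.
#' @export
rank_frequency_table <- function(pop) {
  stopifnot(pop$representation == "finite")
  cnt <- table(pop$geno)
  o <- order(cnt, decreasing = TRUE)
  data.frame(rank = seq_along(o),
             genotype = as.integer(names(cnt))[o],
             count = as.integer(cnt)[o],
             frequency = as.integer(cnt)[o] / pop$N,
             row.names = NULL)
}

#' Write a results table with a JSON manifest sidecar
#'
#' Writes `x` as a tab-separated table to `<path>.tsv` and a manifest (run id,
#' timestamps, configuration echo, seed, package version, warnings) to
#' `<path>.json`, so that every output cross-references one manifest.
#'
#' @param x A data frame of results.
#' @param path Output path stem (without extension).
#' @param config The `sim_config` or `sweep_grid` used, echoed in the
#'   manifest.
#' @param warnings Character vector of run warnings.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(x, path, config = NULL, warnings = character(0)) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing manifests requires the 'jsonlite' package")
  }
  run_id <- sprintf("%s-%06d", format(Sys.time(), "%Y%m%dT%H%M%S"),
                    sample.int(1e6, 1L))
  utils::write.table(cbind(run_id = run_id, x), paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    run_id = run_id,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("neutralnets")),
    config = config,
    warnings = warnings)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}
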