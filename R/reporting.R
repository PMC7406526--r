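#' Build an analysis configuration
#'
#' A plain, fully serializable list of every parameter of a batch analysis:
#' input path, filters, cleaning options, hierarchy flag, measure or
#' estimator selection, and output paths. Re-running the same configuration
#' reproduces the same outputs (the summary JSON differs only in its
#' timestamp field).
#'
#' @param input Path to the fluency CSV.
#' @param subject,group,category Optional filter value vectors.
#' @param spell,scheme Optional paths to spell / scheme CSVs.
#' @param target_letter Optional single character (letter fluency).
#' @param prefix_length Optional letter-prefix length used for clustering
#'   instead of a scheme file.
#' @param remove_perseverations,remove_intrusions,remove_nonalpha Cleaning
#'   flags (see [load_fluency_data()]).
#' @param hierarchical Aggregation flag.
#' @param measures Character vector from `n_responses`, `cluster_switches`,
#'   `switch_rate`, `cluster_size`, `perseverations`, `intrusions`,
#'   `word_stat`.
#' @param cluster_mode `"fluid"` or `"static"`.
#' @param norms Optional path to a `word,value` norm CSV (for `word_stat`).
#' @param norms_missing `NULL` (ignore missing words) or a substitute value.
#' @param estimator One of `first_edge`, `naive_random_walk`, `pathfinder`,
#'   `correlation`, `conceptual`, `uinvite`.
#' @param estimator_params Named list of estimator parameters (e.g.
#'   `threshold`, `window`, `alpha`, `prior_edge_probability`,
#'   `max_passes`).
#' @param seed Integer seed for seeded estimators.
#' @param output_csv,output_json,output_edges Output paths.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input,
                            subject = NULL, group = NULL, category = NULL,
                            spell = NULL, scheme = NULL,
                            target_letter = NULL, prefix_length = NULL,
                            remove_perseverations = FALSE,
                            remove_intrusions = FALSE,
                            remove_nonalpha = FALSE,
                            hierarchical = FALSE,
                            measures = c("n_responses", "cluster_switches",
                                         "cluster_size"),
                            cluster_mode = "fluid",
                            norms = NULL, norms_missing = NULL,
                            estimator = "naive_random_walk",
                            estimator_params = list(),
                            seed = 1,
                            output_csv = NULL, output_json = NULL,
                            output_edges = NULL) {
  cfg <- list(input = input, subject = subject, group = group,
              category = category, spell = spell, scheme = scheme,
              target_letter = target_letter, prefix_length = prefix_length,
              remove_perseverations = remove_perseverations,
              remove_intrusions = remove_intrusions,
              remove_nonalpha = remove_nonalpha,
              hierarchical = hierarchical, measures = measures,
              cluster_mode = cluster_mode, norms = norms,
              norms_missing = norms_missing, estimator = estimator,
              estimator_params = estimator_params, seed = seed,
              output_csv = output_csv, output_json = output_json,
              output_edges = output_edges)
  structure(cfg, class = "analysis_config")
}

config_scheme <- function(cfg) {
  if (!is.null(cfg$scheme)) as_scheme(cfg$scheme)
  else if (!is.null(cfg$prefix_length)) letter_scheme(cfg$prefix_length)
  else NULL
}

validate_config <- function(cfg, check_measures = TRUE) {
  if (!inherits(cfg, "analysis_config")) {
    if (is.list(cfg)) cfg <- do.call(analysis_config, cfg)
    else abort("`config` must be an analysis_config or a plain list")
  }
  if (is.null(cfg$input) || !file.exists(cfg$input)) {
    abort(paste0("config field `input`: file not found: ",
                 cfg$input %||% "<missing>"))
  }
  needs_scheme <- cfg$remove_intrusions ||
    (check_measures &&
       any(c("cluster_switches", "switch_rate", "cluster_size", "intrusions")
           %in% cfg$measures))
  if (needs_scheme && is.null(config_scheme(cfg)) &&
      is.null(cfg$target_letter)) {
    abort("config fields `scheme`/`prefix_length`/`target_letter`: one is required by the requested measures")
  }
  if (check_measures && "word_stat" %in% cfg$measures && is.null(cfg$norms)) {
    abort("config field `norms`: required when measure `word_stat` is requested")
  }
  cfg
}

config_load <- function(cfg) {
  load_fluency_data(cfg$input,
                    subject = cfg$subject, group = cfg$group,
                    category = cfg$category, spell = cfg$spell,
                    remove_perseverations = cfg$remove_perseverations,
                    remove_intrusions = cfg$remove_intrusions,
                    scheme = if (cfg$remove_intrusions) config_scheme(cfg),
                    target_letter = if (cfg$remove_intrusions) cfg$target_letter,
                    remove_nonalpha = cfg$remove_nonalpha,
                    hierarchical = cfg$hierarchical)
}

#' Batch fluency measures with a reproducibility summary
#'
#' Loads and cleans the data per the configuration, computes the requested
#' measures, and (optionally) writes a long-format measures CSV (`id`,
#' `listnum` for flat data, `measure`, `value`) plus a summary JSON that
#' contains everything needed to reproduce the analysis except the data
#' itself: the full parameter set, per-measure aggregates, and itemized
#' lists of the spelling corrections applied and the perseverations and
#' intrusions detected. All computation happens before any file is
#' written, so partial outputs are never produced.
#'
#' @param config An [analysis_config()] (or plain list of its fields).
#' @return Invisibly, a list with `measures` (tibble) and `summary` (the
#'   JSON-ready list).
#' @export
run_stats <- function(config) {
  cfg <- validate_config(config)
  data <- config_load(cfg)
  scheme <- config_scheme(cfg)
  warnings_log <- character()
  with_log <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  measure_one <- function(name) {
    switch(name,
      n_responses = n_responses(data),
      cluster_switches = cluster_switches(data, scheme %||% cfg$target_letter,
                                          mode = cfg$cluster_mode),
      switch_rate = cluster_switches(data, scheme %||% cfg$target_letter,
                                     mode = cfg$cluster_mode,
                                     switch_rate = TRUE),
      cluster_size = cluster_sizes(data, scheme %||% cfg$target_letter,
                                   mode = cfg$cluster_mode),
      perseverations = perseverations(data),
      intrusions = intrusions(data, scheme = scheme,
                              target_letter = cfg$target_letter),
      word_stat = word_stat(data, read_norms(cfg$norms,
                                             missing = cfg$norms_missing)),
      abort(paste0("unknown measure: ", name))
    )
  }
  measures <- with_log(dplyr::bind_rows(lapply(cfg$measures, measure_one)))
  aggregates <- dplyr::summarise(dplyr::group_by(measures, .data$measure),
                                 mean = mean(.data$value, na.rm = TRUE),
                                 sd = stats::sd(.data$value, na.rm = TRUE),
                                 n = dplyr::n(), .groups = "drop")
  pers_detected <- with_log(perseverations(set_hierarchy(data, FALSE),
                                           as_list = TRUE))
  intr_detected <- if (!is.null(scheme) || !is.null(cfg$target_letter)) {
    with_log(intrusions(set_hierarchy(data, FALSE), scheme = scheme,
                        target_letter = cfg$target_letter, as_list = TRUE))
  } else {
    empty_removed()
  }
  summary <- list(
    schema_version = "1",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = unclass(cfg),
    aggregates = aggregates,
    spelling_corrections = attr(data, "corrections"),
    perseverations_removed = attr(data, "removed_perseverations"),
    intrusions_removed = attr(data, "removed_intrusions"),
    perseverations_detected = pers_detected,
    intrusions_detected = intr_detected,
    warnings = warnings_log
  )
  if (!is.null(cfg$output_csv)) {
    readr::write_csv(measures, cfg$output_csv, progress = FALSE)
  }
  if (!is.null(cfg$output_json)) write_summary_json(summary, cfg$output_json)
  invisible(list(measures = measures, summary = summary))
}

#' Batch network estimation with serialized statistics
#'
#' Loads the data per the configuration (forced flat: estimation treats
#' lists as units), runs the selected estimator, and (optionally) writes
#' the canonical edge list plus a JSON report with the network statistics
#' and the full parameter set.
#'
#' @param config An [analysis_config()] (or plain list of its fields).
#' @return Invisibly, a list with `network` (the [semantic_network()]) and
#'   `summary` (the JSON-ready list).
#' @export
run_network <- function(config) {
  cfg <- validate_config(config, check_measures = FALSE)
  estimators <- c("first_edge", "naive_random_walk", "pathfinder",
                  "correlation", "conceptual", "uinvite")
  if (!cfg$estimator %in% estimators) {
    abort(paste0("unknown estimator `", cfg$estimator,
                 "`; available: ", paste(estimators, collapse = ", ")))
  }
  data <- set_hierarchy(config_load(cfg), FALSE)
  p <- cfg$estimator_params
  net <- switch(cfg$estimator,
    first_edge = estimate_first_edge(data),
    naive_random_walk = estimate_naive_random_walk(data),
    pathfinder = estimate_pathfinder(data),
    correlation = estimate_correlation_network(data,
      threshold = p$threshold %||% 0.5),
    conceptual = estimate_conceptual_network(data,
      window = p$window %||% 2, alpha = p$alpha %||% 0.05),
    uinvite = estimate_uinvite(data,
      prior_edge_probability = p$prior_edge_probability %||% 0.5,
      max_passes = p$max_passes %||% 20, seed = cfg$seed)
  )
  stats <- network_statistics(net)
  largest <- stats$component_sizes[[1]]
  summary <- list(
    schema_version = "1",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = unclass(cfg),
    network_statistics = dplyr::select(stats, -"component_sizes"),
    component_sizes = largest
  )
  if (!is.null(cfg$output_edges)) export_edge_list(net, cfg$output_edges)
  if (!is.null(cfg$output_json)) write_summary_json(summary, cfg$output_json)
  invisible(list(network = net, summary = summary))
}

#' Write a summary list as JSON
#'
#' @param summary List as produced by [run_stats()] / [run_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Implements the `stats` and `network` subcommands over
#' [run_stats()]/[run_network()]. Options can come from a JSON config file
#' (`--config`) and/or individual flags, flags taking precedence. Errors
#' are reported on standard error with a nonzero return value.
#'
#' Flags: `--input`, `--scheme`, `--spell`, `--norms`, `--target-letter`,
#' `--prefix-length`, `--subject`, `--group`, `--category` (comma-separated
#' values), `--measures` (comma-separated), `--cluster-mode`,
#' `--estimator`, `--threshold`, `--window`, `--alpha`, `--prior`,
#' `--max-passes`, `--seed`, `--hierarchical`, `--remove-perseverations`,
#' `--remove-intrusions`, `--remove-nonalpha`, `--output-csv`,
#' `--output-json`, `--output-edges`.
#'
#' @param args Character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 on success.
#' @export
fluency_cli <- function(args) {
  usage <- "usage: fluencynet (stats|network) [--config FILE] [--flag value ...]"
  if (length(args) == 0 || !args[1] %in% c("stats", "network")) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  res <- tryCatch({
    opts <- parse_cli_flags(args[-1])
    cfg <- list()
    if (!is.null(opts$config)) {
      cfg <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
      opts$config <- NULL
    }
    cfg[names(opts)] <- opts
    if (!is.null(cfg$estimator_flat)) {
      cfg$estimator_params <- cfg$estimator_flat
      cfg$estimator_flat <- NULL
    }
    cfg <- do.call(analysis_config, cfg)
    if (sub == "stats") run_stats(cfg) else run_network(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}

parse_cli_flags <- function(args) {
  flag_map <- c(
    "--config" = "config", "--input" = "input", "--scheme" = "scheme",
    "--spell" = "spell", "--norms" = "norms",
    "--target-letter" = "target_letter",
    "--output-csv" = "output_csv", "--output-json" = "output_json",
    "--output-edges" = "output_edges", "--estimator" = "estimator",
    "--cluster-mode" = "cluster_mode"
  )
  multi_map <- c("--subject" = "subject", "--group" = "group",
                 "--category" = "category", "--measures" = "measures")
  num_map <- c("--prefix-length" = "prefix_length", "--seed" = "seed")
  param_map <- c("--threshold" = "threshold", "--window" = "window",
                 "--alpha" = "alpha", "--prior" = "prior_edge_probability",
                 "--max-passes" = "max_passes")
  bool_map <- c("--hierarchical" = "hierarchical",
                "--remove-perseverations" = "remove_perseverations",
                "--remove-intrusions" = "remove_intrusions",
                "--remove-nonalpha" = "remove_nonalpha")
  opts <- list()
  params <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% names(bool_map)) {
      opts[[bool_map[[a]]]] <- TRUE
      i <- i + 1
      next
    }
    if (i == length(args)) abort(paste0("flag ", a, " needs a value"))
    v <- args[i + 1]
    if (a %in% names(flag_map)) {
      opts[[flag_map[[a]]]] <- v
    } else if (a %in% names(multi_map)) {
      opts[[multi_map[[a]]]] <- strsplit(v, ",", fixed = TRUE)[[1]]
    } else if (a %in% names(num_map)) {
      opts[[num_map[[a]]]] <- as.numeric(v)
    } else if (a %in% names(param_map)) {
      params[[param_map[[a]]]] <- as.numeric(v)
    } else {
      abort(paste0("unknown flag: ", a))
    }
    i <- i + 2
  }
  if (length(params) > 0) opts$estimator_flat <- params
  opts
}
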