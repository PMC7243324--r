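# Pipeline assembly, file outputs, and the run manifest.

#' Run manifest for reproducibility
#'
#' Captures everything needed to reproduce a run byte-for-byte with the
#' same code version: a hash of the game configuration, the cohort source
#' (file path or generator spec hash plus seed), the simulation parameters
#' and the package version.
#'
#' @param config A [game_config()].
#' @param cohort_source Path of the cohort file, or a [cohort_spec()] when
#'   the cohort was generated.
#' @param cohort_seed Seed used for generation (`NA` for file input).
#' @param iterations,price_rule,seed Simulation parameters.
#' @return A named list.
#' @export
run_manifest <- function(config, cohort_source = NULL, cohort_seed = NA,
                         iterations = NA, price_rule = NA, seed = NA) {
  src <- if (inherits(cohort_source, "cohort_spec")) {
    list(type = "generated", spec_hash = rlang::hash(unclass(cohort_source)),
         seed = cohort_seed)
  } else if (is.character(cohort_source)) {
    list(type = "file", path = cohort_source)
  } else {
    list(type = "unspecified")
  }
  list(
    tool = "bargainsim",
    version = as.character(utils::packageVersion("bargainsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = rlang::hash(unclass(config)),
    cohort_source = src,
    simulation = list(iterations = iterations, price_rule = price_rule,
                      seed = seed)
  )
}

#' Write pipeline outputs
#'
#' `write_market_states()` writes one CSV row per iteration x round x
#' frame; `write_market_summary()` writes the per-cell summary as CSV and
#' the full summary (cells + grand averages) as JSON;
#' `write_test_results()` writes the tidy battery table as CSV and JSON;
#' `write_manifest()` writes a [run_manifest()] as JSON.
#'
#' @param states,summary,results,manifest The respective objects.
#' @param path Output file path (for the CSV where two files are written;
#'   the JSON twin replaces the extension).
#' @return The primary path, invisibly.
#' @export
write_market_states <- function(states, path) {
  readr::write_csv(states, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_market_states
#' @export
write_market_summary <- function(summary, path) {
  readr::write_csv(summary$cells, path, progress = FALSE)
  jsonlite::write_json(
    list(cells = summary$cells, grand = summary$grand,
         n_iterations = summary$n_iterations),
    sub("\\.csv$", ".json", path),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' @rdname write_market_states
#' @export
write_test_results <- function(results, path) {
  readr::write_csv(results, path, progress = FALSE)
  jsonlite::write_json(results, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_market_states
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full negotiation-analysis pipeline
#'
#' Generates (or reads) a cohort, applies the inclusion filters, simulates
#' the matching markets, summarises them, computes the funder
#' redistribution and runs the hypothesis-test battery. With `out_dir` set,
#' all artifacts (participant CSV, market states, summary, redistribution,
#' test results, manifest) are written there.
#'
#' @param cohort Participant tibble (internal scale) or a path to a
#'   participant CSV; `NULL` generates one from `spec`.
#' @param spec A [cohort_spec()] used when `cohort` is `NULL`.
#' @param config A [game_config()].
#' @param iterations,price_rule Simulation parameters.
#' @param seed Integer seed driving generation and simulation (two
#'   sub-seeds are derived from it).
#' @param monotone_only,consistency,screening Passed to
#'   [filter_population()].
#' @param out_dir Optional output directory.
#' @return A list with `cohort`, `population`, `states`, `summary`,
#'   `redistribution`, `tests`, `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, spec = cohort_spec(),
                         config = game_config(), iterations = 500,
                         price_rule = "seller_offer", seed = 1,
                         monotone_only = TRUE, consistency = "per_round",
                         screening = FALSE, out_dir = NULL) {
  cohort_seed <- seed
  sim_seed <- seed + 1L
  if (is.null(cohort)) {
    source <- spec
    cohort <- generate_cohort(spec, config, seed = cohort_seed)
  } else if (is.character(cohort)) {
    source <- cohort
    cohort <- read_participants(cohort, config)
  } else {
    source <- "in-memory cohort"
  }
  population <- filter_population(cohort, monotone_only = monotone_only,
                                  consistency = consistency,
                                  screening = screening, config = config)
  states <- simulate_markets(population, iterations, config, price_rule,
                             seed = sim_seed)
  summary <- summarize_markets(states)
  redistribution <- redistribution_trajectory(states, config)
  tests <- run_test_battery(population, states)
  manifest <- run_manifest(config, source, cohort_seed, iterations,
                           price_rule, sim_seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_participants(cohort, file.path(out_dir, "participants.csv"), config)
    write_market_states(states, file.path(out_dir, "market_states.csv"))
    write_market_summary(summary, file.path(out_dir, "market_summary.csv"))
    readr::write_csv(redistribution$trajectory,
                     file.path(out_dir, "redistribution_trajectory.csv"),
                     progress = FALSE)
    readr::write_csv(redistribution$totals,
                     file.path(out_dir, "redistribution_totals.csv"),
                     progress = FALSE)
    write_test_results(tests, file.path(out_dir, "test_results.csv"))
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(cohort = cohort, population = population, states = states,
       summary = summary, redistribution = redistribution, tests = tests,
       manifest = manifest)
}
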