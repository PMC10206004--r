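#' Pipeline run configuration
#'
#' Bundles paths and the scoring constants: 90-day washout, 182-day
#' (six-month) evidence target, 14-day MMSE window, and the bootstrap
#' iteration counts (500 for reliability statistics, 10000 for
#' correlations).
#'
#' @param notes,prescriptions,cognitive,lexicon input paths (`NULL` where
#'   unused; a `NULL` lexicon means the built-in default)
#' @param output_dir directory for output artifacts
#' @param washout_days,target_days,mmse_window_days scoring constants
#' @param boot_reliability,boot_correlation bootstrap iteration counts
#' @param seed integer seed
#' @return a `run_config` list
#' @export
run_config <- function(notes = NULL, prescriptions = NULL, cognitive = NULL,
                       lexicon = NULL, output_dir = NULL,
                       washout_days = 90L, target_days = 182L,
                       mmse_window_days = 14L, boot_reliability = 500L,
                       boot_correlation = 10000L, seed = 1L) {
  stopifnot(washout_days > 0, target_days > 0, mmse_window_days > 0)
  structure(list(notes = notes, prescriptions = prescriptions,
                 cognitive = cognitive, lexicon = lexicon,
                 output_dir = output_dir, washout_days = washout_days,
                 target_days = target_days,
                 mmse_window_days = mmse_window_days,
                 boot_reliability = boot_reliability,
                 boot_correlation = boot_correlation, seed = seed),
            class = "run_config")
}

#' Read the pipeline inputs named by a run configuration
#'
#' @param config a [run_config()]
#' @return list with `notes`, `prescriptions`, `cognitive`, `lexicon`
#' @export
read_inputs <- function(config) {
  list(
    notes = if (!is.null(config$notes)) read_notes(config$notes),
    prescriptions = if (!is.null(config$prescriptions)) {
      read_prescriptions(config$prescriptions)
    },
    cognitive = if (!is.null(config$cognitive)) {
      read_cognitive_scores(config$cognitive)
    },
    lexicon = load_lexicon(config$lexicon))
}

#' Run the full annotate-score-classify pipeline
#'
#' Either pass a [run_config()] naming input files, or in-memory data
#' frames. Stages: annotate notes, build episodes, apply exclusions,
#' score included episodes on both domains, classify responders, and
#' tabulate rates. Deterministic given the inputs.
#'
#' @param config a [run_config()] (optional when data frames are given)
#' @param notes,prescriptions,cognitive in-memory inputs overriding the
#'   config paths
#' @param covariates optional per-episode covariates for the rate table
#' @return list with `annotations`, `episodes`, `scores`, `responders`,
#'   `rate_table`, `counts` (screening flow: screened, excluded per
#'   reason, included)
#' @export
run_pipeline <- function(config = run_config(), notes = NULL,
                         prescriptions = NULL, cognitive = NULL,
                         covariates = NULL) {
  lex <- load_lexicon(config$lexicon)
  if (is.null(notes) && !is.null(config$notes)) notes <- read_notes(config$notes)
  if (is.null(prescriptions) && !is.null(config$prescriptions)) {
    prescriptions <- read_prescriptions(config$prescriptions)
  }
  if (is.null(cognitive) && !is.null(config$cognitive)) {
    cognitive <- read_cognitive_scores(config$cognitive)
  }
  if (is.null(notes) || is.null(prescriptions)) {
    stop_contract("run_pipeline needs notes and prescriptions")
  }
  annotations <- annotate_notes(notes, lex)
  episodes <- build_episodes(prescriptions, config$washout_days, lex)
  episodes <- apply_exclusions(episodes, annotations)
  scored <- score_episodes(episodes, annotations, cognitive,
                           target_days = config$target_days,
                           washout_days = config$washout_days,
                           mmse_window = config$mmse_window_days)
  prioritized <- prioritized_scores(scored$scores)
  rate_table <- if (nrow(scored$responders)) {
    responder_rate_table(scored$responders, prioritized, covariates)
  } else NULL
  excl <- episodes$exclusion_reason[episodes$status == "excluded"]
  counts <- c(screened = nrow(episodes),
              excluded = sum(episodes$status == "excluded"),
              included = sum(episodes$status == "included"))
  list(annotations = annotations, episodes = episodes,
       scores = scored$scores, responders = scored$responders,
       rate_table = rate_table,
       counts = counts,
       exclusion_reasons = if (length(excl)) table(excl) else table(character()))
}

#' Prioritized-domain score per episode
#'
#' One row per episode, keeping the score of the drug class's prioritized
#' domain (psychiatric for SSRIs, cognitive for CEIs).
#'
#' @param scores score data frame from [score_episodes()]
#' @return data frame with one row per episode
#' @export
prioritized_scores <- function(scores) {
  keep <- scores$domain == default_domain(scores$drug_class)
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pipeline artifacts to an output directory
#'
#' Scores, responder classifications and rate tables as RFC-4180 CSV, each
#' stamped with the run's seed and a config fingerprint in a `#` header
#' comment.
#'
#' @param result list from [run_pipeline()]
#' @param config the [run_config()] used
#' @return named vector of written paths, invisibly
#' @export
write_pipeline_outputs <- function(result, config) {
  dir <- config$output_dir %||% "."
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- fnv1a_hash(unclass(config)[setdiff(names(config), "output_dir")])
  paths <- c(scores = file.path(dir, "scores.csv"),
             responders = file.path(dir, "responders.csv"))
  write_csv_stamped(result$scores, paths["scores"], config$seed, h)
  write_csv_stamped(result$responders, paths["responders"], config$seed, h)
  if (!is.null(result$rate_table)) {
    for (nm in names(result$rate_table)) {
      p <- file.path(dir, sprintf("rates_%s.csv", nm))
      write_csv_stamped(result$rate_table[[nm]], p, config$seed, h)
      paths[paste0("rates_", nm)] <- p
    }
  }
  invisible(paths)
}
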