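#' Read clinical notes from a line-delimited record file
#'
#' One JSON object per line with keys `note_id`, `patient_id`, `date`
#' (ISO-8601), `author_role`, `text`. Unknown author roles are mapped to
#' `"unknown"` with a warning; an unparseable date is a row error naming
#' the line.
#'
#' @param path file path
#' @return data frame of notes
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(note_id = character(), patient_id = character(),
                      date = as.Date(character()), author_role = character(),
                      text = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop_contract(
                      "line %d: malformed record (%s)", i, conditionMessage(e)))
    need <- c("note_id", "patient_id", "date", "author_role", "text")
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      stop_contract("line %d: missing key(s) %s", i,
                    paste(miss, collapse = ", "))
    }
    d <- tryCatch(as_date_strict(rec$date), error = function(e)
      stop_contract("line %d: %s", i, conditionMessage(e)))
    role <- rec$author_role
    if (!(role %in% c("clinician", "caregiver", "patient", "unknown"))) {
      warning(sprintf("line %d: author_role '%s' mapped to 'unknown'",
                      i, role))
      role <- "unknown"
    }
    data.frame(note_id = rec$note_id, patient_id = rec$patient_id, date = d,
               author_role = role, text = rec$text, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write clinical notes to the line-delimited record format
#' @param notes data frame of notes
#' @param path output path
#' @return `path`, invisibly
#' @export
write_notes <- function(notes, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    rec <- list(note_id = notes$note_id[i], patient_id = notes$patient_id[i],
                date = format(as.Date(notes$date[i])),
                author_role = notes$author_role[i], text = notes$text[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

read_csv_checked <- function(path, required) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", comment.char = "#")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop_contract("%s: missing required column(s): %s", path,
                  paste(miss, collapse = ", "))
  }
  d
}

#' Read prescription records (CSV)
#'
#' Columns: `patient_id`, `drug_name`, `order_date`,
#' `reported_start_date`, `reported_stop_date`, `flags` (semicolon-joined
#' tokens), `prior_snri_end_date`; optional `record_id`. CEIs unrelated to
#' dementia treatment (neostigmine, pyridostigmine) are dropped at
#' ingestion.
#'
#' @param path file path
#' @return data frame of prescription records
#' @export
read_prescriptions <- function(path) {
  d <- read_csv_checked(path, c("patient_id", "drug_name", "order_date"))
  for (col in c("reported_start_date", "reported_stop_date",
                "prior_snri_end_date")) {
    if (is.null(d[[col]])) d[[col]] <- NA_character_
    d[[col]] <- as_date_strict(d[[col]], col)
  }
  d$order_date <- as_date_strict(d$order_date, "order_date")
  if (is.null(d$flags)) d$flags <- ""
  d <- d[!(tolower(d$drug_name) %in% c("neostigmine", "bloxiverz",
                                       "pyridostigmine", "mestinon")), ,
         drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read cognitive assessment records (CSV)
#'
#' Columns: `patient_id`, `date`, `instrument` (`MMSE`/`MoCA`),
#' `raw_score`. An `mmse_equivalent` column is added via the bundled
#' crosswalk.
#'
#' @param path file path
#' @return data frame of cognitive score records
#' @export
read_cognitive_scores <- function(path) {
  d <- read_csv_checked(path, c("patient_id", "date", "instrument",
                                "raw_score"))
  d$date <- as_date_strict(d$date, "date")
  d$raw_score <- as.integer(d$raw_score)
  d$mmse_equivalent <- mmse_equivalent(d$instrument, d$raw_score)
  d
}

write_csv_stamped <- function(d, path, seed, config_hash) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s config_hash=%s", seed, config_hash), con)
  utils::write.csv(format_dates(d), con, row.names = FALSE)
  invisible(path)
}

format_dates <- function(d) {
  for (col in names(d)) {
    if (inherits(d[[col]], "Date")) d[[col]] <- format(d[[col]])
  }
  d
}

#' Write a synthetic corpus to disk in the pipeline's input formats
#'
#' @param corpus list from [render_note_corpus()]
#' @param dir output directory (created if needed)
#' @param seed seed recorded in the file headers
#' @return named vector of written paths, invisibly
#' @export
write_corpus <- function(corpus, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- fnv1a_hash(corpus$truth)
  paths <- c(
    notes = file.path(dir, "notes.jsonl"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    cognitive = file.path(dir, "cognitive_scores.csv"),
    truth = file.path(dir, "truth.csv"))
  write_notes(corpus$notes, paths["notes"])
  write_csv_stamped(corpus$prescriptions, paths["prescriptions"], seed, h)
  write_csv_stamped(corpus$cognitive, paths["cognitive"], seed, h)
  write_csv_stamped(corpus$truth, paths["truth"], seed, h)
  invisible(paths)
}
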