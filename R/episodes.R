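#' Build medication episodes from prescription records
#'
#' Groups same-class prescription records per patient into continuous usage
#' episodes under the washout rule: a switch or disuse gap shorter than
#' `washout_days` merges into one episode (the new drug is appended to the
#' drug sequence); a gap of `washout_days` or more starts a new episode.
#' Episode start is the reported start date when present, otherwise the
#' order date; the index date is the first order date of the episode. An
#' episode is flagged intolerant when any of its records carries an
#' adverse-event discontinuation or allergy-list flag.
#'
#' @param records data frame of prescription records: `record_id`
#'   (optional), `patient_id`, `drug_name`, `order_date`,
#'   `reported_start_date`, `reported_stop_date` (Dates or ISO strings, NA
#'   allowed), `flags` (semicolon-joined tokens), `prior_snri_end_date`
#' @param washout_days washout length in days (default 90; the three-month
#'   carryover window)
#' @param lexicon lexicon used to map drug names to classes
#' @return data frame of episodes: `episode_id`, `patient_id`,
#'   `drug_class`, `drug_sequence` (comma-joined in order of use),
#'   `start_date`, `end_date`, `index_date`, `intolerant`, `flags`,
#'   `prior_snri_end_date`, `status` (= "included" until exclusions are
#'   applied), `exclusion_reason`
#' @export
build_episodes <- function(records, washout_days = 90L,
                           lexicon = load_lexicon()) {
  stopifnot(washout_days > 0)
  r <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(r)) return(empty_episodes())
  if (is.null(r$record_id)) r$record_id <- sprintf("R%04d", seq_len(nrow(r)))
  for (col in c("order_date", "reported_start_date", "reported_stop_date",
                "prior_snri_end_date")) {
    if (is.null(r[[col]])) r[[col]] <- as.Date(NA)
    r[[col]] <- as.Date(r[[col]])
  }
  if (is.null(r$flags)) r$flags <- ""
  r$flags[is.na(r$flags)] <- ""
  if (any(is.na(r$order_date))) {
    stop_contract("order_date missing for record(s): %s",
                  paste(r$record_id[is.na(r$order_date)], collapse = ", "))
  }
  bad <- !is.na(r$reported_start_date) & !is.na(r$reported_stop_date) &
    r$reported_stop_date < r$reported_start_date
  if (any(bad)) {
    stop_contract("inconsistent dates (stop before start) in record(s): %s",
                  paste(r$record_id[bad], collapse = ", "))
  }
  r$drug_class <- drug_class_of(r$drug_name, lexicon)
  r <- r[!is.na(r$drug_class), , drop = FALSE]
  if (!nrow(r)) return(empty_episodes())
  r$start <- r$reported_start_date
  r$start[is.na(r$start)] <- r$order_date[is.na(r$start)]

  out <- list()
  for (key in unique(paste(r$patient_id, r$drug_class, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- r[r$patient_id == parts[1] & r$drug_class == parts[2], , drop = FALSE]
    g <- g[order(g$start, g$order_date), , drop = FALSE]
    ep_idx <- 1L
    cur <- integer()
    flush <- function(rows, idx) {
      gg <- g[rows, , drop = FALSE]
      flags <- unique(unlist(strsplit(gg$flags, ";", fixed = TRUE)))
      flags <- trimws(flags[nzchar(trimws(flags))])
      stop_d <- gg$reported_stop_date
      end_date <- if (any(is.na(stop_d))) as.Date(NA) else max(stop_d)
      snri <- gg$prior_snri_end_date
      snri <- if (all(is.na(snri))) as.Date(NA) else max(snri, na.rm = TRUE)
      data.frame(
        episode_id = sprintf("%s-%s-%d", parts[1], parts[2], idx),
        patient_id = parts[1], drug_class = parts[2],
        drug_sequence = paste(unique(gg$drug_name), collapse = ","),
        start_date = min(gg$start), end_date = end_date,
        index_date = min(gg$order_date),
        intolerant = any(c("discontinued_adverse_event", "allergy_listed")
                         %in% flags),
        flags = paste(flags, collapse = ";"),
        prior_snri_end_date = snri,
        status = "included", exclusion_reason = NA_character_,
        stringsAsFactors = FALSE)
    }
    prev_stop <- as.Date(NA)
    for (i in seq_len(nrow(g))) {
      if (!length(cur)) {
        cur <- i
      } else {
        # gap measured from the last known stop; an open-ended previous
        # record means ongoing use, so a same-class switch merges (gap 0)
        gap <- if (is.na(prev_stop)) 0L else as.integer(g$start[i] - prev_stop)
        if (gap >= washout_days) {
          out[[length(out) + 1L]] <- flush(cur, ep_idx)
          ep_idx <- ep_idx + 1L
          cur <- i
          prev_stop <- as.Date(NA)
        } else {
          cur <- c(cur, i)
        }
      }
      s <- g$reported_stop_date[i]
      if (!is.na(s) && (is.na(prev_stop) || s > prev_stop)) prev_stop <- s
      if (is.na(s)) prev_stop <- as.Date(NA)  # open-ended record dominates
    }
    if (length(cur)) out[[length(out) + 1L]] <- flush(cur, ep_idx)
  }
  ep <- do.call(rbind, out)
  ep <- ep[order(ep$patient_id, ep$drug_class, ep$start_date), , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

empty_episodes <- function() {
  data.frame(episode_id = character(), patient_id = character(),
             drug_class = character(), drug_sequence = character(),
             start_date = as.Date(character()), end_date = as.Date(character()),
             index_date = as.Date(character()), intolerant = logical(),
             flags = character(), prior_snri_end_date = as.Date(character()),
             status = character(), exclusion_reason = NA_character_[0],
             stringsAsFactors = FALSE)
}

#' Apply the exclusion rules to built episodes
#'
#' Marks episodes excluded for the enumerated screening reasons: reported
#' start more than 6 months (182 days) before or more than 3 months
#' (91 days) after the index date; an SSRI episode starting within 90 days
#' of a prior SNRI end (carryover); unknown start date; protected record;
#' never started; discontinued because the original diagnosis changed; or
#' no evaluable follow-up (no annotation dated after the start). Intolerant
#' episodes are never excluded for lack of follow-up: intolerance is itself
#' the evaluable outcome (scored 0.5).
#'
#' @param episodes data frame from [build_episodes()]
#' @param annotations annotation data frame (used for the follow-up rule);
#'   `NULL` skips that rule
#' @return `episodes` with `status` and `exclusion_reason` updated
#' @export
apply_exclusions <- function(episodes, annotations = NULL) {
  ep <- episodes
  if (!nrow(ep)) return(ep)
  has_flag <- function(i, f) {
    f %in% trimws(strsplit(ep$flags[i], ";", fixed = TRUE)[[1]])
  }
  for (i in seq_len(nrow(ep))) {
    reason <- NA_character_
    d_before <- as.integer(ep$index_date[i] - ep$start_date[i])
    d_after <- as.integer(ep$start_date[i] - ep$index_date[i])
    if (d_before > 182L) {
      reason <- "early_start"
    } else if (d_after > 91L) {
      reason <- "late_start"
    } else if (ep$drug_class[i] == "SSRI" &&
               !is.na(ep$prior_snri_end_date[i]) &&
               as.integer(ep$start_date[i] - ep$prior_snri_end_date[i]) < 90L) {
      reason <- "snri_carryover"
    } else if (has_flag(i, "start_unknown")) {
      reason <- "start_unknown"
    } else if (has_flag(i, "record_protected")) {
      reason <- "record_protected"
    } else if (has_flag(i, "never_started")) {
      reason <- "never_started"
    } else if (has_flag(i, "discontinued_diagnosis_change")) {
      reason <- "diagnosis_change"
    } else if (!is.null(annotations) && !ep$intolerant[i]) {
      ann <- annotations[annotations$patient_id == ep$patient_id[i] &
                           as.Date(annotations$date) > ep$start_date[i], ,
                         drop = FALSE]
      if (nrow(ann) == 0L) reason <- "no_followup"
    }
    if (!is.na(reason)) {
      ep$status[i] <- "excluded"
      ep$exclusion_reason[i] <- reason
    } else {
      ep$status[i] <- "included"
      ep$exclusion_reason[i] <- NA_character_
    }
  }
  ep
}
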