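.author_priority <- c(clinician = 1L, caregiver = 2L, patient = 3L,
                      unknown = 4L)

default_domain <- function(drug_class) {
  c(SSRI = "psychiatric", CEI = "cognitive")[drug_class]
}

# annotations usable for an episode and domain; unclassified annotations
# count only toward the drug class's prioritized domain
episode_domain_annotations <- function(annotations, episode, domain,
                                       washout_days = 90L) {
  a <- annotations
  a$date <- as.Date(a$date)
  a <- a[a$patient_id == episode$patient_id & !is.na(a$direction), ,
         drop = FALSE]
  a <- a[a$date >= episode$start_date, , drop = FALSE]
  if (!is.na(episode$end_date)) {
    a <- a[a$date <= episode$end_date + washout_days, , drop = FALSE]
  }
  take <- a$domain == domain
  if (domain == default_domain(episode$drug_class)) {
    uncl <- a$domain == "unclassified"
    # an unclassified comment must concern this episode's drug class (or
    # name no drug class at all, e.g. "the medication is working well")
    mentions <- vapply(strsplit(a$drug_classes, ",", fixed = TRUE),
                       function(x) episode$drug_class %in% x ||
                         !length(x[nzchar(x)]), TRUE)
    take <- take | (uncl & mentions)
  }
  a[take, , drop = FALSE]
}

#' Select the prioritized comment for an episode and domain
#'
#' Applies the evidence-prioritization rules: (1) direction precedence
#' improve > worsen > no change across the whole episode (an improvement
#' marks the drug effective even if decline is reported later); (2) among
#' comments of the chosen direction, only the highest-ranked author
#' present is considered (clinician > caregiver > patient > unknown);
#' (3) for the cognitive domain, comments dated within `mmse_window` days
#' of an MMSE-change date win; (4) otherwise the comment closest to
#' `target_days` (six months) after the episode start is chosen, earlier
#' date breaking ties.
#'
#' @param annotations annotation data frame (already restricted per
#'   episode/domain, e.g. by [assign_note()]; rows must have `date`,
#'   `direction`, `author_role`)
#' @param episode one-row episode data frame
#' @param mmse_change_dates Dates of secondary MMSE measurements for this
#'   episode (may be empty)
#' @param target_days target follow-up in days (default 182)
#' @param mmse_window tolerance for MMSE-date matching (default 14 days)
#' @return one-row data frame (the chosen annotation) or `NULL`
#' @export
select_prioritized_comment <- function(annotations, episode,
                                       mmse_change_dates = as.Date(character()),
                                       target_days = 182L,
                                       mmse_window = 14L) {
  a <- annotations
  if (is.null(a) || nrow(a) == 0L) return(NULL)
  a$date <- as.Date(a$date)
  for (dir in c("improve", "worsen", "no_change")) {
    if (any(a$direction == dir)) {
      a <- a[a$direction == dir, , drop = FALSE]
      break
    }
  }
  pr <- .author_priority[a$author_role]
  a <- a[pr == min(pr), , drop = FALSE]
  if (length(mmse_change_dates)) {
    matched <- vapply(a$date, function(d) {
      any(abs(as.integer(d - mmse_change_dates)) <= mmse_window)
    }, TRUE)
    if (any(matched)) a <- a[matched, , drop = FALSE]
  }
  off <- abs(as.integer(a$date - episode$start_date) - target_days)
  a <- a[order(off, a$date), , drop = FALSE]
  a[1, , drop = FALSE]
}

#' Assign the three-point NOTE score for one episode and domain
#'
#' Intolerant episodes score 0.5 regardless of comments; otherwise the
#' prioritized comment's direction maps improve/no change/worsen to 1/2/3,
#' and 0 (N/A) is assigned when no comment is selectable.
#'
#' @inheritParams select_prioritized_comment
#' @param episode one-row episode data frame
#' @param annotations full annotation data frame
#' @param domain `"psychiatric"` or `"cognitive"`
#' @return one-row data frame: `episode_id`, `domain`, `note_value`,
#'   `cibic_value`, `evidence_date`, `evidence_annotation_ids`
#' @export
assign_note <- function(episode, annotations, domain,
                        mmse_change_dates = as.Date(character()),
                        target_days = 182L, washout_days = 90L) {
  stopifnot(domain %in% c("psychiatric", "cognitive"))
  score <- data.frame(episode_id = episode$episode_id, domain = domain,
                      note_value = 0, cibic_value = 0,
                      evidence_date = as.Date(NA),
                      evidence_annotation_ids = NA_character_,
                      stringsAsFactors = FALSE)
  if (isTRUE(episode$intolerant)) {
    score$note_value <- 0.5
    score$cibic_value <- 0.5
    return(score)
  }
  cand <- episode_domain_annotations(annotations, episode, domain,
                                     washout_days)
  chosen <- select_prioritized_comment(cand, episode, mmse_change_dates,
                                       target_days)
  if (is.null(chosen)) return(score)
  score$note_value <- c(improve = 1, no_change = 2, worsen = 3)[chosen$direction]
  score$cibic_value <- cibic_from(chosen$direction, chosen$intensity)
  score$evidence_date <- chosen$date
  score$evidence_annotation_ids <- chosen$annotation_id %||% NA_character_
  score
}

# map (direction, intensity) onto the seven-point scale; a direction
# without a usable modifier is 0 (N/A) except "no change", which needs none
cibic_from <- function(direction, intensity) {
  if (direction == "no_change") return(4)
  tab <- list(
    improve = c(markedly = 1, moderately = 2, slightly = 3, none = 0),
    worsen = c(slightly = 5, moderately = 6, markedly = 7, none = 0))
  unname(tab[[direction]][intensity])
}

#' Assign the seven-point CIBIC-plus score
#'
#' Computed on the same prioritized evidence as the NOTE score:
#' markedly/moderately/slightly improved map to 1/2/3, unchanged to 4,
#' slightly/moderately/markedly worse to 5/6/7. A direction cue with no
#' intensity modifier ("working well") is not classifiable on the
#' seven-point scale and scores 0 (N/A); intolerance scores 0.5.
#'
#' @inheritParams assign_note
#' @return one-row score data frame (same shape as [assign_note()])
#' @export
assign_cibic <- function(episode, annotations, domain,
                         mmse_change_dates = as.Date(character()),
                         target_days = 182L, washout_days = 90L) {
  assign_note(episode, annotations, domain, mmse_change_dates, target_days,
              washout_days)
}

#' Classify an episode as responder / non-responder / intolerant
#'
#' Uses the drug class's prioritized domain (psychiatric for SSRIs,
#' cognitive for CEIs). SSRI responders improved (NOTE 1); SSRI
#' non-responders were unchanged or worse (2, 3). CEI responders improved
#' or were stable (1, 2); CEI non-responders worsened (3). 0.5 is
#' intolerant and 0 is not evaluable.
#'
#' @param score one-row score data frame from [assign_note()]
#' @param drug_class `"SSRI"` or `"CEI"`
#' @return one-row data frame: `episode_id`, `drug_class`, `category`
#' @export
classify_responder <- function(score, drug_class) {
  if (score$domain != default_domain(drug_class)) {
    stop_contract("responder classification requires the %s domain for %s",
                  default_domain(drug_class), drug_class)
  }
  v <- score$note_value
  category <-
    if (v == 0.5) "intolerant"
    else if (v == 0) "not_evaluable"
    else if (drug_class == "SSRI") {
      if (v == 1) "responder" else "non_responder"
    } else {
      if (v %in% c(1, 2)) "responder" else "non_responder"
    }
  data.frame(episode_id = score$episode_id, drug_class = drug_class,
             category = category, stringsAsFactors = FALSE)
}

#' Score all included episodes on both domains
#'
#' @param episodes episode data frame (only `status == "included"` rows are
#'   scored)
#' @param annotations annotation data frame
#' @param cognitive_records cognitive assessment records (optional; enables
#'   MMSE-date prioritization and MMSE change)
#' @param target_days,washout_days,mmse_window pipeline constants
#' @return list with `scores` (episode x domain rows, including
#'   `mmse_change` for cognitive rows) and `responders` (one row per
#'   episode)
#' @export
score_episodes <- function(episodes, annotations, cognitive_records = NULL,
                           target_days = 182L, washout_days = 90L,
                           mmse_window = 14L) {
  inc <- episodes[episodes$status == "included", , drop = FALSE]
  scores <- list()
  responders <- list()
  for (i in seq_len(nrow(inc))) {
    ep <- inc[i, , drop = FALSE]
    mcd <- mmse_change_dates(cognitive_records, ep, mmse_window)
    for (domain in c("psychiatric", "cognitive")) {
      s <- assign_note(ep, annotations, domain,
                       mmse_change_dates = if (domain == "cognitive") mcd
                                           else as.Date(character()),
                       target_days = target_days,
                       washout_days = washout_days)
      s$drug_class <- ep$drug_class
      s$mmse_change <- if (domain == "cognitive" && !is.null(cognitive_records)
                           && !is.na(s$evidence_date)) {
        compute_mmse_change(cognitive_records, ep, s$evidence_date,
                            mmse_window) %||% NA_real_
      } else NA_real_
      scores[[length(scores) + 1L]] <- s
      if (domain == default_domain(ep$drug_class)) {
        responders[[length(responders) + 1L]] <- classify_responder(
          s, ep$drug_class)
      }
    }
  }
  list(scores = do.call(rbind, scores) %||% data.frame(),
       responders = do.call(rbind, responders) %||% data.frame())
}

#' Dates of secondary MMSE measurements for an episode
#'
#' A date qualifies as an MMSE-change date when a baseline record exists
#' within `window_days` of the episode start and the record itself is later
#' than the baseline window.
#'
#' @param records cognitive score records (`patient_id`, `date`,
#'   `instrument`, `raw_score`)
#' @param episode one-row episode data frame
#' @param window_days matching window (default 14)
#' @return vector of Dates (possibly empty)
#' @export
mmse_change_dates <- function(records, episode, window_days = 14L) {
  if (is.null(records) || !nrow(records)) return(as.Date(character()))
  r <- records[records$patient_id == episode$patient_id, , drop = FALSE]
  if (!nrow(r)) return(as.Date(character()))
  r$date <- as.Date(r$date)
  base_off <- abs(as.integer(r$date - episode$start_date))
  if (!any(base_off <= window_days)) return(as.Date(character()))
  sort(r$date[r$date > episode$start_date + window_days])
}

#' MMSE change between drug initiation and a cognitive comment
#'
#' Difference between the MMSE (or converted MoCA) score nearest the
#' comment date and the one nearest the episode start, both within
#' `window_days` (inclusive). Ties in distance resolve to the earlier
#' record.
#'
#' @param records cognitive score records
#' @param episode one-row episode data frame
#' @param comment_date date of the prioritized cognitive comment
#' @param window_days matching window in days (default 14)
#' @return integer delta (post minus pre) or `NULL` when either anchor is
#'   missing
#' @export
compute_mmse_change <- function(records, episode, comment_date,
                                window_days = 14L) {
  r <- records[records$patient_id == episode$patient_id, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  r$date <- as.Date(r$date)
  r$mmse <- mmse_equivalent(r$instrument, r$raw_score)
  nearest <- function(anchor) {
    off <- abs(as.integer(r$date - anchor))
    ok <- off <= window_days
    if (!any(ok)) return(NULL)
    cand <- r[ok, , drop = FALSE]
    cand <- cand[order(abs(as.integer(cand$date - anchor)), cand$date), ,
                 drop = FALSE]
    cand[1, , drop = FALSE]
  }
  pre <- nearest(as.Date(episode$start_date))
  post <- nearest(as.Date(comment_date))
  if (is.null(pre) || is.null(post)) return(NULL)
  as.integer(post$mmse - pre$mmse)
}
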