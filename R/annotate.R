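#' Split note text into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`, `;`) and on
#' newlines; an unterminated trailing fragment is kept as a sentence.
#' Spans are half-open character intervals into the original text.
#'
#' @param text free text of one clinical note
#' @return data frame with `sentence`, `start`, `end`
#' @export
segment_sentences <- function(text) {
  empty <- data.frame(sentence = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)
  breaks <- gregexpr("[.!?;]+[[:space:]]*|\n+", text)[[1]]
  starts <- 1L
  out <- list()
  if (breaks[1] != -1L) {
    lens <- attr(breaks, "match.length")
    for (i in seq_along(breaks)) {
      end <- as.integer(breaks[i]) + lens[i]
      out[[length(out) + 1L]] <- c(starts, end)
      starts <- end
    }
  }
  if (starts <= nchar(text)) {
    out[[length(out) + 1L]] <- c(starts, nchar(text) + 1L)
  }
  res <- do.call(rbind, out)
  df <- data.frame(sentence = substring(text, res[, 1], res[, 2] - 1L),
                   start = res[, 1], end = res[, 2], stringsAsFactors = FALSE)
  df <- df[grepl("[[:alnum:]]", df$sentence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

direction_of <- function(category) {
  c(improve_cues = "improve", no_change_cues = "no_change",
    worsen_cues = "worsen")[category]
}

#' Classify one sentence into comment fragments
#'
#' Applies the annotation rules to a single sentence: symptom cues fix the
#' domain (psychiatric and/or cognitive; a sentence touching both yields one
#' fragment per domain); the direction comes from the direction cue nearest
#' the domain's symptom cue, with improve and worsen each taking precedence
#' over no change when both are present ("memory slightly worse or around
#' the same" is worsening); the stable/controlled family resolves to
#' improvement for psychiatric fillers and no change for cognitive fillers;
#' intensity is taken from the nearest modifier within `intensity_window`
#' tokens of the direction cue. A sentence with a direction cue and a drug
#' mention but no symptom cue yields an unclassified-domain fragment
#' ("sertraline working well").
#'
#' @param sentence one sentence string
#' @param lexicon a `keyword_lexicon`
#' @param intensity_window max token gap between direction cue and modifier
#' @return data frame of fragments: `domain`, `direction`, `intensity`,
#'   `drug_classes` (comma-joined), plus the evidence phrases
#' @export
classify_comment <- function(sentence, lexicon, intensity_window = 3L) {
  m <- match_phrases(sentence, lexicon)
  empty <- data.frame(domain = character(), direction = character(),
                      intensity = character(), drug_classes = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  if (nrow(m) == 0L) return(empty)

  drug_classes <- character()
  if (any(m$category == "ssri_names")) drug_classes <- c(drug_classes, "SSRI")
  if (any(m$category == "cei_names")) drug_classes <- c(drug_classes, "CEI")
  drugs_str <- paste(drug_classes, collapse = ",")

  dirs <- m[m$category %in% .direction_categories, , drop = FALSE]
  if (nrow(dirs) == 0L) return(empty)
  dirs$direction <- unname(direction_of(dirs$category))

  ints <- m[startsWith(m$category, "intensity_"), , drop = FALSE]
  evidence_str <- paste(m$phrase, collapse = "; ")

  pick_intensity <- function(dir_row) {
    if (nrow(ints) == 0L) return("none")
    d <- token_distance(dir_row$first_token, dir_row$last_token,
                        ints$first_token, ints$last_token)
    ok <- d <= intensity_window
    if (!any(ok)) return("none")
    best <- ints[ok, , drop = FALSE][which.min(d[ok]), ]
    sub("intensity_", "", best$category)
  }

  # candidate direction rows compatible with a given domain
  compatible <- function(domain) {
    tmpl <- !is.na(dirs$slot)
    comp <- !tmpl |
      dirs$slot == "drug" |
      (dirs$slot %in% c("psychiatric", "cognitive") & dirs$slot == domain) |
      (dirs$slot == "symptom" & dirs$slot_domain == domain)
    dirs[comp, , drop = FALSE]
  }

  choose_direction <- function(cands, anchor_first, anchor_last) {
    if (nrow(cands) == 0L) return(NULL)
    if (any(cands$direction %in% c("improve", "worsen"))) {
      cands <- cands[cands$direction != "no_change", , drop = FALSE]
    }
    d <- token_distance(anchor_first, anchor_last,
                        cands$first_token, cands$last_token)
    cands <- cands[order(d, match(cands$direction,
                                  c("improve", "worsen", "no_change")),
                         cands$first_token), , drop = FALSE]
    cands[1, , drop = FALSE]
  }

  frags <- list()
  for (domain in c("psychiatric", "cognitive")) {
    cue_cat <- paste0(domain, "_cues")
    cues <- m[m$category == cue_cat, , drop = FALSE]
    if (nrow(cues) == 0L) next
    cands <- compatible(domain)
    # anchor at the symptom cue nearest any direction cue
    if (nrow(cands) == 0L) next
    best <- NULL
    best_d <- Inf
    for (ci in seq_len(nrow(cues))) {
      ch <- choose_direction(cands, cues$first_token[ci], cues$last_token[ci])
      if (is.null(ch)) next
      d <- token_distance(cues$first_token[ci], cues$last_token[ci],
                          ch$first_token, ch$last_token)
      if (d < best_d) { best <- ch; best_d <- d }
    }
    if (is.null(best)) next
    frags[[length(frags) + 1L]] <- data.frame(
      domain = domain, direction = best$direction,
      intensity = pick_intensity(best), drug_classes = drugs_str,
      evidence = evidence_str, stringsAsFactors = FALSE)
  }

  if (!length(frags)) {
    # no symptom cue: drug mention + direction -> unclassified
    if (length(drug_classes)) {
      cands <- dirs[is.na(dirs$slot) | dirs$slot == "drug" |
                      !is.na(dirs$slot_domain), , drop = FALSE]
      ch <- choose_direction(cands, 1L, 1L)
      if (!is.null(ch)) {
        frags[[1L]] <- data.frame(
          domain = "unclassified", direction = ch$direction,
          intensity = pick_intensity(ch), drug_classes = drugs_str,
          evidence = evidence_str, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(frags)) return(empty)
  out <- do.call(rbind, frags)
  out[, c("domain", "direction", "intensity", "drug_classes", "evidence")]
}

#' Annotate a clinical note
#'
#' Segments the note into sentences and classifies each one, producing one
#' annotation per (sentence, domain) with a direction match. Author role is
#' carried from the note's structured metadata, never inferred from text.
#'
#' @param note a list or one-row data frame with `note_id`, `patient_id`,
#'   `date` (Date or ISO-8601 string), `author_role`, `text`
#' @param lexicon a `keyword_lexicon`
#' @return data frame of annotations (possibly empty): `note_id`,
#'   `patient_id`, `date`, `author_role`, `domain`, `direction`,
#'   `intensity`, `drug_classes`, `evidence`
#' @export
annotate_note <- function(note, lexicon) {
  role <- as.character(note$author_role %||% "unknown")
  if (!(role %in% c("clinician", "caregiver", "patient", "unknown"))) {
    warning(sprintf("unknown author_role '%s' mapped to 'unknown'", role))
    role <- "unknown"
  }
  sents <- segment_sentences(as.character(note$text))
  frags <- lapply(sents$sentence, classify_comment, lexicon = lexicon)
  frags <- frags[vapply(frags, nrow, 0L) > 0L]
  base <- data.frame(note_id = character(), patient_id = character(),
                     date = as.Date(character()), author_role = character(),
                     domain = character(), direction = character(),
                     intensity = character(), drug_classes = character(),
                     evidence = character(), stringsAsFactors = FALSE)
  if (!length(frags)) return(base)
  out <- do.call(rbind, frags)
  data.frame(note_id = as.character(note$note_id),
             patient_id = as.character(note$patient_id),
             date = as.Date(note$date), author_role = role,
             out, row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate a table of clinical notes
#'
#' @param notes data frame of notes (`note_id`, `patient_id`, `date`,
#'   `author_role`, `text`)
#' @param lexicon a `keyword_lexicon`; default lexicon if omitted
#' @return data frame of annotations with an `annotation_id` column
#' @export
annotate_notes <- function(notes, lexicon = load_lexicon()) {
  res <- lapply(seq_len(nrow(notes)), function(i) {
    annotate_note(notes[i, , drop = FALSE], lexicon)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) {
    out <- annotate_note(list(note_id = "x", patient_id = "x",
                              date = "2000-01-01", author_role = "unknown",
                              text = ""), lexicon)
  }
  out$annotation_id <- if (nrow(out)) sprintf("A%05d", seq_len(nrow(out)))
                       else character()
  rownames(out) <- NULL
  out
}
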