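#' Match lexicon phrases in a sentence
#'
#' Whole-token, case-insensitive matching of every lexicon phrase against
#' one sentence. Matching is token-boundary aware (no substring hits inside
#' words) and applies longest-match suppression within each category group:
#' when two candidate phrases of the same group overlap, only the longer is
#' reported, so "not helpful" suppresses "helpful". Template entries
#' (trigger + slot) only match when a slot-filling cue occurs within
#' `slot_window` tokens in the same sentence; the domain of the filler is
#' recorded so that the stable/controlled rule can resolve direction.
#'
#' @param sentence a single sentence of note text
#' @param lexicon a `keyword_lexicon`
#' @param slot_window maximum token distance between a template trigger and
#'   its slot filler (default 8)
#' @return data frame with one row per match: `phrase`, `category`, `start`,
#'   `end` (half-open character span), `first_token`, `last_token`,
#'   `slot`, `slot_domain` (for templates, the symptom domain of the
#'   filler), ordered left to right
#' @examples
#' match_phrases("Donepezil helpful", load_lexicon())
#' @export
match_phrases <- function(sentence, lexicon, slot_window = 8L) {
  stopifnot(inherits(lexicon, "keyword_lexicon"))
  empty <- data.frame(
    phrase = character(), category = character(), start = integer(),
    end = integer(), first_token = integer(), last_token = integer(),
    slot = character(), slot_domain = character(), stringsAsFactors = FALSE)
  if (is.na(sentence) || !nzchar(sentence)) return(empty)
  toks <- tokenize(normalize_text(sentence))
  if (nrow(toks) == 0L) return(empty)

  tab <- lexicon$match_table
  cand <- list()
  for (r in seq_len(nrow(tab))) {
    pt <- tab$tokens[[r]]
    k <- length(pt)
    if (k == 0L || k > nrow(toks)) next
    for (i in seq_len(nrow(toks) - k + 1L)) {
      if (all(toks$token[i:(i + k - 1L)] == pt)) {
        cand[[length(cand) + 1L]] <- data.frame(
          phrase = tab$phrase[r], category = tab$category[r],
          group = tab$group[r], slot = tab$slot[r],
          start = toks$start[i], end = toks$end[i + k - 1L],
          first_token = i, last_token = i + k - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(empty)
  m <- do.call(rbind, cand)

  # longest-match suppression within group (strictly longer span wins)
  m$len <- m$end - m$start
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    overl <- m$start < m$end[i] & m$end > m$start[i] & m$group == m$group[i]
    if (any(overl & m$len > m$len[i])) keep[i] <- FALSE
  }
  m <- m[keep, , drop = FALSE]

  # resolve templates: require a slot filler nearby among kept matches
  m$slot_domain <- NA_character_
  is_tmpl <- !is.na(m$slot)
  if (any(is_tmpl)) {
    filler_rows <- function(slot) {
      switch(slot,
        psychiatric = which(m$category == "psychiatric_cues"),
        cognitive = which(m$category == "cognitive_cues"),
        symptom = which(m$category %in% c("psychiatric_cues", "cognitive_cues")),
        drug = which(m$category %in% c("ssri_names", "cei_names")))
    }
    drop <- logical(nrow(m))
    for (i in which(is_tmpl)) {
      fr <- filler_rows(m$slot[i])
      if (!length(fr)) { drop[i] <- TRUE; next }
      d <- token_distance(m$first_token[i], m$last_token[i],
                          m$first_token[fr], m$last_token[fr])
      ok <- if (m$slot[i] == "drug") rep(TRUE, length(fr)) else d <= slot_window
      if (!any(ok)) { drop[i] <- TRUE; next }
      best <- fr[ok][which.min(d[ok])]
      m$slot_domain[i] <- switch(m$category[best],
        psychiatric_cues = "psychiatric", cognitive_cues = "cognitive",
        ssri_names = "drug", cei_names = "drug")
    }
    m <- m[!drop, , drop = FALSE]
  }

  m <- m[order(m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  m[, c("phrase", "category", "start", "end", "first_token", "last_token",
        "slot", "slot_domain")]
}

# token gap between two matches (0 when overlapping/adjacent spans)
token_distance <- function(f1, l1, f2, l2) {
  pmax(0L, pmax(f1 - l2, f2 - l1))
}
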