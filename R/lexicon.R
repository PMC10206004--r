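#' @title Keyword lexicon for treatment-response annotation
#' @description
#' The lexicon holds the phrase inventory used to annotate clinical notes:
#' drug names (SSRIs and cholinesterase inhibitors), cognitive-assessment
#' names, symptom cues (psychiatric and cognitive), direction-of-change cues
#' (improve / no change / worsen), and intensity modifiers (markedly /
#' moderately / slightly) that map direction cues onto the seven-point
#' CIBIC-plus scale.
#'
#' Direction entries may be *templates*: a trigger phrase that only acts as
#' a direction cue when a slot-filling cue co-occurs nearby in the same
#' sentence. Templates are written `"trigger|slot"` where `slot` is one of
#' `psychiatric`, `cognitive`, `symptom` (either symptom set) or `drug`
#' (any drug name). The "stable/controlled" family is deliberately present
#' twice with disjoint slots: with a psychiatric filler it signals
#' improvement (agitation that is now stable), with a cognitive filler it
#' signals no change (dementia that is stable is not improving, merely not
#' on its expected decline).
#' @name keyword_lexicon
NULL

.lexicon_categories <- c(
  "ssri_names", "cei_names", "assessment_names",
  "psychiatric_cues", "cognitive_cues",
  "improve_cues", "no_change_cues", "worsen_cues",
  "intensity_markedly", "intensity_moderately", "intensity_slightly"
)

.direction_categories <- c("improve_cues", "no_change_cues", "worsen_cues")
.valid_slots <- c("psychiatric", "cognitive", "symptom", "drug")

# Category groups used for longest-match suppression: a shorter match is
# suppressed only by a longer overlapping match from the same group, so
# "not helpful" (direction) hides "helpful" (direction) but "no longer
# depressed" (direction) does not hide the symptom cue "depressed".
.category_group <- c(
  ssri_names = "drug", cei_names = "drug", assessment_names = "assessment",
  psychiatric_cues = "symptom", cognitive_cues = "symptom",
  improve_cues = "direction", no_change_cues = "direction",
  worsen_cues = "direction",
  intensity_markedly = "intensity", intensity_moderately = "intensity",
  intensity_slightly = "intensity"
)

.default_lexicon_entries <- list(
  ssri_names = c(
    "SSRI", "SSRIs", "citalopram", "Celexa", "escitalopram", "Lexapro",
    "fluoxetine", "Prozac", "Sarafem", "Symbyax", "fluvoxamine", "Luvox",
    "paroxetine", "Paxil", "Pexeva", "sertraline", "Zoloft", "vilazodone",
    "Viibryd"
  ),
  cei_names = c(
    "cholinesterase inhibitor", "donepezil", "Aricept", "rivastigmine",
    "Exelon", "galantamine", "Razadyne", "Namzaric"
  ),
  assessment_names = c(
    "MMSE", "Mini-Mental State Exam", "MoCA", "Montreal Cognitive Assessment"
  ),
  psychiatric_cues = c(
    "depression", "depressed", "anxious", "anxiety", "mood",
    "ruminating thoughts", "nighttime disruption", "hallucination", "focus",
    "attention", "concentration", "alert", "irritation", "irritability",
    "irritated", "agitation", "agitated", "behavior", "challenging behavior",
    "panic attack", "frustration", "apathy", "communicative", "altered",
    "confusion", "mood swings", "emotional", "emotionally", "tearful",
    "crying", "anger", "positivity", "sleep", "sad", "no energy",
    "personality", "paranoia", "feeling", "impulsivity", "active", "engaged",
    "motivated", "hopeful", "interactive", "interacting", "verbal", "aware",
    "delusions", "aggression", "dysphoria", "elation", "euphoria",
    "indifference", "disinhibition", "disinhibited", "labile", "lability",
    "motor disturbances", "nighttime behavior", "psychiatric",
    "psychiatric symptoms"
  ),
  cognitive_cues = c(
    "recall", "memory", "short-term memory", "long-term memory",
    "episodic memory", "cognition", "cognitive", "cognitive performance",
    "cognitive function", "cognitive symptoms", "dementia", "Alzheimer's",
    "word finding difficulty", "sharp", "sharper", "clarity", "memory loss",
    "memory lapses", "remembering", "repeating himself", "repeating herself",
    "repeating questions", "repetitions", "mentation"
  ),
  improve_cues = c(
    "improve", "improvement", "improved", "improving", "better", "well",
    "doing well", "help", "helped", "helpful", "benefits",
    "remembering more things", "no longer depressed", "not depressed",
    "does not feel depressed", "sharper", "more hopeful", "more active",
    "more engaging", "more engaged", "more interactive", "more verbal",
    "close to normal", "almost all the way back to baseline", "calmed down",
    "calmer", "positive effect", "positive turn around",
    # templates
    "working well|drug", "less|symptom", "decreased|symptom",
    "improvement in|symptom", "reduction in|symptom",
    "stable|psychiatric", "controlled|psychiatric",
    "under control|psychiatric"
  ),
  no_change_cues = c(
    "no change", "unchanged", "no major change", "no significant change",
    "no benefit", "uncertain benefit", "no improvement",
    "not noticed a difference", "not noticed any difference",
    "not made noticeable difference", "about the same", "same",
    "not helpful", "did not help", "didn't help", "ineffective",
    "lack of effect", "no significant deterioration",
    "no worsening of symptoms", "has not done much",
    # templates
    "stable|cognitive", "stabilized|cognitive", "not progressing|cognitive",
    "continued|symptom", "remain|symptom", "still have|symptom"
  ),
  worsen_cues = c(
    "worsen", "worsened", "worse", "worst", "worsening", "more trouble",
    "continue to decline", "decline in memory", "decline in cognition",
    "decline in focus", "decline in concentration",
    # templates
    "more|symptom", "increased|symptom", "increasingly|symptom",
    "worsening of|symptom", "advancement in|symptom"
  ),
  intensity_markedly = c(
    "markedly", "marked", "significant", "significantly", "much", "very",
    "very much", "really", "great", "greatly", "quite", "dramatic",
    "dramatically", "clear", "clearly", "notable", "notably", "noticeably"
  ),
  intensity_moderately = c("moderately", "moderate"),
  intensity_slightly = c(
    "slightly", "slight", "minimally", "minimal", "bit", "little",
    "little bit", "some", "somewhat"
  )
)

parse_entry <- function(raw) {
  parts <- strsplit(raw, "|", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    list(phrase = trimws(parts[1]), slot = NA_character_)
  } else if (length(parts) == 2L) {
    list(phrase = trimws(parts[1]), slot = trimws(parts[2]))
  } else {
    stop_contract("malformed lexicon entry: '%s'", raw)
  }
}

# Flatten entry lists into a match table: one row per entry with its
# tokenized phrase precomputed for matching.
build_match_table <- function(entries) {
  rows <- list()
  for (cat in names(entries)) {
    for (raw in entries[[cat]]) {
      e <- parse_entry(raw)
      toks <- tokenize(normalize_text(e$phrase))$token
      rows[[length(rows) + 1L]] <- list(
        phrase = tolower(normalize_text(e$phrase)), category = cat,
        group = unname(.category_group[cat]), slot = e$slot,
        n_tokens = length(toks), tokens = toks
      )
    }
  }
  tab <- data.frame(
    phrase = vapply(rows, `[[`, "", "phrase"),
    category = vapply(rows, `[[`, "", "category"),
    group = vapply(rows, `[[`, "", "group"),
    slot = vapply(rows, `[[`, "", "slot"),
    n_tokens = vapply(rows, `[[`, 0L, "n_tokens"),
    stringsAsFactors = FALSE
  )
  tab$tokens <- lapply(rows, `[[`, "tokens")
  tab
}

validate_lexicon <- function(entries) {
  missing <- setdiff(.lexicon_categories, names(entries))
  if (length(missing)) {
    stop_contract("lexicon is missing categories: %s",
                  paste(missing, collapse = ", "))
  }
  parsed <- lapply(.lexicon_categories, function(cat) {
    lapply(entries[[cat]], function(raw) {
      e <- parse_entry(raw)
      if (!is.na(e$slot) && !(e$slot %in% .valid_slots)) {
        stop_contract("entry '%s' in %s declares unknown slot '%s'",
                      e$phrase, cat, e$slot)
      }
      if (!is.na(e$slot) && !(cat %in% .direction_categories)) {
        stop_contract("slot template '%s' only allowed in direction categories",
                      raw)
      }
      c(phrase = tolower(e$phrase), slot = e$slot, category = cat)
    })
  })
  names(parsed) <- .lexicon_categories

  # direction uniqueness: a literal phrase may appear in only one direction
  # category; template triggers may recur across categories only with
  # different slots (the stable/controlled rule)
  dir <- do.call(rbind, lapply(.direction_categories, function(cat) {
    do.call(rbind, lapply(parsed[[cat]], function(x) {
      data.frame(phrase = x[["phrase"]], slot = x[["slot"]],
                 category = cat, stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(dir)) {
    key <- paste(dir$phrase, ifelse(is.na(dir$slot), "<literal>", dir$slot))
    dup_key <- key[duplicated(key)]
    lit <- dir[is.na(dir$slot), ]
    lit_dup <- lit$phrase[duplicated(lit$phrase)]
    cross <- unique(c(dup_key, lit_dup))
    if (length(cross)) {
      stop_contract("phrase duplicated across direction categories: %s",
                    paste(unique(sub(" <literal>$", "", cross)), collapse = ", "))
    }
  }

  ssri <- tolower(vapply(parsed$ssri_names, `[[`, "", "phrase"))
  cei <- tolower(vapply(parsed$cei_names, `[[`, "", "phrase"))
  both <- intersect(ssri, cei)
  if (length(both)) {
    stop_contract("drug name(s) present in both SSRI and CEI sets: %s",
                  paste(both, collapse = ", "))
  }
  invisible(TRUE)
}

new_lexicon <- function(entries) {
  validate_lexicon(entries)
  obj <- list(entries = entries[.lexicon_categories],
              match_table = build_match_table(entries[.lexicon_categories]))
  class(obj) <- "keyword_lexicon"
  obj
}

#' Load a keyword lexicon
#'
#' With no arguments, returns the built-in default lexicon (the full phrase
#' inventory used for annotation). With a path, parses a plain-text lexicon
#' file: one `[category]` section header per category, one phrase per line,
#' `|` separating a template trigger from its slot name, `#` comments and
#' blank lines ignored.
#'
#' @param path optional path to a lexicon file; `NULL` for the default
#' @return a `keyword_lexicon` object
#' @examples
#' lex <- load_lexicon()
#' "donepezil" %in% lex$entries$cei_names
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    return(new_lexicon(.default_lexicon_entries))
  }
  if (!file.exists(path)) stop_contract("lexicon file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- stats::setNames(
    replicate(length(.lexicon_categories), character(), simplify = FALSE),
    .lexicon_categories)
  current <- NA_character_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!(current %in% .lexicon_categories)) {
        stop_contract("line %d: unknown lexicon section '[%s]'", i, current)
      }
      next
    }
    if (is.na(current)) {
      stop_contract("line %d: phrase '%s' appears before any section header",
                    i, ln)
    }
    entries[[current]] <- c(entries[[current]], ln)
  }
  new_lexicon(entries)
}

#' Write a lexicon to its plain-text file format
#'
#' @param lexicon a `keyword_lexicon`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "keyword_lexicon"))
  out <- character()
  for (cat in .lexicon_categories) {
    out <- c(out, sprintf("[%s]", cat), lexicon$entries[[cat]], "")
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' @export
print.keyword_lexicon <- function(x, ...) {
  n <- vapply(x$entries, length, 0L)
  cat("<keyword_lexicon>\n")
  for (cat in names(n)) cat(sprintf("  %-20s %d entries\n", cat, n[cat]))
  invisible(x)
}

# Map a drug name to its class ("SSRI"/"CEI") or NA.
drug_class_of <- function(drug_name, lexicon = load_lexicon()) {
  d <- tolower(trimws(drug_name))
  ifelse(d %in% tolower(lexicon$entries$ssri_names), "SSRI",
         ifelse(d %in% tolower(lexicon$entries$cei_names), "CEI",
                NA_character_))
}
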