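#' Default ground-truth category counts per drug class
#'
#' The built-in case mix of the synthetic corpus: 225 SSRI cases
#' (6 N/A, 17 intolerant, 156 improved, 28 no change, 18 worse) and 115
#' CEI cases (7 N/A, 12 intolerant, 31 improved, 40 no change, 25 worse),
#' the observed outpatient case mix the generator emulates.
#'
#' @param drug_class `"SSRI"` or `"CEI"`
#' @return named integer vector over
#'   `c("na", "intolerant", "improved", "no_change", "worsen")`
#' @export
default_category_counts <- function(drug_class = c("SSRI", "CEI")) {
  drug_class <- match.arg(drug_class)
  if (drug_class == "SSRI") {
    c(na = 6L, intolerant = 17L, improved = 156L, no_change = 28L,
      worsen = 18L)
  } else {
    c(na = 7L, intolerant = 12L, improved = 31L, no_change = 40L,
      worsen = 25L)
  }
}

.default_diagnosis_counts <- list(
  SSRI = c(AD = 73L, VD = 42L, `AD+VD` = 20L, Others = 90L),
  CEI = c(AD = 54L, VD = 13L, `AD+VD` = 13L, Others = 35L))
.default_sex_counts <- list(SSRI = c(Woman = 117L, Man = 108L),
                            CEI = c(Woman = 55L, Man = 60L))
.default_age <- list(SSRI = c(mean = 73, sd = 9.7),
                     CEI = c(mean = 74, sd = 8.8))

#' Configuration for the synthetic EMR corpus
#'
#' @param drug_class `"SSRI"` or `"CEI"`
#' @param category_counts named counts over the five ground-truth NOTE
#'   categories; defaults to [default_category_counts()]
#' @param source_mix probabilities over author roles for generated comments
#' @param noise_rate probability that a generated comment loses its
#'   direction keyword (the comment becomes unrecoverable) and that a
#'   distractor sentence is added
#' @param cibic_intensity_rate probability an intensity modifier is
#'   attached to a direction cue (it is what makes a comment classifiable
#'   on the seven-point scale)
#' @param mmse_rate fraction of evaluable cognitive cases that also get
#'   pre/post MMSE records whose change sign matches the truth direction
#' @param comment_day_min,comment_day_max window (days after start) in
#'   which the comment date is drawn; centred near the six-month target
#' @param seed integer seed; every downstream draw is deterministic in it
#' @return a `corpus_config` list
#' @export
corpus_config <- function(drug_class = c("SSRI", "CEI"),
                          category_counts = NULL,
                          source_mix = c(clinician = 0.7, caregiver = 0.2,
                                         patient = 0.1),
                          noise_rate = 0,
                          cibic_intensity_rate = 0.7,
                          mmse_rate = 0.5,
                          comment_day_min = 120L, comment_day_max = 240L,
                          seed = 1L) {
  drug_class <- match.arg(drug_class)
  if (is.null(category_counts)) {
    category_counts <- default_category_counts(drug_class)
  }
  need <- c("na", "intolerant", "improved", "no_change", "worsen")
  if (!all(need %in% names(category_counts))) {
    stop_contract("category_counts must name: %s", paste(need, collapse = ", "))
  }
  stopifnot(noise_rate >= 0, noise_rate <= 1,
            cibic_intensity_rate >= 0, cibic_intensity_rate <= 1,
            abs(sum(source_mix) - 1) < 1e-8)
  structure(list(drug_class = drug_class,
                 n_cases = sum(category_counts[need]),
                 category_counts = category_counts[need],
                 source_mix = source_mix, noise_rate = noise_rate,
                 cibic_intensity_rate = cibic_intensity_rate,
                 mmse_rate = mmse_rate,
                 comment_day_min = comment_day_min,
                 comment_day_max = comment_day_max, seed = seed),
            class = "corpus_config")
}

sample_exact <- function(counts, n) {
  if (sum(counts) != n) {
    # scale proportionally, fixing rounding drift on the largest cell
    x <- round(counts / sum(counts) * n)
    x[which.max(x)] <- x[which.max(x)] + (n - sum(x))
    counts <- x
  }
  sample(rep(names(counts), times = counts))
}

#' Generate the per-case ground-truth table
#'
#' Category counts are honoured exactly (never sampled); covariates are
#' drawn from the configured margins. Deterministic per seed.
#'
#' @param config a [corpus_config()]
#' @return data frame with one row per case: `case_id`, `patient_id`,
#'   `drug_class`, `truth_category`, `truth_note`, `domain`,
#'   `diagnosis_group`, `sex`, `age`
#' @export
generate_case_truth_table <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  n <- config$n_cases
  cats <- sample(rep(names(config$category_counts),
                     times = config$category_counts))
  dc <- config$drug_class
  prefix <- if (dc == "SSRI") "S" else "C"
  ages <- round(pmin(pmax(stats::rnorm(n, .default_age[[dc]]["mean"],
                                       .default_age[[dc]]["sd"]), 50), 95))
  data.frame(
    case_id = sprintf("%s%04d", prefix, seq_len(n)),
    patient_id = sprintf("P%s%04d", prefix, seq_len(n)),
    drug_class = dc,
    truth_category = cats,
    truth_note = c(na = 0, intolerant = 0.5, improved = 1, no_change = 2,
                   worsen = 3)[cats],
    domain = unname(default_domain(dc)),
    diagnosis_group = sample_exact(.default_diagnosis_counts[[dc]], n),
    sex = sample_exact(.default_sex_counts[[dc]], n),
    age = ages,
    stringsAsFactors = FALSE)
}

.sentence_templates <- list(
  psychiatric = list(
    improve = c("Anxiety %sbetter.", "Mood %simproved."),
    no_change = c("Anxiety about the same.", "Mood unchanged."),
    worsen = c("Agitation %sworse.", "Anxiety %sworse.")),
  cognitive = list(
    improve = c("Memory %sbetter.", "Memory %simproved."),
    no_change = c("Dementia stable.", "Memory about the same."),
    worsen = c("Memory %sworse.", "Cognition %sworse.")))

.intensity_words <- c(markedly = "much", moderately = "moderately",
                      slightly = "slightly")

.ssri_drugs <- c("sertraline", "citalopram", "escitalopram")
.cei_drugs <- c("donepezil", "rivastigmine", "galantamine")

.distractor <- "Patient accompanied by family at today's clinic visit."

#' Render the synthetic corpus files from a truth table
#'
#' Every evaluable case yields at least one sentence embedding a symptom
#' cue and a direction cue consistent with its truth; intolerant cases are
#' signalled through a structured adverse-event discontinuation flag (not
#' text); N/A cases yield a comment in the non-prioritized domain only, so
#' follow-up exists but the prioritized score stays unavailable. Each case
#' produces exactly one prescription record and hence one included
#' episode.
#'
#' @param truth truth table from [generate_case_truth_table()]
#' @param lexicon lexicon used for drug names (default built-in)
#' @param config the same [corpus_config()] used for the truth table
#' @return list with `notes`, `prescriptions`, `cognitive` (data frames in
#'   the pipeline's input formats) and `truth` (the table augmented with
#'   `truth_intensity` and `comment_date`)
#' @export
render_note_corpus <- function(truth, lexicon = load_lexicon(), config) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  base_date <- as.Date("2015-01-01")
  start <- base_date + sample.int(365L, n, replace = TRUE)
  drugs <- if (config$drug_class == "SSRI") .ssri_drugs else .cei_drugs
  drug <- sample(drugs, n, replace = TRUE)
  roles <- sample(names(config$source_mix), n, replace = TRUE,
                  prob = config$source_mix)
  comment_day <- sample(seq(config$comment_day_min, config$comment_day_max),
                        n, replace = TRUE)
  with_intensity <- stats::runif(n) < config$cibic_intensity_rate
  intensity <- ifelse(with_intensity,
                      sample(names(.intensity_words), n, replace = TRUE),
                      "none")
  noisy <- stats::runif(n) < config$noise_rate

  other <- function(d) if (d == "psychiatric") "cognitive" else "psychiatric"
  notes <- vector("list", n)
  presc <- vector("list", n)
  cogn <- list()
  truth$truth_intensity <- "none"
  truth$comment_date <- as.Date(NA)

  for (i in seq_len(n)) {
    cat_i <- truth$truth_category[i]
    dom <- truth$domain[i]
    cdate <- start[i] + comment_day[i]
    text <- NULL
    if (cat_i == "intolerant") {
      text <- sprintf("Stopped %s due to nausea and vomiting.", drug[i])
    } else if (cat_i == "na") {
      # a real follow-up comment, but in the other domain
      dir_other <- "worsen"
      tpl <- .sentence_templates[[other(dom)]][[dir_other]][1]
      text <- sprintf(tpl, "")
    } else {
      dir <- c(improved = "improve", no_change = "no_change",
               worsen = "worsen")[cat_i]
      use_int <- intensity[i] != "none" && dir != "no_change"
      if (use_int) truth$truth_intensity[i] <- intensity[i]
      tpls <- .sentence_templates[[dom]][[dir]]
      tpl <- tpls[1 + (i %% length(tpls))]
      ins <- if (use_int && grepl("%s", tpl, fixed = TRUE)) {
        paste0(.intensity_words[intensity[i]], " ")
      } else ""
      text <- if (grepl("%s", tpl, fixed = TRUE)) sprintf(tpl, ins) else tpl
      if (noisy[i]) text <- "Plan reviewed with family."  # keyword omitted
    }
    if (noisy[i] && cat_i != "intolerant") {
      text <- paste(text, .distractor)
    }
    truth$comment_date[i] <- cdate
    notes[[i]] <- data.frame(
      note_id = sprintf("N%s", truth$case_id[i]),
      patient_id = truth$patient_id[i],
      date = cdate, author_role = roles[i], text = text,
      stringsAsFactors = FALSE)

    presc[[i]] <- data.frame(
      record_id = sprintf("RX%s", truth$case_id[i]),
      patient_id = truth$patient_id[i], drug_name = drug[i],
      order_date = start[i], reported_start_date = start[i],
      reported_stop_date = if (cat_i == "intolerant") start[i] + 60L
                           else as.Date(NA),
      flags = if (cat_i == "intolerant") "discontinued_adverse_event" else "",
      prior_snri_end_date = as.Date(NA), stringsAsFactors = FALSE)

    if (dom == "cognitive" && cat_i %in% c("improved", "no_change", "worsen")
        && stats::runif(1) < config$mmse_rate) {
      delta <- c(improved = 2L, no_change = 0L, worsen = -3L)[cat_i]
      pre <- 24L
      cogn[[length(cogn) + 1L]] <- data.frame(
        patient_id = rep(truth$patient_id[i], 2L),
        date = c(start[i] - sample.int(10L, 1L), cdate + sample.int(7L, 1L)),
        instrument = "MMSE", raw_score = c(pre, pre + delta),
        stringsAsFactors = FALSE)
    }
  }
  cognitive <- if (length(cogn)) do.call(rbind, cogn) else
    data.frame(patient_id = character(), date = as.Date(character()),
               instrument = character(), raw_score = integer(),
               stringsAsFactors = FALSE)
  list(notes = do.call(rbind, notes), prescriptions = do.call(rbind, presc),
       cognitive = cognitive, truth = truth)
}

#' Generate a paired-rater rating matrix with controlled disagreement
#'
#' Rater 1 is drawn from the category margins; rater 2 equals rater 1
#' except for the transpositions given in `disagreement_spec`.
#' Deterministic per seed.
#'
#' @param n_units number of rated units
#' @param disagreement_spec data frame with `from`, `to`, `count`: how many
#'   of rater 1's `from` ratings rater 2 records as `to`
#' @param margins named counts (summing to `n_units`) or probabilities over
#'   rating categories for rater 1
#' @param seed integer seed
#' @return `n_units` x 2 numeric matrix
#' @export
generate_rater_pair <- function(n_units,
                                disagreement_spec = NULL,
                                margins = c(`0` = 0.15, `1` = 0.45,
                                            `2` = 0.25, `3` = 0.15),
                                seed = 1L) {
  set.seed(seed)
  if (abs(sum(margins) - n_units) < 1e-9 &&
      all(abs(margins - round(margins)) < 1e-9)) {
    r1 <- as.numeric(sample(rep(names(margins), times = round(margins))))
  } else {
    r1 <- as.numeric(sample(names(margins), n_units, replace = TRUE,
                            prob = margins))
  }
  r2 <- r1
  if (!is.null(disagreement_spec) && nrow(disagreement_spec)) {
    for (i in seq_len(nrow(disagreement_spec))) {
      from <- as.numeric(disagreement_spec$from[i])
      to <- as.numeric(disagreement_spec$to[i])
      cnt <- disagreement_spec$count[i]
      idx <- which(r1 == from & r2 == r1)
      if (length(idx) < cnt) {
        stop_contract(
          "infeasible disagreement spec: %d x (%s -> %s) requested, %d available",
          cnt, disagreement_spec$from[i], disagreement_spec$to[i], length(idx))
      }
      r2[idx[seq_len(cnt)]] <- to
    }
  }
  cbind(rater1 = r1, rater2 = r2)
}
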