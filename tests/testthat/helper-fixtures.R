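# Shared fixtures and independent oracles used across tests.

mk_note <- function(text, date = "2015-07-01", role = "clinician",
                    note_id = "N1", patient_id = "P1") {
  data.frame(note_id = note_id, patient_id = patient_id, date = date,
             author_role = role, text = text, stringsAsFactors = FALSE)
}

mk_rx <- function(patient_id = "P1", drug = "sertraline",
                  order = "2015-01-01", start = order, stop = NA,
                  flags = "", snri_end = NA, record_id = NULL) {
  data.frame(record_id = record_id %||% paste0("R", patient_id, drug),
             patient_id = patient_id, drug_name = drug,
             order_date = order, reported_start_date = start,
             reported_stop_date = stop, flags = flags,
             prior_snri_end_date = snri_end, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_episode <- function(patient_id = "P1", drug_class = "SSRI",
                       start = "2015-01-01", end = NA, index = start,
                       intolerant = FALSE) {
  data.frame(episode_id = paste0(patient_id, "-", drug_class, "-1"),
             patient_id = patient_id, drug_class = drug_class,
             drug_sequence = "x", start_date = as.Date(start),
             end_date = as.Date(end), index_date = as.Date(index),
             intolerant = intolerant, flags = "",
             prior_snri_end_date = as.Date(NA), status = "included",
             exclusion_reason = NA_character_, stringsAsFactors = FALSE)
}

mk_ann <- function(date, direction, domain = "psychiatric",
                   role = "clinician", intensity = "none",
                   patient_id = "P1", drug_classes = "",
                   annotation_id = "A1") {
  data.frame(note_id = "N", patient_id = patient_id, date = as.Date(date),
             author_role = role, domain = domain, direction = direction,
             intensity = intensity, drug_classes = drug_classes,
             evidence = "", annotation_id = annotation_id,
             stringsAsFactors = FALSE)
}

# Independent brute-force Krippendorff's alpha (ordinal): explicit loops
# over every pairable value pair, no shared code with the package version.
alpha_oracle_ordinal <- function(m) {
  vals <- sort(unique(na.omit(as.vector(m))))
  # pooled pairable values (margins)
  nc <- setNames(numeric(length(vals)), vals)
  for (u in seq_len(nrow(m))) {
    vu <- m[u, ][!is.na(m[u, ])]
    if (length(vu) < 2) next
    for (v in vu) nc[as.character(v)] <- nc[as.character(v)] + 1
  }
  n <- sum(nc)
  d2 <- function(c1, c2) {
    if (c1 == c2) return(0)
    i1 <- which(vals == c1); i2 <- which(vals == c2)
    lo <- min(i1, i2); hi <- max(i1, i2)
    (sum(nc[lo:hi]) - (nc[i1] + nc[i2]) / 2)^2
  }
  Do <- 0
  for (u in seq_len(nrow(m))) {
    vu <- m[u, ][!is.na(m[u, ])]
    mu <- length(vu)
    if (mu < 2) next
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i != j) Do <- Do + d2(vu[i], vu[j]) / (mu - 1)
    }
  }
  Do <- Do / n
  De <- 0
  for (c1 in vals) for (c2 in vals) {
    De <- De + nc[as.character(c1)] * nc[as.character(c2)] * d2(c1, c2)
  }
  De <- De / (n * (n - 1))
  unname(1 - Do / De)
}

# Negative log-likelihood of a baseline-category logit with one binary
# covariate and a 3-category outcome (used as a brute-force MLE oracle).
mlogit_nll_2x3 <- function(par, x, y) {
  # par: a2, b2, a3, b3 (category 1 is baseline)
  eta2 <- par[1] + par[2] * x
  eta3 <- par[3] + par[4] * x
  denom <- 1 + exp(eta2) + exp(eta3)
  ll <- ifelse(y == 1, -log(denom),
        ifelse(y == 2, eta2 - log(denom), eta3 - log(denom)))
  -sum(ll)
}

run_default_pipeline <- function(drug_class, seed = 11, noise_rate = 0,
                                 counts = NULL) {
  cfg <- corpus_config(drug_class, category_counts = counts,
                       noise_rate = noise_rate, seed = seed)
  corpus <- render_note_corpus(generate_case_truth_table(cfg),
                               load_lexicon(), cfg)
  res <- run_pipeline(notes = corpus$notes,
                      prescriptions = corpus$prescriptions,
                      cognitive = corpus$cognitive)
  list(cfg = cfg, corpus = corpus, res = res)
}

truth_vs_assigned <- function(rt) {
  pr <- prioritized_scores(rt$res$scores)
  pr$patient_id <- sub("-(SSRI|CEI)-[0-9]+$", "", pr$episode_id)
  merge(rt$corpus$truth, pr[, c("patient_id", "note_value", "cibic_value")],
        by = "patient_id", all.x = TRUE)
}
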