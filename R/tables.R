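.note_category_labels <- c(`0` = "N/A", `0.5` = "Intolerance",
                           `1` = "Improved", `2` = "No change",
                           `3` = "Worsen")

note_category <- function(note_value) {
  unname(.note_category_labels[as.character(note_value)])
}

#' Responder / NOTE-category rate table
#'
#' Per-drug-class counts and percentages over the five NOTE categories and
#' over the responder categories, with optional stratification by
#' diagnosis group, sex, and age (mean and SD per NOTE category).
#' Percentages are rounded half-up to one decimal.
#'
#' @param classifications data frame with `episode_id`, `drug_class`,
#'   `category` (responder / non_responder / intolerant / not_evaluable)
#' @param scores data frame with `episode_id` and the prioritized
#'   `note_value` per episode
#' @param covariates optional data frame with `episode_id`,
#'   `diagnosis_group`, `sex`, `age`
#' @return list of data frames: `note_rates`, `responder_rates`, and (when
#'   covariates are given) `by_diagnosis`, `by_sex`, `age_summary`
#' @export
responder_rate_table <- function(classifications, scores, covariates = NULL) {
  cls <- merge(classifications, scores[, c("episode_id", "note_value")],
               by = "episode_id", all.x = TRUE)
  pct <- function(n, total) if (total == 0) 0 else round_half_up(100 * n / total, 1)

  note_rates <- do.call(rbind, lapply(unique(cls$drug_class), function(dc) {
    g <- cls[cls$drug_class == dc, , drop = FALSE]
    total <- nrow(g)
    do.call(rbind, lapply(names(.note_category_labels), function(v) {
      n <- sum(g$note_value == as.numeric(v))
      data.frame(drug_class = dc, note_category = .note_category_labels[[v]],
                 n = n, total = total, percent = pct(n, total),
                 stringsAsFactors = FALSE)
    }))
  }))

  resp_levels <- c("responder", "non_responder", "intolerant", "not_evaluable")
  responder_rates <- do.call(rbind, lapply(unique(cls$drug_class), function(dc) {
    g <- cls[cls$drug_class == dc, , drop = FALSE]
    total <- nrow(g)
    do.call(rbind, lapply(resp_levels, function(ct) {
      n <- sum(g$category == ct)
      data.frame(drug_class = dc, category = ct, n = n, total = total,
                 percent = pct(n, total), stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(note_rates)) {
    note_rates <- data.frame(drug_class = character(),
                             note_category = character(), n = integer(),
                             total = integer(), percent = numeric())
  }
  if (is.null(responder_rates)) {
    responder_rates <- data.frame(drug_class = character(),
                                  category = character(), n = integer(),
                                  total = integer(), percent = numeric())
  }
  rownames(note_rates) <- rownames(responder_rates) <- NULL
  out <- list(note_rates = note_rates, responder_rates = responder_rates)

  if (!is.null(covariates)) {
    cc <- merge(cls, covariates, by = "episode_id")
    strat <- function(var) {
      do.call(rbind, lapply(unique(cc$drug_class), function(dc) {
        g <- cc[cc$drug_class == dc, , drop = FALSE]
        do.call(rbind, lapply(sort(unique(g[[var]])), function(lev) {
          gg <- g[g[[var]] == lev, , drop = FALSE]
          total <- nrow(gg)
          do.call(rbind, lapply(names(.note_category_labels), function(v) {
            n <- sum(gg$note_value == as.numeric(v))
            data.frame(drug_class = dc, level = lev,
                       note_category = .note_category_labels[[v]], n = n,
                       total = total, percent = pct(n, total),
                       stringsAsFactors = FALSE)
          }))
        }))
      }))
    }
    out$by_diagnosis <- strat("diagnosis_group")
    out$by_sex <- strat("sex")
    out$age_summary <- do.call(rbind, lapply(unique(cc$drug_class), function(dc) {
      g <- cc[cc$drug_class == dc, , drop = FALSE]
      do.call(rbind, lapply(c("all", names(.note_category_labels)), function(v) {
        gg <- if (v == "all") g else g[g$note_value == as.numeric(v), ,
                                       drop = FALSE]
        data.frame(drug_class = dc,
                   note_category = if (v == "all") "Total"
                                   else .note_category_labels[[v]],
                   n = nrow(gg),
                   age_mean = if (nrow(gg)) round_half_up(mean(gg$age), 1)
                              else NA_real_,
                   age_sd = if (nrow(gg) > 1) round_half_up(stats::sd(gg$age), 1)
                            else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  out
}

#' Map an ICD-10 dementia code to a diagnosis group
#'
#' F01 alone is vascular dementia, G30 alone Alzheimer's disease, both
#' together mixed dementia, anything else "Others".
#'
#' @param codes character vector of semicolon-joined ICD-10 codes
#' @return character vector of groups: `"AD"`, `"VD"`, `"AD+VD"`, `"Others"`
#' @export
diagnosis_group <- function(codes) {
  vapply(strsplit(codes, ";", fixed = TRUE), function(x) {
    x <- trimws(x)
    has_vd <- any(startsWith(x, "F01"))
    has_ad <- any(startsWith(x, "G30"))
    if (has_vd && has_ad) "AD+VD"
    else if (has_ad) "AD"
    else if (has_vd) "VD"
    else "Others"
  }, "")
}

#' Multinomial baseline-category logit with type-II likelihood-ratio tests
#'
#' Fits the outcome (responder / non-responder / intolerant; not-evaluable
#' episodes must be excluded upstream) against covariates by maximum
#' likelihood, then tests each covariate by the likelihood-ratio test of
#' the full model against the model with that covariate dropped (type II).
#'
#' @param data data frame containing the outcome and covariates
#' @param outcome name of the outcome column (factor or character)
#' @param covariates character vector of covariate column names
#' @return list with `fit` (the full `nnet::multinom` fit), `loglik`, and
#'   `tests` (data frame: covariate, df, LR statistic, p-value)
#' @export
fit_multinomial_logit <- function(data, outcome = "category",
                                  covariates = c("diagnosis_group", "sex",
                                                 "age")) {
  d <- data[!(data[[outcome]] %in% "not_evaluable"), , drop = FALSE]
  d[[outcome]] <- droplevels(factor(d[[outcome]]))
  if (nlevels(d[[outcome]]) < 2L) {
    stop_contract("need at least 2 outcome categories")
  }
  for (v in covariates) {
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  }
  form <- stats::reformulate(covariates, response = outcome)
  fit <- nnet::multinom(form, data = d, trace = FALSE, maxit = 500)
  if (fit$convergence != 0) {
    stop_contract("multinomial fit did not converge (value %.4f)",
                  fit$value)
  }
  ll_full <- -fit$value  # nnet stores the negative log-likelihood
  tests <- do.call(rbind, lapply(covariates, function(v) {
    reduced <- setdiff(covariates, v)
    form_r <- if (length(reduced)) {
      stats::reformulate(reduced, response = outcome)
    } else stats::reformulate("1", response = outcome)
    fit_r <- nnet::multinom(form_r, data = d, trace = FALSE, maxit = 500)
    lr <- 2 * (ll_full - (-fit_r$value))
    df <- fit$edf - fit_r$edf
    data.frame(covariate = v, df = df, lr_stat = lr,
               p = stats::pchisq(max(lr, 0), df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(fit = fit, loglik = ll_full, tests = tests)
}
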