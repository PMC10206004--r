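mk_cls <- function(categories, drug_class = "SSRI") {
  data.frame(episode_id = sprintf("E%03d", seq_along(categories)),
             drug_class = rep(drug_class, length(categories)),
             category = categories, stringsAsFactors = FALSE)
}
mk_scores <- function(values) {
  data.frame(episode_id = sprintf("E%03d", seq_along(values)),
             note_value = values, stringsAsFactors = FALSE)
}

test_that("rate table counts, percentages, and rounding are correct", {
  cls <- mk_cls(c("responder", "responder", "responder", "non_responder"))
  sc <- mk_scores(c(1, 1, 1, 3))
  rt <- responder_rate_table(cls, sc)
  rr <- rt$responder_rates
  expect_equal(rr$percent[rr$category == "responder"], 75.0)
  expect_equal(sum(rr$n), 4L)
  nr <- rt$note_rates
  expect_equal(sum(nr$percent), 100, tolerance = 0.11)  # rounding drift
  expect_equal(nr$n[nr$note_category == "Improved"], 3L)
})

test_that("empty input yields an all-zero but schema-valid table", {
  rt <- responder_rate_table(mk_cls(character()), mk_scores(numeric()))
  expect_s3_class(rt$responder_rates, "data.frame")
  expect_equal(nrow(rt$responder_rates), 0L)
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(69.25, 1), 69.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("diagnosis groups map from ICD-10 codes", {
  expect_equal(diagnosis_group(c("G30", "F01", "F01;G30.9", "F03", "")),
               c("AD", "VD", "AD+VD", "Others", "Others"))
})

test_that("covariate stratification reports per-level counts and ages", {
  cls <- mk_cls(c("responder", "non_responder", "responder", "intolerant"))
  sc <- mk_scores(c(1, 3, 1, 0.5))
  cov <- data.frame(episode_id = cls$episode_id,
                    diagnosis_group = c("AD", "AD", "VD", "Others"),
                    sex = c("Woman", "Man", "Woman", "Man"),
                    age = c(70, 80, 75, 65))
  rt <- responder_rate_table(cls, sc, cov)
  ad <- rt$by_diagnosis[rt$by_diagnosis$level == "AD", ]
  expect_equal(unique(ad$total), 2L)
  expect_equal(ad$n[ad$note_category == "Improved"], 1L)
  tot <- rt$age_summary[rt$age_summary$note_category == "Total", ]
  expect_equal(tot$age_mean, round_half_up(mean(cov$age), 1))
})

test_that("multinomial logit log-likelihood matches a brute-force MLE", {
  set.seed(10)
  x <- rep(c(0, 1), each = 60)
  probs <- cbind(c(0.5, 0.2), c(0.3, 0.3), c(0.2, 0.5))
  y <- vapply(seq_along(x), function(i) {
    sample(1:3, 1, prob = probs[x[i] + 1, ])
  }, 0L)
  d <- data.frame(category = factor(c("a", "b", "c")[y]), x = x)
  fit <- fit_multinomial_logit(d, outcome = "category", covariates = "x")
  oracle <- stats::optim(rep(0, 4), mlogit_nll_2x3, x = x, y = y,
                         method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$loglik, -oracle$value, tolerance = 1e-6)
})

test_that("an outcome determined by a covariate gives a tiny LRT p", {
  d <- data.frame(
    category = rep(c("responder", "non_responder"), each = 40),
    sex = rep(c("Woman", "Man"), each = 40),
    age = rep(70, 80))
  fit <- fit_multinomial_logit(d, covariates = c("sex", "age"))
  p_sex <- fit$tests$p[fit$tests$covariate == "sex"]
  expect_lt(p_sex, 1e-10)
})

test_that("a covariate independent of the outcome is rarely significant", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(1000 + s)
    n <- 2000
    d <- data.frame(
      category = sample(c("responder", "non_responder", "intolerant"), n,
                        replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      sex = sample(c("Woman", "Man"), n, replace = TRUE))
    fit <- fit_multinomial_logit(d, covariates = "sex")
    if (fit$tests$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("single-category outcomes and not-evaluable rows are rejected", {
  d <- data.frame(category = rep("responder", 10),
                  sex = rep(c("Woman", "Man"), 5))
  expect_error(fit_multinomial_logit(d, covariates = "sex"), "2 outcome")
  d2 <- data.frame(category = c(rep("responder", 5), rep("not_evaluable", 5)),
                   sex = rep(c("Woman", "Man"), 5))
  expect_error(fit_multinomial_logit(d2, covariates = "sex"), "2 outcome")
})
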