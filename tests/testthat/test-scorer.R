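lex <- load_lexicon()

test_that("improvement beats a later decline; nearest-to-target breaks within", {
  ep <- mk_episode()
  anns <- rbind(mk_ann("2015-03-02", "improve", annotation_id = "A1"),
                mk_ann("2015-10-28", "worsen", annotation_id = "A2"))
  chosen <- select_prioritized_comment(anns, ep)
  expect_equal(chosen$direction, "improve")

  # only no-change comments: pick the one closest to 182 days
  anns <- rbind(mk_ann("2015-04-11", "no_change", annotation_id = "B1"),
                mk_ann("2016-02-05", "no_change", annotation_id = "B2"))
  chosen <- select_prioritized_comment(anns, ep)
  expect_equal(chosen$annotation_id, "B1")
})

test_that("clinician comments outrank caregiver and patient comments", {
  ep <- mk_episode()
  anns <- rbind(
    mk_ann("2015-11-01", "no_change", role = "patient", annotation_id = "P"),
    mk_ann("2015-03-01", "no_change", role = "clinician", annotation_id = "C"))
  expect_equal(select_prioritized_comment(anns, ep)$annotation_id, "C")
  # unknown ranks below patient
  anns <- rbind(
    mk_ann("2015-07-01", "worsen", role = "unknown", annotation_id = "U"),
    mk_ann("2015-03-01", "worsen", role = "patient", annotation_id = "P"))
  expect_equal(select_prioritized_comment(anns, ep)$annotation_id, "P")
})

test_that("cognitive comments matching an MMSE-change date win", {
  ep <- mk_episode(drug_class = "CEI")
  anns <- rbind(
    mk_ann("2015-04-11", "no_change", domain = "cognitive",
           annotation_id = "EARLY"),                      # day 100
    mk_ann("2015-07-20", "no_change", domain = "cognitive",
           annotation_id = "NEAR182"))                    # day 200
  chosen <- select_prioritized_comment(
    anns, ep, mmse_change_dates = as.Date("2015-04-09"))
  expect_equal(chosen$annotation_id, "EARLY")
  # without the MMSE match the later comment is closer to six months
  chosen <- select_prioritized_comment(anns, ep)
  expect_equal(chosen$annotation_id, "NEAR182")
})

test_that("NOTE assignment maps directions and handles intolerance and N/A", {
  ep <- mk_episode()
  anns <- mk_ann("2015-07-01", "improve")
  s <- assign_note(ep, anns, "psychiatric")
  expect_equal(s$note_value, 1)

  # intolerant episode scores 0.5 regardless of comments
  ep_it <- mk_episode(intolerant = TRUE)
  s <- assign_note(ep_it, anns, "psychiatric")
  expect_equal(s$note_value, 0.5)
  expect_equal(s$cibic_value, 0.5)

  # no annotations at all: N/A on both domains
  s <- assign_note(mk_episode(), anns[0, ], "psychiatric")
  expect_equal(s$note_value, 0)
  expect_equal(s$cibic_value, 0)
})

test_that("unclassified comments count only toward the class's own domain", {
  # CEI episode whose only evidence is "donepezil helpful"
  notes <- mk_note("Donepezil helpful.", date = "2015-07-01")
  anns <- annotate_notes(notes, lex)
  ep <- mk_episode(drug_class = "CEI")
  cog <- assign_note(ep, anns, "cognitive")
  psy <- assign_note(ep, anns, "psychiatric")
  expect_equal(cog$note_value, 1)
  expect_equal(psy$note_value, 0)
  # and an SSRI episode must not absorb the CEI-directed comment
  ep_ssri <- mk_episode(drug_class = "SSRI")
  expect_equal(assign_note(ep_ssri, anns, "psychiatric")$note_value, 0)
})

test_that("CIBIC-plus maps intensity onto the seven-point scale", {
  ep <- mk_episode()
  val <- function(text) {
    anns <- annotate_notes(mk_note(text, date = "2015-07-01"), lex)
    assign_note(ep, anns, "psychiatric")$cibic_value
  }
  expect_equal(val("Anxiety much better."), 1)
  expect_equal(val("Anxiety moderately improved."), 2)
  expect_equal(val("Anxiety slightly better."), 3)
  expect_equal(val("Anxiety unchanged."), 4)
  expect_equal(val("Anxiety slightly worse."), 5)
  expect_equal(val("Anxiety moderately worse."), 6)
  expect_equal(val("Anxiety much worse."), 7)
  # improvement without a modifier is N/A on the detailed scale only
  anns <- annotate_notes(mk_note("Sertraline working well.",
                                 date = "2015-07-01"), lex)
  s <- assign_note(mk_episode(), anns, "psychiatric")
  expect_equal(s$note_value, 1)
  expect_equal(s$cibic_value, 0)
})

test_that("responder definitions differ between drug classes", {
  sc <- function(v, domain) {
    data.frame(episode_id = "E", domain = domain, note_value = v)
  }
  expect_equal(classify_responder(sc(2, "cognitive"), "CEI")$category,
               "responder")
  expect_equal(classify_responder(sc(2, "psychiatric"), "SSRI")$category,
               "non_responder")
  expect_equal(classify_responder(sc(1, "psychiatric"), "SSRI")$category,
               "responder")
  expect_equal(classify_responder(sc(3, "cognitive"), "CEI")$category,
               "non_responder")
  expect_equal(classify_responder(sc(0.5, "psychiatric"), "SSRI")$category,
               "intolerant")
  expect_equal(classify_responder(sc(0, "cognitive"), "CEI")$category,
               "not_evaluable")
  expect_error(classify_responder(sc(1, "cognitive"), "SSRI"), "domain")
})

test_that("MoCA conversion uses the bundled crosswalk and validates range", {
  expect_equal(convert_moca_to_mmse(30), 30)
  expect_equal(convert_moca_to_mmse(0), 0)
  expect_error(convert_moca_to_mmse(31), "0-30")
  expect_error(convert_moca_to_mmse(-1), "0-30")
  # monotone, and MMSE passes through unchanged
  expect_true(all(diff(convert_moca_to_mmse(0:30)) >= 0))
  expect_equal(mmse_equivalent(rep("MMSE", 31), 0:30), 0:30)
  expect_equal(mmse_equivalent("MoCA", 30), 30)
})

test_that("MMSE change uses the nearest record inside the window", {
  ep <- mk_episode()
  rec <- function(days, score) {
    data.frame(patient_id = "P1", date = as.Date("2015-01-01") + days,
               instrument = "MMSE", raw_score = score,
               stringsAsFactors = FALSE)
  }
  records <- rbind(rec(-3, 24), rec(187, 26))
  expect_equal(compute_mmse_change(records, ep, as.Date("2015-07-01")), 2L)

  # no baseline within 14 days -> undefined
  records <- rbind(rec(-30, 24), rec(187, 26))
  expect_null(compute_mmse_change(records, ep, as.Date("2015-07-01")))

  # nearest-date rule, checked exhaustively over candidate offset pairs
  for (o1 in c(-10, -2, 3)) for (o2 in c(-1, 6, 10)) {
    records <- rbind(rec(o1, 20), rec(o2, 25), rec(185, 28))
    got <- compute_mmse_change(records, ep, as.Date("2015-07-05"))
    pre_expected <- if (abs(o1) < abs(o2) ||
                        (abs(o1) == abs(o2) && o1 < o2)) 20 else 25
    expect_equal(got, 28L - pre_expected)
  }
})

test_that("collapsing CIBIC-plus onto three points recovers NOTE", {
  rt <- run_default_pipeline("CEI", seed = 3)
  sc <- rt$res$scores
  ev <- sc[!(sc$cibic_value %in% c(0, 0.5)), ]
  collapsed <- ifelse(ev$cibic_value <= 3, 1,
                      ifelse(ev$cibic_value == 4, 2, 3))
  expect_true(all(collapsed == ev$note_value))
  # scale-consistency invariant on every scored row
  expect_true(all((sc$note_value == 0.5) == (sc$cibic_value == 0.5)))
  expect_true(all(sc$cibic_value[sc$note_value == 1] %in% c(0, 1, 2, 3)))
  expect_true(all(sc$cibic_value[sc$note_value == 2] %in% c(0, 4)))
  expect_true(all(sc$cibic_value[sc$note_value == 3] %in% c(0, 5, 6, 7)))
})
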