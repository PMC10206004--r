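test_that("a switch within the washout window merges into one episode", {
  rx <- rbind(
    mk_rx(drug = "citalopram", order = "2015-01-01", start = "2015-01-01",
          stop = "2015-03-01"),
    mk_rx(drug = "sertraline", order = "2015-03-01", start = "2015-03-01"))
  ep <- build_episodes(rx)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$drug_sequence, "citalopram,sertraline")
  expect_equal(ep$start_date, as.Date("2015-01-01"))
  expect_equal(ep$index_date, as.Date("2015-01-01"))
})

test_that("a gap at or beyond the washout starts a new episode", {
  rx <- rbind(
    mk_rx(drug = "donepezil", order = "2014-06-01", start = "2014-06-01",
          stop = "2015-01-01"),
    mk_rx(drug = "rivastigmine", order = "2015-05-01", start = "2015-05-01"))
  ep <- build_episodes(rx)  # 120-day gap
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$drug_sequence, c("donepezil", "rivastigmine"))

  # exact boundary: 89-day gap merges, 90-day gap splits
  mk_gap <- function(gap) rbind(
    mk_rx(drug = "sertraline", order = "2015-01-01", stop = "2015-02-01"),
    mk_rx(drug = "citalopram",
          order = format(as.Date("2015-02-01") + gap),
          start = format(as.Date("2015-02-01") + gap)))
  expect_equal(nrow(build_episodes(mk_gap(89))), 1L)
  expect_equal(nrow(build_episodes(mk_gap(90))), 2L)
})

test_that("single open-ended record yields one open episode", {
  ep <- build_episodes(mk_rx(drug = "donepezil", order = "2015-01-01"))
  expect_equal(nrow(ep), 1L)
  expect_true(is.na(ep$end_date))
})

test_that("different drug classes never share an episode", {
  rx <- rbind(mk_rx(drug = "sertraline", order = "2015-01-01"),
              mk_rx(drug = "donepezil", order = "2015-01-01"))
  ep <- build_episodes(rx)
  expect_equal(sort(ep$drug_class), c("CEI", "SSRI"))
})

test_that("adverse-event and allergy flags mark the episode intolerant", {
  ep <- build_episodes(mk_rx(flags = "discontinued_adverse_event",
                             stop = "2015-03-01"))
  expect_true(ep$intolerant)
  ep <- build_episodes(mk_rx(flags = "allergy_listed", stop = "2015-03-01"))
  expect_true(ep$intolerant)
  expect_false(build_episodes(mk_rx())$intolerant)
})

test_that("inconsistent stop-before-start dates raise a validation error", {
  expect_error(build_episodes(mk_rx(start = "2015-05-01", stop = "2015-02-01",
                                    record_id = "RBAD")), "RBAD")
})

test_that("episode count is non-increasing in washout_days", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    starts <- cumsum(c(0, sample(10:200, n - 1, replace = TRUE)))
    rx <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_rx(drug = sample(c("sertraline", "citalopram", "escitalopram"), 1),
            order = format(as.Date("2015-01-01") + starts[i]),
            stop = format(as.Date("2015-01-01") + starts[i] +
                            sample(5:120, 1)),
            record_id = paste0("R", rep, "_", i))
    }))
    counts <- vapply(c(30, 60, 90, 120, 180),
                     function(w) nrow(build_episodes(rx, w)), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("every usage day belongs to exactly one episode", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    starts <- cumsum(c(0, sample(10:250, n - 1, replace = TRUE)))
    stops <- starts + sample(5:100, n, replace = TRUE)
    rx <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_rx(drug = "sertraline",
            order = format(as.Date("2015-01-01") + starts[i]),
            stop = format(as.Date("2015-01-01") + stops[i]),
            record_id = paste0("Q", rep, "_", i))
    }))
    ep <- build_episodes(rx)
    for (i in seq_len(n)) {
      day <- as.Date("2015-01-01") + starts[i]
      covering <- sum(ep$start_date <= day &
                        (is.na(ep$end_date) | ep$end_date >= day))
      expect_equal(covering, 1L)
    }
  }
})

test_that("exclusion rules fire with the documented reasons", {
  # started >6 months before the index date
  ep <- build_episodes(mk_rx(order = "2015-07-20", start = "2015-01-01"))
  ep <- apply_exclusions(ep)
  expect_equal(ep$status, "excluded")
  expect_equal(ep$exclusion_reason, "early_start")

  # started >3 months after the index date
  ep <- apply_exclusions(build_episodes(
    mk_rx(order = "2015-01-01", start = "2015-04-15")))
  expect_equal(ep$exclusion_reason, "late_start")

  # SNRI ended 30 days before SSRI start
  ep <- apply_exclusions(build_episodes(
    mk_rx(order = "2015-02-01", snri_end = "2015-01-02")))
  expect_equal(ep$exclusion_reason, "snri_carryover")

  # flags
  for (fl in c("start_unknown", "record_protected", "never_started",
               "discontinued_diagnosis_change")) {
    ep <- apply_exclusions(build_episodes(mk_rx(flags = fl)))
    expect_equal(ep$status, "excluded")
  }

  # boundary: exactly 182 days before / 91 days after stays included
  ep <- apply_exclusions(build_episodes(
    mk_rx(order = format(as.Date("2015-01-01") + 182), start = "2015-01-01")))
  expect_equal(ep$status, "included")
  ep <- apply_exclusions(build_episodes(
    mk_rx(order = "2015-01-01", start = format(as.Date("2015-01-01") + 91))))
  expect_equal(ep$status, "included")
})

test_that("no-followup exclusion spares intolerant episodes", {
  ann <- mk_ann("2015-06-01", "improve")
  ep <- apply_exclusions(build_episodes(mk_rx()), ann)
  expect_equal(ep$status, "included")
  # same episode, annotations from another patient only
  ann2 <- mk_ann("2015-06-01", "improve", patient_id = "OTHER")
  ep2 <- apply_exclusions(build_episodes(mk_rx()), ann2)
  expect_equal(ep2$exclusion_reason, "no_followup")
  # intolerant: included even without follow-up annotations
  ep3 <- apply_exclusions(build_episodes(
    mk_rx(flags = "discontinued_adverse_event", stop = "2015-02-01")), ann2)
  expect_equal(ep3$status, "included")
})
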