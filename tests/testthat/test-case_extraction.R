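# shared fixture: the hand-traceable 12-case dataset
wf <- make_worked_fixture()
cfg <- extraction_config("pitavastatin")

test_that("index-drug selection uses set semantics and warns when empty", {
  ids <- select_cases_with_drug(wf$dataset, "pitavastatin")
  expect_setequal(ids, sprintf("C%02d", 1:12))
  # a case using two index drugs is included once
  ids2 <- select_cases_with_drug(wf$dataset, c("pitavastatin", "allopurinol"))
  expect_equal(anyDuplicated(ids2), 0L)
  expect_warning(none <- select_cases_with_drug(wf$dataset, "nonexistent"),
                 "no case")
  expect_length(none, 0L)
})

test_that("injectable exclusion removes the whole case, substring/case-insensitive", {
  kept <- exclude_injectable_cases(wf$dataset, sprintf("C%02d", 1:12),
                                   c("injection", "intravenous"))
  expect_false("C04" %in% kept)     # one oral + one intravenous drug
  expect_true("C01" %in% kept)      # all oral: retained
  expect_equal(attr(kept, "excluded"), "C04")
  # empty term set is the identity
  same <- exclude_injectable_cases(wf$dataset, sprintf("C%02d", 1:12),
                                   character(0))
  expect_setequal(as.character(same), sprintf("C%02d", 1:12))
})

test_that("duplicate cases collapse to the first-registered report, idempotently", {
  ids <- sprintf("C%02d", 1:12)
  dd <- deduplicate_cases(wf$dataset, ids)
  expect_false("C03" %in% dd)       # C03 matches C02 on sex/age/drug set
  expect_true("C02" %in% dd)        # DEMO order keeps the earlier case
  ex <- attr(dd, "excluded")
  expect_equal(ex$duplicate_of[ex$case_id == "C03"], "C02")
  # one extra drug breaks the match
  expect_true(all(c("C07", "C09") %in% dd))
  # idempotence
  dd2 <- deduplicate_cases(wf$dataset, as.character(dd))
  expect_setequal(as.character(dd2), as.character(dd))
})

test_that("onset resolution takes the earliest dated event", {
  ev <- data.frame(onset_date = as.Date(c("2017-05-01", "2017-03-01", NA)))
  expect_equal(resolve_onset_date(ev), as.Date("2017-03-01"))
  expect_true(is.na(resolve_onset_date(
    data.frame(onset_date = as.Date(c(NA, NA))))))
  expect_equal(resolve_onset_date(
    data.frame(onset_date = as.Date("2017-05-01"))), as.Date("2017-05-01"))
})

test_that("drug-timing rules match the stated windows, boundaries inclusive", {
  onset <- as.Date("2017-06-10")
  mk <- function(start, end) {
    data.frame(drug_name = "x",
               start_date = as.Date(start), end_date = as.Date(end),
               date_conflict = FALSE, stringsAsFactors = FALSE)
  }
  keep1 <- function(start, end, on = onset)
    nrow(filter_concomitant_drugs(mk(start, end), on, cfg)) == 1L
  expect_false(keep1("2017-06-15", NA))            # started after onset
  expect_true(keep1("2017-01-01", "2017-06-05"))   # stopped 5 d before: kept
  expect_true(keep1("2017-01-01", "2017-06-03"))   # exactly 7 d: inclusive
  expect_false(keep1("2017-01-01", "2017-05-20"))  # 21 d: out
  expect_false(keep1("2016-05-01", NA))            # open start 405 d: out
  expect_true(keep1("2016-06-10", NA))             # exactly 365 d: inclusive
  expect_true(keep1("2017-01-01", "2017-08-01"))   # spans onset
  expect_true(keep1(NA, NA))                       # undated: kept
  expect_true(keep1(NA, "2017-08-01"))             # end after onset: kept
  expect_false(keep1(NA, "2017-05-01"))            # end-only, 40 d before
  expect_true(keep1("2017-06-15", NA, on = as.Date(NA))) # no onset: all kept
})

test_that("the full cascade reproduces the hand-traced fixture", {
  cases <- build_analysis_cases(wf$dataset, cfg)
  expect_identical(cases$case_id, wf$expected$surviving_ids)
  aud <- extraction_audit(cases)
  expect_equal(aud$stage[aud$case_id == "C03"], "duplicate")
  expect_equal(aud$stage[aud$case_id == "C04"], "injectable")
  expect_equal(aud$stage[aud$case_id == "C05"], "index_drug_timing")
  # case-count conservation: selected = survivors + exclusions
  expect_equal(attr(cases, "n_selected"), nrow(cases) + nrow(aud))
  # per-case retained concomitant sets match the hand trace
  got <- setNames(cases$concomitant_drugs, cases$case_id)
  expect_identical(lapply(got, identity), wf$expected$concomitant)
  # event flag iff the target PT is reported
  expect_identical(cases$case_id[cases$event_flag], c("C01", "C07"))
  # n_drugs counts distinct retained names including the statin
  expect_equal(cases$n_drugs[cases$case_id == "C07"], 2L)
  # re-running the cascade on the written-out survivors is idempotent
  expect_equal(nrow(build_analysis_cases(wf$dataset, cfg)), 9L)
})

test_that("widening the discontinuation window never shrinks retained sets", {
  onset <- as.Date("2017-06-10")
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    recs <- data.frame(
      drug_name = sprintf("d%d", seq_len(n)),
      start_date = onset - sample(-30:400, n, replace = TRUE),
      end_date = onset - sample(-30:60, n, replace = TRUE),
      date_conflict = FALSE, stringsAsFactors = FALSE)
    recs$end_date[sample(n, 1)] <- NA
    recs$date_conflict <- !is.na(recs$end_date) &
      recs$start_date > recs$end_date
    narrow <- extraction_config("pitavastatin",
                                discontinuation_window_days = 3)
    wide <- extraction_config("pitavastatin",
                              discontinuation_window_days = 30)
    kept_narrow <- filter_concomitant_drugs(recs, onset, narrow)$drug_name
    kept_wide <- filter_concomitant_drugs(recs, onset, wide)$drug_name
    expect_true(all(kept_narrow %in% kept_wide))
  }
})

test_that("exhausted inputs raise an explicit error", {
  demo <- data.frame(case_id = "A", sex = "m", age = "60s")
  drug <- data.frame(case_id = "A", drug_name = "pitavastatin",
                     route = "intravenous drip", start_date = "", end_date = "")
  reac <- data.frame(case_id = "A", pt_code = "10000001", pt_name = "x",
                     onset_date = "")
  ds <- report_dataset(demo, drug, reac)
  expect_error(build_analysis_cases(ds, cfg), "exhausted")
})
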