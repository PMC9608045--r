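test_that("generator is deterministic: same seed, byte-identical tables", {
  cfg <- simulation_config(n_cases = 300, seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$demo, b$dataset$demo)
  expect_identical(a$dataset$drug, b$dataset$drug)
  expect_identical(a$dataset$reac, b$dataset$reac)
  expect_identical(a$truth$event_prob, b$truth$event_prob)
  # different seed changes the draw
  c2 <- simulate_dataset(simulation_config(n_cases = 300, seed = 78))
  expect_false(identical(a$dataset$reac, c2$dataset$reac))
})

test_that("null event fraction sits within 3 binomial SEs of baseline", {
  cfg <- simulation_config(n_cases = 2000, baseline_event_prob = 0.10,
                           seed = 5)
  sim <- simulate_dataset(cfg)
  frac <- mean(sim$truth$event)
  se <- sqrt(0.10 * 0.90 / 2000)
  expect_lt(abs(frac - 0.10), 3 * se)
})

test_that("planted effects apply multiplicatively, only to full carriers", {
  cfg <- simulation_config(
    n_cases = 4000, baseline_event_prob = 0.05,
    drug_prevalence = c(rep(6, 3), rep(1, 27)),
    planted_effects = list(list(drugs = c("drug01", "drug02"),
                                multiplier = 4)),
    seed = 9)
  sim <- simulate_dataset(cfg)
  prob <- sim$truth$event_prob
  expect_setequal(unique(prob), c(0.05, 0.20))
  # ground-truth probabilities match empirical frequencies per stratum
  for (p0 in unique(prob)) {
    idx <- prob == p0
    emp <- mean(sim$truth$event[idx])
    se <- sqrt(p0 * (1 - p0) / sum(idx))
    expect_lt(abs(emp - p0), 4 * se)
  }
  # carriers really carry both drugs (check through the emitted tables)
  carriers <- names(prob[prob == 0.20])
  d <- sim$dataset$drug
  for (cid in sample(carriers, 10)) {
    expect_true(all(c("drug01", "drug02") %in% d$drug_name[d$case_id == cid]))
  }
})

test_that("emitted tables survive the srs_io round trip and carry the noise", {
  cfg <- simulation_config(n_cases = 500, seed = 13)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_report_tables(sim$dataset, dir)
  ds2 <- read_report_tables(file.path(dir, "demo.csv"),
                            file.path(dir, "drug.csv"),
                            file.path(dir, "reac.csv"))
  expect_equal(nrow(ds2$demo), nrow(sim$dataset$demo))
  expect_identical(ds2$drug$drug_name, sim$dataset$drug$drug_name)
  expect_identical(ds2$reac$onset_date, sim$dataset$reac$onset_date)
  # structural noise present at roughly the configured fractions
  flags <- sim$truth$flags
  expect_equal(sum(flags$flag == "injectable"), round(0.02 * 500))
  expect_equal(sum(flags$flag == "duplicate"), round(0.02 * 500))
  # duplicates collapse back onto their sources in extraction
  cases <- suppressWarnings(
    build_analysis_cases(ds2, extraction_config("pitavastatin")))
  aud <- extraction_audit(cases)
  dup_ids <- flags$case_id[flags$flag == "duplicate"]
  expect_true(all(aud$stage[aud$case_id %in% dup_ids] == "duplicate"))
})

test_that("contradictory configurations are rejected", {
  expect_error(simulation_config(planted_effects = list(
    list(drugs = c("pitavastatin", "nosuchdrug"), multiplier = 2))),
    "nosuchdrug")
  expect_error(simulation_config(baseline_event_prob = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(drug_prevalence = c(1, 2)), "one weight")
  expect_error(simulation_config(planted_effects = list(
    list(drugs = "drug01", multiplier = 0.5))), ">= 1")
})
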