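test_that("exact proportion test matches enumeration oracle and edge rules", {
  ir <- 69 / 739
  # frozen from arbitrary-precision enumeration of all 11 outcomes
  expect_equal(node_proportion_test(4, 10, ir), 0.010058969892723641,
               tolerance = 1e-12)
  expect_equal(node_proportion_test(4, 10, ir), oracle_binom_p(4, 10, ir),
               tolerance = 1e-12)
  # random agreement with the enumeration oracle
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.02, 0.9)
    expect_equal(node_proportion_test(k, n, p0), oracle_binom_p(k, n, p0),
                 tolerance = 1e-10)
  }
  # observed equals the null exactly
  expect_equal(node_proportion_test(0, 10, 0), 1)
  expect_equal(node_proportion_test(1, 10, 0.1), 1)
  # impossible observations under degenerate references
  expect_warning(p <- node_proportion_test(2, 10, 0), "smallest positive")
  expect_gt(p, 0)
  expect_warning(node_proportion_test(3, 10, 1), "smallest positive")
  expect_equal(node_proportion_test(10, 10, 1), 1)
  # chi-square variant is a valid p-value and agrees in order of magnitude
  expect_lt(node_proportion_test(4, 10, ir, method = "chisq"), 0.05)
})

test_that("Benjamini-Hochberg matches the hand-applied step-up formula", {
  r1 <- benjamini_hochberg(0.01)
  expect_equal(r1$adjusted, 0.01)
  expect_true(r1$reject)
  # hand computation, m = 4: 0.04*4/4=0.04, then cummin from the top
  r4 <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r4$adjusted, rep(0.04, 4))
  expect_true(all(r4$reject))
  # random lists: equality with the literal definition; adjusted >= raw;
  # order-invariance of the rejection set
  set.seed(31)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))
    r <- benjamini_hochberg(p, q = 0.05)
    expect_equal(r$adjusted, oracle_bh(p))
    expect_true(all(r$adjusted >= p - 1e-15))
    perm <- sample(seq_along(p))
    r2 <- benjamini_hochberg(p[perm], q = 0.05)
    expect_equal(r2$reject, r$reject[perm])
  }
  # empty input
  r0 <- benjamini_hochberg(numeric(0))
  expect_length(r0$adjusted, 0L)
  expect_length(r0$reject, 0L)
})

test_that("root-only trees give an IR-only report", {
  wf <- make_worked_fixture()
  sig <- suppressWarnings(analyze_dataset(wf$dataset, "pitavastatin"))
  expect_equal(sig$n_total, wf$expected$analyzed_n)
  expect_equal(sig$k_total, wf$expected$analyzed_k)
  expect_equal(sig$initial_rate, wf$expected$initial_rate)
  expect_equal(nrow(sig$table), 0L)
  expect_equal(nrow(sig$nodes), 0L)
})

test_that("signal report keeps only presence-path, above-IR, significant rows", {
  sc <- simulation_config(
    n_cases = 3000, baseline_event_prob = 0.05,
    drug_prevalence = c(rep(8, 3), rep(1, 27)),
    planted_effects = list(list(drugs = c("drug01", "drug02", "drug03"),
                                multiplier = 8)),
    seed = 42)
  sim <- simulate_dataset(sc)
  sig <- suppressWarnings(analyze_dataset(sim$dataset, "pitavastatin"))
  expect_gt(nrow(sig$table), 0L)
  expect_true(all(sig$table$significant))
  expect_true(all(sig$table$presence_only))
  expect_true(all(sig$table$rate > sig$initial_rate))
  # some planted-triple row covers all three drugs
  covers <- vapply(strsplit(sig$table$combination, " + ", fixed = TRUE),
                   function(v) all(c("drug01", "drug02", "drug03") %in% v),
                   TRUE)
  expect_true(any(covers))
  # machine-readable output keeps mixed paths too
  expect_gt(nrow(sig$nodes), nrow(sig$table))
  expect_true(all(sig$nodes$p_adj >= sig$nodes$p_raw - 1e-15))
  # conservation at depth 1: the two depth-1 nodes partition the root
  d1 <- sig$nodes[sig$nodes$depth == 1L, ]
  expect_equal(sum(d1$n), sig$n_total)
  expect_equal(sum(d1$k), sig$k_total)
})

test_that("signal TSV output is byte-identical across reruns", {
  wf <- make_worked_fixture()
  sig <- suppressWarnings(analyze_dataset(wf$dataset, "pitavastatin"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_signal_table(sig, f1)
  write_signal_table(sig, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[2], "0.22 \\(IR\\)")
  expect_true(file.exists(paste0(f1, ".nodes.json")))
})
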