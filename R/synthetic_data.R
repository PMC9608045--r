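#' Configuration of the synthetic report generator
#'
#' Describes a simulated spontaneous-reporting extract: every case receives
#' the index drug (first vocabulary entry) plus a truncated-at-one Poisson
#' number of concomitant drugs drawn by prevalence weight; the event
#' probability is multiplicative — baseline times the risk multiplier of
#' every planted drug set fully contained in the case's drug set, capped at
#' \code{max_event_prob}. Structural noise mirrors what real extracts
#' contain: missing onset dates, undated drug rows, duplicate reports and
#' injectable cases.
#'
#' @param n_cases number of primary cases (duplicates are emitted on top).
#' @param drug_vocabulary drug names; the first entry is the index drug.
#' @param mean_concomitant_drugs Poisson mean of the concomitant-drug count
#'   (truncated at 1: every case is polypharmacy-eligible). Default 4, i.e.
#'   around five drugs per case including the index drug.
#' @param drug_prevalence sampling weights over the concomitant vocabulary
#'   (recycled/normalized); default mildly skewed (\eqn{1/\sqrt{j}}),
#'   mimicking the long-tailed frequency of co-prescription.
#' @param baseline_event_prob event probability with no planted set present.
#' @param planted_effects list of \code{list(drugs = c(...), multiplier = m)}
#'   entries; a multiplier applies only when ALL its drugs are present (pure
#'   interaction, no marginal main effect unless planted separately).
#' @param max_event_prob cap keeping multiplicative risks coherent.
#' @param missing_onset_frac fraction of cases with no usable onset date.
#' @param missing_drug_date_frac fraction of drug rows with no dates at all.
#' @param duplicate_frac fraction of cases re-emitted as duplicate reports.
#' @param injectable_case_frac fraction of cases carrying an injectable-route
#'   drug (excluded whole-case by extraction).
#' @param seed RNG seed; identical configs produce byte-identical tables.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_cases = 2000L,
                              drug_vocabulary = c("pitavastatin",
                                                  sprintf("drug%02d", 1:30)),
                              mean_concomitant_drugs = 4,
                              drug_prevalence = NULL,
                              baseline_event_prob = 0.10,
                              planted_effects = list(),
                              max_event_prob = 0.95,
                              missing_onset_frac = 0.10,
                              missing_drug_date_frac = 0.20,
                              duplicate_frac = 0.02,
                              injectable_case_frac = 0.02,
                              seed = 1L) {
  drug_vocabulary <- trimws(as.character(drug_vocabulary))
  if (length(drug_vocabulary) < 2L || anyDuplicated(drug_vocabulary))
    stop("drug_vocabulary needs >= 2 distinct names (index drug first)",
         call. = FALSE)
  conc <- drug_vocabulary[-1L]
  if (is.null(drug_prevalence)) drug_prevalence <- 1 / sqrt(seq_along(conc))
  if (length(drug_prevalence) != length(conc))
    stop("drug_prevalence must have one weight per concomitant drug",
         call. = FALSE)
  if (any(drug_prevalence < 0) || sum(drug_prevalence) <= 0)
    stop("drug_prevalence weights must be non-negative, not all zero",
         call. = FALSE)
  fracs <- c(baseline_event_prob, max_event_prob, missing_onset_frac,
             missing_drug_date_frac, duplicate_frac, injectable_case_frac)
  if (any(fracs < 0 | fracs > 1))
    stop("probabilities and fractions must lie in [0, 1]", call. = FALSE)
  if (mean_concomitant_drugs <= 0)
    stop("mean_concomitant_drugs must be positive", call. = FALSE)
  for (eff in planted_effects) {
    if (!all(c("drugs", "multiplier") %in% names(eff)))
      stop("each planted effect needs $drugs and $multiplier", call. = FALSE)
    if (!all(eff$drugs %in% drug_vocabulary))
      stop(sprintf("planted drug(s) not in vocabulary: %s",
                   paste(setdiff(eff$drugs, drug_vocabulary), collapse = ", ")),
           call. = FALSE)
    if (eff$multiplier < 1)
      stop("planted risk multipliers must be >= 1", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 drug_vocabulary = drug_vocabulary,
                 mean_concomitant_drugs = mean_concomitant_drugs,
                 drug_prevalence = drug_prevalence,
                 baseline_event_prob = baseline_event_prob,
                 planted_effects = planted_effects,
                 max_event_prob = max_event_prob,
                 missing_onset_frac = missing_onset_frac,
                 missing_drug_date_frac = missing_drug_date_frac,
                 duplicate_frac = duplicate_frac,
                 injectable_case_frac = injectable_case_frac,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# truncated-at-1 Poisson via inverse CDF restricted to [P(X=0), 1)
rtpois1 <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  stats::qpois(stats::runif(n, min = p0, max = 1), lambda)
}

#' Simulate a linked report dataset with known ground truth
#'
#' @param config a \code{simulation_config}.
#' @return list with \code{dataset} (a \code{report_dataset}) and
#'   \code{truth} (per-case true event probabilities, the planted effects,
#'   and flags for rows the extraction cascade is expected to act on).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_cases
  index_drug <- config$drug_vocabulary[1L]
  conc_vocab <- config$drug_vocabulary[-1L]
  w <- config$drug_prevalence

  case_id <- sprintf("C%06d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- sample(paste0(seq(20, 90, 10), "s"), n, replace = TRUE,
                prob = c(1, 2, 3, 4, 6, 6, 4, 2))

  cnt <- pmin(rtpois1(n, config$mean_concomitant_drugs), length(conc_vocab))
  drug_sets <- lapply(cnt, function(ci)
    sample(conc_vocab, ci, replace = FALSE, prob = w))

  # membership matrix over concomitant vocabulary; the index drug is present
  # in every case by construction
  M <- matrix(FALSE, n, length(conc_vocab), dimnames = list(NULL, conc_vocab))
  for (i in seq_len(n)) M[i, drug_sets[[i]]] <- TRUE

  prob <- rep(config$baseline_event_prob, n)
  for (eff in config$planted_effects) {
    need <- setdiff(eff$drugs, index_drug)
    carrier <- if (length(need) == 0L) rep(TRUE, n) else
      rowSums(M[, need, drop = FALSE]) == length(need)
    prob[carrier] <- prob[carrier] * eff$multiplier
  }
  prob <- pmin(prob, config$max_event_prob)
  event <- stats::rbinom(n, 1L, prob) == 1L

  onset <- as.Date("2015-01-01") + sample.int(700, n, replace = TRUE)
  onset_missing <- stats::runif(n) < config$missing_onset_frac

  # long drug table: index drug + concomitants per case; dates drawn so that
  # every row passes the timing filter (starts within a year before onset;
  # ends at/after onset, within a week before it, or absent)
  per_case <- lapply(seq_len(n), function(i) c(index_drug, drug_sets[[i]]))
  nrows <- lengths(per_case)
  row_case <- rep(seq_len(n), nrows)
  drug_name <- unlist(per_case, use.names = FALSE)
  m_rows <- length(drug_name)
  start <- onset[row_case] - sample.int(300, m_rows, replace = TRUE)
  u <- stats::runif(m_rows)
  end <- as.Date(rep(NA, m_rows))
  span <- u < 0.5
  end[span] <- onset[row_case][span] + sample.int(60, sum(span), replace = TRUE)
  stopped <- u >= 0.5 & u < 0.7
  end[stopped] <- onset[row_case][stopped] -
    sample(0:7, sum(stopped), replace = TRUE)
  undated <- stats::runif(m_rows) < config$missing_drug_date_frac
  start[undated] <- NA
  end[undated] <- NA

  route <- rep("oral", m_rows)
  n_inj <- round(config$injectable_case_frac * n)
  inj_cases <- if (n_inj > 0L) sort(sample.int(n, n_inj)) else integer(0)
  first_row <- match(seq_len(n), row_case)
  route[first_row[inj_cases]] <- "injection"

  demo <- data.frame(case_id = case_id, sex = sex, age = age,
                     stringsAsFactors = FALSE)
  drug <- data.frame(case_id = case_id[row_case], drug_name = drug_name,
                     route = route,
                     start_date = format_srs_date(start),
                     end_date = format_srs_date(end),
                     stringsAsFactors = FALSE)
  pt_other <- "10000001"
  reac <- data.frame(case_id = case_id,
                     pt_code = ifelse(event, "10039020", pt_other),
                     pt_name = ifelse(event, "Rhabdomyolysis",
                                      "Other adverse event"),
                     onset_date = ifelse(onset_missing, "",
                                         format_srs_date(onset)),
                     stringsAsFactors = FALSE)

  # duplicate reports: same sex/age/drug names under a fresh, later case id
  n_dup <- round(config$duplicate_frac * n)
  dup_src <- if (n_dup > 0L) sort(sample.int(n, n_dup)) else integer(0)
  if (n_dup > 0L) {
    dup_id <- sprintf("D%06d", seq_len(n_dup))
    demo <- rbind(demo, data.frame(case_id = dup_id, sex = sex[dup_src],
                                   age = age[dup_src], stringsAsFactors = FALSE))
    dd <- drug[row_case %in% dup_src, , drop = FALSE]
    dd$case_id <- dup_id[match(match(dd$case_id, case_id), dup_src)]
    drug <- rbind(drug, dd)
    rr <- reac[dup_src, , drop = FALSE]
    rr$case_id <- dup_id
    reac <- rbind(reac, rr)
  }

  truth <- list(
    event_prob = stats::setNames(prob, case_id),
    event = stats::setNames(event, case_id),
    planted_effects = config$planted_effects,
    flags = rbind(
      if (length(inj_cases) > 0L)
        data.frame(case_id = case_id[inj_cases], flag = "injectable",
                   detail = "", stringsAsFactors = FALSE),
      if (n_dup > 0L)
        data.frame(case_id = sprintf("D%06d", seq_len(n_dup)),
                   flag = "duplicate", detail = case_id[dup_src],
                   stringsAsFactors = FALSE),
      data.frame(case_id = character(), flag = character(),
                 detail = character(), stringsAsFactors = FALSE)))

  list(dataset = report_dataset(demo, drug, reac), truth = truth)
}

#' Hand-traceable worked fixture
#'
#' A 12-case dataset exercising every arm of the extraction cascade: one
#' duplicate pair (collapses to the first-registered case), one injectable
#' case (excluded), one case whose only statin record started after onset
#' (dropped when the index drug fails the timing filter), and one drug
#' discontinued three weeks before onset (removed from its case). Nine cases
#' survive; all carry at least one concomitant drug, so nine are analyzed,
#' two with the target event. Too small for any admissible split at the
#' default minimum node size, so the expected signal table is the IR row
#' alone: 2/9.
#'
#' @return list with \code{dataset}, \code{expected} (surviving ids, per-case
#'   retained concomitant sets, analyzed n/k) — all derived by hand from the
#'   rules, committed for golden tests.
#' @export
make_worked_fixture <- function() {
  demo <- data.frame(
    case_id = sprintf("C%02d", 1:12),
    sex = c("male", "female", "female", "male", "male", "female",
            "male", "female", "male", "female", "male", "female"),
    age = c("60s", "70s", "70s", "50s", "30s", "80s",
            "40s", "60s", "70s", "50s", "60s", "70s"),
    stringsAsFactors = FALSE)
  # onset for every case: 2017-06-10 (C06 has none -> all drugs kept)
  on <- "20170610"
  drug <- rbind(
    data.frame(case_id = "C01", drug_name = c("pitavastatin", "allopurinol"),
               route = "oral", start_date = "20170101", end_date = ""),
    data.frame(case_id = "C02", drug_name = c("pitavastatin", "valsartan"),
               route = "oral", start_date = "20170201", end_date = "20170701"),
    # C03 duplicates C02: same sex/age/drug names, registered later
    data.frame(case_id = "C03", drug_name = c("pitavastatin", "valsartan"),
               route = "oral", start_date = "20170210", end_date = "20170705"),
    # C04: injectable route on one drug -> whole case excluded
    data.frame(case_id = "C04",
               drug_name = c("pitavastatin", "furosemide"),
               route = c("oral", "intravenous injection"),
               start_date = "20170301", end_date = ""),
    # C05: statin started after onset -> index drug lost -> case dropped
    data.frame(case_id = "C05", drug_name = c("pitavastatin", "allopurinol"),
               route = "oral", start_date = c("20170615", "20170101"),
               end_date = ""),
    # C06: no onset date registered -> every drug retained
    data.frame(case_id = "C06", drug_name = c("pitavastatin", "amlodipine"),
               route = "oral", start_date = "", end_date = ""),
    # C07: drug discontinued 21 days before onset -> that drug removed
    data.frame(case_id = "C07",
               drug_name = c("pitavastatin", "benzbromarone", "valsartan"),
               route = "oral", start_date = c("20170101", "20170101", "20170105"),
               end_date = c("", "20170520", "")),
    # C08: drug discontinued 5 days before onset -> retained (within a week)
    data.frame(case_id = "C08", drug_name = c("pitavastatin", "allopurinol"),
               route = "oral", start_date = "20170101",
               end_date = c("", "20170605")),
    # C09: open-ended start 405 days before onset -> that drug removed
    data.frame(case_id = "C09",
               drug_name = c("pitavastatin", "diclofenac", "valsartan"),
               route = "oral", start_date = c("20170101", "20160501", "20170201"),
               end_date = ""),
    data.frame(case_id = "C10", drug_name = c("pitavastatin", "amlodipine"),
               route = "oral", start_date = "20170301", end_date = "20170801"),
    data.frame(case_id = "C11", drug_name = c("pitavastatin", "metformin"),
               route = "oral", start_date = "201703", end_date = ""),
    data.frame(case_id = "C12", drug_name = c("pitavastatin", "allopurinol"),
               route = "oral", start_date = "20170401", end_date = ""))
  reac <- data.frame(
    case_id = sprintf("C%02d", c(1:5, 7:12)),   # C06 unregistered onset
    pt_code = c("10039020", "10000001", "10000001", "10000001", "10000001",
                "10039020", "10000001", "10000001", "10000001", "10000001",
                "10000001"),
    pt_name = "fixture event",
    onset_date = on,
    stringsAsFactors = FALSE)
  expected <- list(
    surviving_ids = sprintf("C%02d", c(1, 2, 6:12)),
    removed = list(duplicate = "C03", injectable = "C04",
                   index_drug_timing = "C05"),
    concomitant = list(
      C01 = "allopurinol", C02 = "valsartan", C06 = "amlodipine",
      C07 = "valsartan",              # benzbromarone stopped 21 d before
      C08 = "allopurinol",            # stopped 5 d before: retained
      C09 = "valsartan",              # diclofenac open start 405 d before
      C10 = "amlodipine",
      C11 = "metformin",              # partial start date -> treated undated
      C12 = "allopurinol"),
    analyzed_n = 9L, analyzed_k = 2L, initial_rate = 2 / 9)
  list(dataset = report_dataset(demo, drug, reac), expected = expected)
}

#' Standard planted-triple validation scenario
#'
#' The configuration used by the package's power study: 5000 cases, baseline
#' event probability 0.05, and one planted three-drug interaction with risk
#' multiplier 8. The three planted drugs carry prevalence weight 3.3 against
#' 1 for the rest of the vocabulary, which puts the fraction of cases
#' carrying all three at about 4%; the planted stratum's event probability
#' is 0.40 against the 0.05 background, a jump of the size the signal table
#' is meant to surface.
#'
#' @param seed RNG seed for the scenario.
#' @param n_cases number of cases (default 5000).
#' @return a \code{simulation_config} with the planted triple
#'   \code{drug01 + drug02 + drug03}.
#' @export
planted_triple_config <- function(seed = 1L, n_cases = 5000L) {
  simulation_config(
    n_cases = n_cases,
    baseline_event_prob = 0.05,
    drug_prevalence = c(rep(3.3, 3), rep(1, 27)),
    planted_effects = list(list(drugs = c("drug01", "drug02", "drug03"),
                                multiplier = 8)),
    seed = seed)
}
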