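#' The six statins marketed in Japan
#'
#' Generic names of the six statins used as index drugs; these are also the
#' names removed from every case's concomitant-drug set before the tree is
#' grown (only concomitant non-statin drugs enter as predictors).
#'
#' @return character vector of six generic names.
#' @export
statin_names <- function() {
  c("atorvastatin", "simvastatin", "rosuvastatin",
    "fluvastatin", "pravastatin", "pitavastatin")
}

#' Configuration for index-drug case extraction
#'
#' @param index_drug_names character vector of index drug names (exact-string
#'   match after whitespace trimming). Typically one statin.
#' @param event_pt_code MedDRA preferred-term code defining the target event;
#'   \code{"10039020"} is rhabdomyolysis.
#' @param injectable_route_terms terms matched (substring, case-insensitive)
#'   against the route of administration; any match excludes the whole case.
#' @param discontinuation_window_days a drug discontinued before event onset
#'   is retained only if it was still in use within this many days of onset
#'   (inclusive). Default 7 ("within one week").
#' @param open_start_window_days a drug with a start date but no end date is
#'   retained only if started within this many days before onset (inclusive).
#'   Default 365 ("within 1 year").
#' @param statin_list names excluded from the concomitant-drug predictor set
#'   (the index-drug class); defaults to [statin_names()].
#' @return an object of class \code{extraction_config}.
#' @export
extraction_config <- function(index_drug_names,
                              event_pt_code = "10039020",
                              injectable_route_terms = c("injection",
                                                         "injectable",
                                                         "intravenous"),
                              discontinuation_window_days = 7L,
                              open_start_window_days = 365L,
                              statin_list = statin_names()) {
  index_drug_names <- trimws(as.character(index_drug_names))
  if (length(index_drug_names) == 0L || !all(nzchar(index_drug_names)))
    stop("index_drug_names must be a non-empty set of non-empty names",
         call. = FALSE)
  if (discontinuation_window_days <= 0 || open_start_window_days <= 0)
    stop("timing windows must be positive", call. = FALSE)
  if (!nzchar(event_pt_code)) stop("event_pt_code must be non-empty", call. = FALSE)
  structure(list(index_drug_names = unique(index_drug_names),
                 event_pt_code = as.character(event_pt_code),
                 injectable_route_terms = tolower(as.character(injectable_route_terms)),
                 discontinuation_window_days = as.numeric(discontinuation_window_days),
                 open_start_window_days = as.numeric(open_start_window_days),
                 statin_list = trimws(as.character(statin_list))),
            class = "extraction_config")
}

#' Select cases treated with an index drug
#'
#' @param dataset a \code{report_dataset}.
#' @param index_drug_names character vector of index drug names.
#' @return case ids (in DEMO order) having at least one drug record whose
#'   name is in \code{index_drug_names}; warns if empty.
#' @export
select_cases_with_drug <- function(dataset, index_drug_names) {
  stopifnot(inherits(dataset, "report_dataset"))
  index_drug_names <- trimws(as.character(index_drug_names))
  hit <- dataset$drug$case_id[dataset$drug$drug_name %in% index_drug_names]
  ids <- dataset$demo$case_id[dataset$demo$case_id %in% hit]
  if (length(ids) == 0L)
    warning("no case uses any of the index drugs", call. = FALSE)
  ids
}

#' Exclude cases containing an injectable medication
#'
#' Injectable medications are commonly given to treat an adverse event during
#' hospitalization rather than to cause it, so any case with at least one
#' drug administered by an injectable route is removed in full (whole-case
#' exclusion, not per-drug).
#'
#' @param dataset a \code{report_dataset}.
#' @param case_ids candidate case ids.
#' @param injectable_route_terms substring terms (case-insensitive) matched
#'   against the route field; empty set means no exclusion.
#' @return the retained case ids, with attribute \code{"excluded"} naming the
#'   removed cases.
#' @export
exclude_injectable_cases <- function(dataset, case_ids, injectable_route_terms) {
  stopifnot(inherits(dataset, "report_dataset"))
  if (length(injectable_route_terms) == 0L) {
    return(structure(case_ids, excluded = character(0)))
  }
  d <- dataset$drug[dataset$drug$case_id %in% case_ids, , drop = FALSE]
  route <- tolower(d$route)
  hit <- rep(FALSE, nrow(d))
  for (term in tolower(injectable_route_terms)) {
    if (nzchar(term)) hit <- hit | grepl(term, route, fixed = TRUE)
  }
  bad <- unique(d$case_id[hit])
  structure(setdiff(case_ids, bad), excluded = bad)
}

# Per-case duplicate key: sex, age band (raw strings) and the sorted set of
# all registered drug names. \r is safe as a separator: fields are trimmed
# single-line strings.
duplicate_keys <- function(dataset, case_ids) {
  d <- dataset$drug[dataset$drug$case_id %in% case_ids, , drop = FALSE]
  spl <- split(d$drug_name, factor(d$case_id, levels = case_ids))
  drugkey <- vapply(spl, function(v) paste(sort(unique(v)), collapse = "\r"), "")
  m <- match(case_ids, dataset$demo$case_id)
  paste(dataset$demo$sex[m], dataset$demo$age[m], drugkey[case_ids], sep = "\r\r")
}

#' Collapse duplicate cases to the first-registered report
#'
#' Cases matching on sex, age band, and the full set of registered drug
#' names are treated as duplicate reports of one patient; only the case
#' registered first (DEMO source-file row order) is kept. Missing sex or age
#' matches literally (empty string groups with empty string).
#'
#' @param dataset a \code{report_dataset}.
#' @param case_ids candidate case ids.
#' @return retained case ids, with attribute \code{"excluded"}: a data.frame
#'   of removed ids and the id each duplicates.
#' @export
deduplicate_cases <- function(dataset, case_ids) {
  stopifnot(inherits(dataset, "report_dataset"))
  case_ids <- as.character(case_ids)
  if (length(case_ids) == 0L) {
    return(structure(case_ids,
                     excluded = data.frame(case_id = character(),
                                           duplicate_of = character(),
                                           stringsAsFactors = FALSE)))
  }
  ord <- match(case_ids, dataset$demo$case_id)
  if (anyNA(ord)) stop("case_ids not all present in DEMO", call. = FALSE)
  ids <- case_ids[order(ord)]   # registration order
  key <- duplicate_keys(dataset, ids)
  first <- !duplicated(key)
  kept <- ids[first]
  removed <- ids[!first]
  dup_of <- kept[match(key[!first], key[first])]
  structure(case_ids[case_ids %in% kept],
            excluded = data.frame(case_id = removed, duplicate_of = dup_of,
                                  stringsAsFactors = FALSE))
}

#' Resolve the adverse-event onset date that anchors drug timing
#'
#' When a case carries several adverse events, the earliest non-missing onset
#' date is used as the anchor for the drug-timing filter; missing if no event
#' has a usable onset date.
#'
#' @param events data.frame of the case's REAC rows (needs \code{onset_date}).
#' @return a single \code{Date}, \code{NA} if none available.
#' @export
resolve_onset_date <- function(events) {
  d <- events$onset_date
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(as.Date(NA))
  min(d)
}

# Vectorized timing rule over parallel vectors of start/end dates against a
# per-row onset. Dates on flagged conflict rows must already be NA'd out.
timing_retain <- function(start, end, onset, config) {
  retain <- rep(TRUE, length(start))
  has_onset <- !is.na(onset)
  # (a) started after onset -> excluded
  a <- has_onset & !is.na(start) & start > onset
  retain[a] <- FALSE
  # (b) discontinued before onset -> retained iff within the week window
  b <- has_onset & !a & !is.na(end) & end < onset
  retain[b] <- as.numeric(onset[b] - end[b]) <= config$discontinuation_window_days
  # (c) open-ended start before onset -> retained iff within the year window
  cc <- has_onset & !a & !b & !is.na(start) & is.na(end)
  retain[cc] <- as.numeric(onset[cc] - start[cc]) <= config$open_start_window_days
  # (d) spanning onset and (e) undated rows fall through as retained;
  # cases without an onset date keep every drug
  retain
}

#' Filter one case's drug records by timing relative to event onset
#'
#' Implements the timing rules: drugs started after onset are excluded;
#' drugs discontinued before onset are kept only if still in use within the
#' discontinuation window (default one week, inclusive); drugs with a start
#' date but no end date are kept only if started within the open-start window
#' (default one year, inclusive); drugs spanning onset, and drugs with no
#' usable dates, are kept. If the case has no onset date, every registered
#' drug is kept.
#'
#' @param drug_records data.frame of the case's DRUG rows (normalized).
#' @param onset the case's onset \code{Date} (or \code{NA}).
#' @param config an \code{extraction_config}.
#' @return the retained subset of \code{drug_records}.
#' @export
filter_concomitant_drugs <- function(drug_records, onset, config) {
  stopifnot(inherits(config, "extraction_config"))
  if (nrow(drug_records) == 0L) return(drug_records)
  start <- drug_records$start_date
  end <- drug_records$end_date
  conflict <- drug_records$date_conflict
  if (!is.null(conflict) && any(conflict)) {
    start[conflict] <- as.Date(NA)
    end[conflict] <- as.Date(NA)
  }
  keep <- timing_retain(start, end, rep(onset, nrow(drug_records)), config)
  drug_records[keep, , drop = FALSE]
}

#' Run the full case-extraction cascade
#'
#' Applies, in order: index-drug selection, injectable-case exclusion,
#' duplicate collapsing, and the per-case drug-timing filter anchored at the
#' earliest event onset. Cases whose retained drug set no longer contains an
#' index drug are dropped. Every case-level exclusion is recorded in an audit
#' log so that input cases = survivors + per-stage exclusions.
#'
#' @param dataset a \code{report_dataset}.
#' @param config an \code{extraction_config}.
#' @return an object of class \code{ddi_cases}: a data.frame with one row per
#'   surviving case (\code{case_id, sex, age_band, onset_date, n_drugs,
#'   event_flag} plus list columns \code{index_drugs, concomitant_drugs}),
#'   with attributes \code{audit} (exclusion log), \code{n_selected} and
#'   \code{config}.
#' @export
build_analysis_cases <- function(dataset, config) {
  stopifnot(inherits(dataset, "report_dataset"),
            inherits(config, "extraction_config"))
  audit <- list()
  note <- function(ids, stage, reason) {
    if (length(ids) > 0L) {
      audit[[length(audit) + 1L]] <<- data.frame(
        case_id = ids, stage = stage, reason = reason,
        stringsAsFactors = FALSE)
    }
  }

  sel <- select_cases_with_drug(dataset, config$index_drug_names)
  n_selected <- length(sel)

  kept <- exclude_injectable_cases(dataset, sel, config$injectable_route_terms)
  note(attr(kept, "excluded"), "injectable", "injectable route of administration")

  dd <- deduplicate_cases(dataset, as.character(kept))
  ex <- attr(dd, "excluded")
  note(ex$case_id, "duplicate", paste0("duplicate of ", ex$duplicate_of))
  ids <- as.character(dd)

  if (length(ids) == 0L) {
    stop("no cases survive extraction: inputs exhausted by filters",
         call. = FALSE)
  }

  # onset per case (earliest non-missing over the case's events)
  reac <- dataset$reac[dataset$reac$case_id %in% ids, , drop = FALSE]
  onset_ok <- reac[!is.na(reac$onset_date), , drop = FALSE]
  onset_by <- tapply(as.numeric(onset_ok$onset_date), onset_ok$case_id, min)
  onset <- as.Date(unname(onset_by[ids]), origin = "1970-01-01")

  # timing filter, vectorized across all retained cases' drug rows
  d <- dataset$drug[dataset$drug$case_id %in% ids, , drop = FALSE]
  start <- d$start_date; end <- d$end_date
  start[d$date_conflict] <- as.Date(NA)
  end[d$date_conflict] <- as.Date(NA)
  row_onset <- onset[match(d$case_id, ids)]
  keep <- timing_retain(start, end, row_onset, config)
  dkept <- d[keep, , drop = FALSE]

  fac <- factor(dkept$case_id, levels = ids)
  drugs_by <- split(dkept$drug_name, fac)
  drugs_by <- lapply(drugs_by, unique)
  has_index <- vapply(drugs_by, function(v) any(v %in% config$index_drug_names),
                      logical(1))
  note(ids[!has_index], "index_drug_timing",
       "no index-drug record survives the timing filter")
  survivors <- ids[has_index]
  if (length(survivors) == 0L) {
    stop("no cases survive extraction: inputs exhausted by filters",
         call. = FALSE)
  }

  drugs_by <- drugs_by[has_index]
  event_cases <- unique(dataset$reac$case_id[dataset$reac$pt_code ==
                                               config$event_pt_code])
  m <- match(survivors, dataset$demo$case_id)
  res <- data.frame(case_id = survivors,
                    sex = dataset$demo$sex[m],
                    age_band = dataset$demo$age[m],
                    onset_date = onset[has_index],
                    n_drugs = vapply(drugs_by, length, integer(1)),
                    event_flag = survivors %in% event_cases,
                    stringsAsFactors = FALSE)
  res$index_drugs <- lapply(drugs_by, function(v)
    sort(v[v %in% config$index_drug_names]))
  res$concomitant_drugs <- lapply(drugs_by, function(v)
    sort(setdiff(v, config$statin_list)))
  rownames(res) <- NULL

  audit <- if (length(audit) > 0L) do.call(rbind, audit) else
    data.frame(case_id = character(), stage = character(),
               reason = character(), stringsAsFactors = FALSE)
  structure(res, audit = audit, n_selected = n_selected, config = config,
            class = c("ddi_cases", "data.frame"))
}

#' Exclusion audit log of an extraction
#' @param cases a \code{ddi_cases} object.
#' @return data.frame with columns \code{case_id, stage, reason}.
#' @export
extraction_audit <- function(cases) {
  stopifnot(inherits(cases, "ddi_cases"))
  attr(cases, "audit")
}

#' @export
print.ddi_cases <- function(x, ...) {
  aud <- attr(x, "audit")
  cat(sprintf("Analysis cases: %d survivors of %d selected (%d events)\n",
              nrow(x), attr(x, "n_selected"), sum(x$event_flag)))
  if (nrow(aud) > 0L) {
    tab <- table(aud$stage)
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}
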