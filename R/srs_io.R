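#' Parse a spontaneous-reporting-system date string
#'
#' SRS extracts store dates as digit strings that may be truncated to year
#' (\code{"YYYY"}) or year-month (\code{"YYYYMM"}) precision. The drug-timing
#' rules used downstream need day resolution, so anything short of a full,
#' valid \code{"YYYYMMDD"} string is treated as missing rather than imputed.
#'
#' @param x character vector of raw date strings (may contain \code{NA} or
#'   empty strings).
#' @return a \code{Date} vector of the same length; \code{NA} where the input
#'   is empty, partial, or not a valid calendar date.
#' @examples
#' parse_partial_date(c("20170701", "201707", "2017", "", "20170230"))
#' @export
parse_partial_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  out <- rep(as.Date(NA), length(x))
  full <- grepl("^[0-9]{8}$", x)
  if (any(full)) {
    # as.Date() rejects impossible dates (e.g. Feb 30) with NA
    out[full] <- as.Date(x[full], format = "%Y%m%d")
  }
  out
}

#' Format a Date back to the raw YYYYMMDD convention
#' @param d Date vector
#' @return character vector, "" where \code{d} is missing
#' @keywords internal
format_srs_date <- function(d) {
  out <- character(length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}

demo_required_cols <- c("case_id", "sex", "age")
drug_required_cols <- c("case_id", "drug_name", "route", "start_date", "end_date")
reac_required_cols <- c("case_id", "pt_code", "pt_name", "onset_date")

check_schema <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("table '%s' is missing required column(s): %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Construct a linked report dataset from in-memory tables
#'
#' Normalizes the three SRS tables (demographics, drug records, adverse
#' events) into the internal data model: drug and event names are
#' whitespace-trimmed, dates are parsed with [parse_partial_date()], source
#' row order is recorded, and rows whose \code{case_id} does not appear in
#' the demographics table are moved to a rejects log instead of the dataset.
#' Drug rows whose parsed start date falls after their end date are kept but
#' flagged (\code{date_conflict}); their dates are treated as missing by the
#' timing filter, because silently dropping such rows would bias case counts.
#'
#' @param demo data.frame with columns \code{case_id, sex, age}.
#' @param drug data.frame with columns \code{case_id, drug_name, route,
#'   start_date, end_date} (dates as YYYYMMDD strings, possibly truncated).
#' @param reac data.frame with columns \code{case_id, pt_code, pt_name,
#'   onset_date}.
#' @return an object of class \code{report_dataset}: a list with elements
#'   \code{demo}, \code{drug}, \code{reac} (normalized data.frames) and
#'   \code{rejects} (excluded rows with reasons).
#' @export
report_dataset <- function(demo, drug, reac) {
  demo <- as.data.frame(demo, stringsAsFactors = FALSE)
  drug <- as.data.frame(drug, stringsAsFactors = FALSE)
  reac <- as.data.frame(reac, stringsAsFactors = FALSE)
  check_schema(demo, demo_required_cols, "DEMO")
  check_schema(drug, drug_required_cols, "DRUG")
  check_schema(reac, reac_required_cols, "REAC")

  rejects <- data.frame(table = character(), row = integer(),
                        case_id = character(), reason = character(),
                        stringsAsFactors = FALSE)

  demo$case_id <- trimws(as.character(demo$case_id))
  demo$sex <- as.character(demo$sex)
  demo$age <- as.character(demo$age)
  bad <- !nzchar(demo$case_id)
  if (any(bad)) {
    rejects <- rbind(rejects, data.frame(
      table = "DEMO", row = which(bad), case_id = demo$case_id[bad],
      reason = "empty case_id", stringsAsFactors = FALSE))
    demo <- demo[!bad, , drop = FALSE]
  }
  if (anyDuplicated(demo$case_id)) {
    stop("DEMO case_id values must be unique", call. = FALSE)
  }
  demo$record_order <- seq_len(nrow(demo))

  normalize_child <- function(df, table) {
    df$case_id <- trimws(as.character(df$case_id))
    df$record_order <- seq_len(nrow(df))
    orphan <- !(df$case_id %in% demo$case_id)
    if (any(orphan)) {
      rejects <<- rbind(rejects, data.frame(
        table = table, row = which(orphan), case_id = df$case_id[orphan],
        reason = "case_id absent from DEMO", stringsAsFactors = FALSE))
    }
    df[!orphan, , drop = FALSE]
  }

  drug$drug_name <- trimws(as.character(drug$drug_name))
  drug$route <- as.character(drug$route)
  drug$start_date_raw <- as.character(drug$start_date)
  drug$end_date_raw <- as.character(drug$end_date)
  drug$start_date <- parse_partial_date(drug$start_date_raw)
  drug$end_date <- parse_partial_date(drug$end_date_raw)
  drug$date_conflict <- !is.na(drug$start_date) & !is.na(drug$end_date) &
    drug$start_date > drug$end_date
  drug <- normalize_child(drug, "DRUG")

  reac$pt_code <- trimws(as.character(reac$pt_code))
  reac$pt_name <- as.character(reac$pt_name)
  if (any(!nzchar(reac$pt_code))) {
    stop("REAC pt_code must be non-empty", call. = FALSE)
  }
  reac$onset_date_raw <- as.character(reac$onset_date)
  reac$onset_date <- parse_partial_date(reac$onset_date_raw)
  reac <- normalize_child(reac, "REAC")

  structure(list(demo = demo, drug = drug, reac = reac, rejects = rejects),
            class = "report_dataset")
}

#' Read the linked DEMO/DRUG/REAC tables from delimited files
#'
#' Reads one CSV per table, validates the documented schema, and normalizes
#' into the internal model via [report_dataset()]. Source row order is
#' preserved; rows referencing a \code{case_id} absent from DEMO are logged
#' as rejects, not loaded.
#'
#' @param demo_path,drug_path,reac_path paths to the three CSV files.
#' @param encoding character encoding of the source files (real-world SRS
#'   distributions often ship in a non-UTF-8 Japanese encoding).
#' @return a \code{report_dataset}.
#' @seealso [write_report_tables()]
#' @export
read_report_tables <- function(demo_path, drug_path, reac_path,
                               encoding = "UTF-8") {
  read1 <- function(path) {
    utils::read.csv(path, colClasses = "character", fileEncoding = encoding,
                    check.names = TRUE, stringsAsFactors = FALSE)
  }
  report_dataset(read1(demo_path), read1(drug_path), read1(reac_path))
}

#' Write a report dataset back to the three-table CSV layout
#'
#' Inverse of [read_report_tables()]: emits \code{demo.csv}, \code{drug.csv}
#' and \code{reac.csv} with the raw YYYYMMDD date strings, so a read/write
#' cycle reproduces row counts and field values exactly. The rejects log, if
#' non-empty, is written as \code{rejects.tsv}.
#'
#' @param dataset a \code{report_dataset}.
#' @param dir output directory (created if absent).
#' @param encoding output file encoding.
#' @return invisibly, the paths written.
#' @export
write_report_tables <- function(dataset, dir, encoding = "UTF-8") {
  stopifnot(inherits(dataset, "report_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("demo.csv", "drug.csv", "reac.csv"))
  demo_out <- dataset$demo[, c("case_id", "sex", "age")]
  drug_out <- data.frame(case_id = dataset$drug$case_id,
                         drug_name = dataset$drug$drug_name,
                         route = dataset$drug$route,
                         start_date = dataset$drug$start_date_raw,
                         end_date = dataset$drug$end_date_raw,
                         stringsAsFactors = FALSE)
  reac_out <- data.frame(case_id = dataset$reac$case_id,
                         pt_code = dataset$reac$pt_code,
                         pt_name = dataset$reac$pt_name,
                         onset_date = dataset$reac$onset_date_raw,
                         stringsAsFactors = FALSE)
  utils::write.csv(demo_out, paths[1], row.names = FALSE, fileEncoding = encoding)
  utils::write.csv(drug_out, paths[2], row.names = FALSE, fileEncoding = encoding)
  utils::write.csv(reac_out, paths[3], row.names = FALSE, fileEncoding = encoding)
  if (nrow(dataset$rejects) > 0L) {
    utils::write.table(dataset$rejects, file.path(dir, "rejects.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE,
                       fileEncoding = encoding)
  }
  invisible(paths)
}

#' @export
print.report_dataset <- function(x, ...) {
  cat("Linked spontaneous-report dataset\n")
  cat(sprintf("  DEMO: %d cases   DRUG: %d records   REAC: %d events\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac)))
  if (nrow(x$rejects) > 0L) {
    cat(sprintf("  rejects: %d rows excluded at load (see $rejects)\n",
                nrow(x$rejects)))
  }
  invisible(x)
}
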