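#' Remove index-drug monotherapy cases
#'
#' A monotherapy case — one whose retained drug set contains no concomitant
#' non-statin drug — carries no information about drug-drug interactions and
#' is excluded before the initial rate is computed.
#'
#' @param cases a \code{ddi_cases} object (or compatible data.frame with a
#'   \code{concomitant_drugs} list column).
#' @return the retained cases; errors if none remain.
#' @export
exclude_monotherapy <- function(cases) {
  n_conc <- vapply(cases$concomitant_drugs, length, integer(1))
  out <- cases[n_conc > 0L, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("all cases are index-drug monotherapy; nothing to analyze",
         call. = FALSE)
  out
}

#' Reporting rate of a stratum
#'
#' @param n_cases number of cases in the stratum (>= 1).
#' @param n_events number of event-positive cases (0 <= n_events <= n_cases).
#' @return \code{n_events / n_cases} at full precision. Use
#'   [round_half_up()] for the 2-decimal display convention.
#' @examples
#' compute_rate(739, 69)   # 0.0933...; displays as 0.09
#' compute_rate(10, 4)     # 0.40
#' @export
compute_rate <- function(n_cases, n_events) {
  if (any(n_cases < 1)) stop("n_cases must be >= 1", call. = FALSE)
  if (any(n_events < 0) || any(n_events > n_cases))
    stop("n_events must lie in [0, n_cases]", call. = FALSE)
  n_events / n_cases
}

#' Round half away from zero
#'
#' Display rounding for reporting rates: half-up to \code{digits} decimals
#' (so 5/13 = 0.3846 -> 0.38 and 7/16 = 0.4375 -> 0.44), unlike base
#' \code{round()}'s round-half-to-even. Internal arithmetic stays at full
#' precision; this is applied only when printing.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Build the case-by-drug analysis matrix
#'
#' Converts extracted cases into the inputs of the partitioning step: a
#' binary indicator matrix over all concomitant drugs (column order is
#' lexicographic for run-to-run stability), the per-case count of retained
#' drugs as an ordered numeric covariate, the binary event outcome, and the
#' initial rate (IR) — the event proportion over all included cases before
#' any stratification.
#'
#' @param cases a \code{ddi_cases} object, already monotherapy-filtered via
#'   [exclude_monotherapy()] (cases with empty concomitant sets are rejected).
#' @return an object of class \code{ddi_features}: list with \code{case_ids},
#'   \code{drugs}, \code{X} (0/1 integer matrix), \code{drug_count},
#'   \code{event} (0/1 integer), \code{initial_rate}.
#' @export
build_feature_matrix <- function(cases) {
  if (nrow(cases) == 0L) stop("no cases to build features from", call. = FALSE)
  n_conc <- vapply(cases$concomitant_drugs, length, integer(1))
  if (any(n_conc == 0L))
    stop("monotherapy cases present; apply exclude_monotherapy() first",
         call. = FALSE)
  drugs <- sort(unique(unlist(cases$concomitant_drugs)))
  n <- nrow(cases)
  X <- matrix(0L, nrow = n, ncol = length(drugs),
              dimnames = list(cases$case_id, drugs))
  ji <- lapply(cases$concomitant_drugs, match, table = drugs)
  for (i in seq_len(n)) X[i, ji[[i]]] <- 1L
  event <- as.integer(cases$event_flag)
  structure(list(case_ids = cases$case_id,
                 drugs = drugs,
                 X = X,
                 drug_count = as.numeric(cases$n_drugs),
                 event = event,
                 initial_rate = mean(event)),
            class = "ddi_features")
}

#' @export
print.ddi_features <- function(x, ...) {
  cat(sprintf(paste0("Feature matrix: %d cases x %d concomitant drugs ",
                     "(+ drug count)\n"),
              length(x$case_ids), length(x$drugs)))
  cat(sprintf("  events: %d   initial rate: %.4f\n",
              sum(x$event), x$initial_rate))
  invisible(x)
}

#' Dump the feature matrix as TSV for audit
#' @param fm a \code{ddi_features} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "ddi_features"))
  df <- data.frame(case_id = fm$case_ids, fm$X,
                   drug_count = fm$drug_count, event = fm$event,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
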