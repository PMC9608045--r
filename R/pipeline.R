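#' Analyze one index drug on an in-memory dataset
#'
#' The end-to-end per-index-drug analysis: case extraction (timing rules,
#' injectable exclusion, deduplication), monotherapy exclusion, feature
#' matrix, tree growth, and node-wise testing against the initial rate with
#' Benjamini-Hochberg control.
#'
#' @param dataset a \code{report_dataset}.
#' @param index_drug name of the index drug.
#' @param extraction an \code{extraction_config}; defaults to one built for
#'   \code{index_drug} with standard settings.
#' @param tree a \code{tree_config}.
#' @param fdr_q FDR level (default 0.05).
#' @param method proportion-test method, see [node_proportion_test()].
#' @return a \code{ddi_signals} object with attributes \code{tree},
#'   \code{cases} (post-extraction) and \code{features}.
#' @export
analyze_dataset <- function(dataset, index_drug,
                            extraction = extraction_config(index_drug),
                            tree = tree_config(),
                            fdr_q = 0.05,
                            method = c("exact", "chisq")) {
  method <- match.arg(method)
  cases <- build_analysis_cases(dataset, extraction)
  analyzed <- exclude_monotherapy(cases)
  fm <- build_feature_matrix(analyzed)
  tr <- grow_tree(fm, tree)
  sig <- extract_signals(tr, q = fdr_q, method = method,
                         index_drug = index_drug)
  attr(sig, "tree") <- tr
  attr(sig, "cases") <- cases
  attr(sig, "features") <- fm
  sig
}

#' Run the full analysis from files, per index drug, with artifacts
#'
#' Reads the three linked tables and runs [analyze_dataset()] independently
#' for each configured index drug (analyses never share state). A failure in
#' one index drug's analysis — e.g. no case uses it — is recorded and does
#' not abort the others. When \code{out_dir} is given, each analysis writes
#' its signal TSV (+ node sidecar), tree JSON and exclusion audit log, plus a
#' run manifest with input checksums and the configuration.
#'
#' @param demo_path,drug_path,reac_path input CSV paths.
#' @param index_drugs character vector of index drug names (default: the six
#'   statins).
#' @param event_pt_code target MedDRA PT code.
#' @param tree a \code{tree_config}.
#' @param fdr_q FDR level.
#' @param method proportion-test method.
#' @param encoding source file encoding.
#' @param out_dir optional output directory for artifacts.
#' @return named list (one element per index drug) of \code{ddi_signals}
#'   objects, or \code{condition} objects where an analysis failed; attribute
#'   \code{"failed"} names the failures.
#' @export
run_analysis <- function(demo_path, drug_path, reac_path,
                         index_drugs = statin_names(),
                         event_pt_code = "10039020",
                         tree = tree_config(),
                         fdr_q = 0.05,
                         method = c("exact", "chisq"),
                         encoding = "UTF-8",
                         out_dir = NULL) {
  method <- match.arg(method)
  dataset <- read_report_tables(demo_path, drug_path, reac_path,
                                encoding = encoding)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- list()
  for (dg in index_drugs) {
    res <- tryCatch(
      suppressWarnings(analyze_dataset(
        dataset, dg,
        extraction = extraction_config(dg, event_pt_code = event_pt_code),
        tree = tree, fdr_q = fdr_q, method = method)),
      error = function(e) e)
    results[[dg]] <- res
    if (!is.null(out_dir) && inherits(res, "ddi_signals")) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", dg)
      write_signal_table(res, file.path(out_dir, paste0(safe, "_signals.tsv")))
      tree_to_json(attr(res, "tree"),
                   file.path(out_dir, paste0(safe, "_tree.json")))
      utils::write.table(extraction_audit(attr(res, "cases")),
                         file.path(out_dir, paste0(safe, "_audit.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  failed <- names(results)[vapply(results, inherits, TRUE, "condition")]
  if (!is.null(out_dir)) {
    manifest <- list(
      inputs = as.list(tools::md5sum(c(demo = demo_path, drug = drug_path,
                                       reac = reac_path))),
      index_drugs = index_drugs, event_pt_code = event_pt_code,
      min_node = tree$min_node, max_depth = tree$max_depth,
      criterion = tree$criterion, fdr_q = fdr_q, method = method,
      failed = failed, timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(results, "failed") <- failed
  results
}

#' Count the headline signals of one analysis
#' @param signals a \code{ddi_signals}.
#' @return number of reported (significant, presence-only, above-IR) rows.
#' @export
n_signals <- function(signals) {
  stopifnot(inherits(signals, "ddi_signals"))
  nrow(signals$table)
}

#' Null calibration of the signal frequency
#'
#' Because the tree selects nodes greedily before they are tested, nominal
#' FDR control does not follow from the Benjamini-Hochberg step; this
#' routine measures the operating characteristic empirically. It simulates
#' \code{n_replicates} datasets from a no-planted-effect configuration, runs
#' the full pipeline on each, and reports the per-replicate headline-signal
#' counts and the frequency of at least one signal.
#'
#' @param config a \code{simulation_config} with no planted effects; its
#'   \code{seed} seeds replicate \code{r} as \code{seed + r}.
#' @param n_replicates number of simulated datasets.
#' @param fdr_q FDR level used in each analysis.
#' @param tree a \code{tree_config}.
#' @return an object of class \code{ddi_calibration}: data.frame with
#'   \code{replicate, seed, n_analyzed, n_signals}; attribute
#'   \code{freq_any}, the empirical frequency of >= 1 signal.
#' @export
run_null_calibration <- function(config, n_replicates, fdr_q = 0.05,
                                 tree = tree_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$planted_effects) > 0L)
    stop("null calibration requires a config with no planted effects",
         call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_dataset(cfg)
    sig <- suppressWarnings(analyze_dataset(
      sim$dataset, cfg$drug_vocabulary[1L],
      extraction = extraction_config(cfg$drug_vocabulary[1L]),
      tree = tree, fdr_q = fdr_q))
    rows[[r]] <- data.frame(replicate = r, seed = cfg$seed,
                            n_analyzed = sig$n_total,
                            n_signals = n_signals(sig))
  }
  out <- if (n_replicates > 0L) do.call(rbind, rows) else
    data.frame(replicate = integer(), seed = integer(),
               n_analyzed = integer(), n_signals = integer())
  structure(out,
            freq_any = if (n_replicates > 0L) mean(out$n_signals >= 1L) else
              NA_real_,
            class = c("ddi_calibration", "data.frame"))
}

#' @export
print.ddi_calibration <- function(x, ...) {
  cat(sprintf("Null calibration: %d replicates, >=1-signal frequency %.3f\n",
              nrow(x), attr(x, "freq_any")))
  invisible(x)
}

# does any headline row's presence path cover every non-index drug of the set?
covers_planted_set <- function(signals, drugs, index_drug) {
  need <- setdiff(drugs, index_drug)
  if (nrow(signals$table) == 0L) return(FALSE)
  any(vapply(strsplit(signals$table$combination, " + ", fixed = TRUE),
             function(v) all(need %in% v), TRUE))
}

#' Recovery (power) study for planted interaction effects
#'
#' Simulates \code{n_replicates} datasets from a configuration with planted
#' effects, runs the full pipeline on each, and records whether every
#' planted drug set is recovered — i.e. some reported significant
#' combination's presence path covers all of the set's non-index drugs.
#'
#' @param config a \code{simulation_config} with at least one planted
#'   effect; replicate \code{r} uses seed \code{config$seed + r}.
#' @param n_replicates number of simulated datasets.
#' @param fdr_q FDR level.
#' @param tree a \code{tree_config}.
#' @return an object of class \code{ddi_recovery}: data.frame with
#'   \code{replicate, seed, n_signals, detected}; attribute \code{power},
#'   the fraction of replicates with full recovery.
#' @export
run_recovery_study <- function(config, n_replicates, fdr_q = 0.05,
                               tree = tree_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$planted_effects) == 0L)
    stop("recovery study requires planted effects", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  index_drug <- config$drug_vocabulary[1L]
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_dataset(cfg)
    sig <- suppressWarnings(analyze_dataset(
      sim$dataset, index_drug,
      extraction = extraction_config(index_drug),
      tree = tree, fdr_q = fdr_q))
    detected <- all(vapply(config$planted_effects, function(eff)
      covers_planted_set(sig, eff$drugs, index_drug), TRUE))
    rows[[r]] <- data.frame(replicate = r, seed = cfg$seed,
                            n_signals = n_signals(sig), detected = detected)
  }
  out <- if (n_replicates > 0L) do.call(rbind, rows) else
    data.frame(replicate = integer(), seed = integer(),
               n_signals = integer(), detected = logical())
  structure(out,
            power = if (n_replicates > 0L) mean(out$detected) else NA_real_,
            class = c("ddi_recovery", "data.frame"))
}

#' @export
print.ddi_recovery <- function(x, ...) {
  cat(sprintf("Recovery study: %d replicates, planted-set recovery %.2f\n",
              nrow(x), attr(x, "power")))
  invisible(x)
}
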