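#' Exact test of a node's reporting rate against the initial rate
#'
#' Two-sided exact binomial test of \code{k} events in \code{n} cases against
#' the null proportion \code{ir}: the p-value is the sum of the probabilities
#' of all outcomes no more likely than the observed one. The IR enters as a
#' fixed reference proportion; exact tests remain well behaved at the small
#' node sizes the minimum-node rule produces (n as low as 10).
#'
#' Degenerate references: at \code{ir = 0} observing \code{k > 0} (or at
#' \code{ir = 1} observing \code{k < n}) is impossible under the null; the
#' smallest representable positive double is returned instead of an exact 0,
#' with a warning.
#'
#' @param k observed event count.
#' @param n node size (>= 1).
#' @param ir null proportion in \code{[0, 1]}.
#' @param method \code{"exact"} (default) or \code{"chisq"} (one-sample
#'   chi-square without continuity correction, for sensitivity analysis).
#' @return p-value in \code{(0, 1]}.
#' @examples
#' node_proportion_test(4, 10, 69 / 739)  # ~0.0101
#' @export
node_proportion_test <- function(k, n, ir, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  if (ir < 0 || ir > 1) stop("ir must lie in [0, 1]", call. = FALSE)
  if (ir == 0) {
    if (k == 0) return(1)
    warning("observed events impossible under ir = 0; returning smallest positive p",
            call. = FALSE)
    return(.Machine$double.xmin)
  }
  if (ir == 1) {
    if (k == n) return(1)
    warning("observed non-events impossible under ir = 1; returning smallest positive p",
            call. = FALSE)
    return(.Machine$double.xmin)
  }
  if (method == "exact") {
    stats::binom.test(k, n, p = ir, alternative = "two.sided")$p.value
  } else {
    stat <- (k - n * ir)^2 / (n * ir * (1 - ir))
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate procedure: with p-values sorted
#' ascending, adjusted(i) = min over j >= i of min(1, p(j) * m / j), returned
#' in the original order, with rejections where the adjusted value is at most
#' \code{q}.
#'
#' @param p_values numeric vector of p-values in \code{[0, 1]}.
#' @param q FDR level (default 0.05).
#' @return list with \code{adjusted} (numeric) and \code{reject} (logical),
#'   both in input order; empty inputs give empty outputs.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Test every decision node and assemble the signal report
#'
#' Each non-root node's reporting rate is compared with the initial rate by
#' [node_proportion_test()]; Benjamini-Hochberg adjustment is applied across
#' all non-root nodes of the tree (the per-index-drug analysis is the family
#' unit). The headline table lists, after the IR row, only significant nodes
#' whose path consists solely of drug-presence conditions and whose rate
#' exceeds the IR — i.e. interpretable drug combinations that increase the
#' reporting rate. All tested nodes, including mixed presence/absence and
#' drug-count paths, remain available in the \code{nodes} element.
#'
#' @param tree a \code{ddi_tree}.
#' @param q FDR level (default 0.05).
#' @param method test method, see [node_proportion_test()].
#' @param index_drug optional label naming the analysis (shown in output).
#' @return an object of class \code{ddi_signals}: list with
#'   \code{index_drug}, \code{n_total}, \code{k_total}, \code{initial_rate},
#'   \code{fdr_q}, \code{method}, \code{nodes} (all tested nodes) and
#'   \code{table} (the headline rows).
#' @export
extract_signals <- function(tree, q = 0.05, method = c("exact", "chisq"),
                            index_drug = NULL) {
  stopifnot(inherits(tree, "ddi_tree"))
  method <- match.arg(method)
  ir <- tree$k_total / tree$n_total
  nodes <- enumerate_nodes(tree)
  if (length(nodes) == 0L) {
    nd <- data.frame(combination = character(), path = character(),
                     depth = integer(), n = integer(), k = integer(),
                     rate = numeric(), p_raw = numeric(), p_adj = numeric(),
                     significant = logical(), direction = character(),
                     presence_only = logical(), stringsAsFactors = FALSE)
  } else {
    n <- vapply(nodes, `[[`, 0, "n")
    k <- vapply(nodes, `[[`, 0, "k")
    p_raw <- vapply(seq_along(nodes), function(i)
      node_proportion_test(k[i], n[i], ir, method), 0)
    bh <- benjamini_hochberg(p_raw, q)
    presence_only <- vapply(nodes, function(nd)
      all(vapply(nd$path, function(cd)
        cd$kind == "presence" && cd$side == "right", TRUE)), TRUE)
    combo <- vapply(nodes, function(nd) {
      pres <- Filter(function(cd) cd$kind == "presence" && cd$side == "right",
                     nd$path)
      if (length(pres) == 0L) path_label(nd$path) else
        paste(vapply(pres, `[[`, "", "variable"), collapse = " + ")
    }, "")
    nd <- data.frame(combination = combo,
                     path = vapply(nodes, function(x) path_label(x$path), ""),
                     depth = vapply(nodes, `[[`, 0L, "depth"),
                     n = as.integer(n), k = as.integer(k),
                     rate = k / n,
                     p_raw = p_raw, p_adj = bh$adjusted,
                     significant = bh$reject,
                     direction = ifelse(k / n > ir, "above",
                                        ifelse(k / n < ir, "below", "equal")),
                     presence_only = presence_only,
                     stringsAsFactors = FALSE)
  }
  headline <- nd[nd$significant & nd$presence_only & nd$rate > ir, ,
                 drop = FALSE]
  headline <- headline[order(headline$depth, headline$combination), ,
                       drop = FALSE]
  rownames(headline) <- NULL
  structure(list(index_drug = index_drug,
                 n_total = tree$n_total, k_total = tree$k_total,
                 initial_rate = ir, fdr_q = q, method = method,
                 nodes = nd, table = headline),
            class = "ddi_signals")
}

#' @export
print.ddi_signals <- function(x, ...) {
  cat(sprintf("Signal report%s\n",
              if (!is.null(x$index_drug)) paste0(": ", x$index_drug) else ""))
  cat(sprintf("  %-34s %6s %9s %6s\n", "Combination", "Cases", "Cases(+)", "Rate"))
  cat(sprintf("  %-34s %6d %9d %5.2f (IR)\n", "-",
              x$n_total, x$k_total, round_half_up(x$initial_rate)))
  if (nrow(x$table) == 0L) {
    cat("  (no significant combination at FDR", x$fdr_q, ")\n")
  } else {
    for (i in seq_len(nrow(x$table))) {
      cat(sprintf("  %-34s %6d %9d %5.2f   p.adj=%.4g\n",
                  x$table$combination[i], x$table$n[i], x$table$k[i],
                  round_half_up(x$table$rate[i]), x$table$p_adj[i]))
    }
  }
  invisible(x)
}

#' Write the signal report as TSV (+ JSON sidecar of all tested nodes)
#'
#' The TSV carries the headline rows (IR row first); the sidecar JSON carries
#' every tested node for machine consumption. Byte-identical for identical
#' inputs.
#'
#' @param signals a \code{ddi_signals}.
#' @param path TSV output path; the sidecar is written next to it as
#'   \code{<path>.nodes.json}.
#' @return invisibly, \code{path}.
#' @export
write_signal_table <- function(signals, path) {
  stopifnot(inherits(signals, "ddi_signals"))
  ir_row <- data.frame(combination = "-", cases = signals$n_total,
                       cases_positive = signals$k_total,
                       rate = sprintf("%.2f (IR)",
                                      round_half_up(signals$initial_rate)),
                       p_raw = "", p_adj = "", significant = "",
                       stringsAsFactors = FALSE)
  rows <- signals$table
  body <- if (nrow(rows) > 0L) data.frame(
    combination = rows$combination, cases = rows$n,
    cases_positive = rows$k,
    rate = sprintf("%.2f", round_half_up(rows$rate)),
    p_raw = sprintf("%.6g", rows$p_raw),
    p_adj = sprintf("%.6g", rows$p_adj),
    significant = ifelse(rows$significant, "yes", "no"),
    stringsAsFactors = FALSE) else NULL
  utils::write.table(rbind(ir_row, body), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".nodes.json")
  jsonlite::write_json(list(index_drug = signals$index_drug,
                            n_total = signals$n_total,
                            k_total = signals$k_total,
                            initial_rate = signals$initial_rate,
                            fdr_q = signals$fdr_q, method = signals$method,
                            nodes = signals$nodes),
                       sidecar, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
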