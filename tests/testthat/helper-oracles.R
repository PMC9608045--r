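# Independent oracles and generators used across the suite. These stay
# deliberately naive and algebraically separate from the package's
# implementations.

# G2 via the binomial log-likelihood-ratio identity (different route from
# the package's observed/expected cell sum)
oracle_g2 <- function(n1, k1, n0, k0) {
  ll <- function(k, n, p) {
    (if (k > 0) k * log(p) else 0) +
      (if (n - k > 0) (n - k) * log(1 - p) else 0)
  }
  p1 <- k1 / n1
  p0 <- k0 / n0
  p <- (k1 + k0) / (n1 + n0)
  2 * (ll(k1, n1, p1) + ll(k0, n0, p0) - ll(k1, n1, p) - ll(k0, n0, p))
}

# exact two-sided binomial p by explicit enumeration of all n+1 outcomes
# (small-p relative tolerance as in the classical definition)
oracle_binom_p <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up applied literally from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  adj[order(o)]
}

# brute-force best admissible split statistic over every drug column and
# every drug-count midpoint threshold
oracle_best_split_stat <- function(fm, idx = seq_along(fm$event),
                                   min_node = 10L) {
  y <- fm$event[idx]
  n <- length(idx)
  best <- -Inf
  for (j in seq_along(fm$drugs)) {
    x <- fm$X[idx, j]
    n1 <- sum(x)
    if (n1 < min_node || n - n1 < min_node) next
    best <- max(best, oracle_g2(n1, sum(y[x == 1L]), n - n1, sum(y[x == 0L])))
  }
  dc <- fm$drug_count[idx]
  uv <- sort(unique(dc))
  if (length(uv) >= 2L) {
    for (thr in (uv[-length(uv)] + uv[-1L]) / 2) {
      r <- dc >= thr
      n1 <- sum(r)
      if (n1 < min_node || n - n1 < min_node) next
      best <- max(best, oracle_g2(n1, sum(y[r]), n - n1, sum(y[!r])))
    }
  }
  best
}

# random feature-matrix object built directly (bypasses extraction)
random_features <- function(n, p_drugs, event_prob = 0.2,
                            drug_prob = 0.3) {
  X <- matrix(rbinom(n * p_drugs, 1L, drug_prob), n, p_drugs,
              dimnames = list(NULL, sprintf("d%02d", seq_len(p_drugs))))
  event <- rbinom(n, 1L, event_prob)
  structure(list(case_ids = sprintf("C%04d", seq_len(n)),
                 drugs = colnames(X), X = X,
                 drug_count = rowSums(X) + 1,
                 event = as.integer(event),
                 initial_rate = mean(event)),
            class = "ddi_features")
}

# recursive structural checks on a grown tree
check_tree_invariants <- function(tree, min_node) {
  ok <- TRUE
  walk <- function(node) {
    if (node$n < min_node) ok <<- FALSE
    if (!is.null(node$children)) {
      l <- node$children[[1L]]
      r <- node$children[[2L]]
      if (l$n + r$n != node$n || l$k + r$k != node$k) ok <<- FALSE
      if (!setequal(c(l$case_ids, r$case_ids), node$case_ids)) ok <<- FALSE
      walk(l)
      walk(r)
    }
  }
  walk(tree$root)
  ok
}

# tiny three-table fixture written to disk; returns the file paths
write_tiny_tables <- function(dir, encoding = "UTF-8",
                              extra_drug_rows = NULL) {
  demo <- data.frame(case_id = c("A", "B", "C"),
                     sex = c("male", "female", "male"),
                     age = c("60s", "70s", "50s"))
  drug <- data.frame(case_id = c("A", "B", "C"),
                     drug_name = c("pitavastatin", "allopurinol", "valsartan"),
                     route = "oral",
                     start_date = c("20170101", "201701", ""),
                     end_date = c("20170601", "", ""))
  if (!is.null(extra_drug_rows)) drug <- rbind(drug, extra_drug_rows)
  reac <- data.frame(case_id = c("A", "B", "C"),
                     pt_code = c("10039020", "10000001", "10000001"),
                     pt_name = c("Rhabdomyolysis", "Other", "Other"),
                     onset_date = c("20170315", "", "20170801"))
  paths <- file.path(dir, c("demo.csv", "drug.csv", "reac.csv"))
  write.csv(demo, paths[1], row.names = FALSE, fileEncoding = encoding)
  write.csv(drug, paths[2], row.names = FALSE, fileEncoding = encoding)
  write.csv(reac, paths[3], row.names = FALSE, fileEncoding = encoding)
  paths
}
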