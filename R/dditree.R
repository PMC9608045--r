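#' Tree-growing configuration
#'
#' @param min_node minimum number of cases in every node, parent and child
#'   alike (default 10).
#' @param max_depth maximum number of splits on any root-to-leaf path
#'   (default 10).
#' @param min_split_stat a candidate split is accepted only if its statistic
#'   strictly exceeds this value (default 0: any positive improvement splits;
#'   signal screening happens downstream in the testing step, not by
#'   pruning).
#' @param criterion split-selection statistic: \code{"g2"} (likelihood-ratio
#'   chi-square, the default and tested path) or \code{"pearson"}.
#' @return an object of class \code{tree_config}.
#' @export
tree_config <- function(min_node = 10L, max_depth = 10L, min_split_stat = 0,
                        criterion = c("g2", "pearson")) {
  criterion <- match.arg(criterion)
  if (min_node < 2L) stop("min_node must be >= 2", call. = FALSE)
  if (max_depth < 0L) stop("max_depth must be >= 0", call. = FALSE)
  structure(list(min_node = as.integer(min_node),
                 max_depth = as.integer(max_depth),
                 min_split_stat = as.numeric(min_split_stat),
                 criterion = criterion),
            class = "tree_config")
}

# vectorized G^2 over parallel 2x2 tables; 0*log(0/E) taken as 0, degenerate
# event margins give exactly 0
g2_vec <- function(n1, k1, n0, k0) {
  n <- n1 + n0
  k <- k1 + k0
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * (term(k1, n1 * k / n) +
            term(n1 - k1, n1 * (n - k) / n) +
            term(k0, n0 * k / n) +
            term(n0 - k0, n0 * (n - k) / n))
  g[k == 0 | k == n] <- 0
  pmax(g, 0)
}

pearson_vec <- function(n1, k1, n0, k0) {
  n <- n1 + n0
  k <- k1 + k0
  e11 <- n1 * k / n; e10 <- n1 * (n - k) / n
  e01 <- n0 * k / n; e00 <- n0 * (n - k) / n
  x <- (k1 - e11)^2 / e11 + (n1 - k1 - e10)^2 / e10 +
       (k0 - e01)^2 / e01 + (n0 - k0 - e00)^2 / e00
  x[k == 0 | k == n] <- 0
  x
}

criterion_fun <- function(criterion) {
  switch(criterion, g2 = g2_vec, pearson = pearson_vec,
         stop("unknown criterion", call. = FALSE))
}

#' Likelihood-ratio chi-square of a 2x2 group-by-event table
#'
#' The split-selection statistic: \eqn{G^2 = 2 \sum O \ln(O/E)} over the four
#' cells of the table (group 1 vs group 0, event vs no event), with
#' \eqn{0\ln(0/E) = 0}. Equals 0 exactly when the two groups share the same
#' event proportion, and when the event margin is degenerate (no events, or
#' all events).
#'
#' @param n1,k1 cases and events in group 1.
#' @param n0,k0 cases and events in group 0.
#' @return the non-negative statistic (1 degree of freedom).
#' @examples
#' g2_statistic(10, 1, 90, 9)    # equal proportions: 0
#' g2_statistic(10, 4, 729, 65)  # 6.84
#' @export
g2_statistic <- function(n1, k1, n0, k0) {
  if (n1 < 1 || n0 < 1) stop("both groups must be non-empty", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k0 < 0 || k0 > n0)
    stop("event counts must lie within group sizes", call. = FALSE)
  g2_vec(n1, k1, n0, k0)
}

#' Pearson chi-square of a 2x2 group-by-event table
#'
#' Alternative split criterion (no continuity correction); same degenerate
#' conventions as [g2_statistic()].
#'
#' @inheritParams g2_statistic
#' @return the non-negative statistic.
#' @export
pearson_statistic <- function(n1, k1, n0, k0) {
  if (n1 < 1 || n0 < 1) stop("both groups must be non-empty", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k0 < 0 || k0 > n0)
    stop("event counts must lie within group sizes", call. = FALSE)
  pearson_vec(n1, k1, n0, k0)
}

# numeric rank used in tie-breaking: binary drug splits before drug_count
split_kind_rank <- function(kind) ifelse(kind == "presence", 0L, 1L)

#' Find the best admissible split of a node
#'
#' Evaluates every binary concomitant-drug column (present vs absent) and
#' every midpoint threshold of the drug-count covariate; candidates leaving a
#' child below \code{min_node} are inadmissible. Returns the candidate with
#' the maximal criterion statistic, provided it strictly exceeds
#' \code{min_split_stat}. Ties (within 1e-9 relative tolerance) are broken:
#' binary before numeric, then lexicographic variable name, then smaller
#' threshold. The "drug present" / "count >= threshold" side is always the
#' right child.
#'
#' @param fm a \code{ddi_features} object.
#' @param idx integer row indices defining the node (default: all cases).
#' @param config a \code{tree_config}.
#' @return a list of class \code{ddi_split} with elements \code{variable},
#'   \code{kind} ("presence" or "threshold"), \code{threshold} (NA for
#'   presence splits), \code{stat}, \code{n_right}, \code{k_right}; or
#'   \code{NULL} when no admissible improving split exists.
#' @export
find_best_split <- function(fm, idx = seq_along(fm$event), config = tree_config()) {
  stopifnot(inherits(fm, "ddi_features"))
  n <- length(idx)
  if (n < 2L * config$min_node) return(NULL)
  y <- fm$event[idx]
  k <- sum(y)
  if (k == 0L || k == n) return(NULL)
  statfun <- criterion_fun(config$criterion)

  vars <- character(0); kinds <- character(0)
  thrs <- numeric(0); stats <- numeric(0)
  nr <- integer(0); kr <- integer(0)

  if (length(fm$drugs) > 0L) {
    X <- fm$X[idx, , drop = FALSE]
    n1 <- colSums(X)
    k1 <- as.vector(crossprod(X, y))
    ok <- n1 >= config$min_node & (n - n1) >= config$min_node
    if (any(ok)) {
      s <- statfun(n1[ok], k1[ok], n - n1[ok], k - k1[ok])
      vars <- c(vars, fm$drugs[ok])
      kinds <- c(kinds, rep("presence", sum(ok)))
      thrs <- c(thrs, rep(NA_real_, sum(ok)))
      stats <- c(stats, s)
      nr <- c(nr, as.integer(n1[ok]))
      kr <- c(kr, as.integer(k1[ok]))
    }
  }

  dc <- fm$drug_count[idx]
  uv <- sort(unique(dc))
  if (length(uv) >= 2L) {
    mids <- (uv[-length(uv)] + uv[-1L]) / 2
    for (thr in mids) {
      right <- dc >= thr
      n1 <- sum(right)
      if (n1 < config$min_node || (n - n1) < config$min_node) next
      k1 <- sum(y[right])
      vars <- c(vars, "drug_count")
      kinds <- c(kinds, "threshold")
      thrs <- c(thrs, thr)
      stats <- c(stats, statfun(n1, k1, n - n1, k - k1))
      nr <- c(nr, n1)
      kr <- c(kr, k1)
    }
  }

  if (length(stats) == 0L) return(NULL)
  best <- max(stats)
  if (!(best > config$min_split_stat)) return(NULL)
  tol <- 1e-9 * max(1, abs(best))
  tied <- which(stats >= best - tol)
  o <- tied[order(split_kind_rank(kinds[tied]), vars[tied], thrs[tied],
                  method = "radix", na.last = TRUE)]
  i <- o[1L]
  structure(list(variable = unname(vars[i]), kind = kinds[i],
                 threshold = unname(thrs[i]), stat = unname(stats[i]),
                 n_right = unname(nr[i]), k_right = unname(kr[i])),
            class = "ddi_split")
}

split_goes_right <- function(split, fm, idx) {
  if (split$kind == "presence") {
    fm$X[idx, split$variable] == 1L
  } else {
    fm$drug_count[idx] >= split$threshold
  }
}

#' Grow the recursive-partitioning tree
#'
#' Greedy recursive application of [find_best_split()]: starting from the
#' root (all cases), each node is split by the candidate maximizing the
#' criterion statistic, until a node is smaller than twice \code{min_node},
#' event-pure, at \code{max_depth}, or no admissible improving split remains.
#' Deterministic for identical input.
#'
#' @param fm a \code{ddi_features} object.
#' @param config a \code{tree_config}.
#' @return an object of class \code{ddi_tree}: list with \code{root} (nested
#'   node lists carrying \code{n}, \code{k}, \code{depth}, \code{path},
#'   \code{case_ids}, \code{split}, \code{children}), \code{config}, and the
#'   originating \code{fm} totals.
#' @export
grow_tree <- function(fm, config = tree_config()) {
  stopifnot(inherits(fm, "ddi_features"))
  n_all <- length(fm$event)
  if (n_all == 0L) stop("feature matrix is empty", call. = FALSE)

  build <- function(idx, depth, path) {
    node <- list(n = length(idx), k = sum(fm$event[idx]), depth = depth,
                 path = path, case_ids = fm$case_ids[idx],
                 split = NULL, children = NULL)
    if (depth >= config$max_depth) return(node)
    if (node$k == 0L || node$k == node$n) return(node)
    sp <- find_best_split(fm, idx, config)
    if (is.null(sp)) return(node)
    right <- split_goes_right(sp, fm, idx)
    cond_l <- list(variable = sp$variable, kind = sp$kind,
                   side = "left", threshold = sp$threshold)
    cond_r <- list(variable = sp$variable, kind = sp$kind,
                   side = "right", threshold = sp$threshold)
    node$split <- sp
    node$children <- list(
      build(idx[!right], depth + 1L, c(path, list(cond_l))),
      build(idx[right],  depth + 1L, c(path, list(cond_r))))
    node
  }

  root <- build(seq_len(n_all), 0L, list())
  structure(list(root = root, config = config,
                 n_total = n_all, k_total = sum(fm$event),
                 initial_rate = fm$initial_rate),
            class = "ddi_tree")
}

#' Enumerate all non-root decision nodes in pre-order
#'
#' The testing population for the signal step: every subgroup created by a
#' split, left (condition absent / below threshold) before right, parents
#' before children. The root is not listed — it defines the initial rate the
#' nodes are tested against.
#'
#' @param tree a \code{ddi_tree} (or a root node list).
#' @return list of node lists, each carrying its \code{path} of conditions.
#' @export
enumerate_nodes <- function(tree) {
  root <- if (inherits(tree, "ddi_tree")) tree$root else tree
  out <- list()
  walk <- function(node, is_root) {
    if (!is_root) out[[length(out) + 1L]] <<- node
    if (!is.null(node$children)) {
      walk(node$children[[1L]], FALSE)
      walk(node$children[[2L]], FALSE)
    }
  }
  walk(root, TRUE)
  out
}

#' Human-readable label of one path condition
#' @keywords internal
condition_label <- function(cond) {
  if (cond$kind == "presence") {
    paste0(if (cond$side == "right") "+" else "-", cond$variable)
  } else {
    paste0("drug_count", if (cond$side == "right") ">=" else "<",
           format(cond$threshold))
  }
}

path_label <- function(path) {
  if (length(path) == 0L) return("(root)")
  paste(vapply(path, condition_label, ""), collapse = " & ")
}

#' Flatten a tree to a node table
#'
#' @param x a \code{ddi_tree}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per node (root included): \code{path},
#'   \code{depth}, \code{n}, \code{k}, \code{rate}, \code{split_variable},
#'   \code{split_stat}, \code{is_leaf}.
#' @export
as.data.frame.ddi_tree <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list()
  walk <- function(node) {
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path_label(node$path), depth = node$depth,
      n = node$n, k = node$k, rate = node$k / node$n,
      split_variable = if (is.null(node$split)) NA_character_ else
        node$split$variable,
      split_stat = if (is.null(node$split)) NA_real_ else node$split$stat,
      is_leaf = is.null(node$children), stringsAsFactors = FALSE)
    if (!is.null(node$children)) {
      walk(node$children[[1L]]); walk(node$children[[2L]])
    }
  }
  walk(x$root)
  do.call(rbind, rows)
}

#' Serialize a tree to JSON for audit and golden-file comparison
#'
#' Case ids are omitted; node identity is carried by the path conditions.
#'
#' @param tree a \code{ddi_tree}.
#' @param path optional file path; if \code{NULL} the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ddi_tree"))
  strip <- function(node) {
    out <- list(n = node$n, k = node$k, depth = node$depth,
                path = path_label(node$path))
    if (!is.null(node$split)) {
      out$split <- list(variable = node$split$variable,
                        kind = node$split$kind,
                        threshold = node$split$threshold,
                        stat = node$split$stat)
      out$children <- list(strip(node$children[[1L]]),
                           strip(node$children[[2L]]))
    }
    out
  }
  js <- jsonlite::toJSON(list(
    n_total = tree$n_total, k_total = tree$k_total,
    initial_rate = tree$initial_rate,
    min_node = tree$config$min_node, criterion = tree$config$criterion,
    root = strip(tree$root)), auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @export
print.ddi_tree <- function(x, ...) {
  cat(sprintf("Recursive-partitioning tree (%s criterion, min node %d)\n",
              x$config$criterion, x$config$min_node))
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("%s%s  n=%d k=%d rate=%.3f%s\n",
                strrep("  ", df$depth[i]),
                if (df$depth[i] == 0L) "(root)" else
                  sub(".*& ", "", df$path[i]),
                df$n[i], df$k[i], df$rate[i],
                if (!df$is_leaf[i])
                  sprintf("  [split %s, G2=%.3f]", df$split_variable[i],
                          df$split_stat[i]) else ""))
  }
  invisible(x)
}
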