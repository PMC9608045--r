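test_that("G2 statistic: frozen oracle value, symmetry, zero at equal rates", {
  # independent high-precision evaluation of 2*sum(O ln(O/E)), frozen
  expect_equal(g2_statistic(10, 4, 729, 65), 6.8399999134329614,
               tolerance = 1e-12)
  # equal proportions give exactly zero
  expect_identical(g2_statistic(10, 1, 90, 9), 0)
  # group-label symmetry
  expect_equal(g2_statistic(25, 7, 80, 9), g2_statistic(80, 9, 25, 7))
  # degenerate event margins
  expect_identical(g2_statistic(20, 0, 30, 0), 0)
  expect_identical(g2_statistic(20, 20, 30, 30), 0)
  # agreement with the binomial log-likelihood-ratio identity
  set.seed(11)
  for (i in 1:50) {
    n1 <- sample(5:80, 1); n0 <- sample(5:80, 1)
    k1 <- rbinom(1, n1, 0.3); k0 <- rbinom(1, n0, 0.3)
    expect_equal(g2_statistic(n1, k1, n0, k0), oracle_g2(n1, k1, n0, k0),
                 tolerance = 1e-10)
  }
  expect_error(g2_statistic(0, 0, 5, 1), "non-empty")
  # Pearson alternative agrees with chisq.test (no correction) where defined
  tab <- matrix(c(12, 18, 40, 60), 2)
  expect_equal(pearson_statistic(30, 12, 100, 40),
               unname(chisq.test(cbind(c(12, 40), c(18, 60)),
                                 correct = FALSE)$statistic))
})

test_that("best split: perfect separator wins, node-size arithmetic, tie-break", {
  # drug d01 present in exactly the 12 event cases, absent elsewhere
  n <- 100
  X <- matrix(0L, n, 2, dimnames = list(NULL, c("d01", "d02")))
  event <- c(rep(1L, 12), rep(0L, 88))
  X[1:12, "d01"] <- 1L
  X[sample(seq_len(n), 40), "d02"] <- 1L
  fm <- structure(list(case_ids = as.character(1:n), drugs = colnames(X),
                       X = X, drug_count = rep(3, n), event = event,
                       initial_rate = mean(event)),
                  class = "ddi_features")
  sp <- find_best_split(fm, config = tree_config())
  expect_equal(sp$variable, "d01")
  expect_equal(sp$kind, "presence")

  # 15 cases cannot yield two children of >= 10
  set.seed(3)
  fm15 <- random_features(15, 4)
  expect_null(find_best_split(fm15, config = tree_config(min_node = 10)))

  # identical 2x2 tables tie; lexicographically first drug is returned
  X2 <- cbind(a_drug = X[, "d01"], z_drug = X[, "d01"])
  fm2 <- fm; fm2$X <- X2; fm2$drugs <- colnames(X2)
  sp2 <- find_best_split(fm2, config = tree_config())
  expect_equal(sp2$variable, "a_drug")
})

test_that("chosen split equals the brute-force maximum on random matrices", {
  set.seed(101)
  for (i in 1:40) {
    fm <- random_features(sample(40:200, 1), sample(2:12, 1),
                          event_prob = runif(1, 0.05, 0.5))
    sp <- find_best_split(fm, config = tree_config())
    best <- oracle_best_split_stat(fm, min_node = 10L)
    if (is.null(sp)) {
      expect_true(!is.finite(best) || best <= 0 + 1e-12)
    } else {
      expect_equal(sp$stat, best, tolerance = 1e-9)
    }
  }
})

test_that("grown trees conserve counts, respect node size, and are deterministic", {
  set.seed(55)
  for (i in 1:15) {
    fm <- random_features(sample(60:250, 1), sample(3:10, 1),
                          event_prob = runif(1, 0.1, 0.4))
    tr <- grow_tree(fm, tree_config())
    expect_true(check_tree_invariants(tr, min_node = 10L))
    expect_equal(tr$root$n, length(fm$event))
    expect_equal(tr$root$k, sum(fm$event))
  }
  # determinism: identical input, identical serialized tree
  set.seed(9)
  fm <- random_features(150, 6)
  expect_identical(tree_to_json(grow_tree(fm, tree_config())),
                   tree_to_json(grow_tree(fm, tree_config())))
})

test_that("degenerate matrices give a root leaf; depth-1 tree lists 2 nodes", {
  # zero-variance drug columns only, constant drug count
  n <- 60
  fm <- structure(list(case_ids = as.character(1:n), drugs = c("d1", "d2"),
                       X = matrix(0L, n, 2, dimnames = list(NULL, c("d1", "d2"))),
                       drug_count = rep(2, n),
                       event = rep(c(1L, 0L), c(10, 50)),
                       initial_rate = 10 / 60),
                  class = "ddi_features")
  tr <- grow_tree(fm, tree_config())
  expect_null(tr$root$children)
  expect_length(enumerate_nodes(tr), 0L)

  # one strong drug, max_depth 1: exactly two non-root nodes, totals conserved
  fm$X[, "d1"] <- rep(c(1L, 0L), c(10, 50))
  tr1 <- grow_tree(fm, tree_config(max_depth = 1))
  nodes <- enumerate_nodes(tr1)
  expect_length(nodes, 2L)
  expect_equal(sum(vapply(nodes, `[[`, 0, "n")), 60)
  expect_equal(sum(vapply(nodes, `[[`, 0, "k")), 10)
  # the event-carrying side is the "present" right child
  expect_equal(tr1$root$split$variable, "d1")
})

test_that("planted strong effect yields a depth-1 split on the planted drug", {
  set.seed(404)
  n <- 300
  X <- matrix(rbinom(n * 5, 1L, 0.3), n, 5,
              dimnames = list(NULL, sprintf("d%02d", 1:5)))
  p <- ifelse(X[, "d03"] == 1L, 0.5, 0.05)
  fm <- structure(list(case_ids = as.character(1:n),
                       drugs = colnames(X), X = X,
                       drug_count = rowSums(X) + 1,
                       event = rbinom(n, 1L, p),
                       initial_rate = NA_real_),
                  class = "ddi_features")
  fm$initial_rate <- mean(fm$event)
  tr <- grow_tree(fm, tree_config(max_depth = 1))
  expect_equal(tr$root$split$variable, "d03")
})
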