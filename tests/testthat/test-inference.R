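test_that("permutation p-value follows the add-one formula and never hits 0", {
  # score ignores the target: all null scores equal the observed
  flat <- function(X, y) 1
  X <- matrix(rnorm(40), 10, dimnames = list(sprintf("s%02d", 1:10), NULL))
  res <- permutation_test(flat, X, rnorm(10), n_perm = 19, seed = 1)
  expect_equal(res$p_value, 1)
  # a score no permutation can match gives the formula floor
  y <- c(rep(0, 5), rep(1, 5))
  sharp <- function(X, yy) if (identical(yy, y)) 2 else 1
  res <- permutation_test(sharp, X, y, n_perm = 199, seed = 1,
                          better = "higher")
  expect_equal(res$p_value, 1 / 200)
  expect_gt(res$p_value, 0)
  expect_error(permutation_test(flat, X, rnorm(10), n_perm = 0), "at least 1")
})

test_that("permutation p is invariant to subject reordering given the seed", {
  score <- function(X, y) mean(abs(X[, 1] - y))
  set.seed(4)
  X <- matrix(rnorm(60), 20,
              dimnames = list(sprintf("s%02d", 1:20), NULL))
  y <- rnorm(20)
  res1 <- permutation_test(score, X, y, n_perm = 49, seed = 7)
  perm <- sample(20)
  res2 <- permutation_test(score, X[perm, ], y[perm], n_perm = 49, seed = 7)
  expect_equal(res2$p_value, res1$p_value)
  expect_equal(sort(res2$scores), sort(res1$scores), tolerance = 1e-12)
})

test_that("permutation p-values are uniform under a null pipeline", {
  # cheap null model: ridge-free OLS on 3 noise features, 5-fold MAE
  pipeline <- function(X, y) {
    fold <- rep_len(1:5, length(y))
    pred <- numeric(length(y))
    for (f in 1:5) {
      tr <- fold != f
      fit <- stats::lm.fit(cbind(1, X[tr, ]), y[tr])
      pred[!tr] <- cbind(1, X[!tr, ]) %*% fit$coefficients
    }
    mean(abs(pred - y))
  }
  set.seed(31)
  pvals <- vapply(1:50, function(r) {
    X <- matrix(rnorm(30 * 3), 30)
    rownames(X) <- sprintf("s%02d", 1:30)
    y <- rnorm(30)
    permutation_test(pipeline, X, y, n_perm = 99, seed = 100 + r)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.192)   # 5% critical value at n = 50
})

test_that("stable edge selection counts fold masks correctly", {
  masks <- matrix(FALSE, 105, 4)        # col 4 plays a confound column
  masks[seq_len(103), 1] <- TRUE        # 103/105 = 0.981
  masks[, 2] <- TRUE                    # 105/105
  masks[seq_len(52), 3] <- TRUE         # 52/105
  cv <- list(fold_masks = masks, n_edge_features = 3L)
  class(cv) <- "msn_cv"
  se <- stable_edges(cv, threshold = 0.99)
  # direct counting oracle
  expect_equal(unname(se$frequency), colSums(masks[, 1:3]) / 105)
  expect_equal(se$edge_index, 2L)           # 105/105 retained
  expect_false(1L %in% se$edge_index)       # 103/105 = 0.981 excluded
  # retained set shrinks monotonically with the threshold
  sizes <- vapply(c(0, 0.5, 0.9, 0.99, 1), function(th) {
    length(stable_edges(cv, th)$edge_index)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  # signing against the target across subjects
  edges <- cbind(1:6, c(6, 5, 4, 3, 2, 1), rep(1, 6))
  target <- 1:6
  se <- stable_edges(list(fold_masks = matrix(TRUE, 10, 3), n_edge_features = 3L),
                     threshold = 0.5, edges = edges, target = target)
  expect_equal(se$sign, c(1, -1, 0))
})

test_that("chi-squared worked example and invariances", {
  # sex-by-group counts: preterm 29M:30F, term 26M:20F
  counts <- matrix(c(29, 26, 30, 20), 2)
  res <- chi2_2x2(counts)
  expect_equal(round(res$p_value, 4), 0.4532)
  # independent oracle: stats::chisq.test without continuity correction
  ref <- stats::chisq.test(counts, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # proportional table: statistic 0, p = 1
  res0 <- chi2_2x2(matrix(10, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # hand formula on a skewed table
  counts2 <- matrix(c(20, 10, 10, 20), 2)
  expected <- outer(rowSums(counts2), colSums(counts2)) / sum(counts2)
  expect_equal(chi2_2x2(counts2)$statistic,
               sum((counts2 - expected)^2 / expected), tolerance = 1e-12)
  # invariance to transposition and simultaneous row/column swap
  expect_equal(chi2_2x2(t(counts))$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(chi2_2x2(counts[2:1, 2:1])$statistic, res$statistic,
               tolerance = 1e-12)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("rank tests agree with exact null enumeration at small n", {
  a <- c(1.2, 3.1, 4.5, 2.2)
  b <- c(5.1, 6.3, 4.9, 7.2, 8.0)
  got <- rank_sum_test(a, b)
  # enumeration oracle over all assignments of ranks to the first sample
  ranks <- rank(c(a, b))
  W_obs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(9, 4)
  W_null <- apply(combos, 2, function(ix) sum(seq_len(9)[ix]) - 10)
  p_exact <- mean(abs(W_null - 10) >= abs(W_obs - 10))
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  expect_equal(unname(got$W), W_obs)
  # disjoint ranges are detected decisively
  res <- rank_sum_test(1:10 / 10, 2 + 1:10 / 10)
  expect_lt(res$p_value, 0.001)
  # identical samples: p near 1
  expect_gt(rank_sum_test(c(1, 2, 3.5), c(1.1, 2.1, 3.4))$p_value, 0.5)
})

test_that("signed-rank test handles zeros, shifts and enumeration", {
  expect_equal(signed_rank_test(rep(0, 10))$p_value, 1)
  # all-positive differences, n = 20: decisive
  expect_lt(signed_rank_test(rep(0.5, 20) + (1:20) / 100)$p_value, 0.01)
  # exact enumeration oracle at n = 6
  d <- c(0.3, -0.1, 0.25, 0.4, -0.2, 0.15)
  got <- signed_rank_test(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  W_null <- as.matrix(signs) %*% r
  p_exact <- mean(abs(W_null - sum(r) / 2) >= abs(W_obs - sum(r) / 2))
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)
})

test_that("cohort descriptives expose the confound structure", {
  # study-scale group sizes: the motion comparison needs their power
  ds <- generate_cohort(synthetic_config(n_term = 46, n_preterm = 59,
                                         atlas = toy_atlas(), seed = 17))
  desc <- cohort_descriptives(ds$subjects)
  expect_gt(desc$rho_scan_birth$rho, 0)      # planted monotone relation
  expect_true(is.finite(desc$interaction_p))
  # preterm motion excess is visible
  expect_lt(desc$motion_abs_test$p_value, 0.05)
  # constant sex: correlation flagged, not computed
  meta <- ds$subjects
  meta$sex <- 1
  desc2 <- cohort_descriptives(meta)
  expect_true(is.na(desc2$rho_scan_sex$rho))
  expect_match(desc2$rho_scan_sex$note, "constant")
})
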