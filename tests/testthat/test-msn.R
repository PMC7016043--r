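test_that("z-scoring matches the direct formula and its invariances", {
  tab <- toy_table()
  # hand oracle on a 4-ROI toy column
  x <- c(1, 2, 3, 4)
  z_oracle <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  tab4 <- tab[1:4, ]
  tab4[, "FA"] <- x / 10
  z <- zscore_within_subject(tab4, c("FA", "MD", "AD"))
  expect_equal(unname(z[, "FA"]), z_oracle, tolerance = 1e-12)
  # idempotence: an already standardized column is returned unchanged
  z2 <- zscore_within_subject(z, colnames(z))
  expect_equal(z2, z, tolerance = 1e-12)
  # affine invariance: a*x + b (a > 0) gives identical z-scores
  tab_aff <- tab
  tab_aff[, "MD"] <- 3.7 * tab[, "MD"] + 0.002
  expect_equal(zscore_within_subject(tab_aff, c("FA", "MD", "MK")),
               zscore_within_subject(tab, c("FA", "MD", "MK")),
               tolerance = 1e-12)
  # zero-variance column is refused, naming the metric
  tab_const <- tab
  tab_const[, "MK"] <- 0.9
  expect_error(zscore_within_subject(tab_const, c("FA", "MD", "MK")), "MK")
})

test_that("build_msn equals the direct-formula Pearson oracle", {
  # 4 ROIs x 5 metrics integer-valued toy table
  atlas4 <- synthetic_atlas(1, 1, 0, cerebellum = FALSE, brainstem = FALSE)
  tab <- matrix(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4),
                4, 5) / 10
  dimnames(tab) <- list(atlas4$roi_name, c("FA", "MD", "AD", "RD", "MK"))
  tab[, "MD"] <- tab[, "MD"] * 1e-3
  tab[, "AD"] <- tab[, "AD"] * 1e-3
  tab[, "RD"] <- tab[, "RD"] * 1e-3
  subset <- c("FA", "MD", "AD", "RD", "MK")
  got <- build_msn(tab, subset)
  want <- msn_oracle(tab, subset)
  expect_equal(unname(unclass(got))[seq_len(4), ], want, tolerance = 1e-12,
               ignore_attr = TRUE)
  # random 81 x 12 table
  atlas <- default_atlas()
  set.seed(99)
  big <- matrix(runif(81 * 12, 0.1, 0.9), 81, 12,
                dimnames = list(atlas$roi_name, metric_names()))
  got <- build_msn(big, metric_names())
  want <- msn_oracle(big, metric_names())
  expect_lt(max(abs(unname(unclass(got)) - want)), 1e-12)
  expect_true(isSymmetric(unclass(got)))
  expect_equal(unname(diag(got)), rep(1, 81))
})

test_that("identical and negated ROI profiles give edges of +1 and -1", {
  atlas <- synthetic_atlas(2, 0, 0, cerebellum = FALSE, brainstem = FALSE)
  # symmetric design: per metric the 4 ROIs take (c+d, c+d, c-d, c-d), so
  # ROIs 1 and 2 share a profile and ROI 3's z-profile negates ROI 1's
  base <- c(FA = 0.3, MD = 1.2e-3, MK = 0.9, ODI_P = 0.4)
  dev <- c(FA = 0.05, MD = -2e-4, MK = 0.15, ODI_P = 0.02)
  tab <- rbind(base + dev, base + dev, base - dev, base - dev)
  dimnames(tab) <- list(atlas$roi_name, names(base))
  m <- build_msn(tab, colnames(tab))
  expect_equal(m[1, 2], 1, tolerance = 1e-12)   # identical profiles
  expect_equal(m[1, 3], -1, tolerance = 1e-12)  # exact negation
})

test_that("vectorize is the row-major upper triangle and inverts cleanly", {
  m3 <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3)
  expect_equal(as.vector(vectorize(m3)), c(.1, .2, .3))
  expect_equal(length(vectorize(diag(81))), 3240)
  # round-trip identity over a range of sizes
  for (n in c(3, 5, 17, 40, 81)) {
    set.seed(n)
    v <- rnorm(n * (n - 1) / 2)
    m <- devectorize(v, n)
    expect_true(isSymmetric(m))
    expect_equal(as.vector(vectorize(m)), v)
  }
  expect_error(devectorize(rnorm(7)), "does not match")
})

test_that("MSN invariants hold across generated subjects and subset sizes", {
  ds <- toy_dataset(n_term = 2, n_preterm = 2, seed = 5)
  subsets <- list(metric_names()[1:3], metric_names()[c(1, 3, 5, 7, 9)],
                  metric_names())
  for (sid in ds$subjects$subject_id) {
    for (subset in subsets) {
      m <- build_msn(ds$tables[[sid]], subset)
      expect_true(isSymmetric(unclass(m)))
      expect_equal(unname(diag(m)), rep(1, nrow(m)))
      off <- m[upper.tri(m)]
      expect_true(all(off >= -1 & off <= 1))
      # metric order within the subset is irrelevant
      expect_equal(unclass(build_msn(ds$tables[[sid]], rev(subset))),
                   unclass(m), ignore_attr = TRUE)
    }
    # per-metric positive affine rescaling leaves the MSN unchanged
    tab <- ds$tables[[sid]]
    tab[, "MK"] <- tab[, "MK"] * 2.5 + 0.1
    expect_equal(unclass(build_msn(tab, metric_names())),
                 unclass(build_msn(ds$tables[[sid]], metric_names())),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("mean_msn averages element-wise", {
  set.seed(3)
  ms <- lapply(1:3, function(i) devectorize(runif(10, -1, 1), 5))
  avg <- mean_msn(ms)
  # direct loop oracle
  want <- matrix(0, 5, 5)
  for (m in ms) want <- want + m / 3
  expect_equal(avg, want, tolerance = 1e-12)
  expect_equal(mean_msn(ms[1]), ms[[1]])
  expect_equal(max(abs((mean_msn(list(ms[[1]], 2 * diag(5) - ms[[1]]))
                        - diag(5)))), 0, tolerance = 1e-12)
})

test_that("edge-wise covariate correlation matches a per-edge oracle", {
  set.seed(8)
  n_sub <- 5; n_node <- 4
  edges <- matrix(rnorm(n_sub * n_node * (n_node - 1) / 2), n_sub)
  covariate <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  got <- edgewise_covariate_correlation(edges, covariate)
  v <- vectorize(got)
  for (k in seq_len(ncol(edges))) {
    expect_equal(v[[k]], pearson_oracle(edges[, k], covariate),
                 tolerance = 1e-12)
  }
  # an edge identical to the covariate correlates perfectly
  edges[, 2] <- covariate
  got <- edgewise_covariate_correlation(edges, covariate)
  expect_equal(vectorize(got)[[2]], 1, tolerance = 1e-12)
  expect_error(edgewise_covariate_correlation(edges, rep(1, 5)), "constant")
})

test_that("covariate-independent edges show small mean correlation", {
  set.seed(11)
  edges <- matrix(rnorm(200 * 28), 200)   # 28 edges = 8-node network
  covariate <- rnorm(200)
  got <- edgewise_covariate_correlation(edges, covariate)
  expect_lt(mean(abs(vectorize(got))), 0.2)
})
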