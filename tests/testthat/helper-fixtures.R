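# Shared fixtures: all built in code, sized for fast runs.

# Small atlas used by most simulation-based tests (15 ROIs, 7 homotopic pairs).
toy_atlas <- function() synthetic_atlas(3, 3, 1)

# Fast model configurations: reduced grids, same machinery.
fast_reg_cfg <- function(seed = 1, ...) {
  regression_config(alpha_grid = 0.5,
                    lambda_grid = 10^seq(-3, 1, length.out = 8),
                    repeats = 1, k = 5, seed = seed, ...)
}

fast_cls_cfg <- function(seed = 1, ...) {
  classification_config(cost_grid = 1, rfe_grid = c(8, 32), rfe_step = 0.5,
                        repeats = 1, k = 5, seed = seed, ...)
}

# A tiny deterministic regional metrics table (no randomness).
toy_table <- function(atlas = toy_atlas()) {
  n <- nrow(atlas)
  metrics <- metric_names()
  base <- c(2000, 1.2, 0.2, 1.1e-3, 1.4e-3, 1.0e-3, 0.9, 0.35, 0.08,
            0.35, 0.25, 0.40)
  mat <- outer(1 + 0.1 * sin(seq_len(n)), base)
  dimnames(mat) <- list(atlas$roi_name, metrics)
  mat
}

# A small valid dataset built from the synthetic generator.
toy_dataset <- function(n_term = 6, n_preterm = 6, seed = 1, ...) {
  generate_cohort(synthetic_config(n_term = n_term, n_preterm = n_preterm,
                                   atlas = toy_atlas(), seed = seed, ...))
}

# Direct-formula Pearson correlation, the independent oracle for build_msn.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

msn_oracle <- function(table, subset) {
  z <- apply(table[, subset, drop = FALSE], 2, function(col) {
    (col - mean(col)) / sqrt(mean((col - mean(col))^2))
  })
  n <- nrow(z)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- pearson_oracle(z[i, ], z[j, ])
    }
  }
  m
}
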