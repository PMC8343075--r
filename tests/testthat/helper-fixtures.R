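# Shared fixtures: small cohorts, simple geometric bundles, and independent
# oracles used across the test files.

# small null cohort (no implanted effect)
small_null_cohort <- function(seed, n_C = 10L, n_NC = 12L, n_nodes = 25L,
                              ell = 5, tract = "left_ilf", property = "FA") {
  generate_cohort(sim_config(n_C = n_C, n_NC = n_NC, tracts = tract,
                             properties = property, n_nodes = n_nodes,
                             correlation_length = ell, seed = seed))
}

# small cohort with one implanted effect
small_effect_cohort <- function(seed, nodes = 10:16, d = 2, n_C = 10L,
                                n_NC = 12L, n_nodes = 25L, ell = 5,
                                tract = "left_ilf", property = "FA") {
  generate_cohort(sim_config(
    n_C = n_C, n_NC = n_NC, tracts = tract, properties = property,
    n_nodes = n_nodes, correlation_length = ell,
    effects = list(effect_spec(tract, property, nodes, d)), seed = seed))
}

# straight centerline along x of given length
straight_centerline <- function(length = 99, n = 50) {
  cbind(seq(0, length, length.out = n), 0, 0)
}

# two-class Gaussian blobs with all features shifted by d
blob_data <- function(n_per_class = 20L, p = 2L, d = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class, p) + d / 2,
             matrix(rnorm(n_per_class * p), n_per_class, p) - d / 2)
  list(x = x, y = rep(c("C", "NC"), each = n_per_class))
}

# --- independent oracles -------------------------------------------------

# RBF kernel matrix computed directly from coordinates
rbf_kernel <- function(a, b = a, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# Single-step RFE oracle: fit an e1071 SVM, then compute the objective drop
# dJ(i) = 1/2 a'Ha - 1/2 a'H^(-i)a for every single-feature removal by
# rebuilding the kernel from the raw coordinates, and return the index of
# the feature with the smallest dJ (ties: larger index, matching the
# keep-the-lower-index convention).
rfe_single_step_oracle <- function(x, y, cost = 1) {
  gamma <- 1 / (ncol(x) * mean(apply(x, 2, var)))
  yf <- factor(y, levels = c("C", "NC"))
  m <- e1071::svm(x, yf, scale = FALSE, kernel = "radial", cost = cost,
                  gamma = gamma)
  svx <- as.matrix(m$SV)
  cf <- as.numeric(m$coefs) # alpha_i * y_i on support vectors
  J_full <- 0.5 * as.numeric(t(cf) %*% rbf_kernel(svx, gamma = gamma) %*% cf)
  dJ <- vapply(seq_len(ncol(x)), function(i) {
    Ki <- rbf_kernel(svx[, -i, drop = FALSE], gamma = gamma)
    J_full - 0.5 * as.numeric(t(cf) %*% Ki %*% cf)
  }, 1)
  mins <- which(dJ <= min(dJ) + 1e-9 * max(1, abs(min(dJ))))
  max(mins)
}

# exact binomial tail-sum chance threshold, by direct enumeration
chance_threshold_oracle <- function(n, alpha = 0.05) {
  probs <- choose(n, 0:n) / 2^n
  for (t in seq(0, 1, by = 0.01)) {
    tail_p <- sum(probs[(0:n) > t * n + 1e-9])
    if (tail_p <= alpha) return(round(t, 2))
  }
  1
}
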