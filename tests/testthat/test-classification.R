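# Normalization contracts, SVM solver equivalence with an established
# implementation, RFE-CBR behavior, and the LOOCV loop's no-leakage
# guarantee.

test_that("normalization standardizes training data and only training data", {
  set.seed(1)
  x <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("n", 1:8)))
  params <- normalize_fit(x)
  z <- normalize_apply(params, x)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # a test row is transformed with the training parameters, not its own
  xt <- matrix(rnorm(8), 1, 8, dimnames = list(NULL, paste0("n", 1:8)))
  zt <- normalize_apply(params, xt)
  expect_equal(as.numeric(zt),
               unname((as.numeric(xt) - params$mean) / params$sd))
})

test_that("normalization uses the n-1 SD convention and round-trips", {
  x <- matrix(c(0, 2, 0, 2), 2, 2)
  params <- normalize_fit(x)
  expect_equal(unname(params$mean), c(1, 1))
  expect_equal(unname(params$sd), c(sqrt(2), sqrt(2)))
  set.seed(2)
  x2 <- matrix(rnorm(30), 10, 3)
  p2 <- normalize_fit(x2)
  z <- normalize_apply(p2, x2)
  back <- sweep(sweep(z, 2, p2$sd, "*"), 2, p2$mean, "+")
  expect_lt(max(abs(back - x2)), 1e-9)
  # not idempotent unless already standardized
  expect_false(isTRUE(all.equal(normalize_apply(p2, z), z)))
})

test_that("constant features are rejected by name", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("node_1", "node_2")))
  x[, 2] <- 7
  expect_error(normalize_fit(x), "node_2")
})

test_that("well-separated blobs are fit perfectly; one-class input errors", {
  bl <- blob_data(20, 2, d = 6, seed = 3)
  m <- train_svm(bl$x, bl$y)
  expect_equal(mean(predict(m, bl$x) == bl$y), 1.0)
  expect_error(train_svm(bl$x, rep("C", 40)), "single class")
})

test_that("duplicating a training row leaves a separable boundary unchanged", {
  bl <- blob_data(15, 2, d = 6, seed = 4)
  m1 <- train_svm(bl$x, bl$y, tol = 1e-8)
  m2 <- train_svm(rbind(bl$x, bl$x[1, ]), c(bl$y, bl$y[1]), tol = 1e-8)
  # duplicated points make the working-set pair degenerate, so agreement
  # is to solver precision, not machine precision
  grid <- as.matrix(expand.grid(seq(-4, 4, 1), seq(-4, 4, 1)))
  expect_lt(max(abs(predict(m1, grid, type = "decision") -
                    predict(m2, grid, type = "decision"))), 0.01)
  expect_identical(predict(m1, grid), predict(m2, grid))
})

test_that("compiled SMO solver agrees with e1071 decision values", {
  skip_if_not_installed("e1071")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40; p <- 8
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c("C", "NC"), length.out = n)
    x[y == "C", 1] <- x[y == "C", 1] + 1
    gamma <- 1 / (p * mean(apply(x, 2, var)))
    mine <- train_svm(x, y, gamma = gamma)
    ref <- e1071::svm(x, factor(y, levels = c("C", "NC")), scale = FALSE,
                      kernel = "radial", cost = 1, gamma = gamma)
    pr <- predict(ref, x, decision.values = TRUE)
    d_ref <- attr(pr, "decision.values")
    if (colnames(d_ref)[1] == "NC/C") d_ref <- -d_ref # orient positive = C
    d_mine <- predict(mine, x, type = "decision")
    expect_lt(max(abs(as.numeric(d_ref) - d_mine)), 1e-2)
    expect_equal(as.character(pr), predict(mine, x))
  }
})

test_that("RFE returns all features when nothing must be eliminated", {
  bl <- blob_data(10, 4, d = 2, seed = 5)
  r <- rfe_cbr(bl$x, bl$y, target_k = 4)
  expect_equal(r$selected, 1:4)
  expect_length(r$elim_order, 0)
  r2 <- rfe_cbr(bl$x, bl$y, target_k = 10) # capped at n_features
  expect_equal(r2$selected, 1:4)
})

test_that("RFE output is a duplicate-free subset of the right size", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(30 * 12), 30, 12)
    y <- rep(c("C", "NC"), 15)
    r <- rfe_cbr(x, y, target_k = 5)
    expect_length(r$selected, 5)
    expect_false(anyDuplicated(r$selected) > 0)
    expect_true(all(r$selected %in% 1:12))
    expect_setequal(c(r$elim_order, r$selected), 1:12)
    # deterministic rerun
    expect_identical(r, rfe_cbr(x, y, target_k = 5))
  }
})

test_that("RFE keeps implanted signal features among 10-of-12", {
  hits <- vapply(1:100, function(seed) {
    set.seed(seed + 4000)
    n <- 60
    x <- matrix(rnorm(n * 12), n, 12)
    y <- rep(c("C", "NC"), c(30, 30))
    x[y == "C", 1:2] <- x[y == "C", 1:2] + 2 # d = 2 on features 1 and 2
    r <- rfe_cbr(x, y, target_k = 10)
    all(c(1, 2) %in% r$selected)
  }, TRUE)
  expect_gte(sum(hits), 95)
})

test_that("correlated features are grouped and share one score", {
  set.seed(6)
  n <- 50
  base <- rnorm(n)
  x <- cbind(base + rnorm(n, 0, 0.05), base + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 4), n, 4))
  groups <- tractclass:::correlation_groups(x, 0.9)
  expect_true(any(vapply(groups, function(g) setequal(g, 1:2), TRUE)))
})

test_that("LOOCV produces one record per subject, each left out once", {
  co <- small_effect_cohort(seed = 41)
  r <- loocv_classify(co, "left_ilf", "FA")
  expect_equal(nrow(r$fold_records), nrow(co$subjects))
  expect_identical(r$fold_records$subject_id, co$subjects$subject_id)
  expect_true(all(lengths(r$fold_records$selected) == 10))
  expect_true(r$accuracy >= 0 && r$accuracy <= 1)
  # deterministic rerun
  expect_identical(r$fold_records, loocv_classify(co, "left_ilf", "FA")$fold_records)
})

test_that("the held-out subject cannot influence its own fold's training", {
  co <- small_null_cohort(seed = 42, n_C = 8, n_NC = 8, n_nodes = 20)
  r1 <- loocv_classify(co, "left_ilf", "FA", target_k = 6)
  spy <- 5L
  co2 <- co
  co2$profiles$left_ilf$FA[spy, ] <- co2$profiles$left_ilf$FA[spy, ] + 50
  r2 <- loocv_classify(co2, "left_ilf", "FA", target_k = 6)
  # fold leaving the perturbed subject out: training artifacts unchanged
  expect_identical(r1$fold_records$selected[[spy]],
                   r2$fold_records$selected[[spy]])
  # but folds that train on the perturbed subject do change
  expect_false(identical(r1$fold_records$score[-spy],
                         r2$fold_records$score[-spy]))
})

test_that("a strong localized effect is detected and localized", {
  co <- small_effect_cohort(seed = 43, nodes = 10:16, d = 2.5,
                            n_C = 17, n_NC = 26, n_nodes = 50)
  r <- loocv_classify(co, "left_ilf", "FA")
  expect_gt(r$accuracy, 0.59)
  expect_gt(r$auc, 0.6)
  sel <- table(unlist(r$fold_records$selected))
  top <- as.integer(names(sort(sel, decreasing = TRUE)))[1:10]
  expect_gte(length(intersect(top, 8:18)), 6)
})

test_that("the ALL feature set concatenates the four properties", {
  co <- generate_cohort(sim_config(n_C = 4, n_NC = 4, tracts = "left_ilf",
                                   n_nodes = 20, seed = 44))
  fm <- feature_matrix(co, "left_ilf", "ALL")
  expect_equal(ncol(fm$x), 80)
  expect_equal(unique(fm$features$property), diffusion_properties())
  expect_error(feature_matrix(co, "left_ilf", "QQ"), "not present")
  expect_error(feature_matrix(co, "right_ilf", "FA"), "not present")
})
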