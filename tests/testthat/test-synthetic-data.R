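# Synthetic cohort generator: determinism, configuration validation,
# null calibration, and implanted-effect recovery.

test_that("same seed gives identical cohorts, different seeds differ", {
  cfg <- sim_config(n_C = 5, n_NC = 5, tracts = "left_ilf",
                    properties = c("FA", "MD"), n_nodes = 30, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$profiles, b$profiles)
  cfg2 <- sim_config(n_C = 5, n_NC = 5, tracts = "left_ilf",
                     properties = c("FA", "MD"), n_nodes = 30, seed = 12)
  c <- generate_cohort(cfg2)
  expect_false(identical(a$profiles$left_ilf$FA, c$profiles$left_ilf$FA))
})

test_that("generator leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  generate_cohort(sim_config(n_C = 2, n_NC = 2, tracts = "left_ilf",
                             properties = "FA", n_nodes = 10, seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_C = 1), "n_C")
  expect_error(sim_config(tracts = "corpus_of_unknown"), "unknown tract")
  expect_error(sim_config(properties = c("FA", "QQ")), "unknown property")
  expect_error(sim_config(correlation_length = -1), "correlation_length")
  expect_error(effect_spec("left_ilf", "XX", 1:5, 1), "unknown property")
  expect_error(effect_spec("left_ilf", "FA", 0:5, 1), "node")
  # effect node range beyond the configured profile length
  expect_error(sim_config(
    tracts = "left_ilf", properties = "FA", n_nodes = 50,
    effects = list(effect_spec("left_ilf", "FA", 45:60, 1))), "n_nodes")
  # effect must reference a simulated tract/property
  expect_error(sim_config(
    tracts = "left_ilf", properties = "FA",
    effects = list(effect_spec("right_ilf", "FA", 1:5, 1))), "not in")
})

test_that("with no effect, node-wise t-tests reject at the nominal rate", {
  n_rep <- 200
  rates <- vapply(seq_len(n_rep), function(r) {
    co <- small_null_cohort(seed = 1000 + r, n_nodes = 20, ell = 4)
    fm <- feature_matrix(co, "left_ilf", "FA")
    p <- vapply(seq_len(ncol(fm$x)), function(j)
      t.test(fm$x[fm$y == "C", j], fm$x[fm$y == "NC", j])$p.value, 1)
    mean(p < 0.05)
  }, 1)
  expect_gt(mean(rates), 0.025)
  expect_lt(mean(rates), 0.075)
})

test_that("labels are exchangeable under the null (KS across groups)", {
  # KS on one node's values: across-subject draws are iid, so the test's
  # nominal level applies (pooling nodes would violate independence)
  n_rep <- 100
  ks_ns <- vapply(seq_len(n_rep), function(r) {
    co <- small_null_cohort(seed = 3000 + r, n_nodes = 15, ell = 3,
                            n_C = 20, n_NC = 20)
    fm <- feature_matrix(co, "left_ilf", "FA")
    stats::ks.test(fm$x[fm$y == "C", 8], fm$x[fm$y == "NC", 8])$p.value >= 0.05
  }, TRUE)
  expect_gte(sum(ks_ns), 90)
})

test_that("implanted effect size is recovered at large n", {
  cfg <- sim_config(n_C = 2000, n_NC = 2000, tracts = "left_ilf",
                    properties = "MD", n_nodes = 100,
                    effects = list(effect_spec("left_ilf", "MD", 40:50, 2.0)),
                    seed = 21)
  co <- generate_cohort(cfg)
  fm <- feature_matrix(co, "left_ilf", "MD")
  xC <- fm$x[fm$y == "C", 40:50]; xNC <- fm$x[fm$y == "NC", 40:50]
  sp <- sqrt((var(as.vector(xC)) + var(as.vector(xNC))) / 2)
  d_hat <- (mean(xC) - mean(xNC)) / sp
  expect_lt(abs(d_hat - 2.0), 0.35)
  # effect is confined to the configured node range
  off <- setdiff(seq_len(100), 38:52)
  d_off <- (mean(fm$x[fm$y == "C", off]) - mean(fm$x[fm$y == "NC", off]))
  expect_lt(abs(d_off), 0.01)
})

test_that("node noise carries the configured autocorrelation structure", {
  co <- generate_cohort(sim_config(n_C = 150, n_NC = 150, tracts = "left_ilf",
                                   properties = "FA", n_nodes = 60,
                                   correlation_length = 8, seed = 31))
  x <- feature_matrix(co, "left_ilf", "FA")$x
  r_adjacent <- mean(diag(cor(x)[-1, -60]))
  expect_gt(r_adjacent, exp(-1 / (2 * 64)) - 0.05) # theory: exp(-1/(2*8^2))
  r_distant <- cor(x[, 1], x[, 60])
  expect_lt(abs(r_distant), 0.2)
})

test_that("synthetic demographics mirror the configured group contrasts", {
  co <- generate_cohort(sim_config(n_C = 200, n_NC = 300, tracts = "left_ilf",
                                   properties = "FA", n_nodes = 10, seed = 5))
  co <- generate_demographics(co, seed = 6)
  tab <- demographics_table(co)
  expect_setequal(tab$variable, c("age", "mmse", "sex (F/M)"))
  mmse <- tab[tab$variable == "mmse", ]
  expect_lt(mmse$p, 0.01) # configured MMSE deficit in converters
})
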