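# Mixture validation and identifiability machinery.

test_that("r_squared follows its definition about the line of unity", {
  expect_equal(r_squared(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  expect_equal(r_squared(c(0, 0.5, 1), c(0.1, 0.5, 0.9)), 0.96)
  meas <- c(0.2, 0.4, 0.9)
  expect_equal(r_squared(meas, rep(mean(meas), 3)), 0)
  expect_error(r_squared(c(0.5, 0.5), c(0.4, 0.6)), "zero variance")
  expect_error(r_squared(1, 1), "n >= 2")
})

test_that("regression convention returns squared correlation", {
  meas <- c(0, 0.25, 0.5, 0.75, 1)
  est <- 0.1 + 0.8 * meas
  expect_equal(r_squared(meas, est, convention = "regression"), 1)
  expect_lt(r_squared(meas, est), 1)
})

test_that("mixture fractions are recovered from low-noise reference mixtures", {
  truth <- c(0, 0.25, 0.5, 0.75, 1)
  des <- ref_mixture_design()
  sim <- simulate_assay(des, noise_model(0.02, seed = 14))
  res <- suppressWarnings(
    fit_mixture_fractions(sim, v_max = 0.9,
                          measured = stats::setNames(truth,
                                                     names(des$groups))))
  expect_equal(res$table$estimated_f_res, truth, tolerance = 0.05)
  # estimates are monotone in the true mixture fraction
  expect_true(all(diff(res$table$estimated_f_res) > -1e-8))
  expect_gt(res$r_squared, 0.98)
  # pure-sensitive mixture estimated at (or very near) zero resistant
  expect_lt(res$table$estimated_f_res[1], 0.05)
})

test_that("mixture validation R-squared approaches 1 as noise vanishes", {
  truth <- c(0, 0.25, 0.5, 0.75, 1)
  des <- ref_mixture_design()
  r2 <- vapply(c(0.08, 0.01), function(s) {
    sim <- simulate_assay(des, noise_model(s, seed = 25))
    res <- suppressWarnings(
      fit_mixture_fractions(sim, v_max = 0.9,
                            measured = stats::setNames(truth,
                                                       names(des$groups))))
    res$r_squared
  }, numeric(1))
  expect_gt(r2[2], r2[1] - 0.02)
  expect_gt(r2[2], 0.99)
})

test_that("identifiability study collapses to truth without noise", {
  rep_ <- run_identifiability_study(ref_two_pop(),
                                    fractions_res = c(0.25, 0.75),
                                    noise_sd = 0, n_sim = 3, n_starts = 4,
                                    replicates = 2, seed = 3)
  expect_equal(rep_$n_failed, 0)
  expect_true(all(abs(rep_$summary$mean - rep_$summary$truth) < 1e-3))
  expect_true(all(rep_$summary$truth_covered))
})

test_that("identifiability bands cover truth under realistic noise", {
  rep_ <- run_identifiability_study(ref_two_pop(), noise_sd = 0.05,
                                    n_sim = 12, n_starts = 4, seed = 9)
  expect_equal(nrow(rep_$summary), 4 + 5)
  expect_true(all(rep_$summary$truth_covered))
  # reported fractions are resistant fractions in [0, 1]
  f <- rep_$draws[, grep("^f_res", colnames(rep_$draws))]
  expect_true(all(f >= 0 & f <= 1))
})

test_that("pairwise fraction tests resolve well-separated mixtures", {
  set.seed(42)
  m <- cbind(a = rnorm(100, 0.25, 0.05), b = rnorm(100, 0.75, 0.05))
  p <- pairwise_fraction_tests(m)
  expect_lt(p["a", "b"], 1e-6)
  expect_equal(p["a", "b"], p["b", "a"])
  expect_equal(diag(p), c(a = 1, b = 1))
  # identical distributions: exact-equality shortcut gives p = 1
  mm <- cbind(x = rep(0.5, 10), y = rep(0.5, 10))
  expect_equal(pairwise_fraction_tests(mm)["x", "y"], 1)
  # degenerate but different means gives p = 0
  mz <- cbind(x = rep(0.2, 10), y = rep(0.8, 10))
  expect_equal(pairwise_fraction_tests(mz)["x", "y"], 0)
})

test_that("mixture separability degrades as the two LD50s approach", {
  # the same study run with closely spaced states should lose significance
  near <- two_pop_params(45, 0.05, 50, 0.045, f_sens = 1, v_max = 0.9)
  far <- ref_two_pop()
  p_near <- pairwise_fraction_tests(run_identifiability_study(
    near, fractions_res = c(0.4, 0.6), noise_sd = 0.05, n_sim = 10,
    n_starts = 4, seed = 5))
  p_far <- pairwise_fraction_tests(run_identifiability_study(
    far, fractions_res = c(0.4, 0.6), noise_sd = 0.05, n_sim = 10,
    n_starts = 4, seed = 5))
  expect_gt(p_near[1, 2], p_far[1, 2])
})

test_that("bonferroni correction never lowers a p-value", {
  set.seed(7)
  m <- cbind(rnorm(30, 0.4, 0.1), rnorm(30, 0.45, 0.1), rnorm(30, 0.5, 0.1))
  p_raw <- pairwise_fraction_tests(m)
  p_adj <- pairwise_fraction_tests(m, correction = "bonferroni")
  expect_true(all(p_adj >= p_raw - 1e-15))
})
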