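# Nonlinear least-squares calibration of the three models.

test_that("v_max is the mean of dose-0 records and is required", {
  d <- dose_response_data(group = rep("g", 4), dose_uM = c(0, 0, 0, 10),
                          replicate = c(1, 2, 3, 1),
                          viability = c(0.9, 0.9, 0.9, 0.5))
  expect_equal(estimate_vmax(d), 0.9)
  d2 <- dose_response_data(group = rep("g", 3), dose_uM = c(0, 0, 10),
                           replicate = c(1, 2, 1),
                           viability = c(0.8, 1.0, 0.5))
  expect_equal(estimate_vmax(d2), 0.9)
  d3 <- dose_response_data(group = "g", dose_uM = 10, replicate = 1,
                           viability = 0.5)
  expect_error(estimate_vmax(d3), "v_max")
})

test_that("single static fit recovers generative truth from noiseless data", {
  sim <- simulate_assay(one_group_design(), noise_model(sd = 0, seed = 1))
  fit <- fit_single_static(sim, v_max = 0.9)
  expect_true(fit$converged)
  expect_equal(fit$k, 2)
  expect_equal(fit$parameters$c, 37.0, tolerance = 1e-6)
  expect_equal(fit$parameters$m, 0.055, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("flat data (no dose effect) is reported as non-converged", {
  d <- dose_response_data(group = rep("g", 12),
                          dose_uM = rep(c(0, 10, 20, 40), 3),
                          replicate = rep(1:3, each = 4),
                          viability = rep(0.8, 12))
  fit <- fit_single_static(d, v_max = 0.8)
  expect_false(fit$converged)
})

test_that("dynamic fit recovers per-group truth and counts 2 parameters per group", {
  cs <- c(30, 50, 70); ms <- c(0.06, 0.04, 0.03)
  groups <- stats::setNames(lapply(1:3, function(i)
    single_params(cs[i], ms[i], 0.9)), paste0("week", 1:3))
  sim <- simulate_assay(assay_design(groups), noise_model(0, seed = 1))
  fit <- fit_single_dynamic(sim, v_max = 0.9)
  expect_true(fit$converged)
  expect_equal(fit$k, 6)
  expect_equal(unname(fit$parameters$c[paste0("week", 1:3)]), cs,
               tolerance = 1e-6)
  expect_equal(unname(fit$parameters$m[paste0("week", 1:3)]), ms,
               tolerance = 1e-6)
})

test_that("dynamic fit on a single group equals the static fit", {
  sim <- simulate_assay(one_group_design(), noise_model(0.04, seed = 5))
  fs <- fit_single_static(sim, v_max = 0.9)
  fd <- fit_single_dynamic(sim, v_max = 0.9)
  expect_equal(fd$rss, fs$rss, tolerance = 1e-8)
  expect_equal(unname(fd$parameters$c[[1]]), fs$parameters$c,
               tolerance = 1e-5)
})

test_that("joint two-population fit recovers all parameters from noiseless data", {
  f_true <- seq(0.9, 0.3, length.out = 6)
  des <- make_time_course_design(f_true, ref_two_pop())
  sim <- simulate_assay(des, noise_model(0, seed = 1))
  fit <- fit_two_population(sim, v_max = 0.9)
  expect_true(fit$converged)
  expect_equal(fit$k, 4 + 6)
  p <- fit$parameters
  expect_equal(p$c_sens, 22.4, tolerance = 1e-4)
  expect_equal(p$c_res, 79.7, tolerance = 1e-4)
  expect_equal(p$m_sens, 0.06, tolerance = 1e-4)
  expect_equal(p$m_res, 0.028, tolerance = 1e-4)
  expect_equal(unname(p$f_sens), f_true, tolerance = 1e-4)
  # canonical ordering holds by construction
  expect_lt(p$c_sens, p$c_res)
})

test_that("pure-sensitive groups collapse the mixture onto one sigmoid", {
  # every group generated with f_sens = 1: the resistant component carries
  # no signal, so (f, resistant state) are jointly unidentifiable -- what is
  # identified is the curve itself, which must match the sensitive sigmoid
  des <- make_time_course_design(rep(1, 3), ref_two_pop())
  sim <- simulate_assay(des, noise_model(0.01, seed = 8))
  fit <- suppressWarnings(fit_two_population(sim, v_max = 0.9))
  expect_true(all(fit$parameters$f_sens >= 0 & fit$parameters$f_sens <= 1))
  truth_curve <- predict_viability(single_params(22.4, 0.06, 0.9),
                                   dox_dose_panel)
  for (g in names(fit$parameters$f_sens)) {
    v <- predict_viability(fit$parameters, dox_dose_panel, group = g)
    expect_lt(max(abs(v - truth_curve)), 0.02)
  }
})

test_that("static model is nested in dynamic: pooled rss never increases", {
  for (s in 1:5) {
    des <- ref_time_course()
    sim <- simulate_assay(des, noise_model(0.05, seed = 400 + s))
    fs <- fit_single_static(sim, v_max = 0.9)
    fd <- fit_single_dynamic(sim, v_max = 0.9)
    expect_lte(fd$rss, fs$rss + 1e-10)
  }
})

test_that("fits are invariant to record shuffling and group order", {
  sim <- simulate_assay(ref_time_course(), noise_model(0.05, seed = 21))
  shuf <- sim[with_seed_order(nrow(sim)), ]
  f1 <- fit_two_population(sim, v_max = 0.9, n_starts = 4)
  f2 <- fit_two_population(shuf, v_max = 0.9, n_starts = 4)
  # identical optimum up to optimizer tolerance (summation order differs)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-8)
})

test_that("two-population fit warns when the two states coincide", {
  # refitting one-sigmoid data from a start with coincident states keeps
  # the separation near zero and must raise the unidentifiability warning
  groups <- stats::setNames(rep(list(single_params(50, 0.05, 0.9)), 3),
                            paste0("g", 1:3))
  sim <- simulate_assay(assay_design(groups), noise_model(0, seed = 2))
  expect_warning(
    fit_two_population(sim, v_max = 0.9,
                       start = c(50, 0.01, 0.05, 0.05, 0.5, 0.5, 0.5)),
    "unidentifiable")
})

test_that("preconditions on dose support are enforced", {
  d <- dose_response_data(group = rep("g", 4), dose_uM = c(0, 0, 50, 50),
                          replicate = c(1, 2, 1, 2),
                          viability = c(0.9, 0.9, 0.4, 0.4))
  expect_error(fit_single_static(d), ">= 3 distinct doses")
  expect_error(fit_two_population(d), ">= 5 distinct doses")
})

test_that("coef flattens every model's parameters with stable names", {
  sim <- simulate_assay(ref_time_course(), noise_model(0.05, seed = 31))
  fs <- fit_single_static(sim, v_max = 0.9)
  expect_named(coef(fs), c("c_ss", "m_ss"))
  ft <- fit_two_population(sim, v_max = 0.9, n_starts = 4)
  expect_named(coef(ft), c("c_sens", "m_sens", "c_res", "m_res",
                           paste0("f_sens.week", 1:8)))
  expect_equal(length(coef(ft)), ft$k)
})
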