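# Synthetic assay generation: determinism, truncation, noise recovery.

test_that("noiseless simulation reproduces the model exactly", {
  des <- ref_time_course()
  sim <- simulate_assay(des, noise_model(sd = 0, seed = 1))
  expect_equal(nrow(sim), 8 * 12 * 4)
  for (g in names(des$groups)) {
    sub <- sim[sim$group == g, ]
    mu <- drmix:::group_viability(des$groups[[g]], sub$dose_uM)
    expect_equal(sub$viability, mu, tolerance = 1e-15)
  }
})

test_that("same seed gives identical datasets, different seed differs", {
  des <- ref_mixture_design()
  a <- simulate_assay(des, noise_model(sd = 0.05, seed = 99))
  b <- simulate_assay(des, noise_model(sd = 0.05, seed = 99))
  c <- simulate_assay(des, noise_model(sd = 0.05, seed = 100))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(simulate_assay(ref_time_course(), noise_model(0.05, seed = 7)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("viability is always truncated to [0, 1] even under huge noise", {
  des <- one_group_design()
  sim <- simulate_assay(des, noise_model(sd = 5, seed = 2))
  expect_true(all(sim$viability >= 0 & sim$viability <= 1))
})

test_that("noisy records are unbiased at interior viabilities", {
  # law of large numbers: mean of many replicates approaches the model value
  des <- one_group_design(single_params(60, 0.05, 0.9), replicates = 10000,
                          dose_panel = c(0, 60))
  sim <- simulate_assay(des, noise_model(sd = 0.05, seed = 4))
  mu <- 0.9 / (1 + exp(0.05 * (60 - 60)))
  obs <- mean(sim$viability[sim$dose_uM == 60])
  expect_lt(abs(obs - mu), 3 * 0.05 / sqrt(10000))
})

test_that("noise estimation recovers the per-dose sd profile", {
  # identical replicates -> zero sd everywhere
  flat <- dose_response_data(group = rep("g", 6), dose_uM = rep(c(0, 10, 20), 2),
                             replicate = rep(1:2, each = 3),
                             viability = rep(c(0.9, 0.8, 0.7), 2))
  nm0 <- estimate_noise_from_data(flat)
  expect_equal(noise_sd_at(nm0, c(0, 10, 20)), c(0, 0, 0))

  # closed-form sample sd of two replicates 0.4, 0.6
  two <- dose_response_data(group = c("g", "g", "g", "g"),
                            dose_uM = c(0, 0, 5, 5), replicate = c(1, 2, 1, 2),
                            viability = c(0.4, 0.6, 0.4, 0.6))
  nm2 <- estimate_noise_from_data(two)
  expect_equal(noise_sd_at(nm2, 5), sd(c(0.4, 0.6)), tolerance = 1e-12)
  expect_equal(noise_sd_at(nm2, 5), 0.1414, tolerance = 1e-3)

  # simulation oracle: a dose-dependent profile is recovered within
  # sampling error given many replicates
  prof_d <- c(0, 24, 72, 144)
  prof_sd <- c(0.02, 0.05, 0.08, 0.03)
  des <- one_group_design(single_params(60, 0.04, 0.95), replicates = 400,
                          dose_panel = prof_d)
  sim <- simulate_assay(des, noise_model(sd = prof_sd, doses = prof_d,
                                         seed = 11))
  est <- estimate_noise_from_data(sim)
  expect_equal(noise_sd_at(est, prof_d), prof_sd, tolerance = 0.15)
})

test_that("singleton-replicate doses are flagged and interpolated", {
  d <- dose_response_data(group = rep("g", 5),
                          dose_uM = c(0, 0, 10, 20, 20),
                          replicate = c(1, 2, 1, 1, 2),
                          viability = c(0.8, 0.9, 0.7, 0.5, 0.6))
  expect_warning(nm <- estimate_noise_from_data(d), "interpolated")
  expect_equal(attr(nm, "interpolated"), 10)
  s <- noise_sd_at(nm, 10)
  expect_gte(s, min(noise_sd_at(nm, c(0, 20))))
  expect_lte(s, max(noise_sd_at(nm, c(0, 20))))
})

test_that("mixture design maps ratios to resistant fractions", {
  des <- ref_mixture_design()
  expect_length(des$groups, 5)
  # resistant fraction f_res means generating f_sens = 1 - f_res
  f_sens <- vapply(des$groups, function(g) unname(g$f_sens), numeric(1))
  expect_equal(unname(f_sens), c(1, 0.75, 0.5, 0.25, 0))
  # the pure-sensitive group equals the pure sensitive sigmoid
  v <- drmix:::group_viability(des$groups[[1]], c(10, 48, 100))
  expect_equal(v, predict_viability(single_params(22.4, 0.06, 0.9),
                                    c(10, 48, 100)), tolerance = 1e-15)
  # the 50:50 group is the equal-weight mixture by definition
  v50 <- drmix:::group_viability(des$groups[[3]], 48)
  manual <- 0.9 * (0.5 / (1 + exp(0.06 * (48 - 22.4))) +
                   0.5 / (1 + exp(0.028 * (48 - 79.7))))
  expect_equal(v50, manual, tolerance = 1e-15)
  expect_error(make_mixture_design(numeric(0), ref_two_pop()), "at least one")
})

test_that("time-course design produces one group per week with given f_sens", {
  des <- make_time_course_design(rep(0.7, 8), ref_two_pop())
  expect_length(des$groups, 8)
  # constant trajectory: all groups share one generative curve
  vs <- vapply(des$groups, function(g)
    drmix:::group_viability(g, 48), numeric(1))
  expect_equal(unname(vs), rep(vs[[1]], 8))
  sim <- simulate_assay(des, noise_model(0, seed = 1))
  expect_equal(nrow(sim), 384)
})

test_that("design construction validates the dose panel", {
  expect_error(assay_design(list(g = ref_single()), dose_panel = c(4, 14)),
               "include dose 0")
  expect_error(assay_design(list(g = ref_single()),
                            dose_panel = c(0, 10, 10)), "strictly increasing")
  expect_error(assay_design(list(g = ref_single()), replicates = 0), ">= 1")
})
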