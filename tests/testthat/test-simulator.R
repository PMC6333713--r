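test_that("starting points follow the rescaled symmetric Beta", {
  set.seed(1)
  # alpha = 1 is uniform on (-b, b)
  x <- sample_start_point(1e5, 1, 54.6)
  ks <- suppressWarnings(ks.test(x, "punif", -54.6, 54.6))
  expect_lt(unname(ks$statistic), 0.01)
  # variance b^2 / (2 alpha + 1) at the V-T MDMC values
  y <- sample_start_point(1e6, 3.1, 54.6)
  expect_equal(var(y), 54.6^2 / 7.2, tolerance = 0.02)
  expect_lt(abs(mean(y)), 0.2)
  # large alpha concentrates the start at 0
  z <- sample_start_point(1e5, 1e6, 54.6)
  expect_lt(sd(z), 0.01 * 54.6)
  expect_error(sample_start_point(10, 0, 54.6), "start_shape")
  expect_error(sample_start_point(10, 1, -2), "boundary")
})

test_that("noiseless drift crosses the boundary at b / mu_c", {
  p <- mdmc_params(mu_c = 0.52, boundary = 54.6, start_shape = 3.1,
                   mu_r = 313, sigma_r = 33.4, sigma = 0,
                   automatic = list(visual = automatic_spec(0, 39),
                                    tactile = automatic_spec(0, 28.5)))
  d <- simulate_decision(p, vt_conditions[["NVNT"]], 10, fixed_start = 0)
  expect_true(all(d$decision_time == 105))
  expect_true(all(d$correct == 1L))
  expect_true(all(!d$censored))
})

test_that("FN-MDMC applies the faster-neutral residual mean on visual-neutral trials", {
  base <- mdmc_preset("vt_fnmdmc")
  p <- mdmc_params(mu_c = base$mu_c, boundary = base$boundary,
                   start_shape = base$start_shape, mu_r = 317, mu_rn = 303,
                   sigma_r = 1e-9, automatic = base$automatic)
  set.seed(2)
  nv <- simulate_trial(p, vt_conditions[["NVCT"]], 200, "FN-MDMC")
  set.seed(2)
  cv <- simulate_trial(p, vt_conditions[["CVCT"]], 200, "FN-MDMC")
  dec_nv <- nv$rt - 303
  dec_cv <- cv$rt - 317
  expect_true(all(abs(dec_nv - round(dec_nv)) < 1e-5))
  expect_true(all(abs(dec_cv - round(dec_cv)) < 1e-5))
  # MDMC variant always uses mu_r
  set.seed(3)
  mv <- simulate_trial(p, vt_conditions[["NVCT"]], 200, "MDMC")
  expect_true(all(abs((mv$rt - 317) - round(mv$rt - 317)) < 1e-5))
  p_no_rn <- mdmc_preset("vt_mdmc")
  expect_error(simulate_trial(p_no_rn, vt_conditions[["NVCT"]], 5, "FN-MDMC"),
               "mu_rn")
})

test_that("simulate_experiment is reproducible and balanced", {
  p <- mdmc_preset("vt_mdmc")
  a <- simulate_experiment(p, vt_conditions, 50, seed = 9)
  b <- simulate_experiment(p, vt_conditions, 50, seed = 9)
  expect_identical(a, b)
  expect_identical(nrow(a), 450L)
  expect_true(all(table(a$visual, a$tactile) == 50))
  # per-condition sub-streams: first condition unchanged if counts change
  c2 <- simulate_experiment(p, vt_conditions[1], 50, seed = 9)
  expect_identical(a[a$visual == "congruent" & a$tactile == "congruent", ],
                   c2)
  expect_error(simulate_experiment(p, list(), 10), "empty")
  expect_error(simulate_experiment(p, vt_conditions, 0), "n_per_condition")
})

test_that("zero-drift symmetric diffusion is a fair coin", {
  p <- mdmc_params(mu_c = 0, boundary = 30, start_shape = 3,
                   mu_r = 300, sigma_r = 30,
                   automatic = list(visual = automatic_spec(0, 39),
                                    tactile = automatic_spec(0, 28.5)))
  set.seed(4)
  d <- simulate_decision(p, vt_conditions[["NVNT"]], 2e4, fixed_start = 0)
  se <- sqrt(0.25 / 2e4)
  expect_lt(abs(mean(d$correct) - 0.5), 3 * se)
})

test_that("congruent conditions are faster than incongruent at the published parameters", {
  p <- mdmc_preset("vt_mdmc")
  d <- simulate_experiment(p, vt_conditions[c("CVCT", "IVIT")], 20000,
                           seed = 5)
  m <- tapply(d$rt[!d$censored], d$visual[!d$censored], mean)
  expect_lt(m[["congruent"]], m[["incongruent"]])
  expect_lt(mean(d$censored), 1e-4)
})

test_that("halving the Euler step barely moves marginal accuracy and mean RT", {
  p1 <- mdmc_preset("vt_mdmc")
  p2 <- p1
  p2$dt <- 0.5
  d1 <- simulate_experiment(p1, vt_conditions, 3e4, seed = 6)
  d2 <- simulate_experiment(p2, vt_conditions, 3e4, seed = 6)
  expect_lt(abs(mean(d1$accuracy) - mean(d2$accuracy)), 0.005)
  expect_lt(abs(mean(d1$rt) - mean(d2$rt)), 2)
})
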