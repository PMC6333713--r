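test_that("observed proportions split mass into CDF and CAF slots", {
  # 1000 trials, all correct, any RT shape -> (0.1, 0.2, 0.2, 0.2, 0.2; 0...)
  t1 <- data.frame(rt = 1:1000, accuracy = 1L)
  o1 <- observed_proportions(t1)
  expect_equal(o1$proportions, c(0.1, 0.2, 0.2, 0.2, 0.2, rep(0, 5)))
  expect_equal(o1$n, 1000L)
  # accuracy 0.9 spread uniformly over bins
  acc <- rep(1L, 1000)
  acc[seq(5, 1000, by = 10)] <- 0L  # 20 errors in each quintile of 200
  t2 <- data.frame(rt = 1:1000, accuracy = acc)
  o2 <- observed_proportions(t2)
  expect_equal(o2$proportions,
               c(0.09, 0.18, 0.18, 0.18, 0.18, rep(0.02, 5)))
  # the ten slots plus the top-tail correct mass always sum to 1
  set.seed(20)
  for (i in 1:10) {
    n <- sample(100:1000, 1)
    t3 <- data.frame(rt = rgamma(n, 5, 0.01),
                     accuracy = rbinom(n, 1, 0.85))
    o3 <- observed_proportions(t3)
    top_tail <- sum(t3$accuracy == 1L & t3$rt > o3$edges$cdf_q[5]) / n
    expect_equal(sum(o3$proportions) + top_tail, 1)
  }
  expect_error(observed_proportions(data.frame(rt = 1:10, accuracy = 0L),
                                    label = "IVIT"), "IVIT")
})

test_that("scoring a table against its own edges reproduces its proportions", {
  set.seed(21)
  t <- data.frame(rt = rnorm(700, 450, 80), accuracy = rbinom(700, 1, 0.9))
  o <- observed_proportions(t)
  rescored <- mdmc:::score_proportions(t$rt, t$accuracy, o$edges)
  expect_identical(rescored, o$proportions)
})

test_that("predicted proportions are seeded-deterministic and floored", {
  p <- mdmc_preset("vt_mdmc")
  t <- data.frame(rt = seq(200, 800, length.out = 500),
                  accuracy = rep(1L, 500))
  edges <- observed_proportions(t)$edges
  set.seed(22)
  a <- predicted_proportions(p, vt_conditions[["CVCT"]], edges, n_sim = 5000)
  set.seed(22)
  b <- predicted_proportions(p, vt_conditions[["CVCT"]], edges, n_sim = 5000)
  expect_identical(a, b)
  expect_true(all(a$proportions >= 1e-5))
})

test_that("G-squared matches hand computation and scales with N", {
  expect_equal(g_squared(c(0.5, 0.5), c(0.25, 0.75), 100),
               2 * 100 * (0.5 * log(2) + abs(0.5 * log(2 / 3))),
               tolerance = 1e-12)
  expect_equal(g_squared(c(0.5, 0.5), c(0.25, 0.75), 100), 109.8612,
               tolerance = 1e-4)
  expect_equal(g_squared(c(0.3, 0.7), c(0.3, 0.7), 50), 0)
  expect_equal(g_squared(c(0.5, 0.5), c(0.25, 0.75), 200),
               2 * g_squared(c(0.5, 0.5), c(0.25, 0.75), 100))
  # zero observed slots contribute nothing
  expect_equal(g_squared(c(0, 1), c(0.5, 0.5), 10),
               2 * 10 * log(2))
  # the classical signed form can go negative termwise but matches on p = pi
  expect_equal(g_squared(c(0.3, 0.7), c(0.3, 0.7), 50, classical = TRUE), 0)
  expect_error(g_squared(c(0.5, 0.5), c(0, 1), 10), "flooring")
  expect_error(g_squared(list(c(0.5, 0.5)), list(c(0.5, 0.5)), c(10, 20)),
               "per condition")
})

test_that("BIC adds the free-parameter penalty on the natural log scale", {
  expect_equal(bic(100, 0, 270), 100)
  expect_equal(bic(100, 9, 270), 100 + 9 * log(270), tolerance = 1e-12)
  expect_equal(round(bic(126.1, 9, 270), 1), 176.5)
  expect_error(bic(10, 9, 0), "n_total")
  # ordering invariant to adding a constant to both models
  d1 <- bic(120, 9, 270) - bic(110, 10, 270)
  d2 <- bic(120 + 55, 9, 270) - bic(110 + 55, 10, 270)
  expect_equal(d1, d2)
})

test_that("a fit started at the generating parameters cannot get worse", {
  p <- mdmc_preset("vt_mdmc")
  d <- simulate_experiment(p, vt_conditions, 400, seed = 30)
  truth <- mdmc:::params_to_theta(p)
  fit <- mdmc(d, "MDMC", n_sim = 3000, maxit = 25, polish_maxit = 0,
              start = list(truth), seed = 5)
  expect_lte(fit$starts$g2_final, fit$starts$g2_initial)
  expect_equal(fit$g2, min(fit$starts$g2_final))
  expect_gte(fit$g2, 0)
  expect_equal(fit$n_free, 9L)
  expect_equal(fit$bic, fit$g2 + 9 * log(fit$n_total))
  expect_s3_class(fit, "mdmc_fit")
})

test_that("fits are deterministic given the seed and detect missing cells", {
  p <- mdmc_preset("vt_mdmc")
  d <- simulate_experiment(p, vt_conditions, 300, seed = 31)
  f1 <- mdmc(d, "MDMC", n_starts = 1, n_sim = 2000, maxit = 10,
             polish_maxit = 0, seed = 8)
  f2 <- mdmc(d, "MDMC", n_starts = 1, n_sim = 2000, maxit = 10,
             polish_maxit = 0, seed = 8)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$g2, f2$g2)
  d_miss <- d[!(d$visual == "congruent" & d$tactile == "congruent"), ]
  expect_error(mdmc(d_miss, "MDMC"), "CVCT")
})

test_that("fit methods expose coefficients, predictions and residuals", {
  p <- mdmc_preset("vt_fnmdmc")
  d <- simulate_experiment(p, vt_conditions, 400, seed = 32)
  truth <- mdmc:::params_to_theta(p)
  fit <- mdmc(d, "FN-MDMC", n_sim = 2000, maxit = 5, polish_maxit = 0,
              start = list(truth), seed = 9)
  expect_equal(fit$n_free, 10L)
  expect_named(coef(fit), mdmc:::free_parameter_names(
    c("visual", "tactile"), "FN-MDMC"))
  expect_equal(BIC(fit), fit$bic)
  pr <- predict(fit, n_sim = 2000)
  expect_equal(dim(pr), c(9L, 10L))
  expect_true(all(pr >= 1e-5))
  # predicting with the fit's own CRN seed reproduces the fitted G2
  expect_equal(attr(predict(fit), "g2"), fit$g2, tolerance = 1e-10)
  rs <- residuals(fit, n_sim = 2000)
  expect_equal(dim(rs), c(9L, 10L))
  sim <- simulate(fit, nsim = 50, seed = 2)
  expect_equal(nrow(sim), 450L)
  out <- capture.output({print(fit); print(summary(fit))})
  expect_true(any(grepl("FN-MDMC", out)))
})

test_that("the paired sign-flip permutation test behaves at the extremes", {
  # exactly tied pairs: the null is exactly true, every permutation ties
  expect_gte(mdmc:::paired_permutation_test(rep(0, 50), 1000, seed = 1), 0.99)
  # a constant shift with negligible noise is maximally significant
  set.seed(2)
  d <- 10 + rnorm(100, 0, 1e-6)
  expect_lte(mdmc:::paired_permutation_test(d, 2000, seed = 3), 0.001)
})

test_that("the faster-neutral variant wins the permutation test on faster-neutral data", {
  p <- mdmc_preset("vt_fnmdmc")  # mu_r 317, mu_rn 303: a 14 ms neutral speed-up
  d <- simulate_experiment(p, vt_conditions, 2000, seed = 50)
  truth_fn <- mdmc:::params_to_theta(p)
  truth_m <- truth_fn[names(truth_fn) != "mu_rn"]
  fit_fn <- mdmc(d, "FN-MDMC", n_sim = 6000, maxit = 40, polish_maxit = 0,
                 start = list(truth_fn), seed = 12)
  fit_m <- mdmc(d, "MDMC", n_sim = 6000, maxit = 40, polish_maxit = 0,
                start = list(truth_m), seed = 12)
  cmp <- compare_models(fit_m, fit_fn, n_sims = 60, n_perms = 3000,
                        n_sim = 6000, seed = 7)
  expect_lt(cmp$mean_g2[["b"]], cmp$mean_g2[["a"]])   # FN fits better
  expect_lt(cmp$p_g2, 0.05)
  expect_lt(cmp$p_bic, 0.05)
})

test_that("comparing a fit with itself is null; refusing mismatched data", {
  p <- mdmc_preset("vt_mdmc")
  d <- simulate_experiment(p, vt_conditions, 300, seed = 33)
  truth <- mdmc:::params_to_theta(p)
  fit <- mdmc(d, "MDMC", n_sim = 1500, maxit = 3, polish_maxit = 0,
              start = list(truth), seed = 10)
  cmp <- compare_models(fit, fit, n_sims = 20, n_perms = 400,
                        n_sim = 1500, seed = 4)
  expect_gte(cmp$p_g2, 0.99)
  expect_gte(cmp$p_bic, 0.99)
  d2 <- simulate_experiment(p, vt_conditions, 300, seed = 34)
  fit2 <- mdmc(d2, "MDMC", n_sim = 1500, maxit = 3, polish_maxit = 0,
               start = list(truth), seed = 10)
  expect_error(compare_models(fit, fit2), "same data")
})
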