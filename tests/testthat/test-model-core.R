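test_that("congruency labels map to signs and unknown labels are rejected", {
  expect_identical(condition_sign("congruent"), 1L)
  expect_identical(condition_sign("neutral"), 0L)
  expect_identical(condition_sign("incongruent"), -1L)
  expect_identical(condition_sign(c("congruent", "incongruent")), c(1L, -1L))
  expect_error(condition_sign("kongruent"), "kongruent")
})

test_that("automatic_spec and mdmc_params enforce their invariants", {
  expect_error(automatic_spec(-1, 39), "amplitude")
  expect_error(automatic_spec(13.4, 0), "tau")
  expect_error(automatic_spec(13.4, 39, shape = 1), "shape")
  expect_error(mdmc_params(0.5, -1, 3, 300, 30,
                           list(visual = automatic_spec(10, 40))),
               "boundary")
  p <- mdmc_preset("vt_fnmdmc")
  expect_identical(attr(p, "variant"), "FN-MDMC")
  expect_identical(attr(mdmc_preset("vt_mdmc"), "variant"), "MDMC")
})

test_that("the activation pulse peaks at (a-1)*tau with value |A|", {
  spec <- automatic_spec(13.4, 39)  # visual pulse of the V-T MDMC fit
  expect_equal(automatic_activation(39, spec, 1L), 13.4)
  expect_equal(automatic_activation(0, spec, 1L), 0)
  expect_equal(automatic_activation(78, spec, 1L), 26.8 / exp(1),
               tolerance = 1e-12)
  # unique maximum on a dense grid, equal to |A| to 1e-9 relative error
  tt <- seq(0.01, 600, by = 0.01)
  v <- automatic_activation(tt, spec, 1L)
  expect_equal(tt[which.max(v)], 39, tolerance = 1e-3)
  expect_equal(max(v), 13.4, tolerance = 1e-9)
  # monotone decay beyond the peak
  post <- v[tt > 39]
  expect_true(all(diff(post) < 0))
})

test_that("automatic drift is the derivative of the activation pulse", {
  spec <- automatic_spec(13.4, 39)
  expect_equal(automatic_drift(39, spec, 1L), 0, tolerance = 1e-14)
  # finite-difference oracle at t = 20 (step 1e-3 ms)
  h <- 1e-3
  fd <- (automatic_activation(20 + h, spec, 1L) -
           automatic_activation(20 - h, spec, 1L)) / (2 * h)
  expect_equal(automatic_drift(20, spec, 1L), fd, tolerance = 1e-6)
  # sign crosses once: positive before (a-1)*tau, negative after
  tt <- seq(0.5, 500, by = 0.5)
  s <- sign(automatic_drift(tt, spec, 1L))
  expect_true(all(s[tt < 39] == 1) && all(s[tt > 39] == -1))
  expect_error(automatic_drift(0, spec, 1L), "> 0")
  expect_error(automatic_activation(-1, spec, 1L), ">= 0")
})

test_that("numeric integral of the drift recovers the activation", {
  for (spec in list(automatic_spec(13.4, 39), automatic_spec(6.1, 28.5))) {
    for (T_ in spec$tau * c(0.5, 1, 5)) {
      int <- integrate(function(t) automatic_drift(t, spec, 1L), 0, T_,
                       rel.tol = 1e-10)$value
      expect_equal(int, automatic_activation(T_, spec, 1L),
                   tolerance = 1e-4)
    }
  }
})

test_that("activation and drift are antisymmetric in the congruency sign", {
  spec <- automatic_spec(6.1, 28.5)
  tt <- c(1, 10, 28.5, 57, 200)
  expect_equal(automatic_activation(tt, spec, -1L),
               -automatic_activation(tt, spec, 1L))
  expect_equal(automatic_drift(tt, spec, -1L),
               -automatic_drift(tt, spec, 1L))
  expect_true(all(automatic_activation(tt, spec, 0L) == 0))
})

test_that("expected decision path superimposes controlled and automatic parts", {
  p <- mdmc_preset("vt_mdmc")
  neutral <- congruency_condition(visual = "neutral", tactile = "neutral")
  expect_equal(expected_decision_path(100, p, neutral), 52)
  expect_equal(expected_decision_path(0, p, vt_conditions[["CVCT"]]), 0)
  # term-by-term evaluation at t = 39 for the CVCT condition
  tact <- 6.1 * exp(-39 / 28.5) * (39 * exp(1) / 28.5)
  expect_equal(expected_decision_path(39, p, vt_conditions[["CVCT"]]),
               0.52 * 39 + 13.4 + tact, tolerance = 1e-12)
  expect_equal(expected_decision_path(39, p, vt_conditions[["CVCT"]]),
               39.45493, tolerance = 1e-6)
  bad <- congruency_condition(visual = "congruent", auditory = "neutral")
  expect_error(expected_decision_path(10, p, bad), "modalit")
})

test_that("parameter sets round-trip through their text serialisation", {
  p <- mdmc_preset("va_fnmdmc")
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(q, p)
  expect_identical(attr(q, "variant"), "FN-MDMC")
})
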