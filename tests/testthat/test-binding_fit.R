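p65_pars <- c(delta_t_max = 1.678, kd = 2.228)
p50_pars <- c(delta_t_max = 2.462, kd = 0.794)
titration <- c(0.5, 1, 2, 4, 6, 8, 10)

test_that("the depletion equation evaluates to its closed-form values", {
  # direct evaluation of the model at the fitted parameter sets
  expect_equal(predict_delta_tm(1.678, 2.228, 10), 1.33480, tolerance = 1e-5)
  expect_equal(predict_delta_tm(2.462, 0.794, 10), 2.23364, tolerance = 1e-5)
  expect_equal(predict_delta_tm(1.678, 2.228, 0), 0)
  expect_equal(predict_delta_tm(5, 0.3, 0), 0)
})

test_that("the depletion equation is monotone, bounded and saturating", {
  d <- seq(0, 50, by = 0.25)
  for (pars in list(p65_pars, p50_pars, c(delta_t_max = 4, kd = 9))) {
    y <- predict_delta_tm(pars[1], pars[2], d)
    expect_true(all(diff(y) >= -1e-12))           # non-decreasing in [D]
    expect_true(all(y <= pars[1] + 1e-12))        # never exceeds the maximum
    expect_true(all(y >= 0))
    # kd ordering: higher kd, lower shift at fixed [D]
    expect_true(all(predict_delta_tm(pars[1], pars[2] + 1, d) <= y + 1e-12))
  }
  expect_equal(predict_delta_tm(1.678, 2.228, 1e7), 1.678, tolerance = 1e-4)
})

test_that("fit_binding recovers generating parameters from noiseless data", {
  y <- predict_delta_tm(p65_pars[1], p65_pars[2], titration)
  fit <- fit_binding(binding_series(titration, y))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), unname(p65_pars), tolerance = 1e-4)
  expect_lt(fit$sse, 1e-10)
  expect_equal(predict(fit, titration), y, tolerance = 1e-5)
  # order of the points is irrelevant
  o <- c(4, 1, 7, 2, 6, 3, 5)
  fit2 <- fit_binding(binding_series(titration[o], y[o]))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
})

test_that("fit_binding tolerates replicate-scale noise", {
  set.seed(42)
  y <- predict_delta_tm(p65_pars[1], p65_pars[2], titration) +
    rnorm(7, 0, 0.05)
  fit <- fit_binding(binding_series(titration, y))
  expect_true(fit$converged)
  expect_lt(abs(fit$kd - p65_pars[2]) / p65_pars[2], 0.25)
})

test_that("degenerate and invalid series are rejected", {
  expect_error(fit_binding(binding_series(titration, rep(0, 7))),
               "degenerate")
  expect_error(binding_series(1:2, 1:2), "at least 3")
  expect_error(binding_series(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(binding_series(c(-1, 2, 3), c(1, 2, 3)), ">= 0")
})

test_that("matched site-multiplicity conventions recover kd exactly", {
  # generator and fitter sharing the convention is exact ...
  y2 <- predict_delta_tm(1.678, 2.228, titration * 2)
  fit2 <- fit_binding(binding_series(titration, y2, site_multiplicity = 2))
  expect_equal(fit2$kd, 2.228, tolerance = 1e-4)
  # ... while a mismatched convention rescales only the concentration axis:
  # fitting with multiplicity m equals fitting multiplicity 1 on m-scaled
  # concentrations (the model itself is not closed under axis scaling, so
  # the often-quoted "kd changes by exactly m" holds only approximately)
  y1 <- predict_delta_tm(1.678, 2.228, titration)
  fa <- fit_binding(binding_series(titration, y1, site_multiplicity = 2))
  fb <- fit_binding(binding_series(titration * 2, y1))
  expect_equal(coef(fa), coef(fb), tolerance = 1e-6)
  expect_gt(fa$kd / 2.228, 1)  # rescaling direction
})

test_that("bootstrap intervals are seeded, and collapse on noiseless data", {
  y <- predict_delta_tm(1.678, 2.228, titration)
  fit <- fit_binding(binding_series(titration, y))
  b1 <- bootstrap_ci(fit, n_boot = 200, seed = 7)
  b2 <- bootstrap_ci(fit, n_boot = 200, seed = 7)
  expect_identical(b1$ci_kd, b2$ci_kd)
  expect_lt(diff(b1$ci_kd), 1e-6)
  expect_lt(diff(b1$ci_delta_t_max), 1e-6)
  expect_error(bootstrap_ci(fit, n_boot = 50), ">= 100")
  small <- fit_binding(binding_series(c(1, 2, 4), c(0.3, 0.5, 0.8)))
  expect_error(bootstrap_ci(small, n_boot = 200), "at least 4")
})

test_that("bootstrap intervals cover the generating kd at realistic noise", {
  # 40 seeded replicates at the replicate-noise scale; the residual
  # bootstrap at n=7 undercovers mildly, so the bound asserted here is the
  # measured performance, not the nominal 95%
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    y <- predict_delta_tm(1.678, 2.228, titration) + rnorm(7, 0, 0.05)
    f <- bootstrap_ci(fit_binding(binding_series(titration, y)),
                      n_boot = 300, seed = s)
    f$ci_kd[1] <= 2.228 && 2.228 <= f$ci_kd[2]
  }, logical(1))
  expect_gte(sum(hits), 32)
})
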