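test_that("smoothers preserve identity, constants and linear ramps", {
  x <- sin(seq(0, 3, length.out = 50))
  expect_identical(smooth_curve(x, smoothing_spec("none")), x)
  for (m in c("moving_average", "savitzky_golay")) {
    expect_equal(smooth_curve(rep(3.2, 30), smoothing_spec(m, 7)),
                 rep(3.2, 30))
  }
  ramp <- seq(1, 10, length.out = 40)
  sm <- smooth_curve(ramp, smoothing_spec("moving_average", 5))
  expect_equal(sm[3:38], ramp[3:38])
  expect_error(smooth_curve(1:5, smoothing_spec(window = 7)), "shorter")
  expect_error(smoothing_spec(window = 4), "odd")
  expect_error(smoothing_spec(window = 3, polyorder = 3), "polyorder")
})

test_that("derivative_curve matches known slopes", {
  t <- seq(25, 30, by = 0.5)
  expect_equal(derivative_curve(t, 2 * t), rep(2, length(t)))
  expect_equal(derivative_curve(t, rep(7, length(t))), rep(0, length(t)))
  expect_error(derivative_curve(t, 1:3), "mismatch")
  # derivative maximum falls within one grid step of the generating Tm
  cv <- simulate_melt_curve(flat_sim(42.5))
  d <- derivative_curve(cv$temperatures, cv$rfu)
  expect_lte(abs(cv$temperatures[which.max(d)] - 42.5), 0.2)
})

test_that("estimate_tm recovers generating Tm values on clean curves", {
  for (tm0 in c(30, 42.5, 44.5, 57.3, 70)) {
    cv <- simulate_melt_curve(flat_sim(tm0))
    est <- estimate_tm(cv$temperatures, cv$rfu)
    expect_length(est$flags, 0)
    expect_lte(abs(est$tm - tm0), 0.2)
    expect_gt(est$peak_height, 0)
    expect_true(est$tm >= est$search_range[1] && est$tm <= est$search_range[2])
  }
})

test_that("estimate_tm is invariant to affine rescaling of the RFU axis", {
  cv <- simulate_melt_curve(sim_spec(tm0 = 46), seed = 2)
  e1 <- estimate_tm(cv$temperatures, cv$rfu)
  e2 <- estimate_tm(cv$temperatures, 3.7 * cv$rfu + 250)
  expect_equal(e2$tm, e1$tm)
  expect_equal(e2$flags, e1$flags)
  expect_equal(e2$peak_height, 3.7 * e1$peak_height)
})

test_that("wider smoothing never raises the derivative peak on clean curves", {
  cv <- simulate_melt_curve(flat_sim(45))
  for (m in c("savitzky_golay", "moving_average")) {
    peaks <- vapply(c(5, 7, 9, 11, 15, 21), function(w) {
      max(derivative_curve(cv$temperatures,
                           smooth_curve(cv$rfu, smoothing_spec(m, w))))
    }, numeric(1))
    expect_true(all(diff(peaks) <= 1e-9))
  }
})

test_that("transition-free and degenerate curves are flagged", {
  t <- seq(25, 95, by = 0.2)
  mono <- estimate_tm(t, 100 + 2 * (t - 25))  # strictly monotone ramp
  expect_true("no_transition" %in% mono$flags)
  expect_true(is.na(mono$tm))
  flat <- qc_curve(t, rep(0, length(t)))
  expect_true(all(c("low_signal", "no_transition") %in% flat))
  # high initial fluorescence with a minor increase on heating
  hb <- qc_curve(t, 900 + 100 * (t - 25) / 70)
  expect_true("high_background" %in% hb)
  cv <- simulate_melt_curve(flat_sim(42.5))
  expect_length(qc_curve(cv$temperatures, cv$rfu,
                         search_range = c(25.4, 90)), 0)
  expect_error(estimate_tm(t, rep(1, length(t)), search_range = c(10, 50)),
               "outside")
  expect_error(estimate_tm(t, rep(1, length(t)), search_range = c(30, 30.1)),
               "fewer than 3")
})

test_that("delta_tm does group arithmetic and propagates dispersion", {
  dt <- delta_tm(c(43.5, 43.7, 43.6), c(42.4, 42.5, 42.6))
  expect_equal(dt$value, 1.1)
  expect_equal(dt$sd, sqrt(0.1^2 / 3 + 0.1^2 / 3), tolerance = 1e-10)
  expect_equal(delta_tm(c(42.5, 42.6), c(42.5, 42.6))$value, 0)
  # antisymmetry
  a <- c(43.1, 43.3); b <- c(42.2, 42.1)
  expect_equal(delta_tm(a, b)$value, -delta_tm(b, a)$value)
})

test_that("delta_tm rejects flagged estimates unless overridden", {
  t <- seq(25, 95, by = 0.2)
  bad <- estimate_tm(t, 100 + 2 * (t - 25), well_id = "B2")
  good <- estimate_tm(t, simulate_melt_curve(flat_sim(42.5))$rfu)
  expect_error(delta_tm(list(bad), list(good)), "flagged.*B2")
  expect_equal(delta_tm(list(good), list(good))$value, 0)
})

test_that("an injected shift is recovered through the Tm pipeline", {
  ref <- simulate_melt_curve(flat_sim(42.5))
  smp <- simulate_melt_curve(flat_sim(42.5), tm_override = 42.5 + 1.335)
  est_r <- estimate_tm(ref$temperatures, ref$rfu)
  est_s <- estimate_tm(smp$temperatures, smp$rfu)
  dt <- delta_tm(list(est_s), list(est_r))
  expect_lte(abs(dt$value - 1.335), 0.2)
})
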