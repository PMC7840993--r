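test_that("destabilization profiles recover injected Tm losses", {
  # WFA-like: -0.7 and -1.7 degrees at 24 and 50 uM, zero noise
  sim <- simulate_inhibition_experiment(
    plate_sim_spec(destab_map = c("24" = -0.7, "50" = -1.7)),
    doses = c(24, 50), seed = 3)
  wf <- run_ic50_workflow(sim$plate, sim$layout)
  expect_equal(wf$destabilization$doses, c(24, 50))
  expect_equal(wf$destabilization$responses, c(-0.7, -1.7), tolerance = 0.02)
})

test_that("destabilization is zero when doses match the reference", {
  prof <- destabilization_profile(
    list("10" = c(42.5, 42.6, 42.4), "30" = c(42.5, 42.4, 42.6)),
    c(42.4, 42.5, 42.6))
  expect_equal(prof$responses, c(0, 0))
  expect_equal(prof$response_kind, "tm_shift")
  expect_error(destabilization_profile(list("10" = 42), numeric(0)),
               "empty reference")
})

test_that("noisy destabilization stays within sampling error of truth", {
  shifts <- c("24" = -0.7, "50" = -1.7)
  set.seed(9)
  groups <- lapply(shifts, function(s) 42.5 + s + rnorm(3, 0, 0.1))
  ref <- 42.5 + rnorm(3, 0, 0.1)
  prof <- destabilization_profile(groups, ref)
  sem <- sqrt(0.1^2 / 3 + 0.1^2 / 3)
  expect_true(all(abs(prof$responses - shifts) <= 2 * sem))
})

test_that("suppression maps unchanged and abolished shifts to 0 and 100", {
  probe <- list("0" = rep(42.5, 3))
  dna <- list("0" = rep(43.84, 3),   # +1.34 shift
              "5" = rep(43.84, 3),   # unchanged
              "20" = rep(43.17, 3),  # half suppressed
              "80" = rep(42.5, 3))   # abolished
  s <- stabilization_suppression(probe, dna)
  expect_equal(s$responses[s$doses == 5], 0)
  expect_equal(s$responses[s$doses == 20], 50, tolerance = 1e-6)
  expect_equal(s$responses[s$doses == 80], 100)
  expect_error(
    stabilization_suppression(list("0" = 42.5), list("0" = 42.4, "5" = 42)),
    "no stabilization")
})

test_that("fit_4pl recovers IC50 from clean and noisy sigmoids", {
  doses <- 10^seq(0, 2, length.out = 8)
  y <- 100 / (1 + (16.4 / doses))
  fit <- fit_4pl(dose_series(doses, y, "stabilization_fraction"))
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 16.4) / 16.4, 1e-3)
  expect_equal(fit$hill, 1, tolerance = 1e-3)
  # midpoint definition: response exactly 50 at dose 10
  y10 <- 100 / (1 + (10 / doses))
  expect_equal(fit_4pl(dose_series(doses, y10,
                                   "stabilization_fraction"))$ic50,
               10, tolerance = 1e-6)
  set.seed(5)
  yn <- 100 / (1 + (19.1 / doses)) + rnorm(8, 0, 2)
  fn <- fit_4pl(dose_series(doses, yn, "stabilization_fraction"),
                fix_bottom = 0, fix_top = 100)
  expect_lt(abs(fn$ic50 - 19.1) / 19.1, 0.15)
})

test_that("fit_4pl is scale-equivariant in dose", {
  doses <- 10^seq(0, 2, length.out = 8)
  set.seed(11)
  y <- 100 / (1 + (16.4 / doses)^1.3) + rnorm(8, 0, 1)
  f1 <- fit_4pl(dose_series(doses, y, "stabilization_fraction"))
  f2 <- fit_4pl(dose_series(doses * 7, y, "stabilization_fraction"))
  expect_equal(f2$ic50 / f1$ic50, 7, tolerance = 1e-4)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-4)
})

test_that("underdetermined dose series are rejected", {
  expect_error(fit_4pl(dose_series(c(1, 2, 3), c(1, 2, 3))), "4 distinct")
  expect_error(fit_4pl(dose_series(c(0, 0.1, 1, 1), c(0, 1, 2, 3))),
               "4 distinct")
})

test_that("pooled t comparison matches its closed form and stats::t.test", {
  cmp <- compare_tm_groups(c(42.4, 42.5, 42.6), c(43.4, 43.5, 43.6))
  expect_equal(cmp$t_stat, -12.247, tolerance = 1e-3)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$stars, "***")
  # identical groups: p = 1 by convention
  same <- compare_tm_groups(rep(42.5, 3), rep(42.5, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")
  # cross-check on irregular data against the reference implementation
  set.seed(3)
  a <- rnorm(5, 42, 0.3); b <- rnorm(4, 42.4, 0.2)
  ref <- t.test(a, b, var.equal = TRUE)
  cmp2 <- compare_tm_groups(a, b)
  expect_equal(cmp2$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cmp2$p_value, ref$p.value, tolerance = 1e-10)
  refw <- t.test(a, b)
  cmpw <- compare_tm_groups(a, b, var_equal = FALSE)
  expect_equal(cmpw$p_value, refw$p.value, tolerance = 1e-10)
})

test_that("t comparison is antisymmetric and monotone in separation", {
  set.seed(8)
  a <- rnorm(4, 42.5, 0.1); b <- rnorm(4, 43.0, 0.1)
  expect_equal(compare_tm_groups(a, b)$t_stat,
               -compare_tm_groups(b, a)$t_stat)
  expect_equal(compare_tm_groups(a, b)$p_value,
               compare_tm_groups(b, a)$p_value)
  # a ten-sigma separation is always ***
  expect_equal(compare_tm_groups(a, a + 10 * 0.1)$stars, "***")
  expect_error(compare_tm_groups(42.5, c(42, 43)), "at least 2")
})
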