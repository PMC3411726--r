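# First-order depletion fits and rate comparisons.

grid <- c(0, 0.5, 1, 2, 4, 8)

test_that("fraction_remaining is the plain area ratio, no interpolation", {
  tc <- tibble::tibble(time_min = grid, area = 1000)
  expect_equal(fraction_remaining(tc, grid), rep(1, length(grid)))
  tc$area <- 1000 * exp(-0.15 * grid)
  expect_equal(fraction_remaining(tc, 8), exp(-1.2))
  expect_error(fraction_remaining(tc, 3), "not sampled")
})

test_that("time-course validation catches malformed input", {
  expect_error(fit_depletion(tibble::tibble(time_min = c(0, 1), area = c(1, 1))),
               "at least 3")
  expect_error(fit_depletion(tibble::tibble(time_min = c(0, 2, 1), area = 1)),
               "increasing")
  expect_error(fit_depletion(tibble::tibble(time_min = c(1, 2, 3), area = 1)),
               "start at time 0")
  expect_error(fit_depletion(tibble::tibble(time_min = grid, area = 0)),
               "positive")
})

test_that("noiseless exponentials are recovered to numerical precision", {
  for (k in c(0, 0.05, 0.2, 0.5, 1)) {
    tc <- tibble::tibble(time_min = grid, area = 5e5 * exp(-k * grid))
    fit <- fit_depletion(tc)
    expect_equal(fit$k, k, tolerance = 1e-9)
    if (k > 0) {
      expect_equal(fit$half_life, log(2) / k, tolerance = 1e-9)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    } else {
      expect_identical(fit$half_life, Inf)
    }
    expect_equal(fit$f_end, exp(-8 * k))
  }
})

test_that("drift correction with an identical control gives k = 0", {
  sim <- simulate_depletion(k = 0.3, control_drift_frac = 0.15, noise_cv = 0,
                            seed = 2)
  ctrl <- sim[sim$course == "control", ]
  fit <- fit_depletion(ctrl, control = ctrl)
  expect_equal(fit$k, 0)
  # and correcting the decaying signal by the control recovers k exactly
  sig <- sim[sim$course == "signal", ]
  fit2 <- fit_depletion(sig, control = ctrl)
  expect_equal(fit2$k, 0.3, tolerance = 1e-9)
  expect_error(fit_depletion(sig, control = ctrl[c(1, 2, 4, 5, 6), ]),
               "time grid")
})

test_that("tidy and glance expose the fit in broom form", {
  tc <- tibble::tibble(time_min = grid, area = 1e6 * exp(-0.2 * grid))
  fit <- fit_depletion(tc)
  td <- tidy(fit)
  expect_identical(td$term, c("k", "half_life", "f_end"))
  expect_equal(td$estimate[1], 0.2, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_points, 6L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("compare_depletion orders courses by rate and flags similarity", {
  mk <- function(k) tibble::tibble(time_min = grid, area = 1e6 * exp(-k * grid))
  # three noiseless courses: strict ordering recovered
  cmp <- compare_depletion(list(slow = mk(0.1), fast = mk(0.3), mid = mk(0.2)))
  expect_identical(cmp$label, c("fast", "mid", "slow"))
  # identical courses are "similar"
  noisy <- function(k, seed) {
    s <- simulate_depletion(k, noise_cv = 0.05, seed = seed)
    s[s$course == "signal", c("time_min", "area")]
  }
  cmp2 <- compare_depletion(list(a = noisy(0.2, 1), b = noisy(0.2, 2)))
  expect_identical(cmp2$vs_next[1], "similar")
  # clearly separated rates: Cys-like course faster than Lys-like
  cmp3 <- compare_depletion(list(cys = mk(0.25), lys = mk(0.05)))
  expect_identical(cmp3$label[1], "cys")
  expect_error(compare_depletion(list(a = mk(0.1))), "at least two")
  bad <- mk(0.1)
  bad$time_min <- bad$time_min + c(0, 0.1, 0, 0, 0, 0)
  expect_error(compare_depletion(list(a = mk(0.1), b = bad)), "common time grid")
})

test_that("rate recovery is accurate under 5% multiplicative noise", {
  errs <- vapply(1:50, function(s) {
    sim <- simulate_depletion(k = 0.1, control_drift_frac = 0,
                              noise_cv = 0.05, seed = s)
    fit <- fit_depletion(sim[sim$course == "signal", ])
    abs(fit$k - 0.1) / 0.1
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})
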