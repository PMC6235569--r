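test_that("damped-sinusoid fit recovers generator parameters exactly at zero noise", {
  for (cond in c("+Shear", "-Shear", "+Jasp")) {
    p <- make_condition_preset(cond, noise_sd = 0)
    s <- generate_velocity_series(p, grid_spec(), seed = 1)
    k <- fold_kymograph(build_kymograph(s, "y", plank = "top"),
                        build_kymograph(s, "y", plank = "bottom"))
    mv <- mean_velocity_series(k)
    # fit after the wave has reached the farthest row: from there the mean
    # is an exact damped sinusoid
    arrival <- 250 / p$wave_speed_initial
    fit <- fit_damped_sinusoid(mv, t_min = arrival)
    gt <- s$ground_truth
    expect_lt(abs(fit$A - gt$mean_amplitude) / gt$mean_amplitude, 0.01)
    expect_lt(abs(fit$P - p$osc_period) / p$osc_period, 0.01)
    if (is.finite(p$osc_damping_D)) {
      expect_lt(abs(fit$D - p$osc_damping_D) / p$osc_damping_D, 0.01)
    } else {
      expect_identical(fit$D, Inf)   # undamped limit -> Inf sentinel
    }
    expect_lt(abs(fit$t0 - ((gt$t0 + gt$delta_eff) %% fit$P)), 0.02)
  }
})

test_that("pure undamped sine returns the Inf damping sentinel", {
  tt <- seq(0, 23, by = 1 / 12)
  mv <- list(times = tt, mean_v = 10 * sin(2 * pi * (tt - 3) / 8))
  fit <- fit_damped_sinusoid(mv)
  expect_identical(fit$D, Inf)
  expect_equal(fit$A, 10, tolerance = 1e-4)
  expect_equal(fit$P, 8, tolerance = 1e-4)
})

test_that("flat series gives a flagged degenerate fit", {
  mv <- list(times = seq(0, 20, 0.25), mean_v = rep(2, 81))
  fit <- fit_damped_sinusoid(mv)
  expect_true(fit$degenerate)
  expect_equal(fit$A, 0)
  expect_equal(fit$v0, 2)
})

test_that("fitted +Shear amplitude exceeds the -Shear amplitude", {
  fits <- lapply(c("+Shear", "-Shear"), function(cond) {
    k <- folded_kymo(cond, noise_sd = 3, seed = 11)
    fit_damped_sinusoid(mean_velocity_series(k))
  })
  expect_gt(fits[[1]]$A, fits[[2]]$A)
})

test_that("parameter recovery under default noise: median errors < 10%", {
  p <- make_condition_preset("+Shear")   # default noise_sd = 3
  g <- grid_spec()
  arrival <- 250 / p$wave_speed_initial
  errs <- t(vapply(1:50, function(s) {
    ser <- generate_velocity_series(p, g, seed = s)
    k <- fold_kymograph(build_kymograph(ser, "y", plank = "top"),
                        build_kymograph(ser, "y", plank = "bottom"))
    fit <- fit_damped_sinusoid(mean_velocity_series(k), t_min = arrival)
    gt <- ser$ground_truth
    c(A = abs(fit$A - gt$mean_amplitude) / gt$mean_amplitude,
      P = abs(fit$P - p$osc_period) / p$osc_period,
      D = abs(fit$D - p$osc_damping_D) / p$osc_damping_D)
  }, c(A = 0, P = 0, D = 0)))
  expect_lt(median(errs[, "A"]), 0.10)
  expect_lt(median(errs[, "P"]), 0.10)
  expect_lt(median(errs[, "D"]), 0.10)
})

test_that("reversals are the zeros of the sine factor", {
  tt <- seq(0, 20, by = 1 / 12)
  mv <- list(times = tt, mean_v = exp(-tt / 10) * sin(2 * pi * (tt - 3) / 8))
  rv <- find_reversals(mv)
  expect_equal(rv$times[1:4], c(3, 7, 11, 15), tolerance = 0.01)
  expect_identical(rv$direction[1], "inward-to-outward")
  expect_identical(rv$direction[2], "outward-to-inward")
  # constant positive series: no reversals
  expect_length(find_reversals(list(times = tt, mean_v = rep(3, length(tt))))$times, 0L)
})

test_that("reversal spacing on a damped sinusoid equals P/2 within one bin", {
  k <- folded_kymo("+Shear")
  rv <- find_reversals(mean_velocity_series(k))
  expect_gte(length(rv$times), 3L)
  expect_true(all(abs(diff(rv$times) - 4) < 1 / 12 + 1e-9))
})

test_that("generated +Jasp series reverses every half period while sustained", {
  k <- folded_kymo("+Jasp")
  rv <- find_reversals(mean_velocity_series(k))
  within20 <- rv$times[rv$times <= 20]
  expect_gte(length(within20), 4L)
  # undamped: spacing stays P/2 to the end of the record
  expect_true(all(abs(diff(rv$times) - 4) < 1 / 12 + 0.2))
  # the first sustained-oscillation reversal is at first_reversal = 7 h
  expect_true(any(abs(rv$times - 7) < 0.05))
})

test_that("time-shift equivariance of fit and reversals", {
  tt <- seq(0, 23, by = 1 / 12)
  v <- 12 * exp(-tt / 8) * sin(2 * pi * (tt - 3) / 8) + 1
  f0 <- fit_damped_sinusoid(list(times = tt, mean_v = v))
  r0 <- find_reversals(list(times = tt, mean_v = v))
  delta <- 2
  # same samples, clock shifted by delta (envelope tied to the old origin)
  f1 <- fit_damped_sinusoid(list(times = tt + delta, mean_v = v), t_min = delta)
  r1 <- find_reversals(list(times = tt + delta, mean_v = v))
  expect_equal(f1$P, f0$P, tolerance = 1e-3)
  # envelope referenced to the shifted clock absorbs exp(delta/(2D)) into A
  expect_equal(f1$A * exp(-delta / (2 * f1$D)), f0$A, tolerance = 0.01)
  expect_equal((f1$t0 - delta) %% f1$P, f0$t0 %% f0$P, tolerance = 0.01)
  expect_equal(r1$times[seq_along(r0$times)], r0$times + delta, tolerance = 1e-6)
})

test_that("exact Mann-Whitney matches full permutation enumeration for n <= 5", {
  set.seed(42)
  for (n1 in 3:5) for (n2 in 3:5) {
    x <- round(rnorm(n1, 0, 2), 2)
    y <- round(rnorm(n2, 1, 2), 2)
    if (anyDuplicated(c(x, y))) next  # exact null assumes no ties
    p_ref <- brute_force_mw(x, y, "two.sided")
    p_pkg <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
  # the worked case: {1,2,3} vs {4,5,6}, one-sided exact p = 1/20
  expect_equal(brute_force_mw(1:3, 4:6, "less"), 1 / 20)
  expect_equal(stats::wilcox.test(1:3, 4:6, alternative = "less",
                                  exact = TRUE)$p.value, 1 / 20)
})

test_that("condition comparison gates pairwise tests on the omnibus result", {
  # identical samples in all groups: omnibus p = 1, no pairwise tests
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1))
  cmp <- compare_conditions(same, "A")
  expect_equal(cmp$omnibus$p, 1)
  expect_null(cmp$pairwise)
  # clearly separated groups: omnibus fires, pairwise exact p reported
  sep <- list(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13), c = c(20, 21, 22, 23))
  cmp2 <- compare_conditions(sep, "A")
  expect_lt(cmp2$omnibus$p, 0.05)
  expect_equal(nrow(cmp2$pairwise), 3L)
  expect_equal(cmp2$pairwise$p[1],
               stats::wilcox.test(sep$a, sep$b, exact = TRUE)$p.value)
  # overlapping groups: omnibus not significant, pairwise absent
  ovl <- list(a = c(1, 5, 3), b = c(2, 4, 6))
  cmp3 <- compare_conditions(ovl, "A")
  expect_gte(cmp3$omnibus$p, 0.05)
  expect_null(cmp3$pairwise)
  expect_error(compare_conditions(list(a = 1:3), "A"), "at least 2")
})
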