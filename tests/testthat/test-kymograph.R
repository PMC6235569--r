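test_that("building a kymograph is horizontal averaging", {
  g <- grid_spec(n_cols = 18, n_rows = 15, t_start = 0, t_end = 0.25)
  mk_field <- function(time, v) structure(
    list(time = time, plank = "top",
         u = matrix(0, 15, 18), v = v, grid = g), class = "epi_field")
  # 18 identical columns of 30 -> row value 30
  f1 <- mk_field(0, matrix(30, 15, 18))
  # all zero except one cell of 18 in row 4 -> that row averages to 1
  v2 <- matrix(0, 15, 18); v2[4, 7] <- 18
  f2 <- mk_field(0.25, v2)
  k <- build_kymograph(list(f1, f2), "y")
  expect_equal(dim(k$values), c(2L, 15L))   # 1 x 15 per frame
  expect_true(all(k$values[1, ] == 30))
  expect_equal(k$values[2, 4], 1)
  expect_equal(k$values[2, 5], 0)
  expect_false(k$folded)
})

test_that("kymograph construction validates its inputs", {
  p <- make_condition_preset("+Shear", noise_sd = 0)
  s <- generate_velocity_series(p, small_grid(t_end = 0.5), seed = 1)
  expect_error(build_kymograph(list()), "empty")
  f <- Filter(function(x) x$plank == "top", s$fields)
  f2 <- f
  f2[[2]]$grid <- grid_spec(n_cols = 3, n_rows = 15)
  expect_error(build_kymograph(f2), "common grid")
})

test_that("folding flips the bottom-plank y sign and averages", {
  tt <- c(0, 0.5); yp <- c(10, 30)
  top <- kymo_from_matrix(matrix(5, 2, 2), tt, yp, folded = FALSE)
  bot_anti <- kymo_from_matrix(matrix(-5, 2, 2), tt, yp, folded = FALSE)
  bot_same <- kymo_from_matrix(matrix(5, 2, 2), tt, yp, folded = FALSE)
  # antisymmetric pair folds to the top plank exactly
  expect_equal(fold_kymograph(top, bot_anti)$values, top$values)
  # symmetric y-motion cancels after the sign flip
  expect_true(all(fold_kymograph(top, bot_same)$values == 0))
  # x-component averages without a sign flip
  topx <- kymo_from_matrix(matrix(5, 2, 2), tt, yp, "x", folded = FALSE)
  botx <- kymo_from_matrix(matrix(5, 2, 2), tt, yp, "x", folded = FALSE)
  expect_true(all(fold_kymograph(topx, botx)$values == 5))
  expect_true(fold_kymograph(top, bot_anti)$folded)
})

test_that("folding an antisymmetric generated pair is exact at zero noise", {
  p <- make_condition_preset("+Shear", noise_sd = 0)
  s <- generate_velocity_series(p, small_grid(t_end = 3), seed = 1)
  top <- build_kymograph(s, "y", plank = "top")
  bot <- build_kymograph(s, "y", plank = "bottom")
  folded <- fold_kymograph(top, bot)
  expect_identical(folded$values, top$values)  # exact, no tolerance
})

test_that("fold rejects mismatched inputs", {
  tt <- c(0, 0.5); yp <- c(10, 30)
  a <- kymo_from_matrix(matrix(1, 2, 2), tt, yp, folded = FALSE)
  b <- kymo_from_matrix(matrix(1, 2, 2), tt, yp, "x", folded = FALSE)
  expect_error(fold_kymograph(a, b), "component")
  d <- kymo_from_matrix(matrix(1, 3, 2), c(tt, 1), yp, folded = FALSE)
  expect_error(fold_kymograph(a, d), "mismatch")
})

test_that("temporal binning averages blocks, including a partial tail", {
  yp <- c(10, 30)
  k <- kymo_from_matrix(matrix(c(10, 20, 30, 10, 20, 30), 3, 2),
                        c(0, 1, 2), yp)
  b <- bin_kymograph(k, 3)
  expect_equal(dim(b$values), c(1L, 2L))
  expect_true(all(b$values == 20))
  # n = 1 is the identity
  expect_identical(bin_kymograph(k, 1), k)
  # 302 frames at n = 3: 100 full bins + 1 partial bin of 2
  k302 <- kymo_from_matrix(matrix(seq_len(302), 302, 1), seq_len(302) / 12, 10)
  b302 <- bin_kymograph(k302, 3)
  expect_equal(length(b302$times), 101L)
  expect_equal(b302$values[101, 1], mean(c(301, 302)))  # partial tail
  # n larger than the series: a single bin
  expect_equal(length(bin_kymograph(k, 10)$times), 1L)
})

test_that("displacement integration is the cumulative trapezoid", {
  tt <- seq(0, 2, by = 0.25)
  # constant 30 um/h for 2 h -> 60 um
  k <- kymo_from_matrix(matrix(30, length(tt), 1), tt, 10)
  d <- integrate_displacement(k, 10)
  expect_equal(d$displacement[1, 1], 0)
  expect_equal(tail(d$displacement[, 1], 1), 60)
  # sine over whole periods -> net zero
  tt2 <- seq(0, 4, by = 0.01)
  k2 <- kymo_from_matrix(matrix(sin(2 * pi * tt2), ncol = 1), tt2, 10)
  d2 <- integrate_displacement(k2, 10)
  expect_equal(tail(d2$displacement[, 1], 1), 0, tolerance = 1e-6)
  # agrees with the independent trapezoid oracle on an arbitrary signal
  v <- cos(tt2) + 0.3 * tt2
  k3 <- kymo_from_matrix(matrix(v, ncol = 1), tt2, 10)
  d3 <- integrate_displacement(k3, 10)
  expect_equal(d3$displacement[, 1], trapz_cum(tt2, v))
})

test_that("positions snap to row centers and out-of-range errors", {
  k <- folded_kymo("+Shear", grid = small_grid(t_end = 1))
  d <- integrate_displacement(k, c(8, 242))
  expect_equal(d$y_positions, c(250 / 30, 250 - 250 / 30), tolerance = 1e-10)
  expect_error(integrate_displacement(k, 400), "valid range")
})

test_that("integration is linear in the kymograph", {
  tt <- seq(0, 5, by = 0.1)
  v1 <- sin(tt); v2 <- exp(-tt / 2)
  mk <- function(v) kymo_from_matrix(matrix(v, ncol = 1), tt, 10)
  d12 <- integrate_displacement(mk(2 * v1 + 3 * v2), 10)$displacement
  d1 <- integrate_displacement(mk(v1), 10)$displacement
  d2 <- integrate_displacement(mk(v2), 10)$displacement
  expect_equal(d12, 2 * d1 + 3 * d2)
})

test_that("bin-then-integrate matches integrate-then-average on smooth fields", {
  tt <- seq(0, 10, by = 1 / 12)
  v <- 20 * exp(-tt / 8) * sin(2 * pi * tt / 8)
  k <- kymo_from_matrix(matrix(v, ncol = 1), tt, 10)
  end_binned <- tail(integrate_displacement(bin_kymograph(k, 3), 10)$displacement[, 1], 1)
  end_raw <- tail(integrate_displacement(k, 10)$displacement[, 1], 1)
  # trapezoid-rule error bound scale: h^2/12 * max|v''| * T
  h <- 0.25
  bound <- h^2 / 12 * max(abs(diff(diff(v)) / (1 / 12)^2)) * 10
  expect_lt(abs(end_binned - end_raw), bound + 0.5)
})

test_that("mean velocity series averages positions per time point", {
  tt <- c(0, 1); yp <- c(10, 30, 50)
  k <- kymo_from_matrix(matrix(4, 2, 3), tt, yp)
  expect_true(all(mean_velocity_series(k)$mean_v == 4))
  k2 <- kymo_from_matrix(cbind(rep(3, 2), rep(-3, 2), rep(0, 2)), tt, yp)
  expect_true(all(mean_velocity_series(k2)$mean_v == 0))
  # linear-in-y field: mean is the mean of the 15 row centers = 125
  g <- grid_spec()
  klin <- kymo_from_matrix(matrix(row_centers(g), 2, 15, byrow = TRUE),
                           c(0, 1), row_centers(g))
  expect_equal(mean_velocity_series(klin)$mean_v, c(125, 125))
})

test_that("front estimator recovers the generating wave speed within 5%", {
  for (w in c(50, 150, 290, 500)) {
    k <- folded_kymo("+Shear", wave_speed_initial = w)
    est <- estimate_propagation_speed(k)
    expect_lt(abs(est$speed - w) / w, 0.05)
    expect_gt(est$r_squared, 0.95)
  }
})

test_that("simultaneous onset yields the infinite-speed sentinel", {
  tt <- seq(0, 2, by = 0.1)
  vals <- matrix(0, length(tt), 4)
  vals[tt >= 1, ] <- -10   # all rows switch on together
  k <- kymo_from_matrix(vals, tt, c(10, 20, 30, 40))
  expect_warning(est <- estimate_propagation_speed(k), "infinite")
  expect_identical(est$speed, Inf)
})

test_that("front estimator requires a detectable front", {
  tt <- seq(0, 2, by = 0.1)
  k <- kymo_from_matrix(matrix(1e-3, length(tt), 4), tt, c(10, 20, 30, 40))
  # positive (outward) everywhere: no inward onset anywhere
  expect_error(estimate_propagation_speed(k), "no propagating front")
})
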