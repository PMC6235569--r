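## Damped-sinusoid fitting of the collective y-velocity, reversal detection,
## and the nonparametric condition comparisons.

#' Fit an exponentially decaying sinusoid to a mean-velocity series
#'
#' Model: `v(t) = v0 + A * exp(-t/(2 D)) * sin(2 pi (t - t0)/P)`, fitted to
#' t >= `t_min` by Levenberg-Marquardt least squares. The envelope is
#' parameterized as `exp(-t/(2 D))` so that, combined with the mechanical
#' model's damping map c = k D, the fitted D corresponds exactly to the
#' model pole real part -k/(2c).
#'
#' Initialization: P from the dominant discrete-Fourier peak of the
#' detrended series; a linear solve of the sin/cos basis at that period
#' gives A and t0; D from log-envelope regression on successive absolute
#' extrema. D is reported as `Inf` when the fitted envelope decays by less
#' than 5% over the observation window.
#'
#' @param series an `epi_mean_velocity`, or a list with `times` (h) and
#'   `mean_v` (um/h)
#' @param t_min start of the fit window in hours (default 0; only t >= 0 is
#'   ever used)
#' @return an `epi_sine_fit`: list with `A`, `P`, `D` (possibly `Inf`),
#'   `t0`, `v0`, `rss`, `degenerate` flag, and the underlying `nls` fit
#' @export
fit_damped_sinusoid <- function(series, t_min = 0) {
  t_min <- max(t_min, 0)
  sel <- series$times >= t_min
  tt <- series$times[sel]
  vv <- series$mean_v[sel]
  if (length(tt) < 8L) stop("too few post-shear samples to fit")
  v0_0 <- mean(vv)
  d <- vv - v0_0
  if (stats::sd(vv) < 1e-12 * max(1, abs(v0_0))) {
    return(structure(list(A = 0, P = NA_real_, D = NA_real_, t0 = NA_real_,
                          v0 = v0_0, rss = sum(d^2), degenerate = TRUE,
                          fit = NULL),
                     class = "epi_sine_fit"))
  }
  dt <- stats::median(diff(tt))
  P0 <- dominant_period(d, dt)
  init <- sine_linear_init(tt, d, P0)
  r0 <- envelope_decay_rate(tt, d, P0)
  # a tiny positive start underflows the relative-step numeric Jacobian;
  # exactly 0 gets an absolute step and fits fine
  if (r0 < 1e-6) r0 <- 0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vv ~ v0 + A * exp(-r * tt) * sin(2 * pi * (tt - t0) / P),
      start = list(A = init$A, P = P0, r = r0, t0 = init$t0, v0 = v0_0),
      lower = c(0, dt * 4, 0, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("damped-sinusoid fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  r <- est[["r"]]
  span <- diff(range(tt))
  D <- if (1 - exp(-r * span) < 0.05) Inf else 1 / (2 * r)
  # canonical phase: t0 in [0, P)
  t0 <- est[["t0"]] %% est[["P"]]
  structure(list(A = est[["A"]], P = est[["P"]], D = D, t0 = t0,
                 v0 = est[["v0"]], rss = sum(stats::residuals(fit)^2),
                 degenerate = est[["A"]] < 1e-8 * max(abs(vv)),
                 fit = fit),
            class = "epi_sine_fit")
}

## Period of the dominant DFT peak of a detrended, uniformly sampled series.
#' @keywords internal
dominant_period <- function(d, dt) {
  n <- length(d)
  sp <- Mod(stats::fft(d))[2:floor(n / 2)]
  k <- which.max(sp)  # k cycles over the record
  (n * dt) / k
}

## Linear solve of v ~ B sin(2 pi t/P) + C cos(2 pi t/P) for amplitude/phase.
#' @keywords internal
sine_linear_init <- function(tt, d, P) {
  s <- sin(2 * pi * tt / P); cc <- cos(2 * pi * tt / P)
  co <- stats::coef(stats::lm(d ~ s + cc - 1))
  A <- sqrt(sum(co^2))
  # B sin(th) + C cos(th) = A sin(th + phi), phi = atan2(C, B); t0 = -phi P/(2 pi)
  t0 <- (-atan2(co[2], co[1]) * P / (2 * pi)) %% P
  list(A = max(A, 1e-8), t0 = unname(t0))
}

## Decay rate from log-linear regression on successive absolute extrema.
#' @keywords internal
envelope_decay_rate <- function(tt, d, P) {
  a <- abs(d)
  # local maxima of |detrended signal|
  pk <- which(diff(sign(diff(a))) < 0) + 1L
  pk <- pk[a[pk] > 0.05 * max(a)]
  if (length(pk) < 3L) return(0)
  co <- stats::coef(stats::lm(log(a[pk]) ~ tt[pk]))
  max(-co[[2]], 0)
}

#' Detect velocity reversals (zero crossings) in a mean-velocity series
#'
#' The series is smoothed with a centered moving average, then sign changes
#' are located by linear interpolation between the bracketing samples.
#' Crossings within the deformation transient (first `t_exclude` hours) are
#' excluded.
#'
#' @param series an `epi_mean_velocity` (post-shear samples are used)
#' @param smooth_window moving-average window in samples (default 3)
#' @param t_exclude exclusion window after shear in hours (default 0.5)
#' @return an `epi_reversals`: list with `times` (h, strictly increasing,
#'   possibly empty) and `direction` (`"outward-to-inward"` /
#'   `"inward-to-outward"` per crossing)
#' @export
find_reversals <- function(series, smooth_window = 3L, t_exclude = 0.5) {
  sel <- series$times >= 0
  tt <- series$times[sel]
  vv <- series$mean_v[sel]
  if (smooth_window > 1L) {
    sm <- stats::filter(vv, rep(1 / smooth_window, smooth_window), sides = 2)
    vv <- ifelse(is.na(sm), vv, as.numeric(sm))
  }
  s <- sign(vv)
  # carry the previous sign across exact zeros so each crossing counts once
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (!length(idx))
    return(structure(list(times = numeric(0), direction = character(0)),
                     class = "epi_reversals"))
  times <- vapply(idx, function(i)
    tt[i] + (tt[i + 1] - tt[i]) * vv[i] / (vv[i] - vv[i + 1]), numeric(1))
  dir <- ifelse(vv[idx] > 0, "outward-to-inward", "inward-to-outward")
  keep <- times >= t_exclude
  structure(list(times = times[keep], direction = dir[keep]),
            class = "epi_reversals")
}

#' Nonparametric comparison of a fitted parameter across conditions
#'
#' Omnibus Kruskal-Wallis rank test (with tie correction) across all
#' conditions; pairwise Mann-Whitney U tests are run only when the omnibus
#' p-value is below `alpha`. Pairwise tests use the exact null distribution
#' when both group sizes are at most 8 (and there are no ties), the normal
#' approximation otherwise.
#'
#' @param values named list of numeric replicate vectors, one per condition
#' @param parameter label of the compared parameter (e.g. `"A"`, `"P"`,
#'   `"D"`), recorded in the output
#' @param alpha significance gate for the omnibus test (default 0.05)
#' @return an `epi_comparison`: list with `parameter`, `omnibus`
#'   (`statistic`, `p`), and `pairwise` (data.frame with columns
#'   `condition_a`, `condition_b`, `statistic`, `p`, or NULL when the
#'   omnibus test is not significant)
#' @export
compare_conditions <- function(values, parameter = NA_character_, alpha = 0.05) {
  if (!is.list(values) || length(values) < 2L)
    stop("need replicate values for at least 2 conditions")
  if (is.null(names(values)) || any(names(values) == ""))
    stop("conditions must be named")
  kw <- suppressWarnings(stats::kruskal.test(values))
  stat <- unname(kw$statistic)
  p <- kw$p.value
  if (!is.finite(stat)) { stat <- 0; p <- 1 }  # all observations tied
  pairwise <- NULL
  if (p < alpha) {
    prs <- utils::combn(names(values), 2)
    pairwise <- do.call(rbind, apply(prs, 2, function(pair) {
      x <- values[[pair[1]]]; y <- values[[pair[2]]]
      exact <- length(x) <= 8 && length(y) <= 8
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
      data.frame(condition_a = pair[1], condition_b = pair[2],
                 statistic = unname(wt$statistic), p = wt$p.value)
    }))
    rownames(pairwise) <- NULL
  }
  structure(list(parameter = parameter,
                 omnibus = list(statistic = stat, p = p),
                 alpha = alpha, pairwise = pairwise),
            class = "epi_comparison")
}

#' @export
print.epi_sine_fit <- function(x, ...) {
  cat(sprintf("Damped-sinusoid fit: A = %.4g um/h, P = %.4g h, D = %.4g h, t0 = %.4g h, v0 = %.4g (rss %.3g)%s\n",
              x$A, x$P, x$D, x$t0, x$v0, x$rss,
              if (isTRUE(x$degenerate)) " [degenerate: flat series]" else ""))
  invisible(x)
}

#' @export
print.epi_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison (%s): Kruskal-Wallis chi-sq = %.4g, p = %.4g\n",
              x$parameter, x$omnibus$statistic, x$omnibus$p))
  if (is.null(x$pairwise)) {
    cat("  omnibus not significant at alpha =", x$alpha,
        "-> no pairwise tests\n")
  } else {
    print(x$pairwise)
  }
  invisible(x)
}
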