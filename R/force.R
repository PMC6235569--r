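## Force sensing: spring-constant conversion of the sensing-plank deflection
## and viscoelastic relaxation fitting.

#' Convert sensing-plank displacement to force
#'
#' The sensing plank is a calibrated spring: force = k_s x displacement,
#' with 1 um x 1 N/m = 1 uN.
#'
#' @param trace an `epi_sensing_trace`, or a list/data.frame with `times_s`
#'   and `displacement_um`
#' @param k_s spring constant in N/m (default 0.93)
#' @return an `epi_force_trace`: list with `times_min` (minutes relative to
#'   shear), `force_uN`, `k_s`
#' @examples
#' # 10 um deflection of a 0.93 N/m spring is 9.3 uN
#' @export
displacement_to_force <- function(trace, k_s = 0.93) {
  if (k_s <= 0) stop("k_s must be positive")
  structure(list(times_min = trace$times_s / 60,
                 force_uN = k_s * trace$displacement_um,
                 k_s = k_s),
            class = "epi_force_trace")
}

#' Peak force immediately after shear
#'
#' @param trace an `epi_force_trace` spanning t = 0
#' @return list with `f_max` (uN, maximum over t >= 0) and `t_max` (min)
#' @export
extract_fmax <- function(trace) {
  post <- trace$times_min >= 0
  if (!any(post)) stop("trace has no post-shear samples")
  f <- trace$force_uN[post]
  tt <- trace$times_min[post]
  i <- which.max(f)
  list(f_max = f[i], t_max = tt[i])
}

#' Fit the viscoelastic force relaxation
#'
#' Fits `F(t) = F_inf + (F_MAX - F_inf) * exp(-t/tau)` to the post-shear
#' force by nonlinear least squares (Levenberg-Marquardt, all parameters
#' bounded below by 0). tau is the 63.2% decay time of the decaying span
#' `F_MAX - F_inf`. Initialization: `F_MAX` from the first post-shear
#' sample, `F_inf` from the last, tau from the linearly interpolated
#' 63.2%-crossing of the span. Pre-shear samples are used only to check the
#' baseline (warning when its mean magnitude exceeds 5% of `F_MAX`).
#'
#' @param trace an `epi_force_trace`
#' @param window fit window in minutes after shear (default `c(0, 30)`)
#' @return an `epi_expdecay_fit`: list with `f_max`, `f_inf` (uN), `tau`
#'   (min), `rss`, `tau_crossing` (direct 63.2%-crossing read-out, as a
#'   cross-check) and the underlying `nls` fit
#' @export
fit_exponential_decay <- function(trace, window = c(0, 30)) {
  stopifnot(inherits(trace, "epi_force_trace"))
  sel <- trace$times_min >= window[1] & trace$times_min <= window[2]
  tt <- trace$times_min[sel]
  ff <- trace$force_uN[sel]
  if (length(tt) < 10L) stop("need at least 10 post-shear samples to fit")
  if (diff(range(ff)) == 0) stop("constant trace: nothing to fit")
  f0 <- ff[1]; finf0 <- ff[length(ff)]
  tau0 <- tau_crossing_time(tt, ff, f0, finf0)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(tt)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ff ~ f_inf + (f_max - f_inf) * exp(-tt / tau),
      start = list(f_max = f0, f_inf = max(finf0, 0), tau = tau0),
      lower = c(0, 0, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("exponential fit did not converge (starts: f_max=", signif(f0, 4),
           ", f_inf=", signif(finf0, 4), ", tau=", signif(tau0, 4), "): ",
           conditionMessage(e)))
  pre <- trace$times_min < 0
  est <- stats::coef(fit)
  if (any(pre)) {
    base <- mean(abs(trace$force_uN[pre]))
    if (base > 0.05 * est[["f_max"]])
      warning("pre-shear baseline is ", signif(base, 3),
              " uN, above 5% of F_MAX")
  }
  structure(list(f_max = est[["f_max"]], f_inf = est[["f_inf"]],
                 tau = est[["tau"]],
                 rss = sum(stats::residuals(fit)^2),
                 tau_crossing = tau_crossing_time(tt, ff, est[["f_max"]],
                                                 est[["f_inf"]]),
                 fit = fit),
            class = "epi_expdecay_fit")
}

## Direct read-out of the 63.2% decay time: first crossing of
## f_inf + (f_max - f_inf)/e, linearly interpolated.
#' @keywords internal
tau_crossing_time <- function(tt, ff, f_max, f_inf) {
  target <- f_inf + (f_max - f_inf) * exp(-1)
  below <- which(ff <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(tt[1])
  # linear interpolation between the bracketing samples
  tt[i - 1] + (tt[i] - tt[i - 1]) * (ff[i - 1] - target) / (ff[i - 1] - ff[i])
}

#' @export
print.epi_expdecay_fit <- function(x, ...) {
  cat(sprintf("Force relaxation fit: F_MAX = %.4g uN, F_inf = %.4g uN, tau = %.4g min (rss %.3g)\n",
              x$f_max, x$f_inf, x$tau, x$rss))
  invisible(x)
}
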