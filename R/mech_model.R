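## Lumped mechanical circuit for the y-direction response of the sheared
## epithelium: a Maxwell branch (spring k in series with damper c) in
## parallel with an inerter b, driven by a step of inward shear force.
## State: node velocity v and Maxwell branch force F_m:
##   b dv/dt   = F(t) - F_m
##   dF_m/dt   = k v - (k/c) F_m
## Characteristic polynomial s^2 + (k/c) s + (k/b) = 0, so the natural
## frequency is omega0 = sqrt(k/b) and the damping ratio
## zeta = sqrt(k b)/(2 c).

#' Construct the spring-damper-inerter model
#'
#' @param k stiffness (force/length, arbitrary units; held constant across
#'   conditions)
#' @param c damping (force.time/length); the damping map from the fitted
#'   oscillation is c = k D
#' @param b inertance (force.time^2/length); `Inf` is accepted and realized
#'   as a large finite sentinel, `1e4` times the oscillatory value for an
#'   8 h intrinsic period, which drives the strongly overdamped
#'   (non-oscillating) regime
#' @param f_int intrinsic step force magnitude (default 1; only normalized
#'   output is compared across conditions)
#' @param f_ratio extrinsic-to-intrinsic force ratio F_EXT/F_INT (default 4)
#' @param condition optional condition label
#' @return an `epi_mech_model`
#' @export
mech_model <- function(k, c, b, f_int = 1, f_ratio = 4,
                       condition = NA_character_) {
  if (k <= 0 || c <= 0) stop("k and c must be positive")
  b_sentinel <- FALSE
  if (is.infinite(b)) {
    b <- 1e4 * k * 8^2 / (4 * pi^2)
    b_sentinel <- TRUE
  }
  if (b <= 0) stop("b must be positive or Inf")
  structure(list(k = k, c = c, b = b, b_sentinel = b_sentinel,
                 f_int = f_int, f_ext = f_ratio * f_int, f_ratio = f_ratio,
                 condition = condition),
            class = "epi_mech_model")
}

#' State-space description of the model
#'
#' @param m an `epi_mech_model`
#' @return list with the system matrix `A` (state `c(v, F_m)`), input vector
#'   `B` (force enters as F/b on v), natural frequency `omega0 = sqrt(k/b)`,
#'   damping ratio `zeta = sqrt(k b)/(2 c)`, the complex `poles`, and the
#'   terminal creep velocity per unit force `1/c`
#' @export
equations_of_motion <- function(m) {
  stopifnot(inherits(m, "epi_mech_model"))
  A <- matrix(c(0, -1 / m$b,
                m$k, -m$k / m$c), nrow = 2, byrow = TRUE)
  omega0 <- sqrt(m$k / m$b)
  zeta <- sqrt(m$k * m$b) / (2 * m$c)
  disc <- as.complex((m$k / m$c)^2 - 4 * m$k / m$b)
  poles <- (-(m$k / m$c) + c(1, -1) * sqrt(disc)) / 2
  list(A = A, B = c(1 / m$b, 0), omega0 = omega0, zeta = zeta,
       poles = poles, creep_per_force = 1 / m$c)
}

#' Natural (intrinsic) period of the spring-inerter pair
#'
#' `P = 2 pi sqrt(b/k)`; the inverse map is `b = k P^2/(4 pi^2)`.
#'
#' @param m an `epi_mech_model`
#' @return period in hours (`Inf` when the model was built with `b = Inf`)
#' @export
natural_period <- function(m) {
  stopifnot(inherits(m, "epi_mech_model"))
  if (isTRUE(m$b_sentinel)) return(Inf)
  2 * pi * sqrt(m$b / m$k)
}

#' Simulate the step response with a fixed-step RK4 integrator
#'
#' From rest, a constant inward force (negative sign convention) is applied
#' at t = 0 and the state is integrated with a classical 4th-order
#' Runge-Kutta scheme at fixed step `dt` (deterministic, bit-reproducible).
#'
#' @param m an `epi_mech_model`
#' @param F_total total step force magnitude (applied inward, i.e. as
#'   `-F_total`); default `f_int + f_ext` of the model
#' @param t_end simulation end time in hours
#' @param dt step in hours; default P/1000 where P is the natural period;
#'   must be at most P/100
#' @return an `epi_sim`: list with `times`, `velocity`,
#'   `velocity_detrended` (velocity minus the Maxwell terminal creep
#'   -F_total/c, whose zero crossings are exactly half a damped period
#'   apart), `displacement`, `normalized` flag and the model
#' @export
simulate_step_response <- function(m, F_total = m$f_int + m$f_ext,
                                   t_end = 24, dt = NULL) {
  stopifnot(inherits(m, "epi_mech_model"))
  eq <- equations_of_motion(m)
  P_lim <- 2 * pi / eq$omega0
  if (is.null(dt)) dt <- P_lim / 1000
  if (dt > P_lim / 100)
    stop("step size ", signif(dt, 3), " h too coarse for stability; use dt <= ",
         signif(P_lim / 100, 3), " h")
  F_in <- -F_total  # inward step
  n <- floor(t_end / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  A <- eq$A; B <- eq$B * F_in
  deriv <- function(x) A %*% x + B
  v <- numeric(n); x_disp <- numeric(n)
  state <- c(0, 0)
  for (i in seq_len(n - 1L)) {
    k1 <- deriv(state)
    k2 <- deriv(state + dt / 2 * k1)
    k3 <- deriv(state + dt / 2 * k2)
    k4 <- deriv(state + dt * k3)
    state <- state + dt / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4)
    v[i + 1L] <- state[1]
    x_disp[i + 1L] <- x_disp[i] + dt * (v[i] + v[i + 1L]) / 2
  }
  v_ss <- F_in / m$c
  structure(list(times = times, velocity = v,
                 velocity_detrended = v - v_ss,
                 displacement = x_disp,
                 normalized = FALSE, model = m, F_total = F_total),
            class = "epi_sim")
}

#' Closed-form step response (analytic oracle)
#'
#' Exact solution of the linear system for a constant force applied at
#' t = 0 from rest, via the roots of `s^2 + (k/c) s + k/b`. Handles the
#' under-, over- and critically damped branches (repeated roots within a
#' relative tolerance use the critically damped formula).
#'
#' @param m an `epi_mech_model`
#' @param F_total total step force magnitude (applied inward)
#' @param times evaluation times in hours
#' @return an `epi_sim` with exact `velocity`, `velocity_detrended` and
#'   `displacement`
#' @export
closed_form_response <- function(m, F_total = m$f_int + m$f_ext, times) {
  stopifnot(inherits(m, "epi_mech_model"))
  F_in <- -F_total
  k <- m$k; cc <- m$c; b <- m$b
  v_ss <- F_in / cc
  sigma <- k / (2 * cc)          # half the (k/c) damping coefficient
  disc <- sigma^2 - k / b
  w0 <- -v_ss                    # transient initial value: v(0) - v_ss
  dw0 <- F_in / b                # v'(0)
  tpos <- pmax(times, 0)
  if (abs(disc) < 1e-12 * max(sigma^2, k / b)) {
    # critically damped: w = (a1 + a2 t) e^{-sigma t}
    a1 <- w0; a2 <- dw0 + sigma * w0
    w <- (a1 + a2 * tpos) * exp(-sigma * tpos)
    # integral of w from 0 to t
    iw <- (a1 / sigma + a2 / sigma^2) -
      exp(-sigma * tpos) * ((a1 + a2 * tpos) / sigma + a2 / sigma^2)
  } else if (disc < 0) {
    wd <- sqrt(-disc)
    c1 <- w0; c2 <- (dw0 + sigma * w0) / wd
    e <- exp(-sigma * tpos)
    w <- e * (c1 * cos(wd * tpos) + c2 * sin(wd * tpos))
    den <- sigma^2 + wd^2
    icos <- (e * (-sigma * cos(wd * tpos) + wd * sin(wd * tpos)) + sigma) / den
    isin <- (e * (-sigma * sin(wd * tpos) - wd * cos(wd * tpos)) + wd) / den
    iw <- c1 * icos + c2 * isin
  } else {
    rt <- sqrt(disc)
    r1 <- -sigma + rt; r2 <- -sigma - rt
    a2 <- (dw0 - r1 * w0) / (r2 - r1); a1 <- w0 - a2
    w <- a1 * exp(r1 * tpos) + a2 * exp(r2 * tpos)
    iw <- a1 * (exp(r1 * tpos) - 1) / r1 + a2 * (exp(r2 * tpos) - 1) / r2
  }
  v <- ifelse(times < 0, 0, v_ss + w)
  disp <- ifelse(times < 0, 0, v_ss * tpos + iw)
  structure(list(times = times, velocity = v,
                 velocity_detrended = ifelse(times < 0, 0, w),
                 displacement = disp,
                 normalized = FALSE, model = m, F_total = F_total),
            class = "epi_sim")
}

#' Build a mechanical model from fitted oscillation parameters
#'
#' Parameter maps: damping `c = k D` from the fitted envelope; inertance
#' `b = k P^2/(4 pi^2)` from the fitted period when the mechanical signal
#' propagates, and the `b = Inf` sentinel (realized as `1e4` times the
#' oscillatory value, strongly overdamped) when the propagation rate is
#' zero. When the fitted D is infinite but propagation is finite
#' (undamped oscillation over the window), c is set so the damping ratio
#' equals `zeta_floor`, with a warning.
#'
#' @param k stiffness, held constant across conditions
#' @param fit an `epi_sine_fit` (fields `P` and `D` are used)
#' @param propagation mechanical signal propagation rate in um/h (0 means
#'   no propagation)
#' @param f_int intrinsic step force (default 1)
#' @param f_ratio F_EXT/F_INT ratio (default 4)
#' @param sheared logical: is the extrinsic force applied (default TRUE)
#' @param zeta_floor damping-ratio floor for the undamped case (default 0.02)
#' @param P_default period used for the sentinel-b magnitude and when the
#'   fit carries no period (non-oscillating conditions); default 8 h
#' @return an `epi_mech_model`; its `f_ext` is 0 when `sheared = FALSE`
#' @export
params_from_fit <- function(k, fit, propagation, f_int = 1, f_ratio = 4,
                            sheared = TRUE, zeta_floor = 0.02,
                            P_default = 8) {
  if (k <= 0) stop("k must be positive")
  P <- if (!is.null(fit$P) && is.finite(fit$P)) fit$P else P_default
  b_osc <- k * P^2 / (4 * pi^2)
  b <- if (propagation > 0) b_osc else Inf
  if (is.finite(fit$D)) {
    cc <- k * fit$D
  } else {
    b_num <- if (is.finite(b)) b else 1e4 * k * 8^2 / (4 * pi^2)
    cc <- sqrt(k * b_num) / (2 * zeta_floor)
    if (propagation > 0)
      warning("fitted damping time is infinite with finite propagation; ",
              "c set so the damping ratio equals the floor ", zeta_floor)
  }
  mech_model(k, cc, b, f_int = f_int,
             f_ratio = if (sheared) f_ratio else 0)
}

#' Normalize a simulated response
#'
#' Scales the response so the maximum absolute velocity is 1 (displacement
#' and the detrended velocity are scaled by the same factor, so sign
#' patterns and reversal times are unchanged).
#'
#' @param r an `epi_sim`
#' @return the normalized `epi_sim`
#' @export
normalize_response <- function(r) {
  stopifnot(inherits(r, "epi_sim"))
  mx <- max(abs(r$velocity))
  if (mx == 0) stop("all-zero response cannot be normalized")
  r$velocity <- r$velocity / mx
  r$velocity_detrended <- r$velocity_detrended / mx
  r$displacement <- r$displacement / mx
  r$normalized <- TRUE
  r
}

#' Zero crossings of a simulated velocity
#'
#' Linear-interpolated sign changes of the (by default detrended) simulated
#' velocity; used to read reversal times off a simulation.
#'
#' @param r an `epi_sim`
#' @param detrended use the detrended velocity (default TRUE; raw velocity
#'   crossings are offset by the Maxwell creep)
#' @return numeric vector of crossing times (h)
#' @export
sim_reversal_times <- function(r, detrended = TRUE) {
  stopifnot(inherits(r, "epi_sim"))
  v <- if (detrended) r$velocity_detrended else r$velocity
  tt <- r$times
  keep <- tt > 0
  v <- v[keep]; tt <- tt[keep]
  idx <- which(v[-1] * v[-length(v)] < 0)
  vapply(idx, function(i)
    tt[i] + (tt[i + 1] - tt[i]) * v[i] / (v[i] - v[i + 1]), numeric(1))
}

#' @export
print.epi_mech_model <- function(x, ...) {
  eq <- equations_of_motion(x)
  cat(sprintf("Mechanical model%s: k = %g, c = %g, b = %g%s\n",
              if (is.na(x$condition)) "" else paste0(" (", x$condition, ")"),
              x$k, x$c, x$b,
              if (isTRUE(x$b_sentinel)) " (Inf sentinel)" else ""))
  cat(sprintf("  omega0 = %.4g /h, zeta = %.4g, natural period = %.4g h\n",
              eq$omega0, eq$zeta, natural_period(x)))
  invisible(x)
}

#' Quick-look plot of a simulated response
#' @param x an `epi_sim`
#' @param ... passed to [graphics::plot()]
#' @export
plot.epi_sim <- function(x, ...) {
  graphics::plot(x$times, x$velocity, type = "l",
                 xlab = "time (h)",
                 ylab = if (x$normalized) "normalized velocity" else "velocity",
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
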