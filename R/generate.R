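## Synthetic velocity fields and sensing traces emulating the sheared
## monolayer measurements. All closed-form signal math lives in small
## internal helpers so that tests can compare generated data against the
## exact expressions.

#' @keywords internal
amplitude_envelope <- function(grid) {
  # linear ramp: cells furthest from the shear plane move the most
  n <- grid$n_rows
  if (n == 1L) return(1)
  0.3 + 0.7 * (seq_len(n) - 1) / (n - 1)
}

## Phase bookkeeping for the staggered reversal fronts. Each row's sinusoid
## is delayed by delta_i = y_i / wave_speed_reversal; the global phase t0 is
## chosen analytically so the envelope-weighted mean velocity crosses zero at
## first_reversal - P/2 + n*P/2 (3, 7, 11, 15 h for the defaults).
#' @keywords internal
oscillation_phase <- function(preset, grid) {
  y <- row_centers(grid)
  env <- amplitude_envelope(grid)
  P <- preset$osc_period
  delta <- if (is.finite(preset$wave_speed_reversal))
    y / preset$wave_speed_reversal else rep(0, length(y))
  S <- sum(env * exp(-1i * 2 * pi * delta / P))
  # mean over rows is Mod(S)/n * sin(2 pi (t - t0 - delta_eff)/P) once all
  # rows are active: the effective delay is minus the argument of S
  delta_eff <- -(P / (2 * pi)) * Arg(S)
  t0 <- preset$first_reversal - P / 2 - delta_eff
  list(delta = delta, delta_eff = delta_eff, t0 = t0,
       mean_amplitude = preset$osc_amplitude * Mod(S) / grid$n_rows)
}

## Exact noiseless y-velocity for the top plank: rows x times matrix, um/h.
#' @keywords internal
v_signal_matrix <- function(preset, grid, times) {
  y <- row_centers(grid)
  env <- amplitude_envelope(grid)
  A <- preset$osc_amplitude
  out <- matrix(0, nrow = grid$n_rows, ncol = length(times))
  if (A <= 0 || preset$wave_speed_initial <= 0) return(out)
  ph <- oscillation_phase(preset, grid)
  t_on <- y / preset$wave_speed_initial
  damp <- if (is.finite(preset$osc_damping_D))
    exp(-pmax(times, 0) / (2 * preset$osc_damping_D)) else rep(1, length(times))
  for (i in seq_len(grid$n_rows)) {
    s <- A * env[i] * damp *
      sin(2 * pi * (times - ph$delta[i] - ph$t0) / preset$osc_period)
    s[times < t_on[i]] <- 0
    out[i, ] <- s
  }
  out
}

## Exact noiseless x-velocity (both planks share it): deformation-zone
## recoil opposite the shear, plus the extended-zone x-oscillation for
## conditions with stabilized actin.
#' @keywords internal
u_signal_matrix <- function(preset, grid, times) {
  y <- row_centers(grid)
  out <- matrix(0, nrow = grid$n_rows, ncol = length(times))
  if (preset$deform_peak_speed > 0 && preset$deform_zone_width > 0) {
    taper <- pmax(0, 1 - y / preset$deform_zone_width)
    # transient recoil: decays with deform_decay, ceases by ~3 h
    tt <- exp(-times / preset$deform_decay)
    tt[times < 0 | times > 3] <- 0
    out <- out - preset$deform_peak_speed * outer(taper, tt)
  }
  if (isTRUE(preset$x_osc) && preset$osc_amplitude > 0 &&
      preset$wave_speed_initial > 0) {
    ph <- oscillation_phase(preset, grid)
    taper <- pmax(0, 1 - y / preset$x_osc_zone)
    damp <- if (is.finite(preset$osc_damping_D))
      exp(-pmax(times, 0) / (2 * preset$osc_damping_D)) else rep(1, length(times))
    t_on <- y / preset$wave_speed_initial
    for (i in seq_len(grid$n_rows)) {
      if (taper[i] <= 0) next
      s <- 0.3 * preset$osc_amplitude * taper[i] * damp *
        sin(2 * pi * (times - ph$delta[i] - ph$t0) / preset$osc_period)
      s[times < t_on[i]] <- 0
      out[i, ] <- out[i, ] + s
    }
  }
  out
}

#' Generate a synthetic PIV velocity-field series for both planks
#'
#' Emulates the measured response of a sheared monolayer: an inward
#' y-direction wave starting at the shear plane and propagating outward at
#' `wave_speed_initial`, long-term damped y-oscillations (period
#' `osc_period`, envelope `exp(-t/(2 D))`) whose amplitude increases with
#' distance from the shear plane, reversal fronts staggered at
#' `wave_speed_reversal`, and a transient x-direction recoil opposite the
#' shear confined to the deformation zone. The two planks are antisymmetric
#' in v (outward motion has opposite image-frame sign) up to independent
#' Gaussian noise per PIV cell.
#'
#' @param preset an `epi_preset` (see [make_condition_preset()])
#' @param grid an `epi_grid` (default [grid_spec()])
#' @param seed integer RNG seed; the same seed reproduces the series
#'   bit-for-bit
#' @return an object of class `epi_field_series`: a list with elements
#'   `fields` (list of `epi_field`, one per plank per frame, each holding
#'   `time` (h), `plank` (`"top"`/`"bottom"`), `u` and `v` velocity matrices
#'   (rows x cols, um/h) and the grid) and `ground_truth` (all generating
#'   parameters plus derived phase constants, for recovery tests)
#' @examples
#' p <- make_condition_preset("+Shear", noise_sd = 0)
#' s <- generate_velocity_series(p, grid_spec(), seed = 1)
#' length(s$fields)
#' @export
generate_velocity_series <- function(preset, grid = grid_spec(), seed = preset$seed) {
  stopifnot(inherits(preset, "epi_preset"), inherits(grid, "epi_grid"))
  if (preset$noise_sd < 0) stop("noise_sd must be nonnegative")
  times <- frame_times(grid)
  v_sig <- v_signal_matrix(preset, grid, times)
  u_sig <- u_signal_matrix(preset, grid, times)
  set.seed(as.integer(seed))
  fields <- vector("list", 2L * length(times))
  k <- 0L
  for (j in seq_along(times)) {
    for (plank in c("top", "bottom")) {
      sgn <- if (plank == "top") 1 else -1
      u <- matrix(rep(u_sig[, j], grid$n_cols), nrow = grid$n_rows)
      v <- matrix(rep(sgn * v_sig[, j], grid$n_cols), nrow = grid$n_rows)
      if (preset$noise_sd > 0) {
        u <- u + matrix(stats::rnorm(length(u), 0, preset$noise_sd), nrow = grid$n_rows)
        v <- v + matrix(stats::rnorm(length(v), 0, preset$noise_sd), nrow = grid$n_rows)
      }
      k <- k + 1L
      fields[[k]] <- structure(
        list(time = times[j], plank = plank, u = u, v = v, grid = grid),
        class = "epi_field")
    }
  }
  ph <- oscillation_phase(preset, grid)
  gt <- list(
    kind = "velocity_series", condition = preset$name,
    preset = unclass(preset), seed = as.integer(seed),
    n_frames = length(times),
    t0 = ph$t0, delta_eff = ph$delta_eff,
    mean_amplitude = ph$mean_amplitude,
    envelope = amplitude_envelope(grid),
    grid = unclass(grid))
  structure(list(fields = fields, ground_truth = gt),
            class = "epi_field_series")
}

#' Generate a synthetic sensing-plank displacement trace
#'
#' The sensing plank is deflected by the resistive force of the sheared
#' monolayer; after the shear step the force relaxes exponentially with time
#' constant `tau_force` toward a plateau. Displacement is zero before shear,
#' and for t >= 0 equals
#' `(f_max/k_s) * ((1 - plateau) * exp(-t/tau) + plateau)` plus Gaussian
#' noise.
#'
#' @param preset an `epi_preset` with a finite `tau_force`
#' @param f_max peak force in uN (arbitrary scale)
#' @param seed integer RNG seed
#' @param k_s sensing spring constant in N/m (default 0.93); 1 um deflection
#'   of a 1 N/m spring is 1 uN
#' @param noise_sd displacement noise sd in um; default 5% of the decaying
#'   displacement span, 0 disables noise
#' @param t_min,t_max trace window in minutes relative to shear
#' @return an object of class `epi_sensing_trace`: list with `times_s`
#'   (seconds relative to shear), `displacement_um`, and `ground_truth`
#' @examples
#' p <- make_condition_preset("+Shear")
#' tr <- generate_sensing_trace(p, f_max = 1, seed = 1, noise_sd = 0)
#' @export
generate_sensing_trace <- function(preset, f_max, seed = preset$seed,
                                   k_s = 0.93,
                                   noise_sd = NULL,
                                   t_min = -5, t_max = 30) {
  stopifnot(inherits(preset, "epi_preset"))
  if (is.na(preset$tau_force))
    stop("condition '", preset$name, "' has no force-relaxation stage ",
         "(no applied shear step); skip the force analysis for it")
  if (f_max <= 0) stop("f_max must be positive")
  if (k_s <= 0) stop("k_s must be positive")
  tau <- preset$tau_force
  plateau <- preset$force_plateau
  d_peak <- f_max / k_s
  if (is.null(noise_sd)) noise_sd <- 0.05 * d_peak * (1 - plateau)
  times_s <- seq(t_min * 60, t_max * 60, by = 30)
  t_minute <- times_s / 60
  disp <- ifelse(t_minute < 0, 0,
                 d_peak * ((1 - plateau) * exp(-t_minute / tau) + plateau))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    disp <- disp + stats::rnorm(length(disp), 0, noise_sd)
  }
  gt <- list(kind = "sensing_trace", condition = preset$name,
             f_max = f_max, k_s = k_s, tau = tau, plateau = plateau,
             noise_sd = noise_sd, seed = as.integer(seed))
  structure(list(times_s = times_s, displacement_um = disp,
                 ground_truth = gt),
            class = "epi_sensing_trace")
}

#' Write a velocity-field series as long-format CSV
#'
#' Columns: `time_h, plank, row, col, y_um, u_um_per_h, v_um_per_h`.
#'
#' @param series an `epi_field_series` or list of `epi_field`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_velocity_csv <- function(series, path) {
  fields <- if (inherits(series, "epi_field_series")) series$fields else series
  y <- row_centers(fields[[1]]$grid)
  tabs <- lapply(fields, function(f) {
    nr <- f$grid$n_rows; nc <- f$grid$n_cols
    data.frame(time_h = f$time, plank = f$plank,
               row = rep(seq_len(nr), nc),
               col = rep(seq_len(nc), each = nr),
               y_um = rep(y, nc),
               u_um_per_h = as.vector(f$u),
               v_um_per_h = as.vector(f$v))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Write a sensing trace as CSV (`time_s, displacement_um`)
#' @param trace an `epi_sensing_trace`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_sensing_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times_s,
                              displacement_um = trace$displacement_um),
                   path, row.names = FALSE)
  invisible(path)
}

## JSON cannot carry Inf; encode as the string "Inf" on the way out and
## restore on the way in, recursively.
#' @keywords internal
encode_inf <- function(x) {
  if (is.list(x)) return(lapply(x, encode_inf))
  if (is.numeric(x) && any(is.infinite(x)))
    return(ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"), as.character(x)))
  x
}

#' @keywords internal
decode_inf <- function(x) {
  if (is.list(x)) return(lapply(x, decode_inf))
  if (is.character(x) && length(x) &&
      all(!is.na(suppressWarnings(as.numeric(x)))))
    return(as.numeric(x))
  x
}

#' Write generator ground truth to a JSON sidecar
#' @param gt a ground-truth list (from a generator output)
#' @param path output JSON path
#' @return the path, invisibly
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(encode_inf(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path JSON path written by [write_ground_truth()]
#' @return the ground-truth list, with numeric vectors and Inf restored
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  decode_inf(x)
}
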