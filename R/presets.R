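#' @keywords internal
condition_names <- function() c("+Shear", "-Shear", "+Blebb", "+Jasp", "T151")

#' Experimental condition presets
#'
#' Each condition of the shear experiments is encoded as a parameter set for
#' the synthetic generator and the mechanical model:
#'
#' * `+Shear`: untreated MDCK monolayer with 100 um applied shear. Collective
#'   y-oscillation at 30 um/h cell velocity, 8 h period, damped; inward wave
#'   front at 290 um/h, reversal fronts at 80-100 um/h (default 90); force
#'   relaxation tau = 3.7 min; deformation-zone x-motion within 50 um.
#' * `-Shear`: spontaneous oscillation without applied shear: 9 um/h
#'   amplitude, same period/damping; no deformation zone and no force step.
#' * `+Blebb`: myosin II inhibited (blebbistatin): no y-oscillation, no
#'   propagation, fast force relaxation tau = 1.3 min; passive x-deformation
#'   persists at reduced magnitude.
#' * `+Jasp`: actin filaments stabilized (jasplakinolide): 10 um/h amplitude,
#'   undamped over the observation window, slower initial front (80 um/h),
#'   slow force relaxation tau = 6.2 min, plus a low-amplitude x-direction
#'   oscillation in an extended (100 um) zone.
#' * `T151`: E-cadherin extracellular-domain mutant: no y-oscillation, no
#'   propagation; force relaxation indistinguishable from `+Shear`.
#'
#' Speeds are um/h, periods and damping times hours, tau minutes. An `Inf`
#' damping time means no envelope decay; `tau_force = NA` means the condition
#' has no force-relaxation stage (no applied shear step). Any field can be
#' overridden via `...`.
#'
#' @param name condition name, one of `"+Shear"`, `"-Shear"`, `"+Blebb"`,
#'   `"+Jasp"`, `"T151"`
#' @param ... named overrides of preset fields
#' @return an object of class `epi_preset`
#' @examples
#' p <- make_condition_preset("+Shear")
#' p$wave_speed_initial  # 290 um/h
#' @export
make_condition_preset <- function(name, ...) {
  if (length(name) != 1L || !name %in% condition_names())
    stop("unknown condition '", paste(name, collapse = ","),
         "'; supported conditions: ",
         paste(condition_names(), collapse = ", "))
  base <- list(
    name = name,
    osc_amplitude = 30, osc_period = 8, osc_damping_D = 4,
    first_reversal = 7,
    wave_speed_initial = 290, wave_speed_reversal = 90,
    deform_zone_width = 50, deform_peak_speed = 30, deform_decay = 1,
    x_osc = FALSE, x_osc_zone = 100,
    tau_force = 3.7, force_plateau = 0.2, f_ext_to_f_int = 4,
    noise_sd = 3, seed = 1L)
  mods <- switch(name,
    "+Shear" = list(),
    "-Shear" = list(osc_amplitude = 9, deform_peak_speed = 0,
                    deform_zone_width = 0, tau_force = NA_real_),
    "+Blebb" = list(osc_amplitude = 0, osc_damping_D = Inf,
                    wave_speed_initial = 0, tau_force = 1.3,
                    deform_peak_speed = 15),
    "+Jasp"  = list(osc_amplitude = 10, osc_damping_D = Inf,
                    wave_speed_initial = 80, tau_force = 6.2,
                    x_osc = TRUE),
    "T151"   = list(osc_amplitude = 0, osc_damping_D = Inf,
                    wave_speed_initial = 0, tau_force = 3.7,
                    deform_peak_speed = 15))
  base[names(mods)] <- mods
  user <- list(...)
  if (length(user)) {
    bad <- setdiff(names(user), names(base))
    if (length(bad))
      stop("unknown preset field(s): ", paste(bad, collapse = ", "))
    base[names(user)] <- user
  }
  p <- structure(base, class = "epi_preset")
  validate_preset(p)
  p
}

#' @keywords internal
validate_preset <- function(p) {
  pos <- c("osc_period", "osc_damping_D", "wave_speed_reversal",
           "deform_decay")
  for (f in pos)
    if (!is.na(p[[f]]) && p[[f]] <= 0)
      stop("preset field ", f, " must be positive (or Inf)")
  nonneg <- c("osc_amplitude", "wave_speed_initial", "deform_zone_width",
              "deform_peak_speed", "noise_sd")
  for (f in nonneg)
    if (p[[f]] < 0) stop("preset field ", f, " must be nonnegative")
  if (!is.na(p$tau_force) && p$tau_force <= 0)
    stop("tau_force must be positive or NA")
  invisible(p)
}

#' @export
print.epi_preset <- function(x, ...) {
  cat(sprintf("Condition preset '%s'\n", x$name))
  cat(sprintf("  y-oscillation: A = %g um/h, P = %g h, D = %g h, first reversal %g h\n",
              x$osc_amplitude, x$osc_period, x$osc_damping_D, x$first_reversal))
  cat(sprintf("  fronts: initial %g um/h, reversal %g um/h\n",
              x$wave_speed_initial, x$wave_speed_reversal))
  cat(sprintf("  deformation zone: %g um at %g um/h; force tau = %g min\n",
              x$deform_zone_width, x$deform_peak_speed, x$tau_force))
  invisible(x)
}
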