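## Kymograph construction and analysis: horizontal averaging of PIV fields,
## folding over the shear plane, temporal binning, integration to
## displacement, and wave-front speed estimation.

#' @keywords internal
new_kymograph <- function(component, times, y_positions, values,
                          folded = FALSE, bin_width = 1L, plank = NA_character_) {
  stopifnot(nrow(values) == length(times), ncol(values) == length(y_positions))
  structure(list(component = component, times = times,
                 y_positions = y_positions, values = values,
                 folded = folded, bin_width = as.integer(bin_width),
                 plank = plank),
            class = "epi_kymo")
}

#' Build a kymograph from a velocity-field series
#'
#' Each PIV frame is collapsed by horizontal (column-wise) averaging of the
#' chosen velocity component, turning an 18 x 15 field into a 1 x 15 profile;
#' stacking profiles over time gives the time x position kymograph.
#'
#' @param fields list of `epi_field` (one plank), or an `epi_field_series`
#'   together with `plank` to select one plank
#' @param component `"x"` (u) or `"y"` (v)
#' @param plank when `fields` is a full series: `"top"` or `"bottom"`
#' @return an `epi_kymo` (unfolded), values in um/h, rows = times,
#'   columns = row-center distances from the shear plane
#' @export
build_kymograph <- function(fields, component = c("y", "x"), plank = NULL) {
  component <- match.arg(component)
  if (inherits(fields, "epi_field_series")) {
    if (is.null(plank)) stop("supply plank = 'top' or 'bottom' for a full series")
    fields <- Filter(function(f) f$plank == plank, fields$fields)
  }
  if (!length(fields)) stop("empty field sequence")
  g <- fields[[1]]$grid
  same <- vapply(fields, function(f) identical(unclass(f$grid), unclass(g)),
                 logical(1))
  if (!all(same)) stop("fields do not share a common grid")
  times <- vapply(fields, function(f) f$time, numeric(1))
  if (is.unsorted(times, strictly = TRUE)) stop("field times must be strictly increasing")
  vals <- t(vapply(fields, function(f) {
    m <- if (component == "y") f$v else f$u
    rowMeans(m)
  }, numeric(g$n_rows)))
  new_kymograph(component, times, row_centers(g), vals,
                folded = FALSE, plank = fields[[1]]$plank)
}

#' Fold two plank kymographs over the shear plane
#'
#' Exploits the symmetry of the response: for the y-component the bottom
#' plank's sign is flipped so that positive means outward (away from the
#' shear plane) on both planks, then rows equidistant from the shear plane
#' are averaged. The x-component is averaged without a sign flip.
#'
#' @param top,bottom unfolded `epi_kymo` of the same component and shape
#' @return a folded `epi_kymo`
#' @export
fold_kymograph <- function(top, bottom) {
  stopifnot(inherits(top, "epi_kymo"), inherits(bottom, "epi_kymo"))
  if (top$component != bottom$component)
    stop("component mismatch: ", top$component, " vs ", bottom$component)
  if (isTRUE(top$folded) || isTRUE(bottom$folded))
    stop("inputs must be unfolded kymographs")
  if (!identical(dim(top$values), dim(bottom$values)) ||
      !isTRUE(all.equal(top$times, bottom$times)) ||
      !isTRUE(all.equal(top$y_positions, bottom$y_positions)))
    stop("kymograph shape/axis mismatch between planks")
  sgn <- if (top$component == "y") -1 else 1
  vals <- (top$values + sgn * bottom$values) / 2
  new_kymograph(top$component, top$times, top$y_positions, vals,
                folded = TRUE)
}

#' Bin a kymograph in time
#'
#' Non-overlapping blocks of `n` consecutive frames are averaged (e.g. three
#' 5-min frames into one 15-min bin); a trailing partial block is averaged
#' over its actual frame count. Bin times are the mean frame times of each
#' block.
#'
#' @param k an `epi_kymo`
#' @param n frames per bin (default 3); `n = 1` is the identity
#' @return a binned `epi_kymo`
#' @export
bin_kymograph <- function(k, n = 3L) {
  stopifnot(inherits(k, "epi_kymo"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L) return(k)
  nt <- length(k$times)
  grp <- (seq_len(nt) - 1L) %/% n
  times <- as.vector(tapply(k$times, grp, mean))
  vals <- apply(k$values, 2, function(col) as.vector(tapply(col, grp, mean)))
  vals <- matrix(vals, nrow = length(times))
  new_kymograph(k$component, times, k$y_positions, vals,
                folded = k$folded, bin_width = k$bin_width * n, plank = k$plank)
}

#' Integrate a velocity kymograph into displacement traces
#'
#' Cumulative trapezoidal integration of velocity over time at selected
#' distances from the shear plane, zeroed at the first post-shear frame.
#' Requested positions snap to the nearest row center and must lie within
#' half a row height of one.
#'
#' @param k an `epi_kymo`
#' @param positions distances from the shear plane in um (default the six
#'   standard positions 8, 50, 100, 150, 200, 242)
#' @return an `epi_displacement` object: list with `times` (h),
#'   `y_positions` (snapped, um) and `displacement` (um, times x positions
#'   matrix, 0 at the first post-shear frame)
#' @export
integrate_displacement <- function(k, positions = c(8, 50, 100, 150, 200, 242)) {
  stopifnot(inherits(k, "epi_kymo"))
  yp <- k$y_positions
  half <- if (length(yp) > 1) diff(yp)[1] / 2 else Inf
  idx <- vapply(positions, function(p) {
    i <- which.min(abs(yp - p))
    if (abs(yp[i] - p) > half + 1e-9)
      stop("position ", p, " um is beyond the plank; valid range is 0 to ",
           round(max(yp) + half, 2), " um")
    i
  }, integer(1))
  keep <- k$times >= 0
  if (!any(keep)) stop("no post-shear frames to integrate")
  tt <- k$times[keep]
  disp <- vapply(idx, function(i) {
    v <- k$values[keep, i]
    c(0, cumsum(diff(tt) * (head(v, -1) + tail(v, -1)) / 2))
  }, numeric(length(tt)))
  structure(list(times = tt, y_positions = yp[idx],
                 displacement = matrix(disp, nrow = length(tt))),
            class = "epi_displacement")
}

#' Mean collective velocity series
#'
#' Averages a folded, unbinned kymograph across all positions at each time
#' point, yielding the overall y-direction cell velocity series used for
#' damped-sinusoid fitting.
#'
#' @param k a folded `epi_kymo`
#' @return an `epi_mean_velocity` object: list with `times` (h) and
#'   `mean_v` (um/h)
#' @export
mean_velocity_series <- function(k) {
  stopifnot(inherits(k, "epi_kymo"))
  if (!isTRUE(k$folded))
    warning("mean velocity is normally computed on a folded kymograph")
  structure(list(times = k$times, mean_v = rowMeans(k$values)),
            class = "epi_mean_velocity")
}

#' Estimate the propagation speed of the inward wave front
#'
#' Per position, the onset time is the first time the velocity crosses
#' `threshold_frac` times the global maximum absolute velocity with the
#' inward sign (negative, in the folded convention where positive is
#' outward). A least-squares line of position versus onset time is fitted;
#' its slope is the front speed.
#'
#' @param k a folded y-component `epi_kymo` containing a post-shear inward
#'   wave
#' @param threshold_frac onset threshold as a fraction of the global max
#'   absolute velocity (default 0.25)
#' @return list with `speed` (um/h; `Inf` with a warning when onset is
#'   simultaneous at all positions), `onset_times` (h, NA where no onset),
#'   `y_positions`, `r_squared`, and `fit` (the `lm` object, or NULL)
#' @export
estimate_propagation_speed <- function(k, threshold_frac = 0.25) {
  stopifnot(inherits(k, "epi_kymo"))
  keep <- k$times >= 0
  tt <- k$times[keep]
  vals <- k$values[keep, , drop = FALSE]
  thr <- threshold_frac * max(abs(vals))
  onset <- apply(vals, 2, function(v) {
    i_in <- which(v < -thr)   # inward sign only
    if (!length(i_in)) return(NA_real_)
    # the arriving wave is inward: a detection that happens only after the
    # row's first outward excursion belongs to a later oscillation lobe
    i_out <- which(v > thr)
    if (length(i_out) && i_out[1] < i_in[1]) return(NA_real_)
    tt[i_in[1]]
  })
  ok <- !is.na(onset)
  if (sum(ok) < 3L)
    stop("no propagating front: onset detected at fewer than 3 positions")
  if (length(unique(onset[ok])) == 1L) {
    warning("simultaneous onset at all positions; front speed is infinite")
    return(list(speed = Inf, onset_times = onset,
                y_positions = k$y_positions, r_squared = NA_real_, fit = NULL))
  }
  fit <- stats::lm(y ~ t, data = data.frame(y = k$y_positions[ok], t = onset[ok]))
  list(speed = unname(stats::coef(fit)["t"]), onset_times = onset,
       y_positions = k$y_positions, r_squared = summary(fit)$r.squared,
       fit = fit)
}

#' Write a kymograph as CSV (first column `time_h`, one column per position)
#' @param k an `epi_kymo`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_kymograph_csv <- function(k, path) {
  df <- data.frame(time_h = k$times, k$values)
  names(df)[-1] <- sprintf("y_%.2f_um", k$y_positions)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.epi_kymo <- function(x, ...) {
  cat(sprintf("%s-velocity kymograph: %d times x %d positions, %s, bin width %d frame(s)\n",
              x$component, length(x$times), length(x$y_positions),
              if (isTRUE(x$folded)) "folded" else paste0("unfolded (", x$plank, ")"),
              x$bin_width))
  invisible(x)
}

#' Quick-look image of a kymograph
#' @param x an `epi_kymo`
#' @param ... passed to [graphics::image()]
#' @export
plot.epi_kymo <- function(x, ...) {
  graphics::image(x$times, x$y_positions, x$values,
                  xlab = "time (h)", ylab = "distance from shear plane (um)",
                  main = paste0(x$component, "-velocity kymograph"), ...)
  invisible(x)
}
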