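#' Imaging grid and acquisition geometry
#'
#' Describes the PIV output grid for one plank of the shear device and the
#' acquisition timing. The device planks are 1000 x 250 um; the analyzed
#' field of view per plank is `field_width` x `plank_height` um, divided into
#' `n_cols` x `n_rows` PIV interrogation cells. Row centers are measured as
#' distances from the shear plane (the midline between planks), so the first
#' row center sits at half a row height (~8.3 um for the defaults) and the
#' last at ~241.7 um.
#'
#' @param n_cols number of PIV columns across the field width (default 18)
#' @param n_rows number of PIV rows across the plank height (default 15)
#' @param field_width field-of-view width in um (default 300)
#' @param plank_height plank height in um (default 250)
#' @param frame_interval velocity-frame spacing in minutes (default 5)
#' @param sensing_interval force-sensing sampling interval in seconds
#'   (default 30)
#' @param t_start first frame time in hours relative to shear (default -1)
#' @param t_end last frame time in hours relative to shear (default 23.25)
#'
#' @return an object of class `epi_grid`
#' @examples
#' g <- grid_spec()
#' row_centers(g)[c(1, 15)]  # ~8.33 and ~241.67 um
#' @export
grid_spec <- function(n_cols = 18L, n_rows = 15L,
                      field_width = 300, plank_height = 250,
                      frame_interval = 5, sensing_interval = 30,
                      t_start = -1, t_end = 23.25) {
  if (n_cols < 1L || n_rows < 1L)
    stop("grid dimensions must be positive (got ", n_cols, " x ", n_rows, ")")
  if (field_width <= 0 || plank_height <= 0)
    stop("field_width and plank_height must be positive")
  if (frame_interval <= 0)
    stop("frame_interval must be positive")
  if (t_end <= t_start)
    stop("t_end must exceed t_start")
  structure(
    list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         field_width = field_width, plank_height = plank_height,
         frame_interval = frame_interval, sensing_interval = sensing_interval,
         t_start = t_start, t_end = t_end),
    class = "epi_grid")
}

#' Row-center distances from the shear plane
#'
#' @param grid an `epi_grid`
#' @return numeric vector of length `n_rows`, strictly increasing, in um
#' @export
row_centers <- function(grid) {
  h <- grid$plank_height / grid$n_rows
  (seq_len(grid$n_rows) - 0.5) * h
}

#' Velocity-frame times in hours relative to shear
#'
#' @param grid an `epi_grid`
#' @return strictly increasing numeric vector of frame times (h)
#' @export
frame_times <- function(grid) {
  seq(grid$t_start, grid$t_end, by = grid$frame_interval / 60)
}

#' @export
print.epi_grid <- function(x, ...) {
  cat(sprintf("PIV grid: %d x %d cells over %g x %g um, frames every %g min, t in [%g, %g] h\n",
              x$n_cols, x$n_rows, x$field_width, x$plank_height,
              x$frame_interval, x$t_start, x$t_end))
  invisible(x)
}
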