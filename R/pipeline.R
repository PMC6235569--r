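## End-to-end orchestration: generate -> kymograph -> integrate -> fit ->
## force -> model simulation -> condition comparison, with a JSON report.

#' Run the full analysis pipeline on synthetic data
#'
#' For each requested condition, generates `n_replicates` seeded synthetic
#' datasets (replicate seeds are `seed + 1000*replicate +
#' 100000*(condition_index - 1)`, so any replicate can be regenerated in
#' isolation), builds and folds the y-velocity kymograph, fits the damped
#' sinusoid to the mean velocity, detects reversals, estimates the front
#' propagation speed, runs the force-relaxation stage when the condition has
#' a shear step, derives the mechanical-model parameters and simulates the
#' step response. With two or more conditions, the fitted amplitude, period
#' and damping time are compared across conditions with the
#' Kruskal-Wallis/Mann-Whitney procedure.
#'
#' @param conditions character vector of condition names
#' @param out_dir output directory (created if needed)
#' @param seed master seed
#' @param n_replicates replicate datasets per condition (default 3,
#'   matching three independent experiments)
#' @param grid an `epi_grid`
#' @param preset_overrides named list of preset-field overrides applied to
#'   every condition
#' @param k model stiffness held constant across conditions (default 1)
#' @param bin_frames frames per kymograph bin for the binned outputs
#'   (default 3)
#' @param positions displacement-trace positions in um
#' @param write_fields also write the full long-format velocity CSVs
#'   (large; default FALSE)
#' @param quiet suppress stage messages
#' @return an `epi_report` (also written as `report.json` in `out_dir`)
#' @export
run_pipeline <- function(conditions = "+Shear", out_dir = tempfile("epiosc_run_"),
                         seed = 1L, n_replicates = 3L,
                         grid = grid_spec(), preset_overrides = list(),
                         k = 1, bin_frames = 3L,
                         positions = c(8, 50, 100, 150, 200, 242),
                         write_fields = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  config <- list(conditions = conditions, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 grid = unclass(grid), preset_overrides = preset_overrides,
                 k = k, bin_frames = as.integer(bin_frames),
                 positions = positions)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(encode_inf(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  config_hash <- unname(tools::md5sum(cfg_path))

  per_condition <- list()
  fits_by_cond <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    say("condition ", cond)
    preset <- do.call(make_condition_preset, c(list(cond), preset_overrides))
    slug <- gsub("[^A-Za-z0-9]", "", cond)
    reps <- list()
    fits <- list(A = numeric(0), P = numeric(0), D = numeric(0))
    for (r in seq_len(n_replicates)) {
      rep_seed <- as.integer(seed + 1000L * r + 100000L * (ci - 1L))
      stage <- function(name, expr) tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed for ", cond,
             " replicate ", r, ": ", conditionMessage(e)))
      series <- stage("generate",
                      generate_velocity_series(preset, grid, seed = rep_seed))
      files <- list()
      if (write_fields) {
        p <- file.path(out_dir, sprintf("%s_rep%d_fields.csv", slug, r))
        write_velocity_csv(series, p); files$fields <- p
      }
      gt_path <- file.path(out_dir, sprintf("%s_rep%d_ground_truth.json", slug, r))
      write_ground_truth(series$ground_truth, gt_path)
      files$ground_truth <- gt_path

      ky <- stage("kymograph", {
        top <- build_kymograph(series, "y", plank = "top")
        bot <- build_kymograph(series, "y", plank = "bottom")
        fold_kymograph(top, bot)
      })
      ky_path <- file.path(out_dir, sprintf("%s_rep%d_kymo_y.csv", slug, r))
      write_kymograph_csv(bin_kymograph(ky, bin_frames), ky_path)
      files$kymograph <- ky_path

      dtr <- stage("integrate", integrate_displacement(bin_kymograph(ky, bin_frames),
                                                       positions))
      dpath <- file.path(out_dir, sprintf("%s_rep%d_displacement.csv", slug, r))
      df <- data.frame(time_h = dtr$times, dtr$displacement)
      names(df)[-1] <- sprintf("y_%.2f_um", dtr$y_positions)
      utils::write.csv(df, dpath, row.names = FALSE)
      files$displacement <- dpath

      mv <- mean_velocity_series(ky)
      fit <- stage("fit", fit_damped_sinusoid(mv))
      rev <- find_reversals(mv)
      prop <- tryCatch(estimate_propagation_speed(ky)$speed,
                       error = function(e) 0)
      if (!is.finite(prop)) prop <- 0

      force <- NULL
      if (!is.na(preset$tau_force)) {
        tr <- stage("force", generate_sensing_trace(preset, f_max = 1,
                                                    seed = rep_seed))
        ft <- displacement_to_force(tr)
        efit <- stage("force_fit", fit_exponential_decay(ft))
        force <- list(f_max_uN = efit$f_max, f_inf_uN = efit$f_inf,
                      tau_min = efit$tau, rss = efit$rss)
      }
      reps[[r]] <- list(seed = rep_seed, files = files,
                        sine_fit = list(A = fit$A, P = fit$P, D = fit$D,
                                        t0 = fit$t0, v0 = fit$v0,
                                        degenerate = fit$degenerate),
                        reversal_times_h = rev$times,
                        propagation_um_per_h = prop,
                        force = force)
      if (!fit$degenerate) {
        fits$A <- c(fits$A, fit$A); fits$P <- c(fits$P, fit$P)
        fits$D <- c(fits$D, fit$D)
      }
    }
    # model from the first replicate's fit (k held constant across conditions)
    fit1 <- reps[[1]]$sine_fit
    model <- params_from_fit_safe(k, fit1, reps[[1]]$propagation_um_per_h,
                                  sheared = cond != "-Shear")
    sim <- simulate_step_response(model, t_end = 24)
    sim_n <- normalize_response(sim)
    sim_path <- file.path(out_dir, sprintf("%s_sim.csv", slug))
    step <- max(1L, floor(length(sim_n$times) / 2000))
    idx <- seq(1, length(sim_n$times), by = step)
    utils::write.csv(data.frame(time_h = sim_n$times[idx],
                                velocity = sim_n$velocity[idx],
                                velocity_detrended = sim_n$velocity_detrended[idx]),
                     sim_path, row.names = FALSE)
    eq <- equations_of_motion(model)
    per_condition[[cond]] <- list(
      replicates = reps,
      model = list(k = model$k, c = model$c, b = model$b,
                   b_sentinel = model$b_sentinel,
                   zeta = eq$zeta, natural_period_h = natural_period(model),
                   f_int = model$f_int, f_ext = model$f_ext),
      sim_file = sim_path,
      sim_reversals_h = sim_reversal_times(sim_n))
    fits_by_cond[[cond]] <- fits
  }

  comparisons <- NULL
  if (length(conditions) >= 2L) {
    comparisons <- list()
    for (par in c("A", "P", "D")) {
      vals <- lapply(fits_by_cond, `[[`, par)
      vals <- vals[vapply(vals, length, integer(1)) > 0]
      if (length(vals) < 2L) next
      cmp <- compare_conditions(vals, parameter = par)
      comparisons[[par]] <- list(parameter = par,
                                 omnibus = cmp$omnibus,
                                 pairwise = cmp$pairwise)
      if (!is.null(cmp$pairwise)) {
        cpath <- file.path(out_dir, sprintf("comparison_%s.csv", par))
        utils::write.csv(cmp$pairwise, cpath, row.names = FALSE)
      }
    }
  }

  report <- structure(list(package_version = as.character(utils::packageVersion("epiosc")),
                           config = config, config_hash = config_hash,
                           conditions = per_condition,
                           comparisons = comparisons),
                      class = "epi_report")
  jsonlite::write_json(encode_inf(unclass(report)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report$out_dir <- out_dir
  report
}

## params_from_fit tolerant of degenerate (flat) fits: non-oscillating
## conditions get the default period for the sentinel magnitude and a
## damping time of 4 h (the +Shear scale; with the sentinel inerter any
## moderate c is strongly overdamped and the response never reverses).
#' @keywords internal
params_from_fit_safe <- function(k, fit, propagation, sheared = TRUE,
                                 D_fallback = 4) {
  if (is.null(fit$D) || is.na(fit$D) ||
      (propagation <= 0 && is.infinite(fit$D)))
    fit$D <- D_fallback
  params_from_fit(k, fit, propagation, sheared = sheared)
}

#' Load externally supplied velocity fields from long-format CSV
#'
#' Reads the CSV layout written by [write_velocity_csv()] (columns
#' `time_h, plank, row, col, y_um, u_um_per_h, v_um_per_h`), validates it
#' and reconstructs the field sequence. Field width is not recorded in the
#' format and is inferred as `n_cols` times the row height.
#'
#' @param path CSV path
#' @return list of `epi_field`
#' @export
load_external_fields <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "plank", "row", "col", "y_um", "u_um_per_h", "v_um_per_h")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$time_h, df$plank, df$row, df$col)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate (time, plank, row, col) at data line ", i,
         ": ", key[i])
  }
  n_rows <- max(df$row); n_cols <- max(df$col)
  times <- unique(df$time_h)
  if (is.unsorted(times, strictly = TRUE))
    stop("frame times are not strictly increasing in file order")
  ys <- sort(unique(df$y_um))
  if (length(ys) != n_rows)
    stop("non-uniform grid: ", length(ys), " distinct y positions for ",
         n_rows, " rows")
  dy <- if (n_rows > 1) ys[2] - ys[1] else 2 * ys[1]
  grid <- grid_spec(n_cols = n_cols, n_rows = n_rows,
                    field_width = n_cols * dy, plank_height = n_rows * dy,
                    frame_interval = if (length(times) > 1)
                      min(diff(times)) * 60 else 5,
                    t_start = min(times), t_end = max(times))
  fields <- list()
  for (tm in times) {
    for (pl in unique(df$plank[df$time_h == tm])) {
      sub <- df[df$time_h == tm & df$plank == pl, ]
      if (nrow(sub) != n_rows * n_cols)
        stop("non-uniform grid: frame t=", tm, " plank=", pl, " has ",
             nrow(sub), " cells, expected ", n_rows * n_cols)
      u <- matrix(NA_real_, n_rows, n_cols)
      v <- matrix(NA_real_, n_rows, n_cols)
      u[cbind(sub$row, sub$col)] <- sub$u_um_per_h
      v[cbind(sub$row, sub$col)] <- sub$v_um_per_h
      fields[[length(fields) + 1L]] <- structure(
        list(time = tm, plank = pl, u = u, v = v, grid = grid),
        class = "epi_field")
    }
  }
  fields
}

#' Check a pipeline report against the bundled schema
#'
#' Verifies that the report (or a parsed `report.json`) carries the required
#' top-level and per-condition keys listed in the bundled JSON schema
#' (`inst/extdata/report-schema.json`).
#'
#' @param report an `epi_report` or a list parsed from `report.json`
#' @return TRUE invisibly; errors describe any missing key
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "epiosc"),
                                simplifyVector = TRUE)
  need <- schema$required
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop("report is missing required key(s): ", paste(miss, collapse = ", "))
  cond_need <- schema$properties$conditions$required_each
  for (nm in names(report$conditions)) {
    miss <- setdiff(cond_need, names(report$conditions[[nm]]))
    if (length(miss))
      stop("condition '", nm, "' is missing key(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.epi_report <- function(x, ...) {
  cat("epiosc pipeline report (config hash ", x$config_hash, ")\n", sep = "")
  for (nm in names(x$conditions)) {
    cnd <- x$conditions[[nm]]
    f1 <- cnd$replicates[[1]]$sine_fit
    cat(sprintf("  %s: %d replicate(s); A = %.3g um/h, P = %.3g h, D = %.3g h; zeta = %.3g\n",
                nm, length(cnd$replicates), f1$A, f1$P, f1$D, cnd$model$zeta))
  }
  invisible(x)
}
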