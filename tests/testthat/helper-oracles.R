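# Independent oracles and small fixtures, built in code at test time.

# Brute-force Mann-Whitney: exact one- and two-sided p-values by full
# enumeration of all C(n1+n2, n1) group assignments of the pooled ranks.
# Statistic U = (number of (x, y) pairs with x > y), i.e. wilcox.test's W
# for the first sample.
brute_force_mw <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_stat <- function(ix) {
    xs <- pool[ix]; ys <- pool[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_stat)
  p_less <- mean(all_u <= u_obs)
  p_greater <- mean(all_u >= u_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# Trapezoid cumulative integral (independent of the package's version).
trapz_cum <- function(t, v) c(0, cumsum(diff(t) * (v[-length(v)] + v[-1]) / 2))

# Small grid for fast property loops: full plank height (so positions snap
# as in the default geometry) but few columns and a short record.
small_grid <- function(t_end = 23.25, n_cols = 4L)
  grid_spec(n_cols = n_cols, n_rows = 15L, t_end = t_end)

# Folded y-kymograph for a condition, noiseless unless stated.
folded_kymo <- function(cond = "+Shear", noise_sd = 0, seed = 1,
                        grid = grid_spec(), ...) {
  p <- make_condition_preset(cond, noise_sd = noise_sd, ...)
  s <- generate_velocity_series(p, grid, seed = seed)
  fold_kymograph(build_kymograph(s, "y", plank = "top"),
                 build_kymograph(s, "y", plank = "bottom"))
}

# Hand-built kymograph from an explicit value matrix (times x positions).
kymo_from_matrix <- function(values, times, y_pos, component = "y",
                             folded = TRUE) {
  epiosc:::new_kymograph(component, times, y_pos, values, folded = folded)
}
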