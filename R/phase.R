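## Phase-diagram grids over (Hill coefficient, fold change): bistability
## regimes, maximal sensitivity, stochastic mean induction time, and their
## intersection -- the admissible parameter region for a signalling circuit
## that must be monostable, sensitive, fast, and meaningfully inducible.

default_n_axis <- function() seq(1, 4, length.out = 33)
default_f_axis <- function() 10^seq(0, 3, length.out = 41)

phase_grid <- function(n_axis, f_axis, values, what, fixed_params) {
  stopifnot(!is.unsorted(n_axis), !is.unsorted(f_axis),
            nrow(values) == length(n_axis), ncol(values) == length(f_axis))
  out <- list(n_axis = n_axis, f_axis = f_axis, values = values,
              what = what, fixed_params = fixed_params)
  class(out) <- "phase_grid"
  out
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("Phase grid (%s): %d Hill coefficients x %d fold changes\n",
              x$what, length(x$n_axis), length(x$f_axis)))
  invisible(x)
}

#' Convert a phase grid to a long-format data frame
#'
#' @param x A `phase_grid`.
#' @param ... Unused.
#' @return Data frame with columns `hill_n`, `fold`, `value` (one row per
#'   grid cell, `|n_axis| * |f_axis|` rows).
#' @export
as.data.frame.phase_grid <- function(x, ...) {
  data.frame(hill_n = rep(x$n_axis, times = length(x$f_axis)),
             fold = rep(x$f_axis, each = length(x$n_axis)),
             value = as.vector(x$values), stringsAsFactors = FALSE)
}

with_fold_n <- function(p, fold, hill_n) {
  circuit_params(alpha_max = p$alpha_max, fold = fold, hill_n = hill_n,
                 K = p$K, beta = p$beta, burst = p$burst, volume = p$volume)
}

#' Bistability regime map
#'
#' Classifies every (n, f) cell into regime I (monostable for all inputs),
#' II (bistable input window, not at saturation) or III (bistable at
#' saturating input), at the composite `c` implied by the fixed parameters.
#' The closed-form I/(II,III) boundary [critical_fold()] is returned
#' alongside.
#'
#' @param n_axis,f_axis Grid axes (defaults: n in `[1, 4]`, 33 points; f in
#'   `[1, 1e3]` log-spaced, 41 points).
#' @param p A [circuit_params()] object supplying the non-varying fields.
#' @return A `phase_grid` of regime labels with an extra element
#'   `boundary` (data frame `hill_n`, `f_c`).
#' @export
bistability_map <- function(p, n_axis = default_n_axis(),
                            f_axis = default_f_axis()) {
  p <- as_circuit_params(p)
  vals <- matrix(NA_character_, length(n_axis), length(f_axis))
  for (i in seq_along(n_axis))
    for (j in seq_along(f_axis))
      vals[i, j] <- as.character(
        classify_regime(with_fold_n(p, f_axis[j], n_axis[i])))
  g <- phase_grid(n_axis, f_axis, vals, "regime", p)
  g$boundary <- data.frame(hill_n = n_axis, f_c = critical_fold(n_axis))
  g
}

#' Maximal-sensitivity map
#'
#' [smax_closed_form()] per cell; cells at or beyond the bistability boundary
#' are `NA` (masked as bistable, where the measure is undefined). The flag
#' matrix `shaded` marks cells with `s_max >= s_cutoff` — to be sensitive the
#' circuit must sit close to the bistability line, inside this shaded band.
#'
#' @inheritParams bistability_map
#' @param s_cutoff Sensitivity cutoff for the shaded region (default 3).
#' @return A `phase_grid` of `s_max` values with element `shaded`
#'   (logical matrix).
#' @export
sensitivity_map <- function(p, n_axis = default_n_axis(),
                            f_axis = default_f_axis(), s_cutoff = 3) {
  p <- as_circuit_params(p)
  vals <- matrix(NA_real_, length(n_axis), length(f_axis))
  for (i in seq_along(n_axis)) {
    fc <- critical_fold(n_axis[i])
    ok <- f_axis < fc
    if (any(ok))
      vals[i, ok] <- vapply(f_axis[ok], smax_closed_form, numeric(1),
                            hill_n = n_axis[i])
  }
  g <- phase_grid(n_axis, f_axis, vals, "s_max", p)
  g$s_cutoff <- s_cutoff
  g$shaded <- !is.na(vals) & vals >= s_cutoff
  g
}

#' Stochastic mean-induction-time map
#'
#' [mean_induction_time()] per cell (first-passage solve of the master
#' equation), with `alpha_max` held fixed as the fold change varies — the
#' induced expression level is treated as prescribed by the circuit's
#' function, so raising the fold change lowers the basal rate. Values are in
#' the time units of the rate parameters (minutes for the shipped presets).
#' Cells deep in the bistable regime produce very large but finite
#' first-passage times; per-cell failures are recorded as `NA`, not raised.
#'
#' @inheritParams bistability_map
#' @param level Threshold fraction (default 0.5).
#' @param t_cap Optional early-exit cap: once a cell in a row (scanning
#'   upward in fold) exceeds `t_cap`, higher folds in that row — where the
#'   time can only be larger — are filled with `Inf` instead of being solved.
#'   Default NULL (solve every cell).
#' @return A `phase_grid` of mean induction times.
#' @export
induction_map <- function(p, n_axis = default_n_axis(),
                          f_axis = default_f_axis(), level = 0.5,
                          t_cap = NULL) {
  p <- as_circuit_params(p)
  vals <- matrix(NA_real_, length(n_axis), length(f_axis))
  for (i in seq_along(n_axis)) {
    over <- FALSE
    for (j in seq_along(f_axis)) {
      if (over) { vals[i, j] <- Inf; next }
      vals[i, j] <- tryCatch(
        mean_induction_time(with_fold_n(p, f_axis[j], n_axis[i]),
                            level = level, cv = FALSE)$mean_time,
        error = function(e) NA_real_)
      if (!is.null(t_cap) && is.finite(vals[i, j]) && vals[i, j] > t_cap)
        over <- TRUE
    }
  }
  phase_grid(n_axis, f_axis, vals, "mean_induction_time", p)
}

#' Admissible parameter region
#'
#' A cell (n, f) is admissible iff the circuit is deterministically
#' monostable (regime I), sensitive (`s_max >= s_cutoff`), reasonably fast
#' (stochastic mean induction time `<= t_max`), and has a non-negligible fold
#' change (`f >= f_min`). The admissible set is by construction the
#' cell-by-cell intersection of the three constituent maps' admissible sets
#' with the fold floor.
#'
#' @inheritParams bistability_map
#' @param s_cutoff Sensitivity cutoff (default 3).
#' @param t_max Maximum admissible mean induction time, in the rate
#'   parameters' time units (default 50).
#' @param f_min Minimum meaningful fold change (default 10).
#' @param maps Optional precomputed list with elements `bistability`,
#'   `sensitivity`, `induction` (matching grids) to avoid recomputation.
#' @return A `phase_grid` of logical admissibility flags, with a `summary`
#'   list: `max_fold` (largest admissible f; `-Inf` if the region is empty),
#'   `n_range` (range of admissible n), `n_cells`, and `constraints`.
#' @export
admissible_region <- function(p, n_axis = default_n_axis(),
                              f_axis = default_f_axis(), s_cutoff = 3,
                              t_max = 50, f_min = 10, maps = NULL) {
  p <- as_circuit_params(p)
  if (is.null(maps)) {
    maps <- list(bistability = bistability_map(p, n_axis, f_axis),
                 sensitivity = sensitivity_map(p, n_axis, f_axis, s_cutoff),
                 induction = induction_map(p, n_axis, f_axis, t_cap = t_max))
  }
  mono <- maps$bistability$values == "I"
  sens <- !is.na(maps$sensitivity$values) &
    maps$sensitivity$values >= s_cutoff
  fast <- is.finite(maps$induction$values) & maps$induction$values <= t_max
  fold_ok <- matrix(rep(f_axis >= f_min, each = length(n_axis)),
                    length(n_axis), length(f_axis))
  adm <- mono & sens & fast & fold_ok
  g <- phase_grid(n_axis, f_axis, adm, "admissible", p)
  idx <- which(adm, arr.ind = TRUE)
  g$summary <- list(
    max_fold = if (nrow(idx)) max(f_axis[idx[, 2]]) else -Inf,
    n_range = if (nrow(idx)) range(n_axis[idx[, 1]]) else c(NA, NA),
    n_cells = nrow(idx),
    constraints = list(s_cutoff = s_cutoff, t_max = t_max, f_min = f_min))
  g$maps <- maps
  g
}
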