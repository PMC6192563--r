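#' Global coupling sweep
#'
#' Simulates the resting network (no external input) across an ascending grid
#' of global coupling values `c5` and records the mean excitatory activity
#' (averaged over all regions and all post-stabilization samples) at each
#' grid point. The resulting activity-vs-coupling curve exhibits an abrupt
#' jump where the network transitions from near-fixed-point dynamics to a
#' high-amplitude oscillatory ("excited") state; [detect_transition()] reads
#' the subject-specific transition value c5T off this curve.
#'
#' The conventional grid spans 0.05 to 0.25 at step 0.001; coarser grids
#' trade c5T resolution for runtime.
#'
#' @param conn a `connectome`.
#' @param params a [wc_params()].
#' @param grid ascending numeric vector of c5 values (default
#'   `seq(0.05, 0.25, by = 0.001)`).
#' @param sim_ms analysis window per grid point (ms, after the 1 s
#'   stabilization).
#' @param seed integer seed; each grid point uses a seed derived from it.
#' @param stabilize_ms stabilization window (ms).
#' @return object of class `sweep_curve`: data.frame with columns `c5`,
#'   `mean_activity`, `seed`, plus attribute `grid_step`.
#' @export
sweep_coupling <- function(conn, params, grid = seq(0.05, 0.25, by = 0.001),
                           sim_ms = 1000, seed = 1L, stabilize_ms = 1000) {
  stopifnot(length(grid) >= 1)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly ascending")
  act <- numeric(length(grid))
  seeds <- vapply(seq_along(grid), function(k) derive_seed(seed, k), 1L)
  for (k in seq_along(grid)) {
    tr <- simulate_network(conn, params, grid[k], schedule = NULL,
                           duration_ms = sim_ms, seed = seeds[k],
                           stabilize_ms = stabilize_ms)
    act[k] <- mean(tr$E)
  }
  curve <- data.frame(c5 = grid, mean_activity = act, seed = seeds)
  class(curve) <- c("sweep_curve", "data.frame")
  attr(curve, "grid_step") <- if (length(grid) > 1) stats::median(diff(grid))
                              else NA_real_
  curve
}

#' Detect the excitability transition value c5T
#'
#' Identifies the sudden increase in mean activity along a coupling sweep:
#' the largest forward difference of the curve, required to exceed
#' `jump_factor` times the median absolute forward difference. c5T is the
#' grid value at the left edge of that jump (the largest coupling before the
#' excited state); ties break toward smaller c5. Detection is invariant to
#' affine rescaling of the activity axis.
#'
#' @param curve a `sweep_curve` (length >= 3).
#' @param jump_factor required jump size relative to the median absolute
#'   forward difference (default 5).
#' @param rule `"largest"` (default) reads the maximal forward difference —
#'   the global transition to the excited state. `"first"` takes the
#'   smallest c5 whose forward difference qualifies, which marks the onset
#'   of any ignition; in networks with a strongly coupled subcircuit that
#'   ignites before the bulk, this is the last coupling at which the whole
#'   network is still quiescent, the state the stimulation protocol
#'   requires.
#' @return c5T, the transition coupling value (scalar).
#' @export
detect_transition <- function(curve, jump_factor = 5,
                              rule = c("largest", "first")) {
  rule <- match.arg(rule)
  if (nrow(curve) < 3) stop("sweep curve must have at least 3 points")
  d <- diff(curve$mean_activity)
  med <- stats::median(abs(d))
  qualifies <- d > 0 & d >= jump_factor * med
  if (!any(qualifies))
    stop("no transition detected: largest jump ",
         signif(max(d), 3), " is below ", jump_factor,
         " times the median absolute difference ", signif(med, 3))
  k <- if (rule == "largest") which.max(d) else which(qualifies)[1]
  curve$c5[k]
}

#' Sweep and detect in one call
#'
#' @inheritParams sweep_coupling
#' @inheritParams detect_transition
#' @return list with `c5T` and the `curve`.
#' @export
transition_value <- function(conn, params, grid = seq(0.05, 0.25, by = 0.001),
                             sim_ms = 1000, seed = 1L, jump_factor = 5) {
  curve <- sweep_coupling(conn, params, grid, sim_ms = sim_ms, seed = seed)
  list(c5T = detect_transition(curve, jump_factor), curve = curve)
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("coupling sweep: %d points, c5 in [%.4g, %.4g]\n",
              nrow(x), min(x$c5), max(x$c5)))
  cat(sprintf("  mean activity in [%.4g, %.4g]\n",
              min(x$mean_activity), max(x$mean_activity)))
  invisible(x)
}

#' @export
plot.sweep_curve <- function(x, ...) {
  plot(x$c5, x$mean_activity, type = "b", pch = 16, cex = 0.6,
       xlab = expression(c[5]), ylab = "mean excitatory activity", ...)
  invisible(x)
}
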