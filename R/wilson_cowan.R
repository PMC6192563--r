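#' Wilson-Cowan model parameters
#'
#' Constants of the delay-coupled Wilson-Cowan neural-mass model. Each region
#' carries an excitatory fraction `E_i(t)` and an inhibitory fraction
#' `I_i(t)` evolving as
#'
#' \deqn{\tau \dot E_i = -E_i + (S_E^{max} - E_i)\,
#'   S_E(c_1 E_i - c_2 I_i + c_5 \textstyle\sum_j A_{ij} E_j(t-\tau_{ij})
#'   + P_i(t)) + \sigma w_i(t)}
#' \deqn{\tau \dot I_i = -I_i + (S_I^{max} - I_i)\,
#'   S_I(c_3 E_i - c_4 I_i + c_6 \textstyle\sum_j A_{ij} I_j(t-\tau_{ij}))
#'   + \sigma v_i(t)}
#'
#' with the shifted sigmoid of [wc_sigmoid()], inter-regional conduction
#' delays `tau_ij = d_ij / t_d`, and inhibitory coupling locked to the
#' excitatory one by `c6 = c6_ratio * c5`. Defaults are the biologically
#' derived constants standard for this model. Time is in milliseconds
#' (`tau = 8` ms; `t_d = 10` mm/ms, i.e. 10 m/s).
#'
#' @param c1,c2,c3,c4 local excitatory/inhibitory coupling gains.
#' @param a_E,a_I sigmoid slopes.
#' @param theta_E,theta_I sigmoid thresholds.
#' @param tau relaxation time constant (ms).
#' @param sigma additive noise amplitude (one `sigma * N(0,1)` increment per
#'   state variable per integration step).
#' @param t_d signal transmission velocity (mm/ms).
#' @param step_h integration step (ms) of the second-order Runge-Kutta
#'   scheme.
#' @param c6_ratio ratio `c6 / c5` (approximate inhibitory-to-excitatory
#'   coupling ratio).
#' @return object of class `wc_params`; includes the derived sigmoid ceilings
#'   `S_E_max`, `S_I_max` (`1 - 1/(1 + exp(a * theta))`).
#' @export
wc_params <- function(c1 = 16, c2 = 12, c3 = 15, c4 = 3,
                      a_E = 1.3, a_I = 2, theta_E = 4, theta_I = 3.7,
                      tau = 8, sigma = 1e-5, t_d = 10, step_h = 0.1,
                      c6_ratio = 0.25) {
  stopifnot(c1 > 0, c2 > 0, c3 > 0, c4 > 0, a_E > 0, a_I > 0,
            tau > 0, step_h > 0, sigma >= 0, t_d > 0, c6_ratio > 0)
  structure(
    list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
         a_E = a_E, a_I = a_I, theta_E = theta_E, theta_I = theta_I,
         tau = tau, sigma = sigma, t_d = t_d, step_h = step_h,
         c6_ratio = c6_ratio,
         S_E_max = 1 - 1 / (1 + exp(a_E * theta_E)),
         S_I_max = 1 - 1 / (1 + exp(a_I * theta_I))),
    class = "wc_params"
  )
}

#' Shifted sigmoid activation
#'
#' `S(x) = 1/(1 + exp(-a (x - theta))) - 1/(1 + exp(a theta))`. The
#' subtracted constant enforces `S(0) = 0`, so the origin is an equilibrium
#' of the uncoupled model; the supremum is `S_max = 1 - 1/(1 + exp(a theta))`.
#'
#' @param x input (population drive).
#' @param a slope.
#' @param theta threshold.
#' @return sigmoid value(s), in `(-1/(1+exp(a theta)), S_max)`.
#' @examples
#' wc_sigmoid(0, 1.3, 4)           # 0
#' wc_sigmoid(4, 1.3, 4)           # ~0.4945
#' @export
wc_sigmoid <- function(x, a, theta) {
  1 / (1 + exp(-a * (x - theta))) - 1 / (1 + exp(a * theta))
}

#' Wilson-Cowan drift (deterministic right-hand side)
#'
#' Evaluates `dE/dt` and `dI/dt` for all regions at one time point, given the
#' delayed activity of every source region. Noise is excluded (the integrator
#' adds it). This reference implementation is plain R and vectorized; the
#' production integrator is compiled and is checked against it.
#'
#' @param E,I length-n current state vectors.
#' @param E_delayed,I_delayed n x n matrices with entry `[i, j]` the activity
#'   of region `j` at `t - tau_ij` (the delay relevant to target `i`).
#' @param A n x n weight matrix.
#' @param c5 global excitatory coupling strength (`c6 = c6_ratio * c5`).
#' @param params a [wc_params()].
#' @param P length-n external input vector (or scalar).
#' @return list with vectors `dE`, `dI`.
#' @export
wc_derivatives <- function(E, I, E_delayed, I_delayed, A, c5, params, P = 0) {
  p <- params
  couplE <- rowSums(A * E_delayed)
  couplI <- rowSums(A * I_delayed)
  argE <- p$c1 * E - p$c2 * I + c5 * couplE + P
  argI <- p$c3 * E - p$c4 * I + p$c6_ratio * c5 * couplI
  list(dE = (-E + (p$S_E_max - E) * wc_sigmoid(argE, p$a_E, p$theta_E)) / p$tau,
       dI = (-I + (p$S_I_max - I) * wc_sigmoid(argI, p$a_I, p$theta_I)) / p$tau)
}

#' Piecewise-constant stimulation schedule
#'
#' External input `P_i(t)` applied to a set of target regions over a time
#' interval. Times are in ms relative to the start of the analysis window
#' (after the stabilization period).
#'
#' @param targets a `region_set` or character vector of region labels.
#' @param amplitude input amplitude (the stimulation protocol uses 1.15).
#' @param onset_ms,offset_ms interval bounds (`onset_ms < offset_ms`).
#' @return object of class `stim_schedule`. Schedules can be combined with
#'   `c()`.
#' @export
stim_schedule <- function(targets, amplitude, onset_ms, offset_ms) {
  if (inherits(targets, "region_set")) targets <- targets$labels
  stopifnot(length(targets) > 0, is.finite(amplitude),
            onset_ms < offset_ms)
  structure(
    list(data.frame(label = as.character(targets), amplitude = amplitude,
                    onset_ms = onset_ms, offset_ms = offset_ms)),
    class = "stim_schedule"
  )
}

#' @export
c.stim_schedule <- function(...) {
  parts <- lapply(list(...), unclass)
  structure(do.call(c, parts), class = "stim_schedule")
}

schedule_matrix <- function(schedule, conn, stabilize_ms, step_h) {
  if (is.null(schedule)) return(matrix(0, 0, 4))
  rows <- do.call(rbind, lapply(unclass(schedule), function(d) {
    idx <- match(d$label, conn$labels)
    if (anyNA(idx))
      stop("schedule targets not in connectome: ",
           paste(d$label[is.na(idx)], collapse = ", "))
    cbind(idx - 1L, d$amplitude,
          round((d$onset_ms + stabilize_ms) / step_h),
          round((d$offset_ms + stabilize_ms) / step_h))
  }))
  rows
}

#' Simulate delay-coupled Wilson-Cowan dynamics on a connectome
#'
#' Integrates the network model with a stochastic second-order (midpoint)
#' Runge-Kutta scheme at step `params$step_h` (0.1 ms), initial conditions
#' `E_i(0) = I_i(0) = 0.1` (also filling the pre-`t = 0` delay history), and
#' per-pair conduction delays `round(d_ij / t_d / step_h)` steps. The first
#' `stabilize_ms` of the run are discarded unless `keep_transient = TRUE`;
#' trace time is reported relative to the end of stabilization.
#'
#' @param conn a `connectome`.
#' @param params a [wc_params()].
#' @param c5 global coupling strength (>= 0).
#' @param schedule optional [stim_schedule()]; `NULL` means no external input.
#' @param duration_ms analysis window length after stabilization (ms).
#' @param seed integer seed for the noise stream (required when
#'   `params$sigma > 0` for reproducibility; ignored if sigma is 0).
#' @param stabilize_ms stabilization window (default 1000 ms).
#' @param keep_transient keep the stabilization segment in the returned
#'   trace (its time axis then starts at `-stabilize_ms`).
#' @return object of class `sim_trace`: list with `time_ms`, matrices `E`,
#'   `I` (regions x time), `labels`, `step_h`, `c5`, `seed`, `schedule`.
#' @export
simulate_network <- function(conn, params, c5, schedule = NULL,
                             duration_ms = 1000, seed = NULL,
                             stabilize_ms = 1000, keep_transient = FALSE) {
  stopifnot(inherits(conn, "connectome"), inherits(params, "wc_params"),
            c5 >= 0, duration_ms > 0, stabilize_ms >= 0)
  h <- params$step_h
  n_steps <- round((stabilize_ms + duration_ms) / h)
  Dsteps <- matrix(as.integer(round(conn$distances / params$t_d / h)),
                   nrow(conn$A))
  sched <- schedule_matrix(schedule, conn, stabilize_ms, h)
  par <- c(params, list(c5 = c5, c6 = params$c6_ratio * c5))
  out <- with_seed(seed, wc_integrate(conn$A, Dsteps, par, sched,
                                      n_steps, 0.1))
  time_ms <- seq(0, n_steps) * h - stabilize_ms
  if (!keep_transient) {
    keep <- time_ms >= 0
    out$E <- out$E[, keep, drop = FALSE]
    out$I <- out$I[, keep, drop = FALSE]
    time_ms <- time_ms[keep]
  }
  rownames(out$E) <- rownames(out$I) <- conn$labels
  structure(
    list(time_ms = time_ms, E = out$E, I = out$I, labels = conn$labels,
         step_h = h, c5 = c5, seed = seed, schedule = schedule),
    class = "sim_trace"
  )
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf(
    "Wilson-Cowan trace: %d regions, %.0f ms at %.1f ms step (c5 = %.4g)\n",
    nrow(x$E), diff(range(x$time_ms)), x$step_h, x$c5))
  invisible(x)
}

#' Extract a time window from a trace
#'
#' @param trace a `sim_trace`.
#' @param from_ms,to_ms window bounds in trace time (`from_ms <= t < to_ms`).
#' @return a `sim_trace` restricted to the window.
#' @export
trace_window <- function(trace, from_ms, to_ms) {
  keep <- trace$time_ms >= from_ms & trace$time_ms < to_ms
  if (!any(keep)) stop("empty trace window")
  trace$time_ms <- trace$time_ms[keep]
  trace$E <- trace$E[, keep, drop = FALSE]
  trace$I <- trace$I[, keep, drop = FALSE]
  trace
}

#' Time-averaged regional excitatory activity
#'
#' @param trace a `sim_trace`.
#' @return named vector of per-region time means of `E`.
#' @export
regional_activity <- function(trace) rowMeans(trace$E)
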