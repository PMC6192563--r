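#' Run the targeted stimulation experiment
#'
#' Implements the in-silico stimulation protocol: the global coupling is
#' fixed just below the subject's transition value (one sweep-grid step below
#' c5T, the state of maximal sensitivity to perturbation), the system is
#' stabilized for 1 s, evolves 1 s without external input, and then receives
#' a constant external input (default `P = 1.15`) on the target regions for
#' 1 s. The two 1 s analysis segments ("pre" and "during") are returned.
#'
#' @param conn a `connectome`.
#' @param params a [wc_params()].
#' @param c5T the subject's transition value (from [detect_transition()]).
#' @param targets a `region_set` of stimulation targets (e.g. the four
#'   left-inferior-frontal-gyrus regions).
#' @param seed integer noise seed.
#' @param amplitude stimulation amplitude (default 1.15).
#' @param grid_step sweep grid step defining "just below" (default 0.001).
#' @param segment_ms length of each analysis segment (default 1000 ms).
#' @return list with `sim_trace` elements `pre` and `during`, and the `c5`
#'   actually used.
#' @export
run_stimulation_experiment <- function(conn, params, c5T, targets, seed,
                                       amplitude = 1.15, grid_step = 0.001,
                                       segment_ms = 1000) {
  stopifnot(inherits(targets, "region_set"))
  region_indices(targets, conn)  # validates membership
  c5 <- c5T - grid_step
  if (c5 < 0) stop("c5T - grid_step is negative")
  sched <- stim_schedule(targets, amplitude,
                         onset_ms = segment_ms, offset_ms = 2 * segment_ms)
  tr <- simulate_network(conn, params, c5, schedule = sched,
                         duration_ms = 2 * segment_ms, seed = seed)
  list(pre = trace_window(tr, 0, segment_ms),
       during = trace_window(tr, segment_ms, 2 * segment_ms),
       c5 = c5)
}

#' Maximum-lagged-cross-correlation functional connectivity
#'
#' For each region pair, computes the Pearson correlation between the two
#' excitatory time series at every integer lag within `max_lag_ms` (on
#' overlapping samples, no padding) and keeps the signed maximum over lags.
#' The trace is sampled at `stride_ms` before correlation (the integration
#' grid is finer than any dynamics of interest; the stride is recorded in
#' the output). Pairs involving a constant signal are undefined (`NA`).
#'
#' @param trace a `sim_trace` segment.
#' @param window_ms correlation window length (default 1000 ms); the first
#'   `window_ms` of the segment are used and must fit inside it.
#' @param max_lag_ms maximum lag scanned in both directions (default 250 ms).
#' @param stride_ms sampling stride (default 1 ms).
#' @return n x n matrix of class `fc_matrix` with values in `[-1, 1]` (or
#'   `NA`), unit diagonal where defined; attributes `window_ms`,
#'   `max_lag_ms`, `stride_ms`.
#' @export
functional_connectivity <- function(trace, window_ms = 1000,
                                    max_lag_ms = 250, stride_ms = 1) {
  stride_steps <- max(1L, as.integer(round(stride_ms / trace$step_h)))
  n_samp <- floor(window_ms / (trace$step_h * stride_steps))
  if (1L + (n_samp - 1L) * stride_steps > length(trace$time_ms))
    stop("window (", window_ms, " ms) longer than trace segment (",
         round(diff(range(trace$time_ms))), " ms)")
  idx <- seq(1L, by = stride_steps, length.out = n_samp)
  X <- t(trace$E[, idx, drop = FALSE])
  max_lag <- as.integer(round(max_lag_ms / (trace$step_h * stride_steps)))
  FC <- fc_max_lag(X, max_lag)
  dimnames(FC) <- list(trace$labels, trace$labels)
  structure(FC, window_ms = window_ms, max_lag_ms = max_lag_ms,
            stride_ms = stride_ms, class = c("fc_matrix", "matrix", "array"))
}

#' Stimulation-induced change in functional connectivity
#'
#' `delta_fc` is the pairwise difference between functional connectivity
#' during and before stimulation. [functional_effect()] averages it over a
#' scope.
#'
#' @param experiment output of [run_stimulation_experiment()] (or any list
#'   with `pre` and `during` trace segments).
#' @inheritParams functional_connectivity
#' @return list of class `stim_result`: `delta` (n x n during - pre),
#'   `fc_pre`, `fc_during`, `c5`.
#' @export
delta_fc <- function(experiment, window_ms = 1000, max_lag_ms = 250,
                     stride_ms = 1) {
  fc_pre <- functional_connectivity(experiment$pre, window_ms, max_lag_ms,
                                    stride_ms)
  fc_during <- functional_connectivity(experiment$during, window_ms,
                                       max_lag_ms, stride_ms)
  structure(
    list(delta = unclass(fc_during) - unclass(fc_pre),
         fc_pre = fc_pre, fc_during = fc_during,
         c5 = experiment$c5),
    class = "stim_result"
  )
}

#' Functional effect of stimulation over a scope
#'
#' Averages the change in functional connectivity over a set of unordered
#' off-diagonal region pairs: all pairs (`"global"`), pairs with both
#' endpoints inside a circuit (a `region_set`), or pairs with both endpoints
#' outside it (`scope = "outside"` with `circuit` given). Cross pairs (one
#' endpoint in, one out) belong to neither restricted scope. Undefined pairs
#' are excluded from the average.
#'
#' @param delta n x n change-in-FC matrix (or a `stim_result`).
#' @param scope `"global"`, `"outside"`, or a `region_set`.
#' @param circuit the `region_set` defining inside/outside when
#'   `scope = "outside"`.
#' @return scalar mean change in FC.
#' @export
functional_effect <- function(delta, scope = "global", circuit = NULL) {
  if (inherits(delta, "stim_result")) delta <- delta$delta
  n <- nrow(delta)
  labs <- rownames(delta)
  if (inherits(scope, "region_set")) {
    idx <- match(scope$labels, labs)
    if (anyNA(idx)) stop("scope labels absent from the matrix")
    if (length(idx) < 2) stop("scope must contain at least 2 regions")
    sub <- delta[idx, idx, drop = FALSE]
  } else if (identical(scope, "outside")) {
    if (!inherits(circuit, "region_set"))
      stop("scope = \"outside\" needs a circuit region set")
    idx <- setdiff(seq_len(n), match(circuit$labels, labs))
    if (length(idx) < 2) stop("scope must contain at least 2 regions")
    sub <- delta[idx, idx, drop = FALSE]
  } else if (identical(scope, "global")) {
    sub <- delta
  } else stop("scope must be \"global\", \"outside\", or a region_set")
  vals <- sub[upper.tri(sub)]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Functional effects at the three standard scopes
#'
#' @param result a `stim_result` from [delta_fc()].
#' @param circuit a `region_set` task circuit.
#' @return named list: `global`, `circuit`, `outside`.
#' @export
functional_effects <- function(result, circuit) {
  list(global = functional_effect(result, "global"),
       circuit = functional_effect(result, circuit),
       outside = functional_effect(result, "outside", circuit = circuit))
}

#' Cross-subject variability of regional functional connectivity
#'
#' For each subject, each region is summarized by its mean functional
#' connectivity to all other regions; the map is the standard deviation of
#' that summary across subjects divided by its mean (sample sd). Regions
#' with zero mean are flagged `NA`.
#'
#' @param fc_list list (one per subject) of `fc_matrix` objects sharing
#'   labels.
#' @return named per-region vector.
#' @export
fc_variability <- function(fc_list) {
  if (length(fc_list) < 2) stop("variability needs at least 2 subjects")
  reg <- vapply(fc_list,
                function(fc) rowMeans(strip_diag(unclass(fc)), na.rm = TRUE),
                numeric(nrow(fc_list[[1]])))
  ratio_map(reg)
}

#' Cross-subject variability of regional activity
#'
#' Analogous to [fc_variability()] but applied to the time-averaged
#' excitatory activity of each region: sd across subjects of the regional
#' mean activity, divided by its mean across subjects.
#'
#' @param traces list (one per subject) of `sim_trace` objects sharing
#'   labels.
#' @return named per-region vector.
#' @export
functional_variability <- function(traces) {
  if (length(traces) < 2) stop("variability needs at least 2 subjects")
  reg <- vapply(traces, regional_activity, numeric(nrow(traces[[1]]$E)))
  ratio_map(reg)
}

strip_diag <- function(m) { diag(m) <- NA_real_; m }

# rows: regions, cols: subjects -> per-region sd/mean across subjects
ratio_map <- function(reg) {
  mu <- rowMeans(reg)
  sd <- apply(reg, 1, stats::sd)
  out <- sd / mu
  out[mu == 0] <- NA_real_
  out
}
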